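## Classical two-stage multi-detection pipeline: intensity segmentation of the
## three echogenic structures (ilium, acetabulum, labrum), conversion to a
## white-on-black stage-1 image, and keypoint extraction from the structure
## masks. Deterministic, so it doubles as the reference against which the
## trainable detector is compared.

#' Per-structure binary masks with detection confidences
#'
#' @param ilium,acetabulum,labrum logical matrices of identical dimensions
#'   (or `NULL` when the structure was not found).
#' @param confidence named numeric vector of per-structure confidences in
#'   \[0, 1\].
#' @param complete logical; all three structures found?
#' @return object of class `structure_mask_set`.
#' @export
structure_mask_set <- function(ilium = NULL, acetabulum = NULL, labrum = NULL,
                               confidence = c(ilium = 0, acetabulum = 0,
                                              labrum = 0),
                               complete = !is.null(ilium) &&
                                 !is.null(acetabulum) && !is.null(labrum)) {
  masks <- list(ilium = ilium, acetabulum = acetabulum, labrum = labrum)
  dims <- lapply(Filter(Negate(is.null), masks), dim)
  if (length(dims) > 1 && !all(vapply(dims, identical, TRUE, dims[[1]]))) {
    stop("structure_mask_set: masks must share image dimensions",
         call. = FALSE)
  }
  if (any(confidence < 0 | confidence > 1)) {
    stop("structure_mask_set: confidences must lie in [0, 1]", call. = FALSE)
  }
  structure(list(masks = masks, confidence = confidence,
                 complete = isTRUE(complete)),
            class = "structure_mask_set")
}

## component features from a label matrix: area, centroid, principal axis;
## labels with fewer than min_area pixels are dropped before any costly work
.component_features <- function(lab, img, min_area = 1) {
  idx_all <- which(lab > 0)
  if (length(idx_all) == 0) return(list())
  groups <- split(idx_all, as.integer(lab[idx_all]))
  groups <- groups[lengths(groups) >= min_area]
  H <- nrow(lab)
  mapply(function(idx, l) {
    ys <- (idx - 1) %% H          # 0-based row = y
    xs <- (idx - 1) %/% H         # 0-based col = x
    cx <- mean(xs); cy <- mean(ys)
    cov <- if (length(idx) < 2) diag(1e-9, 2) else
      stats::cov(cbind(xs, ys)) + diag(1e-9, 2)
    eig <- eigen(cov, symmetric = TRUE)
    major <- eig$vectors[, 1]
    if (major[2] < 0) major <- -major   # orient toward +y (distal)
    list(label = as.integer(l), idx = idx, area = length(idx), xs = xs,
         ys = ys, centroid = c(cx, cy), major = major,
         elongation = sqrt(max(eig$values[1], 1e-9) /
                             max(eig$values[2], 1e-9)),
         mean_intensity = mean(img[idx]))
  }, groups, names(groups), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

## sub-pixel endpoint of a component along its principal axis:
## centroid of the pixels whose axial projection lies within `slab` px of the
## extreme projection (end-cap centroid refinement)
.axis_endpoint <- function(feat, direction = c("max", "min"), slab = 1.5) {
  proj <- feat$xs * feat$major[1] + feat$ys * feat$major[2]
  sel <- if (direction == "max") proj >= max(proj) - slab else
    proj <= min(proj) + slab
  ## project the end-cap centroid onto the principal axis: the perpendicular
  ## component is discretisation jitter and would tilt the derived lines
  t_end <- mean(proj[sel]) -
    (feat$centroid[1] * feat$major[1] + feat$centroid[2] * feat$major[2])
  feat$centroid + t_end * feat$major
}

#' Segment the three key structures from a grayscale image
#'
#' Thresholds the image at an intensity quantile, labels connected
#' components, and assigns components to the ilium (largest elongated
#' near-vertical component), the acetabular roof (component adjoining the
#' ilium's distal end) and the labrum (compact blob nearest the lateral end
#' of the roof). Per-structure confidence is the component's mean intensity
#' contrast against the whole-frame mean, scaled to \[0, 1\].
#'
#' @param image numeric/integer matrix, gray levels 0-255 (rows = y).
#' @param threshold_quantile intensity quantile for binarisation (default
#'   0.85: bone occupies a small bright fraction of the frame).
#' @param min_area smallest component area (px) considered a structure.
#' @return a [structure_mask_set()]; `complete = FALSE` when fewer than three
#'   qualifying components are found (never an error).
#' @export
segment_structures <- function(image, threshold_quantile = 0.85,
                               min_area = NULL) {
  stopifnot(is.matrix(image))
  H <- nrow(image); W <- ncol(image); S <- min(W, H)
  if (is.null(min_area)) min_area <- max(9, round(4e-04 * W * H))
  incomplete <- structure_mask_set()
  thr <- stats::quantile(image, threshold_quantile, names = FALSE)
  bw <- image > thr
  if (!any(bw)) return(incomplete)
  lab <- EBImage::bwlabel(bw)
  feats <- .component_features(lab, image, min_area = min_area)
  if (length(feats) < 3) return(incomplete)

  ## ilium: the most plausible elongated near-vertical bright band
  vert_ok <- vapply(feats, function(f) {
    f$elongation >= 2.5 && abs(atan2(f$major[1], f$major[2])) * 180 / pi <= 45
  }, TRUE)
  cand <- feats[vert_ok]
  if (length(cand) == 0) return(incomplete)
  ilium <- cand[[which.max(vapply(cand, function(f) f$area, 0))]]
  distal <- .axis_endpoint(ilium, "max")

  rest <- Filter(function(f) f$label != ilium$label, feats)
  if (length(rest) < 2) return(incomplete)

  ## acetabular roof: component whose nearest end lies closest to the distal
  ## end of the ilium
  d_roof <- vapply(rest, function(f) {
    min(sqrt((f$xs - distal[1])^2 + (f$ys - distal[2])^2))
  }, 0)
  if (min(d_roof) > 0.45 * S) return(incomplete)
  roof <- rest[[which.min(d_roof)]]
  ends <- list(.axis_endpoint(roof, "min"), .axis_endpoint(roof, "max"))
  dd <- vapply(ends, function(e) sum((e - distal)^2), 0)
  lateral <- ends[[which.max(dd)]]

  ## labrum: remaining component nearest the lateral end of the roof
  rest2 <- Filter(function(f) f$label != roof$label, rest)
  if (length(rest2) == 0) return(incomplete)
  d_lab <- vapply(rest2, function(f) {
    min(sqrt((f$xs - lateral[1])^2 + (f$ys - lateral[2])^2))
  }, 0)
  if (min(d_lab) > 0.35 * S) return(incomplete)
  labrum <- rest2[[which.min(d_lab)]]

  frame_mean <- mean(image)
  conf <- vapply(list(ilium = ilium, acetabulum = roof, labrum = labrum),
                 function(f) {
                   min(1, max(0, (f$mean_intensity - frame_mean) / 255))
                 }, 0)
  as_mask <- function(f) {
    m <- matrix(FALSE, H, W)
    m[f$idx] <- TRUE
    m
  }
  structure_mask_set(ilium = as_mask(ilium), acetabulum = as_mask(roof),
                     labrum = as_mask(labrum), confidence = conf,
                     complete = TRUE)
}

#' Convert structure masks to the white-on-black stage-1 image
#'
#' Pixels covered by any structure mask become white (255) and everything
#' else black (0); this composite is the input representation for the second
#' (keypoint) stage.
#'
#' @param masks a [structure_mask_set()] or a list of logical matrices.
#' @return integer matrix of 0/255 values.
#' @export
masks_to_stage1 <- function(masks) {
  ms <- if (inherits(masks, "structure_mask_set")) {
    Filter(Negate(is.null), masks$masks)
  } else {
    Filter(Negate(is.null), masks)
  }
  if (length(ms) == 0) stop("masks_to_stage1: no masks supplied", call. = FALSE)
  out <- matrix(0L, nrow(ms[[1]]), ncol(ms[[1]]))
  for (m in ms) out[m] <- 255L
  out
}

#' Extract the five landmarks from structure masks
#'
#' The two check-angle points are the sub-pixel endpoints of the ilium mask's
#' principal axis (proximal = `check_upper`, distal = `triradiate`); the
#' lower-ilium point and bone edge are the medial and lateral endpoints of
#' the acetabular roof's principal axis; the labrum end is the labrum-mask
#' principal-axis endpoint lying farther from the baseline. All endpoints are
#' refined to sub-pixel precision as end-cap centroids.
#'
#' @param masks a [structure_mask_set()] with all three masks present.
#' @return a [landmark_set()].
#' @export
extract_keypoints <- function(masks) {
  stopifnot(inherits(masks, "structure_mask_set"))
  for (nm in c("ilium", "acetabulum", "labrum")) {
    m <- masks$masks[[nm]]
    if (is.null(m) || !any(m)) {
      stop("extract_keypoints: missing landmark source: empty '", nm,
           "' mask", call. = FALSE)
    }
  }
  img0 <- masks$masks$ilium * 1  # dummy intensities; features only need geometry
  featify <- function(m) {
    lab <- matrix(0L, nrow(m), ncol(m)); lab[m] <- 1L
    .component_features(lab, img0)[[1]]
  }
  fi <- featify(masks$masks$ilium)
  fa <- featify(masks$masks$acetabulum)
  fl <- featify(masks$masks$labrum)

  check_upper <- .axis_endpoint(fi, "min")
  triradiate  <- .axis_endpoint(fi, "max")

  a_ends <- list(.axis_endpoint(fa, "min"), .axis_endpoint(fa, "max"))
  d <- vapply(a_ends, function(e) sum((e - triradiate)^2), 0)
  lower_ilium <- a_ends[[which.min(d)]]
  bone_edge   <- a_ends[[which.max(d)]]

  l_ends <- list(.axis_endpoint(fl, "min"), .axis_endpoint(fl, "max"))
  ## distance of a point from the (undirected) baseline
  bdir <- (triradiate - check_upper)
  bdir <- bdir / sqrt(sum(bdir^2))
  off_baseline <- function(p) {
    r <- p - check_upper
    abs(r[1] * bdir[2] - r[2] * bdir[1])
  }
  dl <- vapply(l_ends, off_baseline, 0)
  labrum_end <- l_ends[[which.max(dl)]]

  landmark_set(check_upper, triradiate, lower_ilium, bone_edge, labrum_end)
}

#' Run the full classical detector on one image
#'
#' Composes [segment_structures()], [masks_to_stage1()] and
#' [extract_keypoints()]. An image is detectable when all three structures
#' are segmented with confidence >= `min_confidence` and all five landmarks
#' are extracted; failures are encoded in the result, never thrown.
#'
#' @param image numeric/integer matrix, gray levels 0-255.
#' @param threshold_quantile passed to [segment_structures()].
#' @param min_confidence per-structure confidence floor for detectability.
#' @return object of class `detection_result`: list with `masks`, `stage1`,
#'   `landmarks` (`NULL` when undetectable), `detectable`.
#' @export
detect <- function(image, threshold_quantile = 0.85, min_confidence = 0.5) {
  masks <- segment_structures(image, threshold_quantile)
  fail <- structure(list(masks = masks, stage1 = NULL, landmarks = NULL,
                         detectable = FALSE), class = "detection_result")
  if (!masks$complete || any(masks$confidence < min_confidence)) return(fail)
  stage1 <- masks_to_stage1(masks)
  lms <- tryCatch(extract_keypoints(masks), error = function(e) NULL)
  if (is.null(lms)) return(fail)
  structure(list(masks = masks, stage1 = stage1, landmarks = lms,
                 detectable = TRUE),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("<detection_result> detectable:", x$detectable, "\n")
  if (x$detectable) print(measure_landmarks(x$landmarks))
  invisible(x)
}

#' Overlap ratio between two binary masks
#'
#' Intersection over the smaller mask's area; used to score recovered masks
#' against phantom ground truth.
#'
#' @param a,b logical matrices of identical dimensions.
#' @return fraction in \[0, 1\].
#' @export
mask_overlap <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- min(sum(a), sum(b))
  if (denom == 0) return(0)
  sum(a & b) / denom
}
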