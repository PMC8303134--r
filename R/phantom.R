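## Synthetic Graf-plane hip phantom: a bright near-vertical iliac band, a bony
## acetabular roof wedge meeting it at a controllable alpha angle, and an
## echogenic labrum ellipse defining a controllable beta angle, over a dark
## soft-tissue background with multiplicative speckle. Every phantom carries
## exact sub-pixel ground-truth landmarks and per-structure masks, so the
## downstream detector and statistics are testable without clinical images.

#' Specification of one synthetic hip phantom
#'
#' @param alpha_deg target Graf alpha angle, degrees, in (0, 90).
#' @param beta_deg target Graf beta angle, degrees, in (0, 90).
#' @param check_deg target signed iliac-wing tilt from the image vertical,
#'   degrees, |check_deg| <= 30.
#' @param width_px,height_px image size in pixels (>= 64).
#' @param bone_intensity,soft_intensity gray levels (0-255) of bone and
#'   background before noise.
#' @param speckle_sigma log-scale SD of the multiplicative speckle; 0 disables
#'   all noise.
#' @param brightness_factor global brightness multiplier in \[0.75, 1\],
#'   mirroring the brightness variation of clinical acquisitions.
#' @param seed integer seed controlling the speckle field.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(alpha_deg = 64.1, beta_deg = 40.7, check_deg = 0,
                         width_px = 256, height_px = 256,
                         bone_intensity = 200, soft_intensity = 40,
                         speckle_sigma = 0.12, brightness_factor = 1.0,
                         seed = 1L) {
  bad <- function(msg) stop("phantom_spec: ", msg, call. = FALSE)
  if (!is.finite(alpha_deg) || alpha_deg <= 0 || alpha_deg >= 90) {
    bad("alpha_deg must lie strictly inside (0, 90)")
  }
  if (!is.finite(beta_deg) || beta_deg <= 0 || beta_deg >= 90) {
    bad("beta_deg must lie strictly inside (0, 90)")
  }
  if (!is.finite(check_deg) || abs(check_deg) > 30) {
    bad("|check_deg| must be <= 30")
  }
  if (width_px < 64 || height_px < 64) {
    bad("width_px and height_px must be >= 64")
  }
  if (brightness_factor < 0.75 || brightness_factor > 1.0) {
    bad("brightness_factor must lie within [0.75, 1.00]")
  }
  if (bone_intensity < 0 || bone_intensity > 255 ||
      soft_intensity < 0 || soft_intensity > 255) {
    bad("intensities must lie within [0, 255]")
  }
  if (speckle_sigma < 0) bad("speckle_sigma must be >= 0")
  structure(
    list(alpha_deg = alpha_deg, beta_deg = beta_deg, check_deg = check_deg,
         width_px = as.integer(width_px), height_px = as.integer(height_px),
         bone_intensity = bone_intensity, soft_intensity = soft_intensity,
         speckle_sigma = speckle_sigma, brightness_factor = brightness_factor,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

## unit direction at angle phi (degrees) from the downward vertical, toward +x
.dir <- function(phi_deg) {
  phi <- phi_deg * pi / 180
  c(sin(phi), cos(phi))
}

## evaluate an expression under a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Exact ground-truth landmarks for a phantom specification
#'
#' Places the five landmarks so that recomputing the three angles with the
#' geometry module reproduces the requested `alpha_deg`, `beta_deg` and
#' `check_deg` exactly (inverse construction). Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @return a [landmark_set()].
#' @export
generate_landmarks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  W <- spec$width_px; H <- spec$height_px; S <- min(W, H)
  u <- .dir(spec$check_deg)                                 # baseline, distal
  w <- .dir(spec$check_deg + 180 - spec$alpha_deg)          # bony roof
  v <- .dir(spec$check_deg + 180 - spec$beta_deg)           # cartilage roof
  triradiate  <- c(0.42 * W, 0.64 * H)
  check_upper <- triradiate - 0.48 * S * u
  lower_ilium <- triradiate + 0.08 * S * u
  bone_edge   <- lower_ilium + 0.24 * S * w
  labrum_end  <- bone_edge + 0.18 * S * v
  ls <- landmark_set(check_upper, triradiate, lower_ilium, bone_edge,
                     labrum_end)
  for (nm in landmark_names()) {
    p <- ls[[nm]]
    if (p[1] < 0 || p[1] > W - 1 || p[2] < 0 || p[2] > H - 1) {
      stop("generate_landmarks: landmark '", nm, "' falls outside the image",
           call. = FALSE)
    }
  }
  ls
}

## flat-ended thick band along segment a->b: pixels whose axial position lies
## within the segment and whose perpendicular distance is <= half_width
.segment_mask <- function(W, H, a, b, half_width) {
  xs <- matrix(rep(0:(W - 1), each = H), nrow = H)   # x = column index
  ys <- matrix(rep(0:(H - 1), times = W), nrow = H)  # y = row index
  d <- b - a
  len <- sqrt(sum(d^2))
  ax <- d / len
  t <- (xs - a[1]) * ax[1] + (ys - a[2]) * ax[2]
  perp <- abs((xs - a[1]) * ax[2] - (ys - a[2]) * ax[1])
  t >= 0 & t <= len & perp <= half_width
}

## filled ellipse: center c0, semi-major a_len along unit dir v, semi-minor b_len
.ellipse_mask <- function(W, H, c0, v, a_len, b_len) {
  xs <- matrix(rep(0:(W - 1), each = H), nrow = H)
  ys <- matrix(rep(0:(H - 1), times = W), nrow = H)
  dx <- xs - c0[1]; dy <- ys - c0[2]
  along <- dx * v[1] + dy * v[2]
  perp  <- -dx * v[2] + dy * v[1]
  (along / a_len)^2 + (perp / b_len)^2 <= 1
}

#' Ground truth (landmarks + structure masks) for one phantom
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth`: list with `landmarks`, `masks`
#'   (logical matrices `ilium`, `acetabulum`, `labrum`) and `spec`.
#' @export
phantom_truth <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ls <- generate_landmarks(spec)
  W <- spec$width_px; H <- spec$height_px; S <- min(W, H)
  v <- .dir(spec$check_deg + 180 - spec$beta_deg)
  a_l <- 0.06 * S; b_l <- 0.018 * S
  masks <- list(
    ilium      = .segment_mask(W, H, ls$check_upper, ls$triradiate, 0.020 * S),
    acetabulum = .segment_mask(W, H, ls$lower_ilium, ls$bone_edge, 0.016 * S),
    labrum     = .ellipse_mask(W, H, ls$labrum_end - a_l * v, v, a_l, b_l)
  )
  for (nm in names(masks)) {
    if (!any(masks[[nm]])) {
      stop("phantom_truth: structure '", nm, "' rasterised to an empty mask",
           call. = FALSE)
    }
  }
  structure(list(landmarks = ls, masks = masks, spec = spec),
            class = "phantom_truth")
}

#' Rasterise a phantom truth into an 8-bit grayscale image
#'
#' Structure pixels take the bone intensity and the background the soft-tissue
#' intensity; the whole frame is scaled by the brightness factor, multiplied
#' by a seeded log-normal speckle field, and perturbed by additive Gaussian
#' noise (both noise scales proportional to `speckle_sigma`, so
#' `speckle_sigma = 0` yields a noise-free image). Identical specs give
#' bit-identical images.
#'
#' @param truth a [phantom_truth()].
#' @return integer matrix (rows = y, columns = x) with values in 0-255.
#' @export
rasterize_phantom <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  W <- spec$width_px; H <- spec$height_px
  img <- matrix(spec$soft_intensity, nrow = H, ncol = W)
  for (m in truth$masks) img[m] <- spec$bone_intensity
  img <- img * spec$brightness_factor
  if (spec$speckle_sigma > 0) {
    img <- with_seed(spec$seed, {
      speckle <- exp(matrix(rnorm(W * H, 0, spec$speckle_sigma), H, W))
      gauss <- matrix(rnorm(W * H, 0, 5 * spec$speckle_sigma), H, W)
      img * speckle + gauss
    })
  }
  img <- round(img)
  img[img < 0] <- 0L
  img[img > 255] <- 255L
  storage.mode(img) <- "integer"
  img
}

#' Generate one phantom (image plus ground truth)
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (integer matrix) and `truth` ([phantom_truth()]).
#' @export
generate_phantom <- function(spec) {
  truth <- phantom_truth(spec)
  list(image = rasterize_phantom(truth), truth = truth)
}
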