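## Coordinate convention used throughout: x grows rightward, y grows downward,
## 0-based pixel indices, sub-pixel coordinates allowed. The "vertical" axis of
## the standard coronal plane is therefore the +y direction.

#' Construct a 2-D landmark point
#'
#' @param x,y coordinates in pixels; x rightward, y downward, sub-pixel allowed.
#' @return numeric vector `c(x = , y = )`.
#' @export
point2d <- function(x, y) {
  if (!is.finite(x) || !is.finite(y)) {
    stop("point2d: coordinates must be finite", call. = FALSE)
  }
  c(x = as.numeric(x), y = as.numeric(y))
}

#' Construct the five-landmark set of the Graf standard plane
#'
#' The five anatomical points from which all angles derive: the two check-angle
#' points along the iliac wing (`check_upper` proximal, `triradiate` distal —
#' the latter shared with the tri-radiate cartilage point), the lower edge of
#' the iliac bone, the acetabular bone edge (bony rim), and the end of the
#' acetabular labrum.
#'
#' @param check_upper,triradiate,lower_ilium,bone_edge,labrum_end points from
#'   [point2d()].
#' @return object of class `landmark_set`.
#' @export
landmark_set <- function(check_upper, triradiate, lower_ilium, bone_edge,
                         labrum_end) {
  ls <- list(
    check_upper = point2d(check_upper[1], check_upper[2]),
    triradiate  = point2d(triradiate[1], triradiate[2]),
    lower_ilium = point2d(lower_ilium[1], lower_ilium[2]),
    bone_edge   = point2d(bone_edge[1], bone_edge[2]),
    labrum_end  = point2d(labrum_end[1], labrum_end[2])
  )
  same <- function(p, q) isTRUE(all(abs(p - q) < 1e-12))
  if (same(ls$check_upper, ls$triradiate)) {
    stop("landmark_set: check_upper and triradiate coincide", call. = FALSE)
  }
  if (same(ls$lower_ilium, ls$bone_edge)) {
    stop("landmark_set: lower_ilium and bone_edge coincide", call. = FALSE)
  }
  if (same(ls$bone_edge, ls$labrum_end)) {
    stop("landmark_set: bone_edge and labrum_end coincide", call. = FALSE)
  }
  structure(ls, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s (%.3f, %.3f)\n", nm, x[[nm]][1], x[[nm]][2]))
  }
  invisible(x)
}

landmark_names <- function() {
  c("check_upper", "triradiate", "lower_ilium", "bone_edge", "labrum_end")
}

#' Minimal angle between two undirected lines
#'
#' Each line is given by two distinct points. The returned angle is the
#' unsigned minimal angle between the undirected lines, symmetric in line
#' order and in point order within a line.
#'
#' @param a1,a2 two points on the first line.
#' @param b1,b2 two points on the second line.
#' @return angle in degrees, in \[0, 90\].
#' @export
angle_between_lines <- function(a1, a2, b1, b2) {
  u <- c(a2[1] - a1[1], a2[2] - a1[2])
  v <- c(b2[1] - b1[1], b2[2] - b1[2])
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) {
    stop("angle_between_lines: degenerate line (coincident endpoints)",
         call. = FALSE)
  }
  cosang <- abs(sum(u * v)) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Signed check angle of the iliac wing
#'
#' Angle between the baseline (the line through `check_upper` and
#' `triradiate`) and the image vertical axis, 0 when the iliac wing is exactly
#' vertical. The sign is positive when the distal end of the wing is rotated
#' toward +x.
#'
#' @param ls a [landmark_set()].
#' @return signed angle in degrees, in (-90, 90\].
#' @export
compute_check_angle <- function(ls) {
  stopifnot(inherits(ls, "landmark_set"))
  v <- ls$triradiate - ls$check_upper
  if (sqrt(sum(v^2)) < 1e-12) {
    stop("compute_check_angle: degenerate baseline", call. = FALSE)
  }
  ## distal direction: triradiate lies distally; sign follows its x-rotation
  ang <- unname(atan2(v[1], v[2])) * 180 / pi
  ## fold into (-90, 90]: the baseline is undirected
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Graf alpha angle (bony roof)
#'
#' Angle between the baseline (`check_upper`, `triradiate`) and the bony roof
#' line (`lower_ilium`, `bone_edge`). Alpha >= 60 degrees defines a normal
#' (Graf type I) hip.
#'
#' @param ls a [landmark_set()].
#' @return angle in degrees, in \[0, 90\].
#' @export
compute_alpha <- function(ls) {
  stopifnot(inherits(ls, "landmark_set"))
  angle_between_lines(ls$check_upper, ls$triradiate, ls$lower_ilium,
                      ls$bone_edge)
}

#' Graf beta angle (cartilaginous roof)
#'
#' Angle between the baseline and the cartilage roof line (`bone_edge`,
#' `labrum_end`).
#'
#' @param ls a [landmark_set()].
#' @return angle in degrees, in \[0, 90\].
#' @export
compute_beta <- function(ls) {
  stopifnot(inherits(ls, "landmark_set"))
  angle_between_lines(ls$check_upper, ls$triradiate, ls$bone_edge,
                      ls$labrum_end)
}

#' Dichotomous Graf classification at the 60-degree alpha threshold
#'
#' A hip is called normal when alpha >= 60 degrees (boundary inclusive,
#' matching the Graf type I definition) and abnormal otherwise.
#'
#' @param alpha_deg alpha angle in degrees, in \[0, 90\].
#' @return `"normal"` or `"abnormal"` (vectorised).
#' @export
classify_graf <- function(alpha_deg) {
  if (any(!is.finite(alpha_deg)) || any(alpha_deg < 0) || any(alpha_deg > 90)) {
    stop("classify_graf: alpha_deg must be finite and within [0, 90]",
         call. = FALSE)
  }
  ifelse(alpha_deg >= 60, "normal", "abnormal")
}

#' Full Graf measurement from a landmark set
#'
#' Computes the signed check angle, alpha, beta, and the normal/abnormal call
#' at the 60-degree alpha threshold.
#'
#' @param ls a [landmark_set()].
#' @return object of class `graf_measurement`: list with `check_deg`,
#'   `alpha_deg`, `beta_deg`, `graf_call`.
#' @export
measure_landmarks <- function(ls) {
  alpha <- compute_alpha(ls)
  structure(
    list(
      check_deg = compute_check_angle(ls),
      alpha_deg = alpha,
      beta_deg  = compute_beta(ls),
      graf_call = classify_graf(alpha)
    ),
    class = "graf_measurement"
  )
}

#' @export
print.graf_measurement <- function(x, ...) {
  cat(sprintf("<graf_measurement> check %.3f deg, alpha %.3f deg, beta %.3f deg -> %s\n",
              x$check_deg, x$alpha_deg, x$beta_deg, x$graf_call))
  invisible(x)
}

#' Export Graf measurements as a data frame
#'
#' Angles are reported to 3 decimal places.
#'
#' @param measurements named list of `graf_measurement` objects (names are
#'   image ids).
#' @param rater rater label recorded in the `rater` column.
#' @return data.frame with columns `image_id`, `rater`, `check_deg`,
#'   `alpha_deg`, `beta_deg`, `graf_call`.
#' @export
measurements_to_df <- function(measurements, rater = "ai") {
  stopifnot(length(measurements) >= 1, !is.null(names(measurements)))
  data.frame(
    image_id  = names(measurements),
    rater     = rater,
    check_deg = round(vapply(measurements, function(m) m$check_deg, 0), 3),
    alpha_deg = round(vapply(measurements, function(m) m$alpha_deg, 0), 3),
    beta_deg  = round(vapply(measurements, function(m) m$beta_deg, 0), 3),
    graf_call = vapply(measurements, function(m) m$graf_call, ""),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
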