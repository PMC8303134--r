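## Cohorts of paired (AI, human) readings: the unit on which every agreement
## statistic operates. A reading is either undetectable (no measurement) or a
## full Graf measurement.

#' One rater's reading of one image
#'
#' @param detectable logical; were all key structures and points observable?
#' @param check_deg,alpha_deg,beta_deg angles in degrees; must be `NA` when
#'   the image is undetectable.
#' @return object of class `rater_reading`.
#' @export
rater_reading <- function(detectable, check_deg = NA_real_,
                          alpha_deg = NA_real_, beta_deg = NA_real_) {
  detectable <- isTRUE(detectable)
  if (!detectable && any(!is.na(c(check_deg, alpha_deg, beta_deg)))) {
    stop("rater_reading: measurement present but image flagged undetectable",
         call. = FALSE)
  }
  if (detectable && any(is.na(c(check_deg, alpha_deg, beta_deg)))) {
    stop("rater_reading: detectable reading requires all three angles",
         call. = FALSE)
  }
  structure(list(detectable = detectable, check_deg = check_deg,
                 alpha_deg = alpha_deg, beta_deg = beta_deg),
            class = "rater_reading")
}

#' Paired AI/human reading of one image
#'
#' @param image_id identifier.
#' @param ai,human [rater_reading()] objects.
#' @return object of class `paired_reading`.
#' @export
paired_reading <- function(image_id, ai, human) {
  stopifnot(inherits(ai, "rater_reading"), inherits(human, "rater_reading"))
  structure(list(image_id = as.character(image_id), ai = ai, human = human),
            class = "paired_reading")
}

## truncated-normal sampling by rejection (bounds well inside the tails here)
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 8, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a cohort of phantoms with simulated paired readings
#'
#' Draws per-image true angles from truncated normal distributions (defaults
#' match the study population summary: alpha 64.117 +/- 7.12, beta
#' 40.679 +/- 8.71 degrees), renders the phantoms, and simulates an AI and a
#' human reading per image. Each detectable reading equals the truth angles
#' plus independent Gaussian rater noise with SD `rater_noise_sd / sqrt(2)`,
#' so that the SD of the AI-minus-human difference is `rater_noise_sd`. A
#' `detect_failure_rate` fraction of readings per rater is flagged
#' undetectable. Deterministic given `seed`.
#'
#' @param n number of images (>= 1).
#' @param angle_distributions list with elements `alpha`, `beta`, `check`,
#'   each `c(mean, sd)` in degrees.
#' @param detect_failure_rate per-rater probability of an undetectable
#'   reading, in \[0, 1).
#' @param rater_noise_sd SD of the paired AI-human angle difference, degrees.
#' @param seed integer seed.
#' @param render if `FALSE`, skip image rasterisation (truth and readings
#'   only); useful for statistics-only simulations.
#' @param width_px,height_px phantom size.
#' @param speckle_sigma speckle level passed to each [phantom_spec()].
#' @return list of class `phantom_cohort`; each element has `image` (or
#'   `NULL`), `truth`, and `reading` (a [paired_reading()]).
#' @export
generate_cohort <- function(n,
                            angle_distributions = list(
                              alpha = c(64.117, 7.12),
                              beta  = c(40.679, 8.71),
                              check = c(0, 3)),
                            detect_failure_rate = 0,
                            rater_noise_sd = 4.5,
                            seed = 1L,
                            render = TRUE,
                            width_px = 256, height_px = 256,
                            speckle_sigma = 0.12) {
  if (n < 1) stop("generate_cohort: n must be >= 1", call. = FALSE)
  if (detect_failure_rate < 0 || detect_failure_rate >= 1) {
    stop("generate_cohort: detect_failure_rate must lie in [0, 1)",
         call. = FALSE)
  }
  ad <- angle_distributions
  with_seed(seed, {
    alpha <- .rtruncnorm(n, ad$alpha[1], ad$alpha[2], 35, 88)
    beta  <- .rtruncnorm(n, ad$beta[1], ad$beta[2], 12, 88)
    check <- .rtruncnorm(n, ad$check[1], ad$check[2], -15, 15)
    per_seed <- sample.int(.Machine$integer.max, n)
    sigma_r <- rater_noise_sd / sqrt(2)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      spec <- phantom_spec(alpha_deg = alpha[i], beta_deg = beta[i],
                           check_deg = check[i], width_px = width_px,
                           height_px = height_px,
                           speckle_sigma = speckle_sigma, seed = per_seed[i])
      truth <- phantom_truth(spec)
      img <- if (render) rasterize_phantom(truth) else NULL
      mk_reading <- function() {
        if (runif(1) < detect_failure_rate) return(rater_reading(FALSE))
        e <- rnorm(3, 0, sigma_r)
        rater_reading(TRUE, check_deg = check[i] + e[1],
                      alpha_deg = alpha[i] + e[2], beta_deg = beta[i] + e[3])
      }
      reading <- paired_reading(sprintf("phantom%04d", i), mk_reading(),
                                mk_reading())
      out[[i]] <- list(image = img, truth = truth, reading = reading)
    }
    structure(out, class = c("phantom_cohort", "list"))
  })
}

#' Deterministic reference cohort reproducing the published screening margins
#'
#' Builds 921 paired readings whose detectability flags and check-angle gates
#' reproduce the reference cross-tabulations: 542 human-detectable, 555
#' AI-detectable, 512 commonly detectable; of those, 320 images pass the
#' +/-5 degree check-angle gate for both raters, 49 for the AI only, 49 for
#' the human only, and 94 for neither. Alpha/beta angles of detectable
#' readings follow deterministic normal quantile spreads around the study
#' population means, so the cohort is identical on every call.
#'
#' @return list of [paired_reading()] objects of class `phantom_cohort`.
#' @export
reference_cohort <- function() {
  n_total <- 921L
  groups <- c(both_ok = 320L, ai_only_ok = 49L, human_only_ok = 49L,
              both_err = 94L, human_only_det = 30L, ai_only_det = 43L,
              neither_det = 336L)
  stopifnot(sum(groups) == n_total)
  ## deterministic check angles: inside the gate = spread over [-4.5, 4.5],
  ## outside = spread over [6, 12]
  ok_seq  <- function(k) seq(-4.5, 4.5, length.out = max(k, 2))[seq_len(k)]
  err_seq <- function(k) seq(6, 12, length.out = max(k, 2))[seq_len(k)]
  ## deterministic alpha/beta via normal quantiles of the population summary
  qspread <- function(k, mean, sd) mean + sd * qnorm((seq_len(k) - 0.5) / k)
  out <- vector("list", n_total)
  idx <- 0L
  emit <- function(ai, human) {
    idx <<- idx + 1L
    out[[idx]] <<- paired_reading(sprintf("ref%04d", idx), ai, human)
  }
  mk_group <- function(k, ai_ok, human_ok) {
    a_chk <- if (ai_ok) ok_seq(k) else err_seq(k)
    h_chk <- if (human_ok) ok_seq(k) else err_seq(k)
    h_alpha <- qspread(k, 64.117, 7.12)
    h_beta  <- qspread(k, 40.679, 8.71)
    d_alpha <- qspread(k, -1.274, 4.555)[order(rep_len(c(1, 3, 2), k))]
    d_beta  <- qspread(k, 0.106, 5.9)[order(rep_len(c(2, 1, 3), k))]
    for (i in seq_len(k)) {
      emit(rater_reading(TRUE, a_chk[i], h_alpha[i] + d_alpha[i],
                         h_beta[i] + d_beta[i]),
           rater_reading(TRUE, h_chk[i], h_alpha[i], h_beta[i]))
    }
  }
  mk_group(groups[["both_ok"]], TRUE, TRUE)
  mk_group(groups[["ai_only_ok"]], TRUE, FALSE)
  mk_group(groups[["human_only_ok"]], FALSE, TRUE)
  mk_group(groups[["both_err"]], FALSE, FALSE)
  for (i in seq_len(groups[["human_only_det"]])) {
    emit(rater_reading(FALSE), rater_reading(TRUE, 0, 64, 41))
  }
  for (i in seq_len(groups[["ai_only_det"]])) {
    emit(rater_reading(TRUE, 0, 63, 41), rater_reading(FALSE))
  }
  for (i in seq_len(groups[["neither_det"]])) {
    emit(rater_reading(FALSE), rater_reading(FALSE))
  }
  structure(out, class = c("phantom_cohort", "list"))
}

#' Extract the paired readings from a cohort
#'
#' @param cohort a `phantom_cohort` (elements may be full phantom entries or
#'   bare [paired_reading()] objects).
#' @return list of [paired_reading()] objects.
#' @export
cohort_readings <- function(cohort) {
  lapply(cohort, function(el) {
    if (inherits(el, "paired_reading")) el else el$reading
  })
}
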