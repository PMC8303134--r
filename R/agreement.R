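## Inter-rater agreement statistics: percent agreement, positive percent
## agreement and Cohen's kappa on the 2x2 check-angle gate table; two-way
## random-effects absolute-agreement single-rater ICC with Cicchetti
## interpretation bands, mean absolute deviation, paired-difference summaries,
## the <5 degree discrepancy fraction, and concordance of the 60-degree Graf
## dichotomy — everything needed to compare an AI rater to a human rater.

#' Percent agreement on a 2x2 table
#'
#' @param t a [contingency_2x2()].
#' @return 100 * (a + d) / n.
#' @export
percent_agreement <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$n < 1) stop("percent_agreement: empty table", call. = FALSE)
  100 * (t$a + t$d) / t$n
}

#' Positive percent agreement on a 2x2 table
#'
#' Agreement restricted to positive (OK) calls: 2a / (2a + b + c).
#'
#' @param t a [contingency_2x2()].
#' @return fraction in \[0, 1\].
#' @export
positive_agreement <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  denom <- 2 * t$a + t$b + t$c
  if (denom == 0) {
    stop("positive_agreement: undefined (no positive calls by either rater)",
         call. = FALSE)
  }
  2 * t$a / denom
}

#' Cohen's kappa on a 2x2 table, with asymptotic 95% CI
#'
#' kappa = (p_o - p_e) / (1 - p_e) with observed agreement
#' p_o = (a + d) / n and chance agreement
#' p_e = ((a+b)(a+c) + (c+d)(b+d)) / n^2. The confidence interval uses the
#' standard large-sample variance (Fleiss, Cohen and Everitt).
#'
#' @param t a [contingency_2x2()].
#' @param conf_level confidence level for the interval.
#' @return list with `kappa`, `se`, `ci_low`, `ci_high`.
#' @export
cohens_kappa <- function(t, conf_level = 0.95) {
  stopifnot(inherits(t, "contingency_2x2"))
  if (t$n < 2) stop("cohens_kappa: need n >= 2", call. = FALSE)
  n <- t$n
  p <- matrix(c(t$a, t$c, t$b, t$d), 2, 2) / n  # [AI, human]
  prow <- rowSums(p)   # AI marginals
  pcol <- colSums(p)   # human marginals
  po <- p[1, 1] + p[2, 2]
  pe <- sum(prow * pcol)
  if (abs(1 - pe) < 1e-12) {
    stop("cohens_kappa: undefined (chance agreement equals 1)", call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  ## Fleiss-Cohen-Everitt asymptotic variance
  s1 <- sum(diag(p) * ((1 - pe) - (prow + pcol) * (1 - po))^2)
  s2 <- 0
  for (i in 1:2) for (j in 1:2) {
    if (i != j) s2 <- s2 + p[i, j] * (pcol[i] + prow[j])^2
  }
  v <- (s1 + (1 - po)^2 * s2 - (po * pe - 2 * pe + po)^2) /
    (n * (1 - pe)^4)
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(kappa = kappa, se = se,
       ci_low = max(-1, kappa - z * se),
       ci_high = min(1, kappa + z * se))
}

#' Cicchetti interpretation band for an ICC value
#'
#' `< 0.40` poor, `0.40-0.59` fair, `0.60-0.74` good, `>= 0.75` excellent.
#'
#' @param icc ICC value(s).
#' @return character vector of band labels.
#' @export
icc_band <- function(icc) {
  cut(icc, breaks = c(-Inf, 0.40, 0.60, 0.75, Inf), right = FALSE,
      labels = c("poor", "fair", "good", "excellent")) |> as.character()
}

#' Two-way absolute-agreement single-rater ICC for paired readings
#'
#' ICC(A,1): two-way random effects, absolute agreement, single measurement —
#' the form matching two raters (AI and human) measuring the same images
#' where systematic offsets between raters should count against agreement.
#' Computed from the two-way ANOVA mean squares
#' (subjects MSR, raters MSC, residual MSE):
#' ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n).
#' The confidence interval follows McGraw and Wong.
#'
#' @param pairs two-column matrix or data.frame of (ai, human) measurements.
#' @param conf_level confidence level.
#' @return list with `icc`, `ci_low`, `ci_high`, `band`.
#' @export
icc_agreement <- function(pairs, conf_level = 0.95) {
  x <- as.matrix(pairs)
  if (ncol(x) != 2) stop("icc_agreement: need two columns", call. = FALSE)
  if (nrow(x) < 3) stop("icc_agreement: need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) < 1e-12) {
    stop("icc_agreement: undefined for constant measurements", call. = FALSE)
  }
  n <- nrow(x); k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- max(sse / ((n - 1) * (k - 1)), 0)
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  ## McGraw & Wong CI for ICC(A,1)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  if (!is.finite(lo)) lo <- -1
  if (!is.finite(hi)) hi <- 1
  list(icc = icc, ci_low = min(lo, icc), ci_high = max(hi, icc),
       band = icc_band(icc))
}

#' Paired-difference summary of AI versus human angle measurements
#'
#' @param pairs two-column matrix or data.frame of (ai, human) angles,
#'   degrees.
#' @param discrepancy_deg half-width of the "small discrepancy" band
#'   (strict: |ai - human| < 5 by default).
#' @param cutoff_deg Graf dichotomy threshold for the concordance fraction
#'   (inclusive boundary, see [classify_graf()]).
#' @return list with `mad` (mean absolute deviation), `diff_mean`,
#'   `diff_sd` (on ai - human), `within5_fraction`, `concordance60_fraction`.
#' @export
paired_summary <- function(pairs, discrepancy_deg = 5, cutoff_deg = 60) {
  x <- as.matrix(pairs)
  if (ncol(x) != 2 || nrow(x) < 1) {
    stop("paired_summary: need a non-empty two-column input", call. = FALSE)
  }
  d <- x[, 1] - x[, 2]
  list(
    mad = mean(abs(d)),
    diff_mean = mean(d),
    diff_sd = if (nrow(x) > 1) stats::sd(d) else NA_real_,
    within5_fraction = mean(abs(d) < discrepancy_deg),
    concordance60_fraction = mean((x[, 1] >= cutoff_deg) ==
                                    (x[, 2] >= cutoff_deg))
  )
}

#' Full agreement evaluation of a cohort of paired readings
#'
#' Reproduces the study's analysis end to end: detectability
#' cross-tabulation, the check-angle 2x2 gate table on commonly detectable
#' images with percent agreement / positive agreement / kappa, and — on the
#' appropriate images (both gates passed) — ICC with Cicchetti band and
#' paired-difference summaries for the alpha and beta angles.
#'
#' @param readings list of [paired_reading()] objects.
#' @param tolerance check-angle gate half-width, degrees.
#' @return list of class `agreement_report` with components `detection`
#'   (data.frame), `check` (table + column percentages), `percent_agreement`,
#'   `positive_agreement`, `kappa`, `triage` (label counts), and per-angle
#'   `alpha`/`beta` lists (`icc`, `summary`) over the appropriate images.
#' @export
evaluate_cohort <- function(readings, tolerance = 5) {
  if (length(readings) == 0) stop("evaluate_cohort: empty cohort",
                                  call. = FALSE)
  detection <- tabulate_detection(readings)
  labels <- vapply(readings, triage, "", tolerance = tolerance)
  common <- readings[vapply(readings, function(r) {
    r$ai$detectable && r$human$detectable
  }, TRUE)]
  check <- if (length(common) > 0) tabulate_check(common, tolerance) else NULL
  pa <- pos <- kap <- NULL
  if (!is.null(check)) {
    pa <- percent_agreement(check$table)
    pos <- positive_agreement(check$table)
    kap <- cohens_kappa(check$table)
  }
  appropriate <- readings[labels == "appropriate"]
  angle_block <- function(field) {
    if (length(appropriate) < 3) return(NULL)
    m <- cbind(
      ai = vapply(appropriate, function(r) r$ai[[field]], 0),
      human = vapply(appropriate, function(r) r$human[[field]], 0)
    )
    list(icc = icc_agreement(m), summary = paired_summary(m), pairs = m)
  }
  structure(
    list(detection = detection,
         check = check,
         percent_agreement = pa,
         positive_agreement = pos,
         kappa = kap,
         triage = table(factor(labels, levels = c(
           "appropriate", "inappropriate_check_angle", "fail_detection"))),
         alpha = angle_block("alpha_deg"),
         beta = angle_block("beta_deg")),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat("== Detectability (criterion 1) ==\n")
  print(x$detection)
  cat("\n== Check-angle gate on commonly detectable images (criterion 2) ==\n")
  if (!is.null(x$check)) {
    print(x$check$table)
    cat(sprintf("percent agreement:  %.1f%%\n", x$percent_agreement))
    cat(sprintf("positive agreement: %.2f\n", x$positive_agreement))
    cat(sprintf("Cohen's kappa:      %.3f (95%% CI %.3f-%.3f)\n",
                x$kappa$kappa, x$kappa$ci_low, x$kappa$ci_high))
  }
  cat("\n== Triage ==\n")
  print(x$triage)
  for (ang in c("alpha", "beta")) {
    blk <- x[[ang]]
    if (is.null(blk)) next
    cat(sprintf("\n== %s angle on appropriate images (n = %d) ==\n",
                ang, nrow(blk$pairs)))
    cat(sprintf("ICC(A,1) %.3f (95%% CI %.3f-%.3f), %s\n",
                blk$icc$icc, blk$icc$ci_low, blk$icc$ci_high, blk$icc$band))
    s <- blk$summary
    cat(sprintf("MAD %.3f; diff %.3f +/- %.3f; <5 deg %.1f%%; 60-deg concordance %.1f%%\n",
                s$mad, s$diff_mean, s$diff_sd, 100 * s$within5_fraction,
                100 * s$concordance60_fraction))
  }
  invisible(x)
}
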