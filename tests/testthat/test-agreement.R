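test_that("percent and positive agreement match the published table", {
  t <- reference_table()
  expect_equal(round(percent_agreement(t), 1), 80.9)
  expect_equal(round(positive_agreement(t), 2), 0.87)
  expect_equal(percent_agreement(contingency_2x2(10, 0, 0, 10)), 100)
  expect_equal(percent_agreement(contingency_2x2(0, 5, 5, 0)), 0)
  expect_equal(positive_agreement(contingency_2x2(10, 0, 0, 0)), 1)
  expect_equal(positive_agreement(contingency_2x2(0, 3, 3, 10)), 0)
  expect_error(positive_agreement(contingency_2x2(0, 0, 0, 4)), "undefined")
})

test_that("Cohen's kappa matches the published value and its identities", {
  k <- cohens_kappa(reference_table())
  expect_equal(round(k$kappa, 3), 0.525)
  expect_true(k$ci_low <= k$kappa && k$kappa <= k$ci_high)
  expect_equal(cohens_kappa(contingency_2x2(10, 0, 0, 10))$kappa, 1)
  expect_equal(cohens_kappa(contingency_2x2(25, 25, 25, 25))$kappa, 0)
  ## invariance under simultaneous label swap of both raters
  set.seed(2)
  for (i in 1:20) {
    x <- rmultinom(1, 40, c(0.4, 0.2, 0.15, 0.25))
    t1 <- contingency_2x2(x[1], x[2], x[3], x[4])
    t2 <- contingency_2x2(x[4], x[3], x[2], x[1])
    k1 <- try(cohens_kappa(t1), silent = TRUE)
    k2 <- try(cohens_kappa(t2), silent = TRUE)
    if (!inherits(k1, "try-error") && !inherits(k2, "try-error")) {
      expect_equal(k1$kappa, k2$kappa, tolerance = 1e-12)
    }
  }
})

test_that("kappa and percent agreement equal the brute-force oracle on all
           small tables", {
  for (n in c(2, 5, 8, 12)) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      t <- contingency_2x2(a, b, cc, d)
      oracle <- oracle_kappa_po_pe(a, b, cc, d)
      expect_equal(percent_agreement(t), 100 * oracle$po, tolerance = 1e-12)
      if (abs(1 - oracle$pe) > 1e-12) {
        expect_equal(cohens_kappa(t)$kappa, oracle$kappa, tolerance = 1e-12)
      } else {
        expect_error(cohens_kappa(t), "undefined")
      }
    }
  }
})

test_that("ICC(A,1) matches the two-way ANOVA mean-squares oracle", {
  pairs <- matrix(c(50, 60, 70, 80, 55, 65,
                    52, 59, 71, 78, 57, 62), ncol = 2)
  r <- icc_agreement(pairs)
  ## oracle: mean squares from stats::aov on the long layout
  df <- data.frame(y = c(pairs), subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  ms <- anova(stats::aov(y ~ subj + rater, df))[["Mean Sq"]]
  oracle <- (ms[1] - ms[3]) / (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / 6)
  expect_equal(r$icc, oracle, tolerance = 1e-10)
  expect_equal(r$icc, 0.9816147, tolerance = 1e-6)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
  ## perfect agreement
  same <- cbind(c(50, 60, 70, 80), c(50, 60, 70, 80))
  expect_equal(icc_agreement(same)$icc, 1)
  expect_error(icc_agreement(cbind(rep(5, 4), rep(5, 4))), "constant")
  expect_error(icc_agreement(same[1:2, ]), "3 pairs")
})

test_that("Cicchetti bands follow the published interpretation", {
  expect_equal(icc_band(0.764), "excellent")
  expect_equal(icc_band(0.743), "good")
  expect_equal(icc_band(c(0.39, 0.40, 0.59, 0.60, 0.74, 0.75)),
               c("poor", "fair", "fair", "good", "good", "excellent"))
})

test_that("absolute-agreement ICC penalises a constant rater offset", {
  x <- seq(40, 80, length.out = 30)
  iccs <- vapply(c(0, 2, 5, 10), function(offset) {
    icc_agreement(cbind(x, x + offset))$icc
  }, 0)
  expect_equal(iccs[1], 1)
  expect_true(all(diff(iccs) < 0))
})

test_that("ICC recovers the simulated variance ratio at n = 2000", {
  set.seed(1234)
  sigma_s <- 7; sigma_e <- 4
  subj <- rnorm(2000, 60, sigma_s)
  pairs <- cbind(subj + rnorm(2000, 0, sigma_e),
                 subj + rnorm(2000, 0, sigma_e))
  truth <- sigma_s^2 / (sigma_s^2 + sigma_e^2)
  expect_lt(abs(icc_agreement(pairs)$icc - truth), 0.05)
})

test_that("paired summary computes MAD, difference stats and fractions", {
  same <- cbind(c(55, 62, 70), c(55, 62, 70))
  s <- paired_summary(same)
  expect_equal(s$mad, 0)
  expect_equal(s$diff_mean, 0)
  expect_equal(s$within5_fraction, 1)
  expect_equal(s$concordance60_fraction, 1)
  s2 <- paired_summary(cbind(c(1, 3), c(2, 5)))
  expect_equal(s2$mad, 1.5)
  expect_equal(s2$diff_mean, -1.5)
  ## strict <5 band; inclusive 60-degree boundary
  s3 <- paired_summary(cbind(c(60, 64.9), c(55, 60)))
  expect_equal(s3$within5_fraction, 0.5)
  expect_equal(s3$concordance60_fraction, 0.5)
})

test_that("paired-difference SD of a simulated appropriate set matches the
           rater noise", {
  co <- generate_cohort(320, rater_noise_sd = 4.5, render = FALSE, seed = 77)
  pairs <- do.call(rbind, lapply(co, function(el) {
    c(el$reading$ai$alpha_deg, el$reading$human$alpha_deg)
  }))
  s <- paired_summary(pairs)
  expect_gt(s$diff_sd, 3.9)
  expect_lt(s$diff_sd, 5.1)
})

test_that("evaluate_cohort assembles the full report", {
  rep <- evaluate_cohort(cohort_readings(reference_cohort()))
  expect_s3_class(rep, "agreement_report")
  expect_equal(round(rep$percent_agreement, 1), 80.9)
  expect_equal(round(rep$kappa$kappa, 3), 0.525)
  expect_equal(as.integer(rep$triage["appropriate"]), 320)
  expect_equal(nrow(rep$alpha$pairs), 320)
  expect_true(rep$alpha$icc$icc > 0 && rep$alpha$icc$icc <= 1)
  out <- capture.output(print(rep))
  expect_true(any(grepl("percent agreement:  80.9%", out, fixed = TRUE)))
})
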