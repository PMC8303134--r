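test_that("phantom spec validation names the violated bound", {
  expect_error(phantom_spec(alpha_deg = 95), "alpha_deg")
  expect_error(phantom_spec(beta_deg = 0), "beta_deg")
  expect_error(phantom_spec(check_deg = 31), "check_deg")
  expect_error(phantom_spec(width_px = 32), "width_px")
  expect_error(phantom_spec(brightness_factor = 0.5), "brightness_factor")
})

test_that("landmark generation round-trips the requested angles", {
  sp <- phantom_spec(alpha_deg = 60, beta_deg = 55, check_deg = 0, seed = 1)
  m <- measure_landmarks(generate_landmarks(sp))
  expect_equal(m$check_deg, 0, tolerance = 1e-6)
  expect_equal(m$alpha_deg, 60, tolerance = 1e-6)
  expect_equal(m$beta_deg, 55, tolerance = 1e-6)
  ## determinism
  expect_identical(generate_landmarks(sp), generate_landmarks(sp))
  sp2 <- phantom_spec(alpha_deg = 43.7, beta_deg = 77.2, check_deg = -4,
                      seed = 9)
  m2 <- measure_landmarks(generate_landmarks(sp2))
  expect_equal(m2$alpha_deg, 43.7, tolerance = 1e-6)
  expect_equal(m2$beta_deg, 77.2, tolerance = 1e-6)
  expect_equal(m2$check_deg, -4, tolerance = 1e-6)
})

test_that("round trip holds across 100 random specs within 1e-6 degrees", {
  for (sp in random_specs(100, seed = 7)) {
    m <- measure_landmarks(generate_landmarks(sp))
    expect_equal(m$alpha_deg, sp$alpha_deg, tolerance = 1e-6)
    expect_equal(m$beta_deg, sp$beta_deg, tolerance = 1e-6)
    expect_equal(m$check_deg, sp$check_deg, tolerance = 1e-6)
  }
})

test_that("recomputed alpha increases strictly with the requested alpha", {
  alphas <- seq(35, 80, by = 5)
  rec <- vapply(alphas, function(a) {
    compute_alpha(generate_landmarks(phantom_spec(alpha_deg = a)))
  }, 0)
  expect_true(all(diff(rec) > 0))
})

test_that("phantom truth masks are valid and landmarks in bounds", {
  tr <- phantom_truth(phantom_spec())
  expect_named(tr$masks, c("ilium", "acetabulum", "labrum"))
  for (m in tr$masks) expect_gt(sum(m), 0)
  expect_false(identical(tr$masks$ilium, tr$masks$acetabulum))
  expect_false(identical(tr$masks$ilium, tr$masks$labrum))
  for (nm in names(tr$landmarks)) {
    p <- tr$landmarks[[nm]]
    expect_true(p[1] >= 0 && p[1] <= tr$spec$width_px - 1)
    expect_true(p[2] >= 0 && p[2] <= tr$spec$height_px - 1)
  }
})

test_that("noise-free rasterisation writes exact bone intensities", {
  ph <- generate_phantom(phantom_spec(speckle_sigma = 0,
                                      brightness_factor = 1))
  expect_true(all(ph$image[ph$truth$masks$ilium] ==
                    ph$truth$spec$bone_intensity))
  bg <- !(ph$truth$masks$ilium | ph$truth$masks$acetabulum |
            ph$truth$masks$labrum)
  expect_true(all(ph$image[bg] == ph$truth$spec$soft_intensity))
})

test_that("rasterisation is seeded and structures stay brighter than
           background under default noise", {
  sp <- phantom_spec(seed = 42)
  img1 <- rasterize_phantom(phantom_truth(sp))
  img2 <- rasterize_phantom(phantom_truth(sp))
  expect_identical(img1, img2)
  tr <- phantom_truth(sp)
  bg <- !(tr$masks$ilium | tr$masks$acetabulum | tr$masks$labrum)
  expect_gt(mean(img1[tr$masks$ilium]), mean(img1[bg]))
  ## different seed changes the speckle
  img3 <- rasterize_phantom(phantom_truth(phantom_spec(seed = 43)))
  expect_false(identical(img1, img3))
})

test_that("cohort generation obeys the failure rate and rater-noise model", {
  co <- generate_cohort(10, detect_failure_rate = 0, render = FALSE, seed = 2)
  expect_length(co, 10)
  expect_true(all(vapply(co, function(el) {
    el$reading$ai$detectable && el$reading$human$detectable
  }, TRUE)))
  ## zero rater noise: AI and human triplets identical
  co0 <- generate_cohort(8, rater_noise_sd = 0, render = FALSE, seed = 3)
  for (el in co0) {
    expect_equal(el$reading$ai$alpha_deg, el$reading$human$alpha_deg)
    expect_equal(el$reading$ai$beta_deg, el$reading$human$beta_deg)
    expect_equal(el$reading$ai$check_deg, el$reading$human$check_deg)
  }
  expect_error(generate_cohort(5, detect_failure_rate = 1), "failure_rate")
  expect_error(generate_cohort(0), "n must")
})

test_that("paired-difference SD matches the requested rater noise at n=500", {
  co <- generate_cohort(500, rater_noise_sd = 4.5, render = FALSE, seed = 10)
  d <- vapply(co, function(el) {
    el$reading$ai$alpha_deg - el$reading$human$alpha_deg
  }, 0)
  expect_gt(sd(d), 3.8)
  expect_lt(sd(d), 5.2)
})

test_that("zero rater noise propagates to perfect downstream agreement", {
  co <- generate_cohort(30, rater_noise_sd = 0, render = FALSE, seed = 6)
  rep <- evaluate_cohort(cohort_readings(co))
  expect_equal(rep$percent_agreement, 100)
  expect_equal(rep$alpha$icc$icc, 1, tolerance = 1e-9)
  expect_equal(rep$alpha$summary$mad, 0)
  expect_equal(rep$alpha$summary$concordance60_fraction, 1)
})
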