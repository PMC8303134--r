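test_that("segmentation recovers the three truth masks on a noise-free
           phantom", {
  ph <- noise_free_phantom(alpha = 64, beta = 41, check = 2, seed = 1)
  masks <- segment_structures(ph$image)
  expect_true(masks$complete)
  for (nm in c("ilium", "acetabulum", "labrum")) {
    expect_gte(mask_overlap(masks$masks[[nm]], ph$truth$masks[[nm]]), 0.8)
  }
  expect_true(all(masks$confidence >= 0.5))
})

test_that("segmentation reports incomplete results instead of raising", {
  expect_false(segment_structures(matrix(0, 128, 128))$complete)
  ## phantom with the labrum erased: only two structures remain
  ph <- noise_free_phantom()
  img <- ph$image
  img[ph$truth$masks$labrum] <- ph$truth$spec$soft_intensity
  expect_false(segment_structures(img)$complete)
  expect_false(detect(img)$detectable)
})

test_that("stage-1 conversion is the white-on-black union of the masks", {
  ph <- noise_free_phantom()
  s1 <- masks_to_stage1(ph$truth$masks)
  expect_setequal(unique(as.vector(s1)), c(0L, 255L))
  union_count <- sum(ph$truth$masks$ilium | ph$truth$masks$acetabulum |
                       ph$truth$masks$labrum)
  expect_equal(sum(s1 == 255), union_count)
  ## degenerate inputs
  empty <- matrix(FALSE, 16, 16)
  expect_true(all(masks_to_stage1(list(empty)) == 0))
  full <- matrix(TRUE, 16, 16)
  expect_true(all(masks_to_stage1(list(full)) == 255))
  ## idempotence: masks derived from the stage-1 output reproduce it
  expect_identical(masks_to_stage1(list(s1 > 0)), s1)
})

test_that("keypoints land within 3 px of truth and angles within 2 degrees
           on noise-free phantoms", {
  ph <- noise_free_phantom(alpha = 58, beta = 47, check = -3, seed = 2)
  masks <- segment_structures(ph$image)
  lms <- extract_keypoints(masks)
  for (nm in names(ph$truth$landmarks)) {
    expect_lt(sqrt(sum((lms[[nm]] - ph$truth$landmarks[[nm]])^2)), 3)
  }
  m <- measure_landmarks(lms)
  tm <- measure_landmarks(ph$truth$landmarks)
  expect_lt(abs(m$alpha_deg - tm$alpha_deg), 2)
  expect_lt(abs(m$beta_deg - tm$beta_deg), 2)
})

test_that("extract_keypoints raises a missing-landmark error on empty masks", {
  ph <- noise_free_phantom()
  masks <- segment_structures(ph$image)
  masks$masks$labrum <- matrix(FALSE, nrow(ph$image), ncol(ph$image))
  expect_error(extract_keypoints(masks), "labrum")
})

test_that("detect composes the stages and encodes failures in the result", {
  ph <- noise_free_phantom(alpha = 70, beta = 50, check = 4, seed = 3)
  dr <- detect(ph$image)
  expect_true(dr$detectable)
  ## stagewise application gives the same landmarks
  lms <- extract_keypoints(segment_structures(ph$image))
  expect_equal(dr$landmarks, lms)
  expect_identical(dr$stage1, masks_to_stage1(dr$masks))
  m <- measure_landmarks(dr$landmarks)
  expect_lt(abs(m$alpha_deg - 70), 2)
  ## structureless input
  set.seed(8)
  noise <- matrix(runif(256 * 256, 0, 255), 256, 256)
  dn <- detect(noise)
  expect_false(dn$detectable)
  expect_null(dn$landmarks)
})

test_that("alpha recovery over 100 noise-free phantoms spanning 40-80 deg
           keeps mean error <= 1 and max <= 2 degrees", {
  set.seed(31)
  alphas <- seq(40, 80, length.out = 100)
  errs <- vapply(seq_along(alphas), function(i) {
    ph <- noise_free_phantom(alpha = alphas[i], beta = runif(1, 25, 70),
                             check = runif(1, -8, 8), seed = i)
    dr <- detect(ph$image)
    expect_true(dr$detectable)
    abs(compute_alpha(dr$landmarks) - alphas[i])
  }, 0)
  expect_lte(mean(errs), 1)
  expect_lte(max(errs), 2)
})

test_that("most phantoms stay detectable at the default speckle level", {
  det <- vapply(1:50, function(i) {
    detect(generate_phantom(phantom_spec(
      alpha_deg = 45 + (i %% 35), beta_deg = 25 + (i %% 40),
      check_deg = (i %% 17) - 8, seed = i))$image)$detectable
  }, TRUE)
  expect_gte(mean(det), 0.9)
})

test_that("detectability degrades monotonically with speckle", {
  frac <- vapply(c(0.05, 0.4, 1.0, 1.6), function(s) {
    mean(vapply(1:20, function(i) {
      detect(generate_phantom(phantom_spec(
        alpha_deg = 45 + i, beta_deg = 30 + i %% 25, speckle_sigma = s,
        seed = i))$image)$detectable
    }, TRUE))
  }, 0)
  expect_true(all(diff(frac) <= 0))
  expect_equal(frac[1], 1)
})
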