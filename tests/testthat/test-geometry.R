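test_that("angle_between_lines handles canonical configurations", {
  expect_equal(angle_between_lines(c(0, 0), c(0, 10), c(0, 0), c(10, 0)), 90)
  expect_equal(angle_between_lines(c(0, 0), c(5, 5), c(2, 2), c(9, 9)), 0)
  expect_equal(angle_between_lines(c(0, 0), c(1, 1), c(0, 0), c(1, 0)), 45)
  expect_error(angle_between_lines(c(0, 0), c(0, 0), c(0, 0), c(1, 0)),
               "degenerate")
})

test_that("angle_between_lines is symmetric in line and point order", {
  set.seed(11)
  for (i in 1:20) {
    a1 <- runif(2, 0, 100); a2 <- runif(2, 0, 100)
    b1 <- runif(2, 0, 100); b2 <- runif(2, 0, 100)
    ang <- angle_between_lines(a1, a2, b1, b2)
    expect_equal(angle_between_lines(b1, b2, a1, a2), ang)
    expect_equal(angle_between_lines(a2, a1, b1, b2), ang)
    expect_gte(ang, 0); expect_lte(ang, 90)
  }
})

test_that("check angle is signed against the image vertical", {
  ls <- landmark_set(c(100, 50), c(100, 200), c(105, 210), c(160, 170),
                     c(180, 150))
  expect_equal(compute_check_angle(ls), 0)
  ls2 <- landmark_set(c(100, 50), c(113.1, 200), c(105, 210), c(160, 170),
                      c(180, 150))
  expect_equal(compute_check_angle(ls2), atan2(13.1, 150) * 180 / pi,
               tolerance = 1e-8)
  expect_equal(compute_check_angle(ls2), 5.0, tolerance = 0.01)
  ## mirroring x negates the sign
  mirror <- landmark_set(c(-100, 50), c(-113.1, 200), c(-105, 210),
                         c(-160, 170), c(-180, 150))
  expect_equal(compute_check_angle(mirror), -compute_check_angle(ls2))
})

test_that("alpha and beta follow the four-point construction", {
  ## vertical baseline with a 30-60-90 bony roof triangle
  ls <- landmark_set(c(100, 50), c(100, 250), c(100, 200), c(186.6, 150),
                     c(200, 100))
  expect_equal(compute_alpha(ls), 60, tolerance = 0.01)
  ## bony roof parallel to the baseline
  lsp <- landmark_set(c(100, 50), c(100, 250), c(120, 100), c(120, 200),
                      c(160, 150))
  expect_equal(compute_alpha(lsp), 0)
  ## cartilage roof parallel to the baseline
  lsb <- landmark_set(c(100, 50), c(100, 250), c(105, 210), c(130, 100),
                      c(130, 180))
  expect_equal(compute_beta(lsb), 0)
  ## beta from the arctan oracle (line from vertical): atan(50 / 34.04)
  ls5 <- landmark_set(c(30, 20), c(30, 240), c(40, 210), c(60, 150),
                      c(110, 115.96))
  expect_equal(compute_beta(ls5), atan2(50, 34.04) * 180 / pi,
               tolerance = 1e-8)
  expect_equal(compute_beta(ls5), 55.75297, tolerance = 0.001)
})

test_that("Graf classification uses an inclusive 60-degree boundary", {
  expect_equal(classify_graf(64.117), "normal")
  expect_equal(classify_graf(59.9), "abnormal")
  expect_equal(classify_graf(60.0), "normal")
  expect_error(classify_graf(95), "0, 90")
})

test_that("angles agree with the arc-cosine oracle on random landmark sets", {
  set.seed(99)
  for (i in 1:200) {
    ls <- random_landmark_set()
    expect_equal(compute_alpha(ls),
                 oracle_line_angle(ls$check_upper, ls$triradiate,
                                   ls$lower_ilium, ls$bone_edge),
                 tolerance = 1e-9)
    expect_equal(compute_beta(ls),
                 oracle_line_angle(ls$check_upper, ls$triradiate,
                                   ls$bone_edge, ls$labrum_end),
                 tolerance = 1e-9)
  }
})

test_that("angles are invariant to translation and scaling, and rotation
           shifts only the check angle", {
  rotate <- function(p, th) {
    th <- th * pi / 180
    c(cos(th) * p[1] + sin(th) * p[2], -sin(th) * p[1] + cos(th) * p[2])
  }
  set.seed(5)
  for (i in 1:100) {
    ls <- random_landmark_set()
    a0 <- compute_alpha(ls); b0 <- compute_beta(ls)
    c0 <- compute_check_angle(ls)
    shift <- runif(2, -50, 50); sc <- runif(1, 0.3, 3)
    tr <- ls
    for (nm in names(tr)) tr[[nm]] <- (tr[[nm]] + shift) * sc
    expect_equal(compute_alpha(tr), a0, tolerance = 1e-9)
    expect_equal(compute_beta(tr), b0, tolerance = 1e-9)
    expect_equal(compute_check_angle(tr), c0, tolerance = 1e-9)
    th <- runif(1, -20, 20)
    rot <- ls
    for (nm in names(rot)) rot[[nm]] <- rotate(rot[[nm]], th)
    expect_equal(compute_alpha(rot), a0, tolerance = 1e-8)
    expect_equal(compute_beta(rot), b0, tolerance = 1e-8)
    ## modulo 180: the undirected baseline folds into (-90, 90]
    wrapped <- (compute_check_angle(rot) - (c0 + th) + 90) %% 180 - 90
    expect_equal(wrapped, 0, tolerance = 1e-8)
  }
})

test_that("measure_landmarks bundles the three angles and the Graf call", {
  ls <- landmark_set(c(100, 50), c(100, 250), c(100, 200), c(186.6, 150),
                     c(200, 100))
  m <- measure_landmarks(ls)
  expect_s3_class(m, "graf_measurement")
  expect_equal(m$alpha_deg, 60, tolerance = 0.01)
  expect_equal(m$graf_call, classify_graf(m$alpha_deg))
  df <- measurements_to_df(list(img1 = m), rater = "human")
  expect_named(df, c("image_id", "rater", "check_deg", "alpha_deg",
                     "beta_deg", "graf_call"))
  expect_equal(df$alpha_deg, round(m$alpha_deg, 3))
})
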