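square <- plane_contour(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))

test_that("normalized position maps chords linearly to [-1, 1]", {
  p <- normalize_position(5, 5, square)
  expect_equal(p$ml, 0)
  expect_equal(p$dv, 0)

  expect_equal(normalize_position(7.5, 5, square)$ml, 0.5)
  expect_equal(normalize_position(5, 2.5, square)$dv, -0.5)

  # direction metadata flips the sign
  flipped <- plane_contour(square$vertices, lateral_dir = -1)
  expect_equal(normalize_position(7.5, 5, flipped)$ml, -0.5)

  expect_error(normalize_position(11, 5, square), "outside")
  expect_error(normalize_position(10, 5, square), "outside")  # on the border
})

test_that("first-intersection logic matches a brute-force oracle on a notched contour", {
  notched <- make_contours(1, notch_depth = 0.5, seed = 20)[[1]]
  set.seed(21)
  n_done <- 0
  while (n_done < 50) {
    x <- runif(1, -2000, 2000); y <- runif(1, -1500, 1500)
    if (!point_in_contour(notched, x, y)) next
    n_done <- n_done + 1
    got <- normalize_position(x, y, notched)
    want <- brute_normalize(notched$vertices, x, y)
    expect_equal(got$ml, unname(want["ml"]), tolerance = 1e-9)
    expect_equal(got$dv, unname(want["dv"]), tolerance = 1e-9)
  }
})

test_that("normalization is invariant to translation and isotropic scaling", {
  ctr <- make_contours(1, seed = 22)[[1]]
  set.seed(23)
  pts <- sample_biased_neurons(ctr, 20, 0.2, -0.1)
  ref <- normalize_position(pts$x, pts$y, ctr)
  moved <- plane_contour(ctr$vertices * 3.7 + 100)
  got <- normalize_position(pts$x * 3.7 + 100, pts$y * 3.7 + 100, moved)
  expect_equal(got$ml, ref$ml, tolerance = 1e-9)
  expect_equal(got$dv, ref$dv, tolerance = 1e-9)
})

test_that("ray-parametrization round-trip reproduces target coordinates", {
  ctr <- make_contours(1, seed = 24)[[1]]
  for (tgt in list(c(0.37, -0.52), c(-0.8, 0.1), c(0, 0), c(0.64, 0.64))) {
    inv <- invert_normalized_position(tgt[1], tgt[2], ctr)
    expect_true(inv$converged)
    got <- normalize_position(inv$x, inv$y, ctr)
    expect_equal(got$ml, tgt[1], tolerance = 1e-9)
    expect_equal(got$dv, tgt[2], tolerance = 1e-9)
  }
})

test_that("mean normalized position of unbiased samples approaches zero", {
  ctr <- make_contours(1, seed = 25)[[1]]
  pts <- sample_biased_neurons(ctr, 1000, 0, 0, seed = 26)
  np <- normalize_position(pts$x, pts$y, ctr)
  expect_lt(abs(mean(np$ml)), 0.05)
  expect_lt(abs(mean(np$dv)), 0.05)
})

test_that("plane bias test skips small planes and detects an imposed shift", {
  expect_s3_class(plane_bias_test(rep(0.3, 5)), "pv_skip")

  ctr <- make_contours(1, seed = 27)[[1]]
  set.seed(28)
  hits_null <- hits_bias <- 0
  for (i in 1:20) {
    unif <- sample_biased_neurons(ctr, 100, 0, 0)
    np0 <- normalize_position(unif$x, unif$y, ctr)
    if (plane_bias_test(np0, "ml")$p_value > 0.05) hits_null <- hits_null + 1
    sh <- sample_biased_neurons(ctr, 100, 0.2, 0)
    np1 <- normalize_position(sh$x, sh$y, ctr)
    if (plane_bias_test(np1, "ml")$p_value < 0.05) hits_bias <- hits_bias + 1
  }
  expect_gte(hits_null, 18)   # alpha control
  expect_gte(hits_bias, 18)   # power at bias 0.2, n = 100
})

test_that("population comparison feeds the FDR correction across planes", {
  expect_s3_class(compare_populations(rep(0.1, 4), rnorm(50)), "pv_skip")

  set.seed(29)
  x <- rnorm(100, 0, 0.3)
  expect_gt(compare_populations(x, x, "ml")$p_value, 0.99)

  # a shifted population should survive BH over 13 planes
  p <- vapply(1:13, function(i) {
    compare_populations(rnorm(100, 0.3, 0.3), rnorm(100, 0, 0.3))$p_value
  }, numeric(1))
  expect_true(all(fdr_adjust(p)$significant))

  # one marginal plane out of 13 does not survive BH
  p2 <- c(0.04, runif(12, 0.2, 0.9))
  expect_false(any(fdr_adjust(p2)$significant))
})

test_that("cross-plane variability statistic matches hand computation", {
  expect_equal(cross_plane_variability(c(0.2, 0.2, 0.2)), c(0, 0, 0))
  expect_equal(cross_plane_variability(c(-1, 0, 1)), c(1.5, 1.0, 1.5))
  # a consistent shared bias scores zero variability
  expect_equal(cross_plane_variability(rep(0.5, 5)), rep(0, 5))
  expect_error(cross_plane_variability(c(1, 2)), "3 planes")

  # signed-mean variant collapses opposing differences
  expect_equal(cross_plane_variability(c(-1, 0, 1), mode = "abs_mean"),
               c(1.5, 0, 1.5))
})

test_that("a rostral-lateral to caudal-medial gradient yields high variability", {
  # 13-plane gradient (lateral rostrally, medial caudally) vs flat pattern
  set.seed(30)
  gradient <- seq(0.5, -0.5, length.out = 13) + rnorm(13, 0, 0.05)
  flat <- rnorm(13, 0, 0.05)
  r <- compare_cross_plane_variability(list(gradient = gradient, flat = flat))
  expect_lt(r$p_value, 0.01)
  expect_gt(mean(r$d$gradient), mean(r$d$flat))
})
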