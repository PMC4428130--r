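test_that("top-quantile median follows the ceiling rule", {
  expect_equal(top_quantile_median(toy_effect(rep(3.2, 50))), 3.2)
  expect_equal(top_quantile_median(toy_effect(1:1000), fraction = 0.001),
               1000)   # n_top = 1
  expect_equal(top_quantile_median(toy_effect(1:2000), fraction = 0.001),
               1999.5) # n_top = 2: median of {1999, 2000}
  expect_error(top_quantile_median(toy_effect(c(-1, -2, 0))), "positive")
})

test_that("packaged models carry the calibrated slopes and predict gamma", {
  loci <- threshold_model("loci")
  extent <- threshold_model("extent")
  expect_equal(loci$slope, 0.497)
  expect_equal(extent$slope, 0.144)
  expect_equal(loci$top_fraction, 0.001)
  # map with 2000 positive voxels whose top-two median is exactly 1.0
  vals <- c(seq(0.0001, 0.998, length.out = 1998), 0.9995, 1.0005)
  eff <- toy_effect(vals)
  expect_equal(top_quantile_median(eff), 1.0)
  expect_equal(predict(loci, eff), 0.497)
  expect_equal(predict(extent, eff), 0.144)
  expect_equal(predict_gamma(loci, eff), predict(loci, eff))
  # homogeneity: doubling the map doubles gamma
  eff2 <- toy_effect(2 * vals)
  expect_equal(predict(loci, eff2), 2 * 0.497)
})

test_that("prediction ignores voxel order and out-of-mask values", {
  set.seed(31)
  vals <- runif(500, 0, 3)
  eff <- toy_effect(vals)
  shuffled <- toy_effect(sample(vals))
  m <- threshold_model("loci")
  expect_equal(predict(m, eff), predict(m, shuffled))
  padded <- toy_effect(c(vals, 99, 999))
  padded$mask[501:502, 1, 1] <- FALSE
  padded$mu[501:502, 1, 1] <- c(99, 999)
  expect_equal(predict(m, padded), predict(m, eff))
})

test_that("reference-cluster selection follows ROI overlap with tie-breaks", {
  t <- array(0, c(10, 3, 1))
  t[1:3, 1, 1] <- 5   # blob A (3 voxels)
  t[6:9, 1, 1] <- 5   # blob B (4 voxels)
  tm <- structure(list(t = t, dof = 50, contrast = c(1),
                       mask = array(TRUE, dim(t))), class = "t_map")
  roiB <- array(FALSE, dim(t)); roiB[7, 1, 1] <- TRUE
  sel <- select_reference_cluster(tm, 1, 18, roiB)
  expect_equal(which(sel), c(6:9))
  # roi covering both equally: larger component wins
  roiAB <- array(FALSE, dim(t)); roiAB[c(2, 7), 1, 1] <- TRUE
  expect_equal(which(select_reference_cluster(tm, 1, 18, roiAB)), 6:9)
  # equal overlap and equal size: lowest linear index wins
  t2 <- array(0, c(7, 1, 1)); t2[1:2] <- 5; t2[6:7] <- 5
  tm2 <- structure(list(t = t2, dof = 50, contrast = c(1),
                        mask = array(TRUE, dim(t2))), class = "t_map")
  roi2 <- array(FALSE, dim(t2)); roi2[c(1, 6)] <- TRUE
  expect_equal(which(select_reference_cluster(tm2, 1, 18, roi2)), 1:2)
  # coordinate ROI and error contracts
  expect_equal(which(select_reference_cluster(tm, 1, 18, c(2, 1, 1))), 1:3)
  roiN <- array(FALSE, dim(t)); roiN[5, 2, 1] <- TRUE
  expect_error(select_reference_cluster(tm, 1, 18, roiN), "disjoint")
  expect_error(select_reference_cluster(tm, 99, 18, roiB), "no voxel")
})

test_that("overlapping union keeps whole clusters that touch the reference", {
  act <- array(FALSE, c(12, 1, 1))
  act[1:4] <- TRUE     # overlapping component
  act[9:11] <- TRUE    # disjoint component
  cref <- array(FALSE, dim(act)); cref[3:6] <- TRUE
  cb <- overlapping_union(act, cref, 18)
  expect_equal(which(cb), 1:4)  # includes voxels outside cref
  # identity and empty cases
  expect_equal(overlapping_union(cref, cref, 18), cref)
  none <- array(FALSE, dim(act)); none[9:11] <- TRUE
  expect_equal(sum(overlapping_union(none, cref, 18)), 0)
})

test_that("gamma sweep finds a constructed plateau and obeys grid rules", {
  # piecewise-constant blob: core mu = 5, shell mu = 2, tiny sigma
  mu <- array(0, c(9, 9, 3))
  mu[3:7, 3:7, 2] <- 2
  mu[4:6, 4:6, 2] <- 5
  eff <- effect_map(mu, array(1e-4, dim(mu)), array(TRUE, dim(mu)))
  cref <- mu == 5
  sw <- gamma_sweep(eff, cref, lbt = 10)
  expect_equal(max(sw$raw_j), 1)
  expect_gte(sw$optimal_gamma, 2)     # inside the (2, 5) plateau
  expect_lt(sw$optimal_gamma, 5)
  expect_equal(sw$gamma_max, 5)       # first empty grid point
  expect_equal(length(sw$gammas), 501)
  # constant-J curve resolves ties toward gamma = 0
  cref2 <- mu > 0
  sw2 <- gamma_sweep(eff, cref2, lbt = 10, delta_gamma = 0.5)
  expect_equal(sw2$raw_j[1], sw2$raw_j[2])
  expect_equal(sw2$optimal_gamma, 0)
  # raw J non-increasing beyond the plateau for a monotone blob
  after <- sw$raw_j[sw$gammas >= 2]
  expect_true(all(diff(after) <= 1e-12))
  # empty activated set at gamma = 0 is an error
  empty <- effect_map(array(-1, c(2, 2, 1)), array(0.01, c(2, 2, 1)),
                      array(TRUE, c(2, 2, 1)))
  expect_error(gamma_sweep(empty, array(TRUE, c(2, 2, 1))), "empty")
})

test_that("grid has 101 points when activation vanishes at gamma = 1", {
  mu <- array(0, c(5, 5, 1)); mu[2:4, 2:4, 1] <- 0.996
  eff <- effect_map(mu, array(1e-4, dim(mu)), array(TRUE, dim(mu)))
  cref <- mu > 0
  sw <- gamma_sweep(eff, cref, lbt = 10)
  expect_equal(sw$gamma_max, 1)
  expect_equal(length(sw$gammas), 101)
})

test_that("bisquare calibration is exact on clean data and rejects outliers", {
  x <- c(1, 2, 3, 4)
  fit <- calibrate_slope(x, 0.5 * x)
  expect_equal(fit$slope, 0.5, tolerance = 1e-10)
  expect_equal(fit$weights, rep(1, 4))
  # single point through the origin
  expect_equal(calibrate_slope(2, 1)$slope, 0.5)
  # 9 points on y = 0.5x plus one gross outlier at x = 5.2
  xg <- seq(1, 5, length.out = 9)
  xo <- c(xg, 5.2); yo <- c(0.5 * xg, 0.5 * 5.2 + 1)
  rob <- calibrate_slope(xo, yo)
  expect_lt(abs(rob$slope - 0.5), 1e-3)
  expect_lt(rob$weights[10], 0.05)
  # ordinary least squares is pulled off 0.5 by the same point
  ols_slope <- sum(xo * yo) / sum(xo^2)
  expect_gt(abs(ols_slope - 0.5), 0.02)
})

test_that("bisquare calibration agrees with an independent robust fitter", {
  skip_if_not_installed("MASS")
  set.seed(43)
  x <- runif(30, 1, 6)
  y <- 0.7 * x + rnorm(30, sd = 0.3)
  y[5] <- y[5] + 8
  ours <- calibrate_slope(x, y)
  theirs <- MASS::rlm(y ~ x - 1, psi = MASS::psi.bisquare, maxit = 100)
  expect_equal(ours$slope, unname(coef(theirs)), tolerance = 0.02)
  expect_lt(ours$weights[5], 0.05)
})

test_that("threshold models serialise to structured text and back", {
  dir <- withr::local_tempdir()
  m <- threshold_model("extent")
  p <- file.path(dir, "model.yaml")
  write_threshold_model(m, p)
  back <- read_threshold_model(p)
  expect_equal(back$slope, m$slope)
  expect_equal(back$scenario, m$scenario)
  expect_s3_class(back, "threshold_model")
})
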