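make_series <- function(Y, tr_s = 2) {
  # wrap a time x voxels matrix as a 1-D row of voxels
  n_vox <- ncol(Y)
  bold_series(array(t(Y), c(n_vox, 1, 1, nrow(Y))), tr_s = tr_s)
}

fake_design <- function(X) {
  structure(list(matrix = X, column_names = colnames(X),
                 task_index = 1L, derivative_index = NA_integer_,
                 mean_index = ncol(X)),
            class = "fmri_design")
}

test_that("fit_glm solves the normal equations (hand-checked 2x2 case)", {
  X <- cbind(effect = c(0, 1, 0, 1), mean = 1)
  fit <- fit_glm(make_series(matrix(1:4, 4, 1)), fake_design(X), whiten = 0)
  # by hand: mean of (1,3) = 2 -> intercept; effect = mean(2,4) - 2 = 1
  expect_equal(unname(fit$beta[1, ]), c(1, 2), tolerance = 1e-12)
})

test_that("unwhitened fit matches a pseudoinverse oracle voxel by voxel", {
  set.seed(42)
  n <- 60
  X <- cbind(task = rnorm(n), drift = seq_len(n) / n, mean = 1)
  Y <- matrix(rnorm(n * 100), n, 100)
  fit <- fit_glm(make_series(Y), fake_design(X), whiten = 0)
  for (v in sample(100, 20)) {
    expect_lt(max(abs(fit$beta[v, ] - ols_oracle(X, Y[, v]))), 1e-8)
  }
  expect_equal(fit$dof, n - 3L)
})

test_that("t maps follow the closed-form simple-regression t", {
  set.seed(1)
  n <- 50
  x <- rnorm(n)
  y <- 0.4 * x + rnorm(n)
  X <- cbind(task = x, mean = 1)
  fit <- fit_glm(make_series(matrix(y, n, 1)), fake_design(X), whiten = 0)
  tm <- t_map(fit, c(1, 0))
  lmfit <- summary(stats::lm(y ~ x))
  expect_equal(tm$t[1, 1, 1], lmfit$coefficients["x", "t value"],
               tolerance = 1e-10)
  # linearity: negating the contrast negates t
  tn <- t_map(fit, c(-1, 0))
  expect_equal(tn$t, -tm$t)
  expect_error(t_map(fit, c(0, 0)), "non-zero")
})

test_that("t map is invariant to positive rescaling of the series", {
  spec <- small_spec(seed = 2L)
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  t1 <- t_map(fit_glm(ph$series, X, whiten = 0), positive_task_contrast(X))
  ph$series$data <- ph$series$data * 3.7
  t2 <- t_map(fit_glm(ph$series, X, whiten = 0), positive_task_contrast(X))
  expect_equal(t1$t, t2$t, tolerance = 1e-9)
})

test_that("Bonferroni FWE conversion round-trips and hits quantile oracles", {
  for (p in c(0.05, 0.01, 0.5)) {
    t <- t_from_fwe(p, dof = 120, n_voxels = 1000)
    expect_equal(fwe_from_t(t, 120, 1000), p, tolerance = 1e-10)
  }
  expect_equal(t_from_fwe(0.05, 30, 1), qt(0.95, 30), tolerance = 1e-12)
  expect_equal(t_from_fwe(0.05, 120, 1000), qt(1 - 5e-5, 120),
               tolerance = 1e-12)
  expect_error(t_from_fwe(0.05, -1, 10))
})

test_that("percent-signal-change map recovers injections and scales correctly", {
  spec <- small_spec(innovation_sd = 0,
                     regions = list(list(center = c(4, 4, 2), radius = 2,
                                         psc = 1.5, shape = "sphere")))
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  fit <- fit_glm(ph$series, X, whiten = 0)
  psc <- percent_signal_change_map(fit)
  blob <- ph$truth$label_map == 1L
  expect_equal(unname(psc$mu[blob]), rep(1.5, sum(blob)), tolerance = 1e-8)
  expect_lt(max(abs(psc$mu[!blob])), 1e-8)
  # doubling baseline and signal together leaves the map unchanged
  ph$series$data <- ph$series$data * 2
  psc2 <- percent_signal_change_map(fit_glm(ph$series, X, whiten = 0))
  expect_equal(psc$mu, psc2$mu, tolerance = 1e-9)
  expect_null(psc$sigma)
})

test_that("null phantom gives nominal uncorrected false-positive rate", {
  # 10,000 voxel fits under pure white noise
  spec <- phantom_spec(grid_dims = c(25, 25, 16), n_volumes = 80, tr_s = 2,
                       n_blocks = 2, block_on_s = 16, block_off_s = 16,
                       regions = list(), ar_coeffs = c(0, 0),
                       innovation_sd = 1, seed = 9L)
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  fit <- fit_glm(ph$series, X, whiten = 0)
  tm <- t_map(fit, positive_task_contrast(X))
  frac <- mean(tm$t > qt(0.95, fit$dof))
  expect_gte(frac, 0.04); expect_lte(frac, 0.06)
})

test_that("scan/regressors mismatches are rejected", {
  X <- build_design_matrix(default_protocol())
  spec <- small_spec()
  ph <- generate_phantom(spec)
  expect_error(fit_glm(ph$series, X), "volumes")
  Xbig <- cbind(diag(4), 1)[, 1:5]
  expect_error(fit_glm(make_series(matrix(rnorm(4), 4, 1)),
                       fake_design(Xbig), whiten = 0), "fewer scans")
})
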