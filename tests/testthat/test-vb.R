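test_that("graph Laplacian matches hand-built and enumerated cases", {
  expect_equal(as.matrix(build_graph_laplacian(array(TRUE, c(1, 1, 1)))),
               matrix(0, 1, 1))
  L2 <- as.matrix(build_graph_laplacian(array(TRUE, c(1, 1, 2))))
  expect_equal(unname(L2), matrix(c(1, -1, -1, 1), 2))
  # 3x3x3 full mask: interior degree 6; trace = 2 x number of face pairs
  m <- array(TRUE, c(3, 3, 3))
  L <- build_graph_laplacian(m, 6)
  deg <- Matrix::diag(L)
  expect_equal(deg[14], 6)  # centre voxel
  # brute-force face-pair enumeration
  pos <- arrayInd(1:27, c(3, 3, 3))
  pairs <- 0
  for (i in 1:26) for (j in (i + 1):27)
    if (sum(abs(pos[i, ] - pos[j, ])) == 1) pairs <- pairs + 1
  expect_equal(sum(deg), 2 * pairs)
  expect_equal(max(abs(Matrix::rowSums(L))), 0)
})

test_that("noise-free phantom drives the posterior onto the truth", {
  spec <- small_spec(innovation_sd = 0)
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  fit <- vb_fit(ph$series, X)
  eff <- to_percent(contrast_posterior(fit, positive_task_contrast(X)), fit)
  blob <- ph$truth$label_map == 1L
  expect_lt(max(abs(eff$mu[blob] - 2)), 1e-4)
  expect_lt(max(abs(eff$mu[!blob])), 1e-4)
  expect_lt(max(eff$sigma[ph$series$mask]), 1e-3)
})

test_that("clamped spatial precisions with white noise recover per-voxel OLS", {
  spec <- phantom_spec(grid_dims = c(10, 10, 4), n_volumes = 120, tr_s = 2.26,
                       n_blocks = 8, seed = 3L)
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  vb <- vb_fit(ph$series, X, ar_order = 0, fixed_spatial_precision = 1e-10)
  ols <- fit_glm(ph$series, X, whiten = 0)
  expect_lt(max(abs(vb$post_mean - ols$beta)), 1e-4)
})

test_that("AR(2) coefficients are recovered on noise-only voxels", {
  spec <- phantom_spec(grid_dims = c(10, 10, 5), regions = list(),
                       ar_coeffs = c(0.3, 0.2), innovation_sd = 1, seed = 4L)
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  vb <- vb_fit(ph$series, X)
  med <- apply(vb$ar_coeffs, 2, median)
  expect_lt(abs(med[1] - 0.3), 0.1)
  expect_lt(abs(med[2] - 0.2), 0.1)
})

test_that("free energy is non-decreasing on every phantom tried", {
  for (s in 1:5) {
    spec <- small_spec(seed = s)
    ph <- generate_phantom(spec)
    X <- build_design_matrix(phantom_protocol(spec))
    vb <- vb_fit(ph$series, X, tolerance = 1e-6, max_iterations = 40)
    fe <- vb$free_energy
    expect_true(all(diff(fe) >= -1e-6 * abs(fe[-length(fe)])),
                info = paste("seed", s))
  }
})

test_that("posterior mean maps are smoother than OLS maps", {
  neighbor_mse <- function(vals, mask) {
    pairs <- bayesppm:::mask_adjacency(mask, 6)
    mean((vals[pairs[, 1]] - vals[pairs[, 2]])^2)
  }
  wins <- vapply(1:20, function(s) {
    spec <- small_spec(seed = s)
    ph <- generate_phantom(spec)
    X <- build_design_matrix(phantom_protocol(spec))
    vb <- vb_fit(ph$series, X, max_iterations = 16)
    ols <- fit_glm(ph$series, X, whiten = 0)
    neighbor_mse(vb$post_mean[, 1], ph$series$mask) <=
      neighbor_mse(ols$beta[, 1], ph$series$mask)
  }, logical(1))
  expect_true(all(wins))
})

test_that("contrast posteriors follow the quadratic form", {
  fit <- structure(list(
    post_mean = matrix(c(1, 2), 1, 2),
    post_cov = array(c(1, 0.5, 0.5, 2), c(2, 2, 1)),
    mask = array(TRUE, c(1, 1, 1)),
    design = list(column_names = c("a", "b"), mean_index = 2L)),
    class = "vb_glm")
  eff <- contrast_posterior(fit, c(1, 1))
  expect_equal(eff$mu[1, 1, 1], 3)
  expect_equal(eff$sigma[1, 1, 1], 2)  # sqrt(1 + 2*0.5 + 2)
  neg <- contrast_posterior(fit, c(-1, -1))
  expect_equal(neg$mu[1, 1, 1], -3)
  expect_equal(neg$sigma[1, 1, 1], 2)
  one <- contrast_posterior(fit, c(1, 0))
  expect_equal(one$mu[1, 1, 1], 1)
  expect_equal(one$sigma[1, 1, 1], 1)
  expect_error(contrast_posterior(fit, c(0, 0)), "non-zero")
})

test_that("percent conversion matches the 1.5%-of-baseline example", {
  baseline <- 250
  fit <- structure(list(
    post_mean = matrix(c(0.015 * baseline, baseline), 1, 2),
    post_cov = array(c(0.01, 0, 0, 0.01), c(2, 2, 1)),
    mask = array(TRUE, c(1, 1, 1)),
    design = list(column_names = c("task", "mean"), mean_index = 2L)),
    class = "vb_glm")
  eff <- contrast_posterior(fit, c(1, 0))
  pct <- to_percent(eff, fit)
  expect_equal(pct$mu[1, 1, 1], 1.5)
  # sigma scales exactly as mu does
  expect_equal(pct$sigma[1, 1, 1], eff$sigma[1, 1, 1] * 100 / baseline)
  expect_equal(pct$units, "percent")
})

test_that("percent effect map is invariant to global intensity rescaling", {
  spec <- small_spec(seed = 8L)
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  v1 <- vb_fit(ph$series, X, tolerance = 1e-8, max_iterations = 150)
  e1 <- to_percent(contrast_posterior(v1, positive_task_contrast(X)), v1)
  ph$series$data <- ph$series$data * 5
  v2 <- vb_fit(ph$series, X, tolerance = 1e-8, max_iterations = 150)
  e2 <- to_percent(contrast_posterior(v2, positive_task_contrast(X)), v2)
  expect_lt(max(abs(e1$mu - e2$mu)), 0.01)
  expect_lt(max(abs(e1$sigma - e2$sigma)), 0.01)
})

test_that("non-convergence is flagged, never silent", {
  spec <- small_spec(seed = 1L)
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  expect_warning(fit <- vb_fit(ph$series, X, max_iterations = 2,
                               tolerance = 1e-12),
                 "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$stop_reason, "max_iterations")
})
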