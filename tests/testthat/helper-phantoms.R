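# Shared phantom builders for the tests. Small grids / short runs keep the
# suite quick; the geometry mirrors the package defaults.

# short acquisition for fast fits
small_spec <- function(..., seed = 1L,
                       regions = list(list(center = c(4, 4, 2), radius = 2,
                                           psc = 2, shape = "sphere"))) {
  phantom_spec(grid_dims = c(8, 8, 3), n_volumes = 80, tr_s = 2,
               n_blocks = 2, block_on_s = 16, block_off_s = 16,
               regions = regions, seed = seed, ...)
}

# radially ramped blob (25 nested shells) whose amplitude falls linearly
# from A at the centre to 0 at radius 5; used for calibration recovery
ramp_spec <- function(A, seed, innovation_sd = 0.05) {
  radii <- seq(5, 0.2, by = -0.2)
  regions <- lapply(radii, function(r)
    list(center = c(7, 7, 5), radius = r, psc = A / length(radii),
         shape = "sphere"))
  phantom_spec(grid_dims = c(14, 14, 10), regions = regions,
               innovation_sd = innovation_sd, seed = seed)
}

# one calibration point: fit the ramp phantom, design the reference cluster
# so the sweep's optimum is 0.5 x top-median by construction, run the sweep
calibration_point <- function(A, seed, lbt = 10) {
  spec <- ramp_spec(A, seed)
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  vb <- vb_fit(ph$series, X)
  eff <- to_percent(contrast_posterior(vb, positive_task_contrast(X)), vb)
  top_med <- top_quantile_median(eff)
  gstar <- 0.5 * top_med
  z <- stats::qnorm(lbt_to_probability(lbt))
  target <- eff$mu > gstar + z * eff$sigma
  n_star <- sum(target, na.rm = TRUE)
  f <- fit_glm(ph$series, X)
  tm <- t_map(f, positive_task_contrast(X))
  t_thr <- sort(tm$t[!is.na(tm$t)], decreasing = TRUE)[n_star] - 1e-9
  cref <- select_reference_cluster(tm, t_thr, 18, roi = c(7, 7, 5))
  sw <- gamma_sweep(eff, cref, lbt = lbt)
  c(top_median = top_med, optimal_gamma = sw$optimal_gamma)
}

# constant-sigma effect map on a small grid, for classifier unit tests
toy_effect <- function(mu, sigma = NULL) {
  mu <- array(mu, c(length(mu), 1, 1))
  mask <- array(TRUE, dim(mu))
  sig <- if (!is.null(sigma)) array(sigma, dim(mu))
  effect_map(mu, sig, mask)
}
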