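test_that("PPM triples match Gaussian-cdf oracles and sum to one", {
  eff <- toy_effect(c(0, 1, -1, 2.5), sigma = 1)
  p <- ppm_maps(eff, gamma = 1.96)
  # mu = 0, sigma = 1, gamma = 1.96: PPMn = 0.9500 to 4 decimals
  expect_equal(round(p$ppm_n[1, 1, 1], 4), 0.95)
  # mu = gamma: PPMa exactly 0.5
  pg <- ppm_maps(toy_effect(1.3, 0.7), gamma = 1.3)
  expect_equal(pg$ppm_a[1, 1, 1], 0.5)
  # gamma = 0: PPMn = 0 and PPMa + PPMd = 1
  p0 <- ppm_maps(eff, gamma = 0)
  expect_equal(max(abs(p0$ppm_n)), 0)
  expect_equal(unname(as.vector(p0$ppm_a + p0$ppm_d)), rep(1, 4))
  # sums to one everywhere
  expect_lt(max(abs(p$ppm_a + p$ppm_d + p$ppm_n - 1)), 1e-10)
})

test_that("PPM normalisation and monotonicity hold over random triples", {
  set.seed(7)
  n <- 1e4
  eff <- toy_effect(rnorm(n, 0, 2), sigma = runif(n, 0.01, 3))
  gammas <- seq(0, 3, length.out = 21)
  prev_a <- prev_d <- prev_n <- NULL
  for (g in gammas) {
    p <- ppm_maps(eff, g)
    expect_lt(max(abs(p$ppm_a + p$ppm_d + p$ppm_n - 1)), 1e-10)
    if (!is.null(prev_a)) {
      expect_true(all(p$ppm_a <= prev_a + 1e-12))
      expect_true(all(p$ppm_d <= prev_d + 1e-12))
      expect_true(all(p$ppm_n >= prev_n - 1e-12))
    }
    prev_a <- p$ppm_a; prev_d <- p$ppm_d; prev_n <- p$ppm_n
  }
})

test_that("frequentist point-estimate maps are refused by ppm_maps", {
  spec <- small_spec(seed = 1L)
  ph <- generate_phantom(spec)
  X <- build_design_matrix(phantom_protocol(spec))
  psc <- percent_signal_change_map(fit_glm(ph$series, X, whiten = 0))
  expect_error(ppm_maps(psc, 0.5), "posterior")
})

test_that("log Bayes factor threshold matches its printed correspondences", {
  expect_equal(round(probability_to_lbt(0.95), 3), 2.944)
  expect_equal(round(probability_to_lbt(0.95)), 3)
  expect_equal(lbt_to_probability(0), 0.5)
  # 1 - p_T at LBT = 10 is 4.54e-5 to 3 significant figures
  expect_equal(signif(1 - lbt_to_probability(10), 3), 4.54e-5)
  for (p in c(1e-8, 0.2, 0.5, 0.95, 1 - 1e-12)) {
    expect_equal(lbt_to_probability(probability_to_lbt(p)), p,
                 tolerance = 1e-12)
  }
  expect_error(probability_to_lbt(0), "0, 1")
  expect_error(probability_to_lbt(1), "0, 1")
})

test_that("four-category classification follows the threshold rules", {
  p_T <- lbt_to_probability(10)
  # dominant activation
  eff <- toy_effect(c(10, 0, 0.001), sigma = c(0.1, 1, 0.01))
  res <- classify_voxels(eff, lbt = 10, gamma = 1)
  expect_equal(res$labels[1, 1, 1], 1L)   # activated: ppm_a ~ 1
  expect_equal(res$labels[2, 1, 1], 0L)   # wide posterior: low-confidence
  expect_equal(res$labels[3, 1, 1], 3L)   # tight around 0: non-activated
  expect_equal(res$p_threshold, p_T)
  # uniform triple can never dominate
  fake <- structure(list(ppm_a = array(1 / 3, c(1, 1, 1)),
                         ppm_d = array(1 / 3, c(1, 1, 1)),
                         ppm_n = array(1 / 3, c(1, 1, 1)),
                         gamma = 1, mask = array(TRUE, c(1, 1, 1))),
                    class = "ppm_triple")
  expect_equal(classify_voxels(fake, p_T = 0.75)$labels[1, 1, 1], 0L)
  expect_warning(classify_voxels(fake, p_T = 0.5), "collide")
})

test_that("negating the effect map swaps activated and deactivated labels", {
  set.seed(11)
  mu <- rnorm(200, 0, 2)
  eff <- toy_effect(mu, sigma = runif(200, 0.05, 0.5))
  neg <- toy_effect(-mu, sigma = eff$sigma[, 1, 1])
  a <- classify_voxels(eff, lbt = 3, gamma = 0.5)$labels
  b <- classify_voxels(neg, lbt = 3, gamma = 0.5)$labels
  expect_identical(a == 1L, b == 2L)
  expect_identical(a == 2L, b == 1L)
  expect_identical(a == 3L, b == 3L)
  expect_identical(a == 0L, b == 0L)
})

test_that("raising the LBT never grows the activated set", {
  set.seed(12)
  eff <- toy_effect(rnorm(300, 1, 1), sigma = runif(300, 0.1, 1))
  for (g in c(0, 0.5, 1)) {
    act3 <- classify_voxels(eff, lbt = 3, gamma = g)$labels == 1L
    act10 <- classify_voxels(eff, lbt = 10, gamma = g)$labels == 1L
    expect_true(all(act3 | !act10))  # act10 subset of act3
  }
})

test_that("out-of-mask voxels are coded -1", {
  mu <- array(1, c(2, 1, 1)); sg <- array(0.1, c(2, 1, 1))
  mask <- array(c(TRUE, FALSE), c(2, 1, 1))
  eff <- effect_map(mu, sg, mask)
  eff$mu[!mask] <- NA; eff$sigma[!mask] <- NA
  res <- classify_voxels(eff, lbt = 3, gamma = 0.2)
  expect_equal(res$labels[2, 1, 1], -1L)
})
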