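#' Effect-size map
#'
#' Per-voxel effect size `mu` with, for Bayesian maps, the posterior
#' standard deviation `sigma`. Frequentist point-estimate maps carry
#' `sigma = NULL`; the posterior-probability machinery refuses them.
#'
#' @param mu 3-D numeric array (NA outside the mask).
#' @param sigma 3-D numeric array of posterior sds, or `NULL`.
#' @param mask logical 3-D array.
#' @param units `"percent"` or `"raw"`.
#' @return An object of class `effect_map`.
#' @export
effect_map <- function(mu, sigma = NULL, mask, units = c("percent", "raw")) {
  units <- match.arg(units)
  stopifnot(identical(dim(mu), dim(mask)))
  if (!is.null(sigma)) {
    stopifnot(identical(dim(sigma), dim(mask)))
    sv <- sigma[mask]
    if (any(!is.na(sv) & sv <= 0))
      stop("posterior sd must be positive wherever present")
  }
  structure(list(mu = mu, sigma = sigma, mask = mask, units = units),
            class = "effect_map")
}

#' @export
print.effect_map <- function(x, ...) {
  cat("<effect_map> (", x$units, " units), mu range [",
      signif(min(x$mu, na.rm = TRUE), 4), ", ",
      signif(max(x$mu, na.rm = TRUE), 4), "], sigma ",
      if (is.null(x$sigma)) "absent (point estimate)" else "present",
      "\n", sep = "")
  invisible(x)
}

#' Posterior distribution of a contrast of effects
#'
#' `mu = c' beta_hat` and `sigma = sqrt(c' Sigma_hat c)` per voxel
#' from a variational posterior fit.
#'
#' @param fit a `vb_glm` from [vb_fit()].
#' @param contrast numeric length-K contrast vector.
#' @return An [effect_map()] in raw coefficient units.
#' @export
contrast_posterior <- function(fit, contrast) {
  stopifnot(inherits(fit, "vb_glm"))
  contrast <- as.numeric(contrast)
  K <- ncol(fit$post_mean)
  if (length(contrast) != K)
    stop("contrast length ", length(contrast), " != K = ", K)
  if (all(contrast == 0)) stop("contrast must have at least one non-zero weight")
  mu <- as.vector(fit$post_mean %*% contrast)
  # post_cov is K x K x voxels
  sig2 <- apply(fit$post_cov, 3, function(S)
    as.numeric(t(contrast) %*% S %*% contrast))
  effect_map(mu = map_to_volume(mu, fit$mask),
             sigma = map_to_volume(sqrt(pmax(sig2, 0)), fit$mask),
             mask = fit$mask, units = "raw")
}

#' Convert an effect map to percent-signal-change units
#'
#' Divides `mu` and `sigma` by the voxel's posterior-mean constant (mean)
#' coefficient and multiplies by 100. With the task regressor
#' peak-normalised upstream, the result is the peak BOLD excursion as a
#' percentage of the temporal-mean intensity.
#'
#' @param effect an [effect_map()] in raw units.
#' @param fit the `vb_glm` the map came from (supplies the mean
#'   coefficient).
#' @return An [effect_map()] in percent units.
#' @export
to_percent <- function(effect, fit) {
  stopifnot(inherits(effect, "effect_map"), inherits(fit, "vb_glm"))
  if (effect$units == "percent") return(effect)
  mu0 <- map_to_volume(fit$post_mean[, fit$design$mean_index], fit$mask)
  bad <- fit$mask & (!is.finite(mu0) | mu0 == 0)
  if (any(bad))
    warning(sum(bad), " voxel(s) with zero mean coefficient marked missing")
  scale <- 100 / mu0
  scale[bad] <- NA_real_
  mu <- effect$mu * scale
  sigma <- if (is.null(effect$sigma)) NULL else abs(effect$sigma * scale)
  effect_map(mu = mu, sigma = sigma, mask = effect$mask, units = "percent")
}
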