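#' Frequentist voxel-wise GLM fit
#'
#' Ordinary least squares per in-mask voxel, optionally with AR
#' prewhitening: AR coefficients of order `whiten` are estimated per voxel
#' from the OLS residuals (Yule–Walker) and both the data and the design are
#' filtered before a single refit (conditional likelihood — the first
#' `whiten` rows are dropped).
#'
#' @param series a [bold_series()].
#' @param design an `fmri_design` with the same number of scans.
#' @param whiten AR order for prewhitening: 0 (plain OLS), 1 (default) or 2.
#' @return An object of class `fmri_glm` with per-voxel coefficients
#'   (`beta`, voxels x K), residual variance `sigma2`, effective degrees of
#'   freedom `dof`, and the per-voxel contrast-variance factors needed for
#'   t maps.
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_dims = c(6, 6, 4)))
#' X <- build_design_matrix(phantom_protocol(ph$spec))
#' fit <- fit_glm(ph$series, X)
#' @export
fit_glm <- function(series, design, whiten = 1L) {
  stopifnot(inherits(series, "bold_series"), inherits(design, "fmri_design"))
  whiten <- as.integer(whiten)
  stopifnot(whiten %in% 0:2)
  X <- design$matrix
  n <- nrow(X)
  if (dim(series$data)[4] != n)
    stop("series has ", dim(series$data)[4], " volumes but the design has ",
         n, " rows")
  K <- ncol(X)
  if (n <= K) stop("fewer scans (", n, ") than regressors (", K, ")")
  Y <- series_matrix(series)  # time x voxels
  n_vox <- ncol(Y)

  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)                      # K x voxels
  res <- Y - X %*% beta
  rank <- qrX$rank

  if (whiten == 0L) {
    dof <- n - rank
    sigma2 <- colSums(res^2) / dof
    XtXinv <- chol2inv(chol(crossprod(X)))
    cvar <- list(shared = XtXinv)
    ar <- NULL
  } else {
    p <- whiten
    ar <- matrix(apply(res, 2, yule_walker, order = p), p, n_vox)
    dof <- (n - p) - rank
    sigma2 <- numeric(n_vox)
    beta_w <- matrix(0, K, n_vox)
    cvar <- vector("list", n_vox)
    rows0 <- (p + 1):n
    for (v in seq_len(n_vox)) {
      a <- ar[, v]
      Xw <- X[rows0, , drop = FALSE]
      yw <- Y[rows0, v]
      for (j in seq_len(p)) {
        Xw <- Xw - a[j] * X[rows0 - j, , drop = FALSE]
        yw <- yw - a[j] * Y[rows0 - j, v]
      }
      XtXinv_v <- chol2inv(chol(crossprod(Xw)))
      bv <- XtXinv_v %*% crossprod(Xw, yw)
      rw <- yw - Xw %*% bv
      beta_w[, v] <- bv
      sigma2[v] <- sum(rw^2) / dof
      cvar[[v]] <- XtXinv_v
    }
    beta <- beta_w
  }
  rownames(beta) <- colnames(X)
  structure(list(beta = t(beta), sigma2 = sigma2, dof = dof,
                 design = design, whiten = whiten, cvar = cvar,
                 ar = ar, mask = series$mask),
            class = "fmri_glm")
}

# Yule-Walker AR coefficient estimate from a (residual) series
yule_walker <- function(e, order) {
  n <- length(e)
  e <- e - mean(e)
  acf0 <- sum(e^2) / n
  if (acf0 <= 0) return(numeric(order))
  g <- vapply(seq_len(order), function(k)
    sum(e[(k + 1):n] * e[1:(n - k)]) / n, numeric(1))
  R <- diag(order) * acf0
  if (order == 2L) R[1, 2] <- R[2, 1] <- g[1]
  a <- tryCatch(solve(R, g), error = function(e) numeric(order))
  # shrink toward stationarity if the estimate is outside the region
  if (any(Mod(polyroot(c(1, -a))) <= 1.001)) a <- a * 0.98 / max(sum(abs(a)), 1)
  a
}

#' @export
print.fmri_glm <- function(x, ...) {
  cat("<fmri_glm> ", nrow(x$beta), " voxels, ", ncol(x$beta),
      " regressors, dof ", x$dof, ", whitening AR(", x$whiten, ")\n", sep = "")
  invisible(x)
}

#' @export
coef.fmri_glm <- function(object, ...) object$beta

#' Voxel-wise t-statistic map
#'
#' `t = c'beta / sqrt(sigma2 * c' (X'X)^{-1} c)` per voxel (with the
#' whitened design when prewhitening was applied).
#'
#' @param fit an `fmri_glm`.
#' @param contrast numeric contrast vector of length K.
#' @return An object of class `t_map`: fields `t` (3-D array, NA outside
#'   mask), `dof`, `contrast`.
#' @export
t_map <- function(fit, contrast) {
  stopifnot(inherits(fit, "fmri_glm"))
  contrast <- as.numeric(contrast)
  if (length(contrast) != ncol(fit$beta))
    stop("contrast length ", length(contrast), " != K = ", ncol(fit$beta))
  if (all(contrast == 0)) stop("contrast must have at least one non-zero weight")
  eff <- as.vector(fit$beta %*% contrast)
  if (fit$whiten == 0L) {
    q <- as.numeric(t(contrast) %*% fit$cvar$shared %*% contrast)
    se2 <- fit$sigma2 * q
  } else {
    q <- vapply(fit$cvar, function(M)
      as.numeric(t(contrast) %*% M %*% contrast), numeric(1))
    se2 <- fit$sigma2 * q
  }
  tval <- numeric(length(eff))
  zero <- se2 <= 0
  if (any(zero)) {
    warning(sum(zero), " voxel(s) with zero residual variance; ",
            "t set to signed infinity")
    tval[zero] <- sign(eff[zero]) * Inf
  }
  tval[!zero] <- eff[!zero] / sqrt(se2[!zero])
  structure(list(t = map_to_volume(tval, fit$mask), dof = fit$dof,
                 contrast = contrast, mask = fit$mask),
            class = "t_map")
}

#' @export
print.t_map <- function(x, ...) {
  cat("<t_map> dof ", x$dof, "; range [",
      signif(min(x$t, na.rm = TRUE), 4), ", ",
      signif(max(x$t, na.rm = TRUE), 4), "]\n", sep = "")
  invisible(x)
}

#' Bonferroni familywise-error conversion for t thresholds
#'
#' Forward: `p_fwe = min(1, n_voxels * P(T_dof > t))` (one-sided).
#' Inverse: the t threshold whose corrected p equals `p_fwe`.
#'
#' @param t_threshold t value.
#' @param dof degrees of freedom (positive).
#' @param n_voxels number of tests.
#' @return A probability (forward) or a t value (inverse).
#' @export
fwe_from_t <- function(t_threshold, dof, n_voxels) {
  stopifnot(dof > 0, n_voxels >= 1)
  pmin(1, n_voxels * stats::pt(t_threshold, df = dof, lower.tail = FALSE))
}

#' @rdname fwe_from_t
#' @param p_fwe familywise-error-corrected p in (0, 1].
#' @export
t_from_fwe <- function(p_fwe, dof, n_voxels) {
  stopifnot(dof > 0, n_voxels >= 1, p_fwe > 0, p_fwe <= 1)
  stats::qt(p_fwe / n_voxels, df = dof, lower.tail = FALSE)
}

#' Percent-signal-change effect map from a frequentist fit
#'
#' `100 * beta_task / beta_mean` per voxel: the task regressor is
#' peak-normalised upstream, so the ratio is the peak BOLD excursion as a
#' percentage of the voxel's temporal-mean intensity. The returned map is a
#' point estimate only — its `sigma` field is absent, so it cannot be fed to
#' [ppm_maps()].
#'
#' @param fit an `fmri_glm`.
#' @return An [effect_map()] with `sigma = NULL`.
#' @export
percent_signal_change_map <- function(fit) {
  stopifnot(inherits(fit, "fmri_glm"))
  task <- fit$beta[, fit$design$task_index]
  mu0 <- fit$beta[, fit$design$mean_index]
  bad <- !is.finite(mu0) | mu0 == 0
  psc <- ifelse(bad, NA_real_, 100 * task / mu0)
  if (any(bad))
    warning(sum(bad), " voxel(s) with zero mean coefficient marked missing")
  effect_map(mu = map_to_volume(psc, fit$mask), sigma = NULL,
             mask = fit$mask, units = "percent")
}
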