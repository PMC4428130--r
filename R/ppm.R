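#' Posterior probability maps
#'
#' Per-voxel probabilities that the effect size exceeds `gamma` (activation),
#' falls below `-gamma` (deactivation), or lies within `(-gamma, gamma)`
#' (non-activation), from the Gaussian effect-size posterior:
#' `PPMa = 1 - Phi((gamma - mu)/sigma)`, `PPMd = Phi((-gamma - mu)/sigma)`,
#' `PPMn = Phi((gamma - mu)/sigma) - Phi((-gamma - mu)/sigma)`.
#' The three maps sum to one at every in-mask voxel. Tail probabilities are
#' computed on the log scale internally so values like `1 - p_T ~ 4.5e-5`
#' (LBT = 10) do not round away.
#'
#' @param effect an [effect_map()] with a posterior sd (`sigma` present);
#'   frequentist point-estimate maps are rejected.
#' @param gamma non-negative effect-size threshold, same units as the map.
#' @return An object of class `ppm_triple` with 3-D arrays `ppm_a`, `ppm_d`,
#'   `ppm_n` (NA outside the mask) and the `gamma` used.
#' @examples
#' m <- array(0, c(1, 1, 1)); s <- array(1, c(1, 1, 1))
#' eff <- effect_map(m, s, array(TRUE, c(1, 1, 1)))
#' ppm_maps(eff, gamma = 1.96)$ppm_n  # ~0.95
#' @export
ppm_maps <- function(effect, gamma) {
  stopifnot(inherits(effect, "effect_map"))
  if (is.null(effect$sigma))
    stop("effect map has no posterior sd (sigma): posterior probability ",
         "maps need a Bayesian effect-size posterior, not a frequentist ",
         "point estimate")
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0)
    stop("`gamma` must be a single non-negative number")
  mu <- effect$mu; sigma <- effect$sigma
  za <- (gamma - mu) / sigma
  zd <- (-gamma - mu) / sigma
  ppm_a <- stats::pnorm(za, lower.tail = FALSE)
  ppm_d <- stats::pnorm(zd)
  ppm_n <- stats::pnorm(za) - stats::pnorm(zd)
  structure(list(ppm_a = ppm_a, ppm_d = ppm_d, ppm_n = ppm_n,
                 gamma = gamma, mask = effect$mask),
            class = "ppm_triple")
}

#' @export
print.ppm_triple <- function(x, ...) {
  cat("<ppm_triple> gamma = ", x$gamma, "; mean PPMa ",
      signif(mean(x$ppm_a, na.rm = TRUE), 3), ", PPMd ",
      signif(mean(x$ppm_d, na.rm = TRUE), 3), ", PPMn ",
      signif(mean(x$ppm_n, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Log Bayes factor threshold and posterior probability threshold
#'
#' The natural-log odds transform `LBT = log(p_T / (1 - p_T))` and its
#' inverse. `p_T = 0.95` corresponds to `LBT ~ 3`; at `LBT = 10`,
#' `1 - p_T ~ 4.5e-5`. The inverse is computed via `plogis` so extreme
#' thresholds keep full precision.
#'
#' @param p_T posterior probability threshold in (0, 1).
#' @return `probability_to_lbt`: the log odds; `lbt_to_probability`: the
#'   probability.
#' @export
probability_to_lbt <- function(p_T) {
  if (any(p_T <= 0 | p_T >= 1)) stop("p_T must lie strictly in (0, 1)")
  log(p_T) - log1p(-p_T)
}

#' @rdname probability_to_lbt
#' @param lbt log Bayes factor threshold (any real).
#' @export
lbt_to_probability <- function(lbt) {
  stats::plogis(lbt)
}

#' Four-category voxel classification
#'
#' Labels each in-mask voxel `activated` if `PPMa > p_T`, `deactivated` if
#' `PPMd > p_T`, `non-activated` if `PPMn > p_T`, otherwise
#' `low-confidence`. With `p_T > 2/3` at most one category can exceed the
#' threshold; for smaller `p_T` a warning is issued and collisions resolve
#' by the largest probability, ties broken activated > deactivated >
#' non-activated.
#'
#' @param ppm a `ppm_triple` from [ppm_maps()], or an [effect_map()] (then
#'   `gamma` must be given and the maps are computed first).
#' @param p_T posterior probability threshold in (0, 1); alternatively give
#'   `lbt`.
#' @param lbt log Bayes factor threshold; used when `p_T` is missing
#'   (default LBT = 10).
#' @param gamma effect-size threshold, only when `ppm` is an effect map.
#' @return An object of class `ppm_result`: integer `labels` 3-D array with
#'   codes 1 activated, 2 deactivated, 3 non-activated, 0 low-confidence,
#'   -1 out-of-mask; plus the probability maps and thresholds used.
#' @export
classify_voxels <- function(ppm, p_T = NULL, lbt = 10, gamma = NULL) {
  if (inherits(ppm, "effect_map")) {
    if (is.null(gamma)) stop("supply `gamma` to classify an effect map")
    ppm <- ppm_maps(ppm, gamma)
  }
  stopifnot(inherits(ppm, "ppm_triple"))
  if (is.null(p_T)) p_T <- lbt_to_probability(lbt) else lbt <- probability_to_lbt(p_T)
  if (p_T <= 2 / 3)
    warning("p_T = ", signif(p_T, 4), " <= 2/3: categories may collide; ",
            "collisions resolved by the largest probability")
  mask <- ppm$mask
  a <- ppm$ppm_a > p_T
  d <- ppm$ppm_d > p_T
  n <- ppm$ppm_n > p_T
  multi <- (a + d + n) > 1
  multi[is.na(multi)] <- FALSE
  if (any(multi)) {
    # resolve by largest probability; ties activated > deactivated > non-act.
    stacked <- rbind(as.vector(ppm$ppm_a)[multi],
                     as.vector(ppm$ppm_d)[multi],
                     as.vector(ppm$ppm_n)[multi])
    win <- apply(stacked, 2, which.max)
    a[multi] <- win == 1; d[multi] <- win == 2; n[multi] <- win == 3
  }
  labels <- array(0L, dim(mask))
  labels[which(a)] <- 1L
  labels[which(d)] <- 2L
  labels[which(n)] <- 3L
  labels[!mask] <- -1L
  structure(list(labels = labels, ppm_a = ppm$ppm_a, ppm_d = ppm$ppm_d,
                 ppm_n = ppm$ppm_n, gamma = ppm$gamma, p_threshold = p_T,
                 lbt = lbt, mask = mask),
            class = "ppm_result")
}

#' @export
print.ppm_result <- function(x, ...) {
  tab <- table(factor(x$labels[x$mask], levels = c(1, 2, 3, 0),
                      labels = c("activated", "deactivated",
                                 "non-activated", "low-confidence")))
  cat("<ppm_result> gamma = ", signif(x$gamma, 4), ", LBT = ",
      signif(x$lbt, 4), " (p_T = ", signif(x$p_threshold, 6), ")\n  ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# binary activated-label map from a ppm_result
activated_mask <- function(ppm_result) {
  ppm_result$labels == 1L
}
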