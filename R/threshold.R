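#' Effect-size threshold model
#'
#' The operator-independent rule for choosing the effect-size threshold
#' gamma of the posterior-probability classification: gamma is a fixed
#' fraction (the `slope`) of the median percent-signal-change of the voxels
#' with the top 0.1% positive effect sizes over the brain mask. Two
#' calibrated scenarios ship with the package: `"loci"` (slope 0.497,
#' thresholds tuned to pinpoint activation loci) and `"extent"` (slope
#' 0.144, tuned to delineate the full activation extent).
#'
#' @param scenario `"loci"` or `"extent"`, or `"custom"` with an explicit
#'   slope.
#' @param slope positive slope; defaults to the packaged calibrated value
#'   for the scenario.
#' @param top_fraction fraction of positive voxels defining the reference
#'   amplitude statistic (default 0.001).
#' @return An object of class `threshold_model`.
#' @examples
#' threshold_model("loci")$slope   # 0.497
#' threshold_model("extent")$slope # 0.144
#' @export
threshold_model <- function(scenario = c("loci", "extent", "custom"),
                            slope = NULL, top_fraction = 0.001) {
  scenario <- match.arg(scenario)
  if (is.null(slope)) {
    slope <- switch(scenario,
                    loci = 0.497,
                    extent = 0.144,
                    custom = stop("scenario 'custom' needs an explicit slope"))
  }
  stopifnot(is.numeric(slope), length(slope) == 1L, slope > 0,
            top_fraction > 0, top_fraction < 1)
  structure(list(scenario = scenario, slope = slope,
                 top_fraction = top_fraction),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat("<threshold_model> scenario '", x$scenario, "': gamma = ", x$slope,
      " x median(top ", x$top_fraction * 100, "% positive effects)\n",
      sep = "")
  invisible(x)
}

#' Median of the top positive effect sizes
#'
#' Let P be the in-mask voxels with positive effect size; the statistic is
#' the median of the `n_top = max(1, ceiling(fraction * |P|))` largest
#' values. This is the reference amplitude the threshold model scales.
#'
#' @param effect an [effect_map()] (its `mu` field is used).
#' @param mask optional mask overriding the map's own.
#' @param fraction top fraction in (0, 1), default 0.001.
#' @return A positive number.
#' @export
top_quantile_median <- function(effect, mask = NULL, fraction = 0.001) {
  stopifnot(inherits(effect, "effect_map"), fraction > 0, fraction < 1)
  if (is.null(mask)) mask <- effect$mask
  vals <- effect$mu[mask]
  vals <- vals[is.finite(vals) & vals > 0]
  if (!length(vals))
    stop("no in-mask voxel has a positive effect size; cannot form the top-",
         fraction * 100, "% statistic")
  n_top <- max(1L, ceiling(fraction * length(vals)))
  stats::median(sort(vals, decreasing = TRUE)[seq_len(n_top)])
}

#' Predict the effect-size threshold gamma
#'
#' `gamma = slope * top_quantile_median(effect, mask, top_fraction)`.
#'
#' @param object a [threshold_model()].
#' @param effect an [effect_map()] in percent units.
#' @param mask optional mask overriding the map's own.
#' @param ... unused.
#' @return The threshold gamma (percent signal change).
#' @export
predict.threshold_model <- function(object, effect, mask = NULL, ...) {
  object$slope * top_quantile_median(effect, mask, object$top_fraction)
}

#' @rdname predict.threshold_model
#' @param model a [threshold_model()].
#' @export
predict_gamma <- function(model, effect, mask = NULL) {
  predict(model, effect, mask)
}

#' Select the reference cluster from a thresholded t-map
#'
#' Connected components of `{t > t_threshold}` are formed and the single
#' component with the largest overlap with the region of interest is
#' returned (replacing the manual erasure of non-target clusters with a
#' deterministic ROI-driven choice). Ties resolve to the larger component,
#' then to the component containing the smallest linear voxel index.
#'
#' @param tmap a `t_map` from [t_map()].
#' @param t_threshold scalar threshold.
#' @param connectivity neighbour system, default 18.
#' @param roi logical array, or a voxel coordinate triple.
#' @return Logical 3-D array: the reference cluster `C_Ref`.
#' @export
select_reference_cluster <- function(tmap, t_threshold, connectivity = 18L,
                                     roi) {
  stopifnot(inherits(tmap, "t_map"))
  thr <- tmap$t > t_threshold
  thr[is.na(thr)] <- FALSE
  if (!any(thr))
    stop("no voxel exceeds t = ", t_threshold, "; cannot select a cluster")
  if (is.numeric(roi) && length(roi) == 3L) {
    r <- array(FALSE, dim(tmap$t)); r[roi[1], roi[2], roi[3]] <- TRUE
    roi <- r
  }
  stopifnot(identical(dim(roi), dim(tmap$t)))
  roi <- array(as.logical(roi), dim(roi)); roi[is.na(roi)] <- FALSE
  cm <- connected_components(thr, connectivity)
  overlaps <- vapply(seq_len(cm$n_clusters), function(cl)
    sum(roi[cm$labels == cl]), integer(1))
  if (all(overlaps == 0L)) {
    inv <- paste0("cluster ", seq_len(cm$n_clusters), ": ",
                  cm$sizes, " voxels", collapse = "; ")
    stop("ROI is disjoint from every suprathreshold cluster (", inv, ")")
  }
  first <- vapply(seq_len(cm$n_clusters), function(cl)
    min(which(cm$labels == cl)), numeric(1))
  ord <- order(-overlaps, -cm$sizes, first)
  cm$labels == ord[1]
}

#' Union of activation clusters overlapping a reference
#'
#' Connected components of the activated-label set are formed and
#' `C_Bayes` is the union of all components intersecting `c_ref` —
#' including their voxels outside `c_ref`.
#'
#' @param labels a `ppm_result`, or an integer label array (code 1 =
#'   activated), or a logical activated map.
#' @param c_ref logical reference cluster.
#' @param connectivity neighbour system, default 18.
#' @return Logical 3-D array (possibly empty).
#' @export
overlapping_union <- function(labels, c_ref, connectivity = 18L) {
  act <- if (inherits(labels, "ppm_result")) activated_mask(labels)
  else if (is.logical(labels)) labels
  else labels == 1L
  if (!identical(dim(act), dim(c_ref)))
    stop("label map and reference cluster must share a grid")
  cm <- connected_components(act, connectivity)
  out <- array(FALSE, dim(act))
  if (cm$n_clusters == 0L) return(out)
  keep <- vapply(seq_len(cm$n_clusters), function(cl)
    any(c_ref[cm$labels == cl]), logical(1))
  out[cm$labels > 0 & keep[pmax(cm$labels, 1)]] <- TRUE
  out
}

#' Jaccard sweep over the effect-size threshold
#'
#' For each gamma on the grid `0, delta_gamma, 2*delta_gamma, ...` the
#' effect map is classified at the given LBT, the activation clusters
#' overlapping `c_ref` are pooled into `C_Bayes`, and the Jaccard index
#' `J(C_Ref, C_Bayes)` is recorded. The grid ends at the first gamma whose
#' activated set is empty (`gamma_max`). The raw curve is smoothed with a
#' centred box kernel (width `smoothing_width`, windows shrinking at the
#' edges) and the gamma maximising the smoothed curve — ties toward smaller
#' gamma — is the optimal threshold.
#'
#' @param effect an [effect_map()] with posterior sds, percent units.
#' @param c_ref logical reference cluster (non-empty).
#' @param lbt log Bayes factor threshold for the classification, default 10.
#' @param delta_gamma grid step, default 0.01.
#' @param smoothing_width box-kernel width in samples, default 8.
#' @param connectivity cluster connectivity, default 18.
#' @return An object of class `jaccard_curve` with fields `gammas`, `raw_j`,
#'   `smoothed_j`, `optimal_gamma`, `gamma_max`.
#' @export
gamma_sweep <- function(effect, c_ref, lbt = 10, delta_gamma = 0.01,
                        smoothing_width = 8L, connectivity = 18L) {
  stopifnot(inherits(effect, "effect_map"), delta_gamma > 0,
            smoothing_width >= 1)
  if (!any(c_ref)) stop("reference cluster is empty")
  p_T <- lbt_to_probability(lbt)
  gammas <- numeric(0); raw_j <- numeric(0)
  i <- 0L
  repeat {
    g <- i * delta_gamma
    ppm <- ppm_maps(effect, g)
    act <- ppm$ppm_a > p_T
    act[is.na(act)] <- FALSE
    if (!any(act)) {
      if (i == 0L) stop("activated set is empty already at gamma = 0; no curve")
      gammas <- c(gammas, g); raw_j <- c(raw_j, 0)
      break
    }
    cb <- overlapping_union(act, c_ref, connectivity)
    gammas <- c(gammas, g)
    raw_j <- c(raw_j, if (any(cb)) jaccard(c_ref, cb) else 0)
    i <- i + 1L
    if (g > 1e6) stop("gamma sweep did not terminate")
  }
  smoothed <- box_smooth(raw_j, smoothing_width)
  opt <- gammas[which.max(smoothed)]  # which.max takes the first maximum
  structure(list(gammas = gammas, raw_j = raw_j, smoothed_j = smoothed,
                 optimal_gamma = opt, gamma_max = gammas[length(gammas)],
                 lbt = lbt, delta_gamma = delta_gamma,
                 smoothing_width = as.integer(smoothing_width)),
            class = "jaccard_curve")
}

# centred moving average of width w; even widths take one extra sample to
# the right; windows shrink at the edges (no phase shift, no padding)
box_smooth <- function(x, w) {
  n <- length(x)
  left <- floor((w - 1) / 2); right <- ceiling((w - 1) / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - left); hi <- min(n, i + right)
    mean(x[lo:hi])
  }, numeric(1))
}

#' @export
print.jaccard_curve <- function(x, ...) {
  cat("<jaccard_curve> ", length(x$gammas), " gammas in [0, ",
      x$gamma_max, "], step ", x$delta_gamma, "\n  optimal gamma ",
      x$optimal_gamma, " (max smoothed J = ",
      signif(max(x$smoothed_j), 4), ", max raw J = ",
      signif(max(x$raw_j), 4), ")\n", sep = "")
  invisible(x)
}

#' @export
plot.jaccard_curve <- function(x, ...) {
  plot(x$gammas, x$raw_j, type = "l", col = "grey60",
       xlab = expression(gamma), ylab = "Jaccard index", ...)
  graphics::lines(x$gammas, x$smoothed_j, col = "black", lwd = 2)
  graphics::abline(v = x$optimal_gamma, lty = 2)
  invisible(x)
}

#' Export a Jaccard curve as a delimited table
#' @param curve a `jaccard_curve`.
#' @param path output path.
#' @export
write_jaccard_curve <- function(curve, path) {
  utils::write.table(
    data.frame(gamma = curve$gammas, raw_j = curve$raw_j,
               smoothed_j = curve$smoothed_j),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Intercept-free robust calibration of the threshold slope
#'
#' Fits `optimal_gamma = slope * top_median` through the origin by
#' iteratively reweighted least squares with Tukey bisquare weights
#' (tuning constant 4.685, median-absolute-deviation scale, at most 50
#' iterations or relative slope change below 1e-8). The origin constraint
#' encodes that a region with no activation has effect size zero.
#'
#' @param top_median numeric vector of per-acquisition top-0.1% median
#'   effect sizes (the predictor).
#' @param optimal_gamma numeric vector of per-acquisition optimal
#'   thresholds from [gamma_sweep()] (the response).
#' @param tuning bisquare tuning constant.
#' @param max_iter,tol IRLS controls.
#' @return An object of class `threshold_calibration`: `slope`, per-point
#'   `weights` in \[0, 1\], `residuals`, `iterations`.
#' @examples
#' calib <- calibrate_slope(c(2, 4, 6), c(1, 2, 3))
#' coef(calib)  # 0.5
#' @export
calibrate_slope <- function(top_median, optimal_gamma, tuning = 4.685,
                            max_iter = 50L, tol = 1e-8) {
  x <- as.numeric(top_median); y <- as.numeric(optimal_gamma)
  stopifnot(length(x) == length(y), length(x) >= 1)
  if (!any(x > 0)) stop("need at least one point with positive top_median")
  w <- rep(1, length(x))
  slope <- sum(w * x * y) / sum(w * x^2)
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    iterations <- it
    r <- y - slope * x
    s <- stats::median(abs(r)) / 0.6745
    if (s <= .Machine$double.eps^0.5 * max(abs(y), 1)) {
      # at least half the points fit exactly: keep those, drop the rest
      w <- as.numeric(abs(r) <= 1e-8 * max(abs(y), 1))
      slope <- sum(w * x * y) / sum(w * x^2)
      break
    }
    u <- r / (tuning * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w * x^2) <= 0)
      stop("all weights driven to zero; calibration degenerate")
    new_slope <- sum(w * x * y) / sum(w * x^2)
    if (abs(new_slope - slope) <= tol * max(abs(slope), 1e-12)) {
      slope <- new_slope; break
    }
    slope <- new_slope
  }
  structure(list(slope = slope, weights = w, residuals = y - slope * x,
                 top_median = x, optimal_gamma = y, tuning = tuning,
                 iterations = iterations),
            class = "threshold_calibration")
}

#' @export
coef.threshold_calibration <- function(object, ...) c(slope = object$slope)

#' @export
print.threshold_calibration <- function(x, ...) {
  cat("<threshold_calibration> slope ", signif(x$slope, 6), " from ",
      length(x$weights), " points (", x$iterations, " IRLS iterations)\n",
      "  weights: ", paste(signif(x$weights, 3), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Serialise a threshold model or calibration to structured text
#' @param x a `threshold_model` or `threshold_calibration`.
#' @param path output path (YAML).
#' @export
write_threshold_model <- function(x, path) {
  obj <- unclass(x)
  obj$class <- class(x)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_threshold_model
#' @export
read_threshold_model <- function(path) {
  obj <- yaml::read_yaml(path)
  cls <- obj$class; obj$class <- NULL
  structure(obj, class = cls)
}
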