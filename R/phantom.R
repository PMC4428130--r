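#' Specification of a block-design fMRI phantom
#'
#' Describes a synthetic 4-D BOLD acquisition: grid geometry, a block
#' protocol, spatially compact activation regions of known percent signal
#' change, AR(2) temporal noise, and optional low-frequency drift and
#' confound contamination. The defaults emulate the passive-hand-motion
#' acquisition the package targets: 142 volumes at TR 2.26 s, ten cycles of
#' 16 s task / 16 s rest, one spherical blob at 2% signal change, AR(2)
#' noise with coefficients (0.3, 0.2), and an innovation scale calibrated so
#' the in-blob ordinary-least-squares t statistic is about 6 (comfortable
#' detection, a 3T-like regime).
#'
#' @param grid_dims integer triple, voxels per axis.
#' @param voxel_size_mm positive real triple, mm.
#' @param tr_s repetition time, seconds.
#' @param n_volumes number of volumes.
#' @param block_on_s,block_off_s,n_blocks block design parameters, seconds.
#' @param regions list of regions; each a list with fields `center` (voxel
#'   triple), `radius` (voxels), `psc` (percent signal change, may be
#'   negative for deactivation), and `shape` ("sphere" or "box").
#' @param baseline temporal-mean intensity.
#' @param ar_coeffs AR(2) coefficient pair; must define a stationary process.
#' @param innovation_sd innovation standard deviation; `NULL` calibrates it
#'   with [calibrate_innovation_sd()] to `target_t`.
#' @param target_t in-blob OLS t statistic targeted when `innovation_sd` is
#'   `NULL`.
#' @param drift_amplitude amplitude of a half-cosine low-frequency drift
#'   (intensity units; 0 disables).
#' @param confound_amplitude amplitude of a sinusoidal nuisance signal
#'   shared by all voxels (0 disables).
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(10, 10, 6),
                         voxel_size_mm = c(3, 3, 3),
                         tr_s = 2.26, n_volumes = 142,
                         block_on_s = 16, block_off_s = 16, n_blocks = 10,
                         regions = list(list(center = c(5, 5, 3), radius = 2.5,
                                             psc = 2, shape = "sphere")),
                         baseline = 100,
                         ar_coeffs = c(0.3, 0.2),
                         innovation_sd = NULL,
                         target_t = 6,
                         drift_amplitude = 0,
                         confound_amplitude = 0,
                         seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  stopifnot(length(grid_dims) == 3L, all(grid_dims >= 1L),
            length(voxel_size_mm) == 3L, all(voxel_size_mm > 0),
            tr_s > 0, n_volumes >= 1, block_on_s > 0, block_off_s > 0,
            n_blocks >= 1, baseline > 0, drift_amplitude >= 0,
            confound_amplitude >= 0)
  check_ar_stationary(ar_coeffs)
  if (n_volumes * tr_s < n_blocks * (block_on_s + block_off_s) - tr_s)
    stop("acquisition shorter than the block design: need n_volumes * tr_s >= ",
         n_blocks * (block_on_s + block_off_s) - tr_s, " s")
  for (r in regions) {
    stopifnot(length(r$center) == 3L, r$radius > 0,
              r$shape %in% c("sphere", "box"))
    if (any(r$center < 1) || any(r$center > grid_dims))
      stop("region center (", paste(r$center, collapse = ","),
           ") lies outside the grid")
  }
  spec <- structure(list(grid_dims = grid_dims, voxel_size_mm = voxel_size_mm,
                         tr_s = tr_s, n_volumes = as.integer(n_volumes),
                         block_on_s = block_on_s, block_off_s = block_off_s,
                         n_blocks = as.integer(n_blocks), regions = regions,
                         baseline = baseline, ar_coeffs = as.numeric(ar_coeffs),
                         innovation_sd = innovation_sd,
                         drift_amplitude = drift_amplitude,
                         confound_amplitude = confound_amplitude,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  if (is.null(innovation_sd)) {
    spec$innovation_sd <- calibrate_innovation_sd(spec, target_t)
  } else {
    stopifnot(innovation_sd >= 0)
    spec$innovation_sd <- innovation_sd
  }
  spec
}

check_ar_stationary <- function(ar) {
  ar <- as.numeric(ar)
  if (length(ar) != 2L) stop("ar_coeffs must be a pair")
  if (all(ar == 0)) return(invisible(TRUE))
  roots <- polyroot(c(1, -ar))
  if (any(Mod(roots) <= 1 + 1e-12))
    stop("AR(2) coefficients (", paste(ar, collapse = ", "),
         ") are non-stationary: characteristic roots at modulus ",
         paste(signif(Mod(roots), 4), collapse = ", "),
         " (need all > 1)")
  invisible(TRUE)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec> ", paste(x$grid_dims, collapse = "x"), " grid, ",
      x$n_volumes, " volumes @ TR ", x$tr_s, " s\n", sep = "")
  cat("  ", x$n_blocks, " blocks of ", x$block_on_s, " s on / ",
      x$block_off_s, " s off; ", length(x$regions), " region(s); AR(2) = (",
      paste(x$ar_coeffs, collapse = ", "), "), innovation sd ",
      signif(x$innovation_sd, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname phantom_spec
#' @param spec a `phantom_spec`.
#' @export
phantom_protocol <- function(spec) {
  stimulus_protocol(
    onsets_s = (seq_len(spec$n_blocks) - 1) * (spec$block_on_s + spec$block_off_s),
    durations_s = spec$block_on_s, tr_s = spec$tr_s, n_scans = spec$n_volumes)
}

#' Calibrate the innovation scale to a target detection strength
#'
#' Closed form: the expected OLS t for an in-blob voxel is approximately
#' `b * ||x_perp|| / sd_noise`, with `b` the injected peak amplitude in
#' intensity units, `x_perp` the task regressor residualised against the
#' other design columns, and `sd_noise` the stationary AR(2) noise standard
#' deviation. Solving for the innovation sd uses the stationary-variance
#' identity for an AR(2) process. Autocorrelation inflation of the OLS t is
#' ignored, so the realised t is only approximately the target.
#'
#' @param spec a `phantom_spec` (its first region sets the amplitude).
#' @param target_t target in-blob OLS t statistic.
#' @return Innovation standard deviation.
#' @export
calibrate_innovation_sd <- function(spec, target_t = 6) {
  stopifnot(target_t > 0, length(spec$regions) >= 1)
  X <- build_design_matrix(phantom_protocol(spec))$matrix
  x <- X[, 1]
  other <- X[, -1, drop = FALSE]
  x_perp <- stats::lm.fit(other, x)$residuals
  b <- spec$baseline * abs(spec$regions[[1]]$psc) / 100
  sd_noise <- b * sqrt(sum(x_perp^2)) / target_t
  a <- spec$ar_coeffs
  # stationary variance of AR(2): sigma_in^2 (1-a2) / ((1+a2)((1-a2)^2-a1^2))
  factor <- (1 - a[2]) / ((1 + a[2]) * ((1 - a[2])^2 - a[1]^2))
  sd_noise / sqrt(factor)
}

region_mask <- function(region, grid_dims) {
  cx <- region$center
  idx <- arrayInd(seq_len(prod(grid_dims)), grid_dims)
  if (region$shape == "sphere") {
    d2 <- (idx[, 1] - cx[1])^2 + (idx[, 2] - cx[2])^2 + (idx[, 3] - cx[3])^2
    inside <- d2 <= region$radius^2 + 1e-12
  } else {
    inside <- pmax(abs(idx[, 1] - cx[1]), abs(idx[, 2] - cx[2]),
                   abs(idx[, 3] - cx[3])) <= region$radius + 1e-12
  }
  array(inside, grid_dims)
}

# run code with a private, seeded RNG stream, restoring the caller's state
with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a block-design fMRI phantom
#'
#' Each in-region voxel's noise-free time course is
#' `baseline * (1 + psc/100 * x_t)` with `x_t` the unit-peak
#' HRF-convolved block regressor; AR(2) noise with the given coefficients
#' and innovation sd is added independently per voxel (100 burn-in samples
#' discarded so the process is approximately stationary at t = 0). Identical
#' specs (including seed) give bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `bold_phantom` with elements `series` (a
#'   [bold_series()]) and `truth` (list with `label_map` — integer codes 1
#'   activated, 2 deactivated, 3 non-activated — and `psc_map`, the true
#'   percent signal change).
#' @examples
#' ph <- generate_phantom(phantom_spec(grid_dims = c(6, 6, 4), seed = 42))
#' ph$series
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dims
  n_vox <- prod(d)
  n_t <- spec$n_volumes
  x <- convolve_task_regressor(phantom_protocol(spec))

  psc <- numeric(n_vox)
  for (r in spec$regions) {
    inside <- as.vector(region_mask(r, d))
    psc[inside] <- psc[inside] + r$psc
  }
  labels <- ifelse(psc > 0, 1L, ifelse(psc < 0, 2L, 3L))

  # noise-free signal: voxels x time
  signal <- spec$baseline * (1 + outer(psc / 100, x))
  if (spec$drift_amplitude > 0) {
    drift <- spec$drift_amplitude * cos(pi * (seq_len(n_t) - 1) / (n_t - 1))
    signal <- sweep(signal, 2, drift, "+")
  }
  if (spec$confound_amplitude > 0) {
    conf <- spec$confound_amplitude * sin(2 * pi * (seq_len(n_t) - 1) / 20)
    signal <- sweep(signal, 2, conf, "+")
  }

  burn <- 100L
  noise <- with_preserved_seed(spec$seed, {
    if (spec$innovation_sd > 0) {
      innov <- matrix(stats::rnorm(n_vox * (n_t + burn), sd = spec$innovation_sd),
                      n_vox, n_t + burn)
      e <- t(apply(innov, 1, function(z)
        stats::filter(z, spec$ar_coeffs, method = "recursive")))
      e[, (burn + 1):(n_t + burn), drop = FALSE]
    } else {
      matrix(0, n_vox, n_t)
    }
  })

  arr <- array(signal + noise, c(d, n_t))
  series <- bold_series(arr, tr_s = spec$tr_s,
                        voxel_size_mm = spec$voxel_size_mm,
                        mask = array(TRUE, d))
  truth <- list(label_map = array(labels, d), psc_map = array(psc, d))
  structure(list(series = series, truth = truth, spec = spec),
            class = "bold_phantom")
}

#' @export
print.bold_phantom <- function(x, ...) {
  cat("<bold_phantom>\n")
  print(x$series)
  tab <- table(factor(x$truth$label_map,
                      levels = 1:3,
                      labels = c("activated", "deactivated", "non-activated")))
  cat("  truth:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Rescale a phantom spec to a different SNR regime
#'
#' Returns a copy of the spec with the innovation sd divided by `snr_scale`,
#' so `snr_scale < 1` emulates a lower-field (noisier) scanner such as an
#' intra-operative 1.5T system.
#'
#' @param spec a [phantom_spec()].
#' @param snr_scale positive scale; 1 leaves the spec unchanged.
#' @return A `phantom_spec`.
#' @export
emulate_snr_regime <- function(spec, snr_scale) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(snr_scale) || length(snr_scale) != 1L || snr_scale <= 0)
    stop("`snr_scale` must be a single positive number")
  spec$innovation_sd <- spec$innovation_sd / snr_scale
  spec
}
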