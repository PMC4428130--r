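#' Canonical haemodynamic response function
#'
#' The canonical double-gamma HRF: a gamma density peaking near 5 s minus a
#' second gamma density modelling the post-stimulus undershoot (peak 16 s,
#' peak-to-undershoot ratio 6), sampled on \[0, 32\] s and scaled to unit
#' peak, so regression coefficients on an HRF-convolved unit boxcar are in
#' peak-response units.
#'
#' @param dt_s sampling interval in seconds, in (0, 4].
#' @return Numeric vector: the kernel sampled at `seq(0, 32, by = dt_s)`.
#' @examples
#' h <- canonical_hrf(0.1)
#' seq(0, 32, by = 0.1)[which.max(h)]  # time-to-peak, about 5 s
#' @export
canonical_hrf <- function(dt_s) {
  if (!is.numeric(dt_s) || length(dt_s) != 1L || dt_s <= 0 || dt_s > 4)
    stop("`dt_s` must be a single value in (0, 4]")
  t <- seq(0, 32, by = dt_s)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Block-design stimulus protocol
#'
#' @param onsets_s strictly increasing non-negative onset times, seconds.
#' @param durations_s positive block durations, seconds (length 1 recycled).
#' @param tr_s repetition time, seconds.
#' @param n_scans number of volumes.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(onsets_s, durations_s, tr_s, n_scans) {
  if (length(onsets_s) == 0L) stop("protocol has no onsets")
  if (any(onsets_s < 0)) stop("onsets must be non-negative")
  if (any(diff(onsets_s) <= 0)) stop("onsets must be strictly increasing")
  durations_s <- rep_len(durations_s, length(onsets_s))
  if (any(durations_s <= 0)) stop("durations must be positive")
  if (tr_s <= 0) stop("tr_s must be positive")
  n_scans <- as.integer(n_scans)
  if (n_scans < 1L) stop("n_scans must be a positive integer")
  if (any(onsets_s + durations_s > n_scans * tr_s + 1e-9))
    stop("a block extends beyond the acquisition (onset + duration > n_scans * tr_s)")
  structure(list(onsets_s = onsets_s, durations_s = durations_s,
                 tr_s = tr_s, n_scans = n_scans),
            class = "stimulus_protocol")
}

#' Default passive-hand-motion protocol
#'
#' Ten cycles of 16 s task / 16 s rest at TR 2.26 s over 142 volumes — the
#' block design the phantom simulator and examples use.
#'
#' @param n_blocks,block_on_s,block_off_s,tr_s,n_scans protocol parameters.
#' @return A [stimulus_protocol()].
#' @export
default_protocol <- function(n_blocks = 10, block_on_s = 16, block_off_s = 16,
                             tr_s = 2.26, n_scans = 142) {
  stimulus_protocol(onsets_s = (seq_len(n_blocks) - 1) * (block_on_s + block_off_s),
                    durations_s = block_on_s, tr_s = tr_s, n_scans = n_scans)
}

# HRF-convolved boxcar sampled at scan starts, on a microtime grid of
# `bins` sub-divisions per TR so onsets need not align to scan boundaries.
convolve_task_regressor <- function(protocol, bins = 16L) {
  dt <- protocol$tr_s / bins
  n_grid <- protocol$n_scans * bins
  tgrid <- (seq_len(n_grid) - 1) * dt
  box <- numeric(n_grid)
  for (i in seq_along(protocol$onsets_s)) {
    on <- protocol$onsets_s[i]
    box[tgrid >= on - 1e-9 & tgrid < on + protocol$durations_s[i] - 1e-9] <- 1
  }
  h <- canonical_hrf(dt)
  # direct causal convolution (exact zeros before the first onset)
  padded <- c(rep(0, length(h) - 1), box)
  conv <- stats::filter(padded, h, method = "convolution",
                        sides = 1)[length(h) - 1 + seq_len(n_grid)] * dt
  x <- conv[1 + bins * (seq_len(protocol$n_scans) - 1)]
  if (max(x) > 0) x <- x / max(x)  # unit peak: coefficients in peak units
  x
}

#' Build the GLM design matrix
#'
#' Columns are: the canonical-HRF-convolved boxcar (peak-normalised), its
#' temporal derivative (one-scan-lag finite difference), any confound
#' regressors, and a constant (mean) column.
#'
#' @param protocol a [stimulus_protocol()].
#' @param confounds optional numeric matrix/data frame with one row per scan
#'   (e.g. six rigid-body motion parameters).
#' @return An object of class `fmri_design` with fields `matrix`,
#'   `column_names`, `task_index`, `derivative_index`, `mean_index`.
#' @examples
#' X <- build_design_matrix(default_protocol())
#' dim(X$matrix)  # 142 x 3
#' @export
build_design_matrix <- function(protocol, confounds = NULL) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  n <- protocol$n_scans
  task <- convolve_task_regressor(protocol)
  deriv <- c(0, diff(task))
  cols <- list(task = task, task_derivative = deriv)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != n)
      stop("confounds have ", nrow(confounds), " rows but the protocol has ",
           n, " scans")
    cn <- colnames(confounds)
    if (is.null(cn)) cn <- paste0("confound", seq_len(ncol(confounds)))
    for (j in seq_len(ncol(confounds))) cols[[cn[j]]] <- confounds[, j]
  }
  cols$mean <- rep(1, n)
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  zero <- apply(X, 2, function(v) all(v == 0))
  if (any(zero))
    stop("design column(s) identically zero: ",
         paste(names(cols)[zero], collapse = ", "))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("design matrix is rank deficient; collinear column(s): ",
            paste(dropped, collapse = ", "))
  }
  structure(list(matrix = X, column_names = colnames(X),
                 task_index = 1L, derivative_index = 2L,
                 mean_index = ncol(X), protocol = protocol),
            class = "fmri_design")
}

#' @export
print.fmri_design <- function(x, ...) {
  cat("<fmri_design> ", nrow(x$matrix), " scans x ", ncol(x$matrix),
      " regressors: ", paste(x$column_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Task contrasts
#'
#' Unit weight on the task regressor (positive BOLD response) or its negation
#' (negative response); zero elsewhere.
#'
#' @param design an `fmri_design`.
#' @return Numeric contrast vector of length K.
#' @export
positive_task_contrast <- function(design) {
  stopifnot(inherits(design, "fmri_design"))
  w <- numeric(ncol(design$matrix))
  w[design$task_index] <- 1
  names(w) <- design$column_names
  w
}

#' @rdname positive_task_contrast
#' @export
negative_task_contrast <- function(design) -positive_task_contrast(design)

#' Read a confound table
#'
#' Whitespace- or comma-delimited text, one row per scan, optional header.
#'
#' @param path file path.
#' @return Numeric matrix.
#' @export
read_confounds <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  header <- !grepl("^[-0-9.eE+ \t,]+$", first)
  as.matrix(utils::read.table(path, sep = sep, header = header))
}

#' Export a design matrix as delimited text
#' @param design an `fmri_design`.
#' @param path output file path.
#' @export
write_design_matrix <- function(design, path) {
  utils::write.table(design$matrix, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
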