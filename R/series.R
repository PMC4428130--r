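#' BOLD time-series container
#'
#' Bundles a 4-D intensity array with its repetition time, voxel size, binary
#' brain mask and affine. This is the unit of analysis consumed by
#' [fit_glm()], [vb_fit()] and [gaussian_smooth()].
#'
#' @param data numeric 4-D array, spatial dims first, time last.
#' @param tr_s repetition time in seconds.
#' @param voxel_size_mm positive length-3 numeric, voxel edge lengths in mm.
#' @param mask logical/0-1 3-D array matching the spatial grid of `data`.
#'   Defaults to all-in.
#' @param affine 4x4 voxel-to-world transform; defaults to a diagonal scaling
#'   by the voxel size.
#' @return An object of class `bold_series`.
#' @export
bold_series <- function(data, tr_s, voxel_size_mm = c(3, 3, 3), mask = NULL,
                        affine = NULL) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4-D array (x, y, z, time); got ",
         length(dim(data)), " dimensions")
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0)
    stop("`tr_s` must be a single positive number")
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be three positive numbers")
  sdim <- dim(data)[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, sdim)
  } else {
    if (!identical(as.integer(dim(mask)), as.integer(sdim)))
      stop("mask grid ", paste(dim(mask), collapse = "x"),
           " does not match series grid ", paste(sdim, collapse = "x"))
    vals <- unique(as.vector(mask[!is.na(mask)]))
    bad <- setdiff(vals, c(0, 1, TRUE, FALSE))
    if (length(bad))
      stop("mask must be binary; offending values: ",
           paste(utils::head(bad, 5), collapse = ", "))
    mask <- array(as.logical(mask), sdim)
  }
  if (!any(mask)) stop("mask is empty")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size_mm, 1))
  }
  structure(list(data = data, tr_s = tr_s, voxel_size_mm = voxel_size_mm,
                 mask = mask, affine = affine),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_series> ", paste(d[1:3], collapse = "x"), " voxels, ",
      d[4], " volumes, TR ", x$tr_s, " s\n", sep = "")
  cat("  voxel size: ", paste(x$voxel_size_mm, collapse = " x "),
      " mm; in-mask voxels: ", sum(x$mask), "\n", sep = "")
  invisible(x)
}

#' @export
dim.bold_series <- function(x) dim(x$data)

# time-by-voxel matrix of in-mask time courses (internal)
series_matrix <- function(series) {
  d <- dim(series$data)
  m <- matrix(series$data, prod(d[1:3]), d[4])
  t(m[as.vector(series$mask), , drop = FALSE])
}

# map per-in-mask-voxel values back onto the 3-D grid, NA outside the mask
map_to_volume <- function(values, mask) {
  vol <- array(NA_real_, dim(mask))
  vol[mask] <- values
  vol
}
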