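#' Isotropic Gaussian pre-smoothing
#'
#' Convolves each volume with a separable Gaussian of the given full width
#' at half maximum (per-axis sd `fwhm / (2 sqrt(2 log 2))` in mm, converted
#' to voxels through the voxel size, so anisotropic voxels are handled
#' per axis). Reflective boundaries conserve total intensity; constant
#' volumes pass through unchanged.
#'
#' @param series a [bold_series()].
#' @param fwhm_mm positive full width at half maximum in mm.
#' @return A smoothed [bold_series()] (mask and header unchanged).
#' @export
gaussian_smooth <- function(series, fwhm_mm) {
  stopifnot(inherits(series, "bold_series"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("`fwhm_mm` must be a single positive number")
  if (any(series$voxel_size_mm <= 0)) stop("zero voxel size")
  sd_vox <- (fwhm_mm / (2 * sqrt(2 * log(2)))) / series$voxel_size_mm
  kerns <- lapply(sd_vox, gaussian_kernel_1d)
  out <- series$data
  d <- dim(out)
  for (ax in 1:3) {
    k <- kerns[[ax]]
    if (length(k) == 1L) next
    out <- apply_along_axis(out, ax, k)
  }
  series$data <- array(out, d)
  series
}

gaussian_kernel_1d <- function(sd_vox) {
  if (sd_vox < 1e-6) return(1)
  half <- max(1L, ceiling(4 * sd_vox))
  k <- stats::dnorm(-half:half, sd = sd_vox)
  k / sum(k)
}

# separable 1-D convolution along one spatial axis with reflective edges
apply_along_axis <- function(arr, axis, kernel) {
  d <- dim(arr)
  half <- (length(kernel) - 1L) / 2L
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  n <- d[axis]
  m <- matrix(a, nrow = n)
  # reflective (whole-sample symmetric) padding; conserves total intensity
  pre <- m[pmin(n, half:1), , drop = FALSE]
  post <- m[pmax(1, n + 1 - (1:half)), , drop = FALSE]
  padded <- rbind(pre, m, post)
  sm <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel)) {
    sm <- sm + kernel[j] * padded[(j - 1) + seq_len(n), , drop = FALSE]
  }
  aperm(array(sm, d[perm]), order(perm))
}

#' Read and write NIfTI volumes
#'
#' `read_bold` loads a 4-D series plus its binary mask and wraps them in a
#' [bold_series()]; `write_volume` writes a 3-D or 4-D array (or any of the
#' package's map objects) as NIfTI-1, carrying voxel size and affine.
#' Write-then-read round-trips double data bit-exactly.
#'
#' @param path NIfTI path of the 4-D series.
#' @param mask_path NIfTI path of the 3-D 0/1 mask.
#' @param tr_s repetition time override; default taken from the header.
#' @return `read_bold`: a [bold_series()].
#' @export
read_bold <- function(path, mask_path = NULL, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected a 4-D series, got ", length(dim(img)),
         " dimensions in ", path)
  pd <- RNifti::pixdim(img)
  if (is.null(tr_s)) {
    tr_s <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else
      stop("TR not recorded in the header; pass `tr_s`")
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    if (length(dim(mimg)) != 3L)
      stop("mask must be 3-D, got ", length(dim(mimg)), " dimensions")
    if (!identical(as.integer(dim(mimg)), as.integer(dim(img)[1:3])))
      stop("mask grid ", paste(dim(mimg), collapse = "x"),
           " does not match series grid ",
           paste(dim(img)[1:3], collapse = "x"))
    mask <- array(as.vector(mimg), dim(mimg))
  }
  bold_series(array(as.vector(img), dim(img)), tr_s = tr_s,
              voxel_size_mm = pd[1:3], mask = mask,
              affine = structure(RNifti::xform(img), class = NULL))
}

#' @rdname read_bold
#' @param x array, [bold_series()], [effect_map()], `t_map`, `ppm_result`
#'   label map or `cluster_map` to write.
#' @param voxel_size_mm voxel size recorded in the header.
#' @param tr_s_out repetition time recorded for 4-D data.
#' @export
write_volume <- function(x, path, voxel_size_mm = c(3, 3, 3),
                         tr_s_out = NULL) {
  arr <- if (inherits(x, "bold_series")) {
    voxel_size_mm <- x$voxel_size_mm; tr_s_out <- x$tr_s; x$data
  } else if (inherits(x, "effect_map")) x$mu
  else if (inherits(x, "t_map")) x$t
  else if (inherits(x, "ppm_result")) x$labels
  else if (inherits(x, "cluster_map")) x$labels
  else x
  pd <- c(voxel_size_mm, if (length(dim(arr)) == 4L)
    (if (is.null(tr_s_out)) 1 else tr_s_out))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path,
                     datatype = if (is.integer(arr)) "int32" else "double")
  invisible(path)
}

#' @rdname read_bold
#' @export
write_mask <- function(mask, path, voxel_size_mm = c(3, 3, 3)) {
  write_volume(array(as.integer(mask), dim(mask)), path,
               voxel_size_mm = voxel_size_mm)
}

#' Intensity-based auto-mask (explicit opt-in utility)
#'
#' Masks voxels whose temporal-mean intensity exceeds `frac` times the
#' grand mean — a crude substitute for a tissue-segmentation mask, never
#' applied silently.
#'
#' @param series a [bold_series()].
#' @param frac threshold fraction of the global mean intensity.
#' @return Logical 3-D array.
#' @export
auto_mask <- function(series, frac = 0.5) {
  mean_img <- apply(series$data, 1:3, mean)
  mean_img > frac * mean(mean_img)
}
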