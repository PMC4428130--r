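# Neighbourhood systems on the voxel grid.
# 6  = faces; 18 = faces + edges; 26 = faces + edges + corners.
connectivity_offsets <- function(connectivity = 6L) {
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  manh <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = manh == 1,
                 "18" = manh <= 2,
                 "26" = rep(TRUE, nrow(off)))
  off[keep, , drop = FALSE]
}

# Pairs of adjacent in-mask voxels (indices in in-mask numbering).
# Each unordered pair appears once.
mask_adjacency <- function(mask, connectivity = 6L) {
  dims <- dim(mask)
  stopifnot(length(dims) == 3L)
  off <- connectivity_offsets(connectivity)
  # keep lexicographically positive half so each pair is listed once
  half <- off[off[, 3] > 0 |
                (off[, 3] == 0 & off[, 2] > 0) |
                (off[, 3] == 0 & off[, 2] == 0 & off[, 1] > 0), ,
              drop = FALSE]
  id <- array(0L, dims)
  id[mask] <- seq_len(sum(mask))
  coords <- arrayInd(which(mask), dims)
  pairs <- vector("list", nrow(half))
  for (h in seq_len(nrow(half))) {
    nb <- sweep(coords, 2, half[h, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1] + dims[1] * (nb[ok, 2] - 1) +
      dims[1] * dims[2] * (nb[ok, 3] - 1)
    nb_id <- id[nb_lin]
    src <- which(ok)[nb_id > 0L]
    pairs[[h]] <- cbind(src, nb_id[nb_id > 0L])
  }
  out <- do.call(rbind, pairs)
  if (is.null(out)) out <- matrix(integer(), 0, 2)
  out
}

#' Unweighted graph Laplacian of a brain mask
#'
#' `L = D - A` over in-mask voxels, with `A` the 0/1 adjacency of the chosen
#' neighbour system restricted to the mask and `D` the degree diagonal.
#' Used as the spatial prior precision structure (scaled by a per-regressor
#' precision) in [vb_fit()].
#'
#' @param mask logical 3-D array.
#' @param connectivity 6 (faces, default for the prior), 18 or 26.
#' @return A sparse symmetric `Matrix::dgCMatrix` whose rows sum to zero.
#' @examples
#' build_graph_laplacian(array(TRUE, c(1, 1, 2)))
#' @export
build_graph_laplacian <- function(mask, connectivity = 6L) {
  mask <- array(as.logical(mask), dim(mask))
  n <- sum(mask)
  if (n == 0L) stop("mask is empty")
  pairs <- mask_adjacency(mask, connectivity)
  if (nrow(pairs) == 0L)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n)))
  A <- Matrix::sparseMatrix(i = c(pairs[, 1], pairs[, 2]),
                            j = c(pairs[, 2], pairs[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(n, deg) - A
}

# number of connected components of the in-mask adjacency graph
mask_graph_components <- function(mask, connectivity = 6L) {
  n <- sum(mask)
  pairs <- mask_adjacency(mask, connectivity)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  igraph::components(g)$no
}

# ragged neighbour list (in in-mask numbering)
mask_neighbor_list <- function(mask, connectivity = 6L) {
  n <- sum(mask)
  pairs <- mask_adjacency(mask, connectivity)
  nb <- vector("list", n)
  if (nrow(pairs)) {
    spl <- split(c(pairs[, 2], pairs[, 1]), c(pairs[, 1], pairs[, 2]))
    nb[as.integer(names(spl))] <- spl
  }
  for (i in seq_len(n)) if (is.null(nb[[i]])) nb[[i]] <- integer()
  nb
}
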