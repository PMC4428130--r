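#' Connected components of a binary voxel map
#'
#' Labels connected clusters of foreground voxels under a 6-, 18- or
#' 26-neighbour system. 18-connectivity (the default used for activation
#' clusters) joins voxels sharing a face or an edge but not only a corner.
#' Components are relabelled 1..n in decreasing size order (ties by smallest
#' linear voxel index).
#'
#' @param binary logical (or 0/1) 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return An object of class `cluster_map`: integer `labels` array (0 =
#'   background), `n_clusters`, `sizes`, `connectivity`.
#' @examples
#' m <- array(FALSE, c(3, 3, 3)); m[1, 1, 1] <- m[2, 2, 2] <- TRUE
#' connected_components(m, 18)$n_clusters  # corner contact: 2 clusters
#' connected_components(m, 26)$n_clusters  # 1 cluster
#' @export
connected_components <- function(binary, connectivity = 18L) {
  dims <- dim(binary)
  stopifnot(length(dims) == 3L)
  fg <- array(as.logical(binary), dims)
  fg[is.na(fg)] <- FALSE
  n <- sum(fg)
  labels <- array(0L, dims)
  if (n == 0L)
    return(structure(list(labels = labels, n_clusters = 0L,
                          sizes = integer(), connectivity = connectivity),
                     class = "cluster_map"))
  pairs <- mask_adjacency(fg, connectivity)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(pairs)) g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)
  # stable relabelling: by decreasing size, then smallest member voxel index
  fg_idx <- which(fg)
  first <- vapply(seq_len(comp$no), function(cl)
    min(fg_idx[comp$membership == cl]), numeric(1))
  ord <- order(-comp$csize, first)
  relabel <- integer(comp$no); relabel[ord] <- seq_len(comp$no)
  labels[fg_idx] <- relabel[comp$membership]
  structure(list(labels = labels, n_clusters = comp$no,
                 sizes = as.integer(comp$csize[ord]),
                 connectivity = as.integer(connectivity)),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("<cluster_map> ", x$n_clusters, " cluster(s), connectivity ",
      x$connectivity, "; sizes: ",
      paste(utils::head(x$sizes, 8), collapse = ", "),
      if (x$n_clusters > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Jaccard overlap of two binary maps
#'
#' `|A intersect B| / |A union B|`. Defined as 0 (with a warning) when both
#' maps are empty.
#'
#' @param a,b logical (or 0/1) arrays of identical shape.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("maps have different shapes: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  a <- as.logical(a); b <- as.logical(b)
  a[is.na(a)] <- FALSE; b[is.na(b)] <- FALSE
  uni <- sum(a | b)
  if (uni == 0L) {
    warning("both maps are empty; Jaccard index defined as 0")
    return(0)
  }
  sum(a & b) / uni
}

#' Voxel-wise confusion metrics against a reference map
#'
#' Counts true/false positives and negatives over in-mask voxels and
#' reports `sensitivity = TP / (TP + FN)` and the false discovery rate
#' `FDR = FP / (FP + TP)`. Degenerate denominators give 0 with a flag.
#'
#' @param test logical test (detection) map.
#' @param reference logical ground-truth map.
#' @param mask logical analysis mask.
#' @return An object of class `confusion_metrics` with fields `tp`, `fp`,
#'   `tn`, `fn`, `sensitivity`, `fdr`, `degenerate`.
#' @examples
#' truth <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
#' confusion_metrics(truth, truth, array(TRUE, c(4, 1, 1)))
#' @export
confusion_metrics <- function(test, reference, mask) {
  if (!identical(dim(test), dim(reference)) ||
      !identical(dim(test), dim(mask)))
    stop("test, reference and mask must share a grid")
  if (!any(mask)) stop("mask is empty")
  tv <- as.logical(test)[mask]; rv <- as.logical(reference)[mask]
  tv[is.na(tv)] <- FALSE; rv[is.na(rv)] <- FALSE
  tp <- sum(tv & rv); fp <- sum(tv & !rv)
  fn <- sum(!tv & rv); tn <- sum(!tv & !rv)
  degenerate <- character()
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    degenerate <- c(degenerate, "no positives in reference"); 0
  }
  fdr <- if (tp + fp > 0) fp / (tp + fp) else {
    degenerate <- c(degenerate, "no positives in test"); 0
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, fdr = fdr, degenerate = degenerate),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("<confusion_metrics> TP=", x$tp, " FP=", x$fp, " TN=", x$tn,
      " FN=", x$fn, "\n  sensitivity ", signif(x$sensitivity, 4),
      ", FDR ", signif(x$fdr, 4),
      if (length(x$degenerate)) paste0(" [", paste(x$degenerate,
                                                   collapse = "; "), "]"),
      "\n", sep = "")
  invisible(x)
}
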