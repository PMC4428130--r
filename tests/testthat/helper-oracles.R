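# Independent oracles used across tests. These deliberately avoid the
# package's own implementations.

# brute-force connected components by union-find over explicit neighbour
# offsets
uf_components <- function(binary, connectivity) {
  dims <- dim(binary)
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(off)) == 1,
                 "18" = rowSums(abs(off)) <= 2,
                 "26" = rep(TRUE, nrow(off)))
  off <- off[keep, , drop = FALSE]
  idx <- which(binary)
  if (!length(idx)) return(list(n = 0L, membership = integer()))
  parent <- seq_along(idx)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pos <- arrayInd(idx, dims)
  lookup <- array(0L, dims); lookup[idx] <- seq_along(idx)
  for (i in seq_along(idx)) {
    for (h in seq_len(nrow(off))) {
      nb <- pos[i, ] + off[h, ]
      if (any(nb < 1) || any(nb > dims)) next
      j <- lookup[nb[1], nb[2], nb[3]]
      if (j > 0L) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_along(idx), find, integer(1))
  list(n = length(unique(roots)), membership = match(roots, unique(roots)))
}

# ordinary least squares via explicit pseudoinverse
ols_oracle <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}

# lag-k sample autocorrelation
acf_lag <- function(x, k) {
  x <- x - mean(x)
  sum(x[(k + 1):length(x)] * x[1:(length(x) - k)]) / sum(x^2)
}
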