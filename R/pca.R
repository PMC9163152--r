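# Dense PCA of a standardized design matrix.

#' Fit dense PCA
#'
#' Principal components as the top-`k` right singular directions of the
#' standardized matrix, computed through the eigendecomposition of the
#' sample covariance `X'X / (n - 1)`. Each component's sign is flipped so
#' that its largest-magnitude loading is positive, which makes outputs
#' deterministic (PCA signs are otherwise arbitrary).
#'
#' @param x a `std_matrix` (see [standardize()]) or numeric matrix.
#' @param k number of components to retain, `1 <= k <= ncol(x)`.
#' @return Object of class `pca_fit`: `loadings` (p x k, orthonormal
#'   columns), `scores` (n x k, columns named `PC1..PCk`), `var_ratios`
#'   (fraction of total variance per retained component) and `sdev`
#'   (all p singular SDs).
#' @export
fit_pca <- function(x, k) {
  v <- std_values(x)
  p <- ncol(v)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > p)
    stopf("k must be an integer in [1, %d]", p)
  k <- as.integer(k)
  G <- crossprod(v) / (nrow(v) - 1)
  e <- eigen(G, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  V <- canonical_signs(V)
  rownames(V) <- colnames(v)
  colnames(V) <- paste0("PC", seq_len(k))
  scores <- v %*% V
  structure(
    list(loadings = V, scores = scores,
         var_ratios = vals[seq_len(k)] / sum(vals),
         sdev = sqrt(vals)),
    class = "pca_fit"
  )
}

# Flip each column so its largest-|entry| is positive.
#' @noRd
canonical_signs <- function(M) {
  for (j in seq_len(ncol(M))) {
    col <- M[, j]
    if (all(col == 0)) next
    if (col[which.max(abs(col))] < 0) M[, j] <- -col
  }
  M
}

#' @export
print.pca_fit <- function(x, ...) {
  cat(sprintf("PCA fit: %d components of %d variables\n",
              ncol(x$loadings), nrow(x$loadings)))
  cat("  explained variance:",
      paste(sprintf("%.3f", x$var_ratios), collapse = " "), "\n")
  invisible(x)
}
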