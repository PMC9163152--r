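# Sparse PCA by variable projection.
#
# The sparse components solve
#
#     min_B  1/2 ||X - X B A'||_F^2 / (n - 1)  +  psi(B)
#     s.t.   A'A = I,
#
# where B (p x k) is the sparse weight matrix, A (p x k) has orthonormal
# columns, and psi is an elastic-net penalty
# lambda * (alpha * ||B||_1 + (1 - alpha)/2 * ||B||_F^2). Scaling the
# reconstruction term by 1/(n - 1) puts it on the covariance scale, so a
# given lambda means the same thing regardless of the number of
# subjects (for standardized data the Gram matrix has unit diagonal).
#
# The optimizer alternates two exact partial minimizations:
#   A-step: orthogonal Procrustes. With G = X'X/(n-1), the A that
#     minimizes the objective at fixed B is UV' from the SVD of G B.
#   B-step: the columns of B decouple into penalized quadratic
#     problems solved by cyclic coordinate descent with
#     soft-thresholding (exact coordinate minimization).
# Both steps monotonically decrease the objective, so the recorded
# objective trace is non-increasing. Initialization is the dense PCA
# basis, which makes the unpenalized fit (lambda = 0) coincide exactly
# with PCA.

#' Fit sparse PCA
#'
#' @param x a `std_matrix` (see [standardize()]) or numeric matrix.
#' @param k number of components, `1 <= k <= ncol(x)`.
#' @param lambda nonnegative sparsity penalty.
#' @param penalty `"elasticnet"` (default), `"l1"` or `"l2"`. `"l1"` and
#'   `"l2"` force `alpha` to 1 and 0 respectively.
#' @param alpha elastic-net mixing weight on the L1 term, default 0.95
#'   (mostly lasso with a small ridge stabilizer).
#' @param max_iter maximum alternating iterations, default 1000.
#' @param tol relative objective-change convergence tolerance, default
#'   1e-6.
#' @param init optional warm start: list with matrices `B` and `A`
#'   (p x k), e.g. from a fit at a nearby penalty. Default is the dense
#'   PCA basis.
#' @return Object of class `spca_fit` with elements `B` (sparse
#'   weights), `A` (orthonormal), `scores = X B` (columns `SPC1..SPCk`),
#'   `lambda`, `alpha`, `penalty`, `objective` (per-iteration trace),
#'   `iterations`, `converged`, and `explained_variance` (adjusted
#'   per-component fractions, see [explained_variance()]).
#' @examples
#' X <- standardize(matrix(rnorm(600), 200, 3))
#' fit <- fit_spca(X, k = 2, lambda = 0.1)
#' spca_support(fit)
#' @export
fit_spca <- function(x, k, lambda, penalty = c("elasticnet", "l1", "l2"),
                     alpha = 0.95, max_iter = 1000, tol = 1e-6, init = NULL) {
  v <- std_values(x)
  n <- nrow(v); p <- ncol(v)
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k > p)
    stopf("k must be an integer in [1, %d]", p)
  if (!is.finite(lambda) || lambda < 0) stopf("lambda must be nonnegative")
  penalty <- match.arg(penalty)
  if (penalty == "l1") alpha <- 1
  if (penalty == "l2") alpha <- 0
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  k <- as.integer(k)

  G <- crossprod(v) / (n - 1)
  trG <- sum(diag(G))
  if (is.null(init)) {
    e <- eigen(G, symmetric = TRUE)
    B <- A <- e$vectors[, seq_len(k), drop = FALSE]
  } else {
    B <- unname(as.matrix(init$B)); A <- unname(as.matrix(init$A))
    if (!all(dim(B) == c(p, k)) || !all(dim(A) == c(p, k)))
      stopf("init B and A must be %d x %d", p, k)
  }

  res <- spca_vp_cpp(G, B, A, l1 = lambda * alpha,
                     l2 = lambda * (1 - alpha), max_iter = max_iter,
                     tol = tol, sweeps = 5L)
  B <- res$B
  A <- res$A
  trace <- res$objective
  converged <- res$converged
  iter <- res$iterations

  # deterministic sign convention; flipping a column of both B and A
  # leaves B A' and the penalty unchanged
  for (j in seq_len(k)) {
    col <- B[, j]
    if (all(col == 0)) next
    if (col[which.max(abs(col))] < 0) {
      B[, j] <- -col
      A[, j] <- -A[, j]
    }
  }
  rownames(B) <- rownames(A) <- colnames(v)
  colnames(B) <- colnames(A) <- paste0("SPC", seq_len(k))
  scores <- v %*% B

  fit <- structure(
    list(B = B, A = A, scores = scores, lambda = lambda, alpha = alpha,
         penalty = penalty, objective = trace, iterations = iter,
         converged = converged),
    class = "spca_fit"
  )
  fit$explained_variance <- explained_variance(fit, x)
  if (!converged)
    warning(sprintf(
      "sparse PCA did not converge in %d iterations (final objective %.6g)",
      max_iter, trace[length(trace)]), call. = FALSE)
  fit
}

#' @export
print.spca_fit <- function(x, ...) {
  supp <- spca_support(x)
  cat(sprintf("Sparse PCA fit: %d components, lambda = %g (%s, alpha = %g)\n",
              ncol(x$B), x$lambda, x$penalty, x$alpha))
  cat("  support sizes:", paste(lengths(supp), collapse = " "), "\n")
  cat("  adjusted explained variance:",
      paste(sprintf("%.3f", x$explained_variance), collapse = " "), "\n")
  invisible(x)
}

#' Adjusted explained variance of sparse components
#'
#' Sparse components are generally correlated, so naive per-component
#' score variances over-count shared variance. The adjusted definition
#' sequentially orthogonalizes the score matrix `Z = X B` by QR
#' decomposition; component `j` contributes the squared `j`-th diagonal
#' of the triangular factor divided by `n - 1`, and fractions are taken
#' against the total column variance of `X`. When the components are
#' uncorrelated (e.g. disjoint supports over uncorrelated blocks) this
#' reduces to the naive score variances; at `lambda = 0` it reduces to
#' the dense PCA explained-variance ratios.
#'
#' @param fit an `spca_fit` (or `pca_fit`).
#' @param x the standardized matrix the fit was computed on.
#' @return Numeric vector of per-component explained-variance fractions.
#' @export
explained_variance <- function(fit, x) {
  v <- std_values(x)
  B <- if (inherits(fit, "pca_fit")) fit$loadings else fit$B
  if (is.null(B) || ncol(B) == 0L) stopf("fit has no components")
  if (nrow(B) != ncol(v)) stopf("fit and matrix are dimensionally incompatible")
  Z <- v %*% B
  R <- qr.R(qr(Z))
  contrib <- diag(R)^2 / (nrow(v) - 1)
  total <- sum(apply(v, 2L, stats::var))
  unname(contrib / total)
}

#' Component supports
#'
#' The support of a component is the set of variables whose weight
#' exceeds `tol` in absolute value. Soft-thresholding produces exact
#' zeros; the tolerance guards rounding.
#'
#' @param fit an `spca_fit` (or `pca_fit`).
#' @param tol zero threshold, default 1e-8.
#' @return List of integer index vectors, one per component.
#' @export
spca_support <- function(fit, tol = 1e-8) {
  B <- if (inherits(fit, "pca_fit")) fit$loadings else fit$B
  lapply(seq_len(ncol(B)), function(j) which(abs(B[, j]) > tol))
}

#' Write loadings as TSV
#'
#' Variables x components with a header of component labels; the fit
#' metadata (lambda, penalty, iterations, final objective) goes to a
#' key-value text block alongside when `meta_path` is given.
#'
#' @param fit an `spca_fit`.
#' @param path loadings output path.
#' @param meta_path optional metadata output path.
#' @return `path`, invisibly.
#' @export
write_spca_fit <- function(fit, path, meta_path = NULL) {
  df <- data.frame(variable = rownames(fit$B), fit$B, check.names = FALSE)
  write_tsv_table(df, path)
  if (!is.null(meta_path)) {
    lines <- c(
      sprintf("lambda\t%.10g", fit$lambda),
      sprintf("penalty\t%s", fit$penalty),
      sprintf("alpha\t%.10g", fit$alpha),
      sprintf("iterations\t%d", fit$iterations),
      sprintf("converged\t%s", fit$converged),
      sprintf("objective\t%.10g", fit$objective[length(fit$objective)])
    )
    writeLines(lines, meta_path)
  }
  invisible(path)
}
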