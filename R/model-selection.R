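# Component-count and sparsity-penalty selection.
#
# Two criteria: the number of components k is the smallest count whose
# cumulative explained variance reaches a threshold (default 90%,
# evaluated on the dense lambda = 0 fit), and the sparsity penalty is
# the smallest grid value at which no two components share a variable
# (pairwise-disjoint supports), so each variable contributes to at most
# one component.

#' Logarithmic penalty grid
#'
#' Default candidate grid for the sparsity penalty: 30 logarithmically
#' spaced values spanning four decades (1e-4 to 1 on the covariance
#' scale used by [fit_spca()]).
#'
#' @param from,to positive grid endpoints.
#' @param length number of grid values.
#' @return Strictly increasing numeric vector.
#' @export
lambda_grid <- function(from = 1e-4, to = 1, length = 30) {
  stopifnot(is.finite(from), is.finite(to), from > 0, to > from, length >= 2)
  10^seq(log10(from), log10(to), length.out = length)
}

#' Select the number of components by explained variance
#'
#' @param fractions per-component explained-variance fractions, in
#'   component order.
#' @param threshold cumulative-variance target in `(0, 1]`, default 0.90.
#' @return Smallest `k` whose cumulative fraction reaches the threshold;
#'   if the threshold is never reached, all components, with a warning.
#' @examples
#' select_n_components(c(0.5, 0.3, 0.15, 0.05), 0.9)  # 3
#' @export
select_n_components <- function(fractions, threshold = 0.90) {
  if (!length(fractions)) stopf("empty explained-variance fractions")
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1)
    stopf("threshold must be in (0, 1]")
  cs <- cumsum(fractions)
  hit <- which(cs >= threshold - 1e-12)
  if (!length(hit)) {
    warning(sprintf(
      "cumulative explained variance (%.3f) never reaches %.3f; keeping all %d components",
      cs[length(cs)], threshold, length(fractions)), call. = FALSE)
    return(length(fractions))
  }
  hit[1L]
}

#' Select the sparsity penalty by the disjoint-support criterion
#'
#' Returns the smallest grid penalty whose fitted component supports
#' are pairwise disjoint. Empty supports are vacuously disjoint, but a
#' fit in which any component has an empty support is rejected as
#' over-penalized: an all-zero component carries no interpretable
#' signal.
#'
#' Each grid value is fitted independently from the dense PCA
#' initialization and the grid is evaluated in increasing order with an
#' early exit at the first disjoint fit, so the result is exactly the
#' smallest grid value whose fit has pairwise-disjoint nonempty
#' supports, and adding grid values above the selected penalty cannot
#' change the answer.
#'
#' @param x standardized matrix (see [standardize()]).
#' @param k number of components.
#' @param grid increasing penalty candidates, see [lambda_grid()].
#' @param penalty,alpha passed to [fit_spca()].
#' @param ... further arguments to [fit_spca()].
#' @return List with `lambda` (the selected value), `fit` (the
#'   `spca_fit` at that value) and `report` (a data.frame with one row
#'   per evaluated grid value, ascending: support sizes, number of
#'   overlapping variables, number of empty components).
#' @export
select_lambda_disjoint <- function(x, k, grid = lambda_grid(),
                                   penalty = "elasticnet", alpha = 0.95, ...) {
  if (!length(grid)) stopf("penalty grid is empty")
  if (is.unsorted(grid, strictly = TRUE)) stopf("grid must be strictly increasing")
  rows <- list()
  for (i in seq_along(grid)) {
    lam <- grid[i]
    fit <- fit_spca(x, k, lambda = lam, penalty = penalty, alpha = alpha, ...)
    supp <- spca_support(fit)
    all_vars <- unlist(supp)
    n_overlap <- length(all_vars) - length(unique(all_vars))
    n_empty <- sum(lengths(supp) == 0L)
    rows[[i]] <- data.frame(
      lambda = lam,
      support_sizes = paste(lengths(supp), collapse = ","),
      n_overlap = n_overlap, n_empty = n_empty
    )
    if (n_overlap == 0L && n_empty == 0L)
      return(list(lambda = lam, fit = fit, report = do.call(rbind, rows)))
  }
  report <- do.call(rbind, rows)
  msg <- paste(
    sprintf("  lambda %.4g: %d overlapping, %d empty",
            report$lambda, report$n_overlap, report$n_empty),
    collapse = "\n")
  stopf("no grid value yields pairwise-disjoint nonempty supports:\n%s", msg)
}
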