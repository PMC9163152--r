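# Standardization and winsorization of the exposure design matrix.
#
# The analysis operates on column-standardized values: each column is
# centred on its sample mean and divided by its sample SD (divisor
# n - 1), after which extreme z-scores are clamped to +/- 5.
# Winsorization is applied AFTER standardization, and the stored
# means/SDs are not recomputed after clamping, so raw-unit
# back-conversion of component loadings stays exact.

#' Column-standardize a design matrix
#'
#' @param x data frame or numeric matrix of raw-unit columns.
#' @return An object of class `std_matrix`: list with `values` (n x p
#'   matrix, each column mean 0 / SD 1 before any clamping), `center`
#'   and `scale` (original raw-unit means and SDs, for unit
#'   back-conversion) and `winsor_bound` (`NA` until [winsorize()] is
#'   applied).
#' @examples
#' standardize(data.frame(a = c(1, 2, 3)))$values
#' @export
standardize <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stopf("all columns must be numeric")
  if (anyNA(m)) stopf("missing values are not allowed; exclude subjects first")
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  center <- colMeans(m)
  scale <- apply(m, 2L, stats::sd)
  bad <- which(!is.finite(scale) | scale <= 0)
  if (length(bad))
    stopf("zero-variance column(s): %s", paste(colnames(m)[bad], collapse = ", "))
  v <- sweep(sweep(m, 2L, center, `-`), 2L, scale, `/`)
  structure(
    list(values = v, center = center, scale = scale, winsor_bound = NA_real_),
    class = "std_matrix"
  )
}

#' Clamp extreme standardized values
#'
#' Values above `bound` are set to `bound`; values below `-bound` to
#' `-bound`. Stored means/SDs are left untouched.
#'
#' @param x a `std_matrix` (or plain numeric matrix).
#' @param bound positive clamp, default 5 standardized units.
#' @return Same class as `x`, clamped.
#' @export
winsorize <- function(x, bound = 5) {
  if (!is.finite(bound) || bound <= 0) stopf("bound must be positive")
  if (inherits(x, "std_matrix")) {
    x$values <- pmin(pmax(x$values, -bound), bound)
    x$winsor_bound <- bound
    return(x)
  }
  pmin(pmax(x, -bound), bound)
}

#' @export
print.std_matrix <- function(x, ...) {
  cat(sprintf("Standardized matrix: %d x %d", nrow(x$values), ncol(x$values)))
  if (is.finite(x$winsor_bound))
    cat(sprintf(", winsorized at +/- %g", x$winsor_bound))
  cat("\n")
  invisible(x)
}

# Internal: pull the numeric matrix out of either representation.
#' @noRd
std_values <- function(x) {
  if (inherits(x, "std_matrix")) x$values else as.matrix(x)
}

#' Pairwise Pearson correlation matrix
#'
#' @param x a `std_matrix`, data frame or numeric matrix with at least
#'   two rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  v <- std_values(x)
  if (nrow(v) < 2L) stopf("need at least 2 rows to correlate")
  stats::cor(v)
}
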