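# Interpretability layer: trace significant components back to their
# constituent variables, convert component units to raw exposure units,
# rescale hazard ratios, and run the decile exposure-response stage.

#' Trace significant components back to variables
#'
#' For every component term whose Wald p-value is below `alpha`, lists
#' the component's support variables, their weights, and (when raw SDs
#' are supplied) the raw-unit change in each variable corresponding to a
#' one-unit increase of the component score. Dense components whose
#' support exceeds the interpretability cap are refused: with (near-)
#' full support the association cannot be disentangled into individual
#' variables, which is precisely the failure mode that motivates the
#' sparse transformation.
#'
#' @param fit an `spca_fit` or `pca_fit`.
#' @param cox a `cox_result` whose terms include the fit's component
#'   labels.
#' @param alpha two-sided significance level, default 0.05.
#' @param max_support interpretability cap on support size, default 6.
#' @param sds optional named raw-unit SDs of the variables (e.g.
#'   `std_matrix$scale`) for raw-unit equivalents.
#' @param tol support tolerance passed to [spca_support()].
#' @return Object of class `attribution_report`: data.frame with one row
#'   per (significant component, support variable): `component`,
#'   `loghr`, `hr`, `ci_low`, `ci_high`, `p`, `variable`, `weight`,
#'   `raw_unit_change`.
#' @export
trace_attribution <- function(fit, cox, alpha = 0.05, max_support = 6,
                              sds = NULL, tol = 1e-8) {
  B <- if (inherits(fit, "pca_fit")) fit$loadings else fit$B
  labels <- colnames(B)
  tab <- cox$table
  missing_terms <- setdiff(labels, tab$term)
  if (length(missing_terms))
    stopf("cox result lacks component term(s): %s",
          paste(missing_terms, collapse = ", "))
  supp <- spca_support(fit, tol = tol)
  rows <- list()
  for (j in seq_along(labels)) {
    r <- tab[tab$term == labels[j], ]
    if (r$p >= alpha) next
    sj <- supp[[j]]
    if (length(sj) > max_support)
      stopf(paste0("component %s is significant but loads on %d variables ",
                   "(cap %d): a dense component cannot be attributed to ",
                   "individual variables"),
            labels[j], length(sj), max_support)
    if (!length(sj)) next
    w <- B[sj, j]
    raw <- rep(NA_real_, length(sj))
    if (!is.null(sds)) {
      s_sj <- sds[rownames(B)[sj]]
      raw <- unname(s_sj * w / sum(w^2))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      component = labels[j], loghr = r$loghr, hr = r$hr,
      ci_low = r$ci_low, ci_high = r$ci_high, p = r$p,
      variable = rownames(B)[sj], weight = unname(w),
      raw_unit_change = raw, row.names = NULL
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(component = character(), loghr = numeric(), hr = numeric(),
               ci_low = numeric(), ci_high = numeric(), p = numeric(),
               variable = character(), weight = numeric(),
               raw_unit_change = numeric())
  structure(out, class = c("attribution_report", "data.frame"),
            alpha = alpha)
}

#' Raw-unit meaning of one component unit
#'
#' A one-unit increase of the component score `z = x' b` along the
#' loading direction changes standardized variable `i` by
#' `b_i / ||b||^2`, hence raw variable `i` by `s_i b_i / ||b||^2`. When
#' all support variables share a physical unit the mean change over the
#' support summarizes the component in that unit (e.g. "one component
#' unit = 2.45 dB of daily noise"); with mixed units only the
#' per-variable changes are reported.
#'
#' @param weights component weight vector (a column of `B`), zeros
#'   allowed.
#' @param sds raw-unit SDs aligned with `weights`.
#' @param units optional character vector of physical units aligned with
#'   `weights`; the aggregate is suppressed unless all support units
#'   agree.
#' @param tol support tolerance.
#' @return List with `per_variable` (named raw-unit changes over the
#'   support) and `mean` (aggregate raw-unit change, `NA` for mixed
#'   units).
#' @export
pc_unit_in_raw_units <- function(weights, sds, units = NULL, tol = 1e-8) {
  supp <- which(abs(weights) > tol)
  if (!length(supp)) stopf("component has empty support")
  if (length(sds) != length(weights))
    stopf("sds must align with weights")
  per <- sds[supp] * weights[supp] / sum(weights[supp]^2)
  names(per) <- names(weights)[supp] %||% paste0("v", supp)
  agg <- if (is.null(units) || length(unique(units[supp])) == 1L)
    mean(per) else NA_real_
  list(per_variable = per, mean = agg)
}

#' Rescale a hazard ratio to a different raw-unit increment
#'
#' A log hazard ratio is linear in the exposure increment it refers to,
#' so an HR quoted per `per` raw units becomes `hr^(target/per)` per
#' `target` raw units; the same power applies to the CI bounds.
#'
#' @param hr hazard ratio (> 0).
#' @param ci length-2 vector of CI bounds (> 0).
#' @param per raw-unit increment the input refers to (> 0).
#' @param target desired raw-unit increment (> 0).
#' @return List with `hr` and `ci`, rescaled.
#' @examples
#' rescale_hr(1.017, c(1.004, 1.030), per = 2.47, target = 10)
#' @export
rescale_hr <- function(hr, ci, per, target) {
  if (any(!is.finite(c(hr, ci, per, target))) ||
      any(c(hr, ci, per, target) <= 0))
    stopf("hr, ci bounds, per and target must all be positive")
  pow <- target / per
  list(hr = hr^pow, ci = ci^pow)
}

#' Row-wise composite of same-unit exposures
#'
#' Unweighted mean across columns in raw units, e.g. averaging the
#' day/evening/night noise levels into a daily-noise variable.
#'
#' @param columns data.frame, matrix, or list of equal-length numeric
#'   vectors.
#' @return Numeric vector of row means.
#' @export
make_composite <- function(columns) {
  if (is.list(columns) && !is.data.frame(columns)) {
    if (length(unique(lengths(columns))) != 1L)
      stopf("composite columns differ in length")
    columns <- do.call(cbind, columns)
  }
  m <- as.matrix(columns)
  if (!ncol(m)) stopf("need at least one column")
  rowMeans(m)
}

#' Decile exposure-response analysis
#'
#' Categorizes a composite exposure into sample deciles (half-open
#' intervals `(a, b]`, ties to the lower decile) and fits a Cox model of
#' indicator terms for deciles 2-10 against the lowest decile,
#' adjusting for the remaining exposures -- replaced by dense principal
#' components reaching `pca_threshold` of their variance -- and for the
#' covariates.
#'
#' @param composite raw-unit composite exposure, one value per subject.
#' @param other_exposures data.frame/matrix of the remaining raw-unit
#'   exposures (standardized and winsorized internally), or `NULL`.
#' @param covariates data.frame/matrix of adjustment covariates, or
#'   `NULL`.
#' @param time,event survival outcome.
#' @param pca_threshold cumulative-variance threshold for the residual
#'   dense PCA adjustment, default 0.92.
#' @param winsor_bound clamp for the standardized exposures, default 5.
#' @return Object of class `decile_result`: `boundaries` (10 rows,
#'   half-open raw-unit intervals), `counts` (subjects per decile),
#'   `table` (9 rows: decile 2-10 log hazard ratios vs decile 1, SE,
#'   Wald 95% CI, p), `n_components` used for adjustment, and `cox`
#'   (the full fit).
#' @export
decile_exposure_response <- function(composite, other_exposures = NULL,
                                     covariates = NULL, time, event,
                                     pca_threshold = 0.92, winsor_bound = 5) {
  composite <- as.numeric(composite)
  if (stats::var(composite) <= 0) stopf("composite has zero variance")
  qs <- stats::quantile(composite, probs = seq(0.1, 0.9, by = 0.1),
                        names = FALSE, type = 7)
  lo <- min(composite); hi <- max(composite)
  breaks <- c(lo - 1e-9 * max(1, abs(lo)), qs, hi)
  if (any(duplicated(breaks)) || length(unique(composite)) < 10L)
    stopf("composite has fewer than 10 distinct decile boundaries")
  dec <- cut(composite, breaks = breaks, labels = FALSE, right = TRUE)
  ind <- sapply(2:10, function(d) as.integer(dec == d))
  colnames(ind) <- paste0("decile", 2:10)

  terms <- ind
  n_comp <- 0L
  if (!is.null(other_exposures) && ncol(as.matrix(other_exposures)) > 0) {
    Xo <- winsorize(standardize(other_exposures), winsor_bound)
    full <- fit_pca(Xo, k = ncol(Xo$values))
    n_comp <- select_n_components(full$var_ratios, pca_threshold)
    terms <- cbind(terms, full$scores[, seq_len(n_comp), drop = FALSE])
  }
  if (!is.null(covariates) && ncol(as.matrix(covariates)) > 0)
    terms <- cbind(terms, as.matrix(covariates))

  design <- survival_design(time, event, terms)
  cox <- fit_cox(design)
  tab <- cox$table[cox$table$term %in% colnames(ind), ]
  boundaries <- data.frame(
    decile = 1:10,
    lower = breaks[1:10], upper = breaks[2:11]
  )
  boundaries$lower[1] <- lo  # print the observed minimum as the open end
  structure(
    list(boundaries = boundaries,
         counts = as.integer(table(factor(dec, levels = 1:10))),
         table = tab, n_components = n_comp, cox = cox),
    class = "decile_result"
  )
}

#' @export
print.decile_result <- function(x, ...) {
  cat("Decile exposure-response\n")
  cat(sprintf("  lowest decile (reference): (%.4g, %.4g], %d subjects\n",
              x$boundaries$lower[1], x$boundaries$upper[1], x$counts[1]))
  cat(sprintf("  residual adjustment: %d principal components\n",
              x$n_components))
  print(format(x$table, digits = 3), row.names = FALSE)
  invisible(x)
}
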