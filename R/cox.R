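# Cox proportional-hazards estimation.
#
# The partial likelihood uses the Efron approximation for tied event
# times. For an event time t with tied set D (d events, eta the linear
# predictor, w = exp(eta)) and risk set R = {i : time_i >= t}:
#
#   l(t) = sum_{i in D} eta_i
#          - sum_{l=0}^{d-1} log( S0(R) - (l/d) S0(D) ),
#
# with matching first and second derivatives built from the weighted
# risk-set sums S0 = sum w, S1 = sum w x, S2 = sum w x x'. Risk-set sums
# are accumulated in one compiled backward scan over subjects sorted by
# follow-up time, so one likelihood/score/information evaluation costs
# O(n p^2). Estimation is by damped Newton iteration (step-halving on a
# likelihood decrease), standard errors come from the inverse observed
# information, and confidence intervals are Wald.

#' Assemble a survival design
#'
#' @param time follow-up in years, one value per subject.
#' @param event 0/1 event indicator.
#' @param terms n x p numeric matrix of regression terms.
#' @param labels term labels; defaults to the column names of `terms`.
#' @param penalized logical mask, one per term: which terms an L1
#'   penalty may shrink (see [fit_cox_l1_path()]). Adjustment covariates
#'   are conventionally left unpenalized. Default: all penalized.
#' @return Object of class `survival_design`.
#' @export
survival_design <- function(time, event, terms, labels = NULL,
                            penalized = NULL) {
  terms <- as.matrix(terms)
  n <- length(time)
  if (length(event) != n || nrow(terms) != n)
    stopf("time, event and terms must agree on the number of subjects")
  if (anyNA(time) || anyNA(event) || anyNA(terms))
    stopf("missing values are not allowed in a survival design")
  if (any(time < 0)) stopf("follow-up times must be nonnegative")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stopf("event must be binary 0/1")
  if (sum(event) < 1L) stopf("at least one event is required")
  labels <- labels %||% colnames(terms) %||% paste0("x", seq_len(ncol(terms)))
  if (anyDuplicated(labels)) stopf("term labels must be unique")
  colnames(terms) <- labels
  penalized <- penalized %||% rep(TRUE, ncol(terms))
  if (length(penalized) != ncol(terms))
    stopf("penalized mask must have one entry per term")
  structure(
    list(time = as.numeric(time), event = event, terms = terms,
         labels = labels, penalized = as.logical(penalized)),
    class = "survival_design"
  )
}

# Precompute the sorted representation reused across Newton iterations.
#' @noRd
cox_prepare <- function(design) {
  ord <- order(design$time)
  list(ts = design$time[ord], es = design$event[ord],
       xs = design$terms[ord, , drop = FALSE],
       p = ncol(design$terms), n = nrow(design$terms))
}

# Efron log partial likelihood, score and observed information at beta;
# a single compiled backward scan over the sorted subjects maintains
# the risk-set sums.
#' @noRd
cox_deriv <- function(beta, prep, hessian = TRUE) {
  cox_deriv_cpp(prep$ts, prep$es, prep$xs, beta, hessian)
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the Efron partial likelihood by damped Newton iteration.
#' Monotone (separating) likelihoods are detected by coefficient
#' blow-up and flagged through `converged = FALSE` rather than silently
#' returned.
#'
#' @param design a [survival_design()].
#' @param max_iter maximum Newton iterations, default 30.
#' @param tol convergence tolerance on the relative log-likelihood
#'   change, default 1e-12.
#' @return Object of class `cox_result`: `table` (one row per term:
#'   `term`, `loghr`, `se`, `z`, `p`, `hr`, `ci_low`, `ci_high`, with
#'   Wald 95% intervals `exp(loghr -/+ 1.95996 se)`), `loglik`,
#'   `iterations`, `converged`, `n`, `n_events`.
#' @examples
#' d <- survival_design(time = c(2, 4, 3, 5, 1, 6),
#'                      event = c(1, 1, 0, 1, 1, 0),
#'                      terms = cbind(x = c(1, 0, 1, 0, 1, 0)))
#' fit_cox(d)$table
#' @export
fit_cox <- function(design, max_iter = 30, tol = 1e-12) {
  stopifnot(inherits(design, "survival_design"))
  sds <- apply(design$terms, 2L, stats::sd)
  if (any(sds == 0))
    stopf("zero-variance term(s): %s",
          paste(design$labels[sds == 0], collapse = ", "))
  prep <- cox_prepare(design)
  p <- prep$p
  beta <- numeric(p)
  dv <- cox_deriv(beta, prep)
  H_cur <- dv$info
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # the information matrix changes little once beta is in the basin:
    # refresh it on early iterations only, then keep Newton steps with
    # the frozen matrix and cheap gradient-only evaluations
    refresh <- iter <= 2L
    step <- tryCatch(solve(H_cur, dv$grad),
                     error = function(e) solve(H_cur + diag(1e-8, p), dv$grad))
    s <- 1
    repeat {
      cand <- beta + s * step
      dv_new <- cox_deriv(cand, prep, hessian = refresh)
      if (is.finite(dv_new$loglik) && dv_new$loglik >= dv$loglik - 1e-12) break
      s <- s / 2
      if (s < 1e-10) break
    }
    moved <- abs(dv_new$loglik - dv$loglik)
    beta <- beta + s * step
    dv <- dv_new
    if (refresh) H_cur <- dv$info
    if (moved <= tol * (abs(dv$loglik) + 1)) { converged <- TRUE; break }
  }
  if (max(abs(beta)) > 20) converged <- FALSE  # monotone likelihood / separation
  H_final <- cox_deriv(beta, prep)$info  # observed information at the optimum
  se <- sqrt(diag(solve(H_final)))
  z <- beta / se
  zq <- stats::qnorm(0.975)
  tab <- data.frame(
    term = design$labels, loghr = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)), hr = exp(beta),
    ci_low = exp(beta - zq * se), ci_high = exp(beta + zq * se),
    row.names = NULL
  )
  structure(
    list(table = tab, loglik = dv$loglik, iterations = iter,
         converged = converged, n = prep$n, n_events = sum(prep$es)),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, digits = 4, ...) {
  cat(sprintf("Cox model: %d subjects, %d events; log partial likelihood %.4f%s\n",
              x$n, x$n_events, x$loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(format(x$table, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a Cox result table as TSV
#'
#' @param x a `cox_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cox_result <- function(x, path) {
  write_tsv_table(x$table, path)
}
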