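# Synthetic cohort generator.
#
# Downstream stages (standardization, sparse PCA, Cox regression, decile
# analysis) are exercised on generated cohorts that reproduce the salient
# structure of a large population study of environmental exposures and
# all-cause mortality: block-correlated Gaussian exposures (a
# near-collinear noise triplet, particulate and gaseous pollution blocks,
# green-space blocks, traffic variables), standard demographic
# covariates, and proportional-hazards event times with administrative
# censoring at a single end-of-follow-up horizon.

#' Define a block of correlated exposures
#'
#' An exposure block groups variables that share a common within-block
#' pairwise correlation, e.g. the day/evening/night noise triplet or the
#' particulate-matter measurements. Marginals are Gaussian in raw units;
#' the analysis pipeline only ever consumes standardized values.
#'
#' @param name block label, used to address the block in cross-block
#'   correlation maps and latent block effects.
#' @param vars character vector of variable (column) names.
#' @param means numeric vector of raw-unit means, one per variable.
#' @param sds numeric vector of strictly positive raw-unit SDs.
#' @param cor common within-block pairwise correlation, in `[0, 1)`.
#' @return An object of class `exposure_block`.
#' @examples
#' exposure_block("noise", c("day", "evening", "night"),
#'                means = c(55.37, 51.62, 46.55), sds = rep(4.24, 3),
#'                cor = 0.98)
#' @export
exposure_block <- function(name, vars, means, sds, cor = 0) {
  stopifnot(is.character(name), length(name) == 1L, is.character(vars))
  p <- length(vars)
  if (length(means) != p || length(sds) != p)
    stopf("block '%s': means/sds must have one entry per variable", name)
  if (any(!is.finite(sds)) || any(sds <= 0))
    stopf("block '%s': sds must be strictly positive", name)
  if (!is.finite(cor) || cor < 0 || cor >= 1)
    stopf("block '%s': within-block correlation must be in [0, 1)", name)
  structure(
    list(name = name, vars = vars, means = as.numeric(means),
         sds = as.numeric(sds), cor = cor),
    class = "exposure_block"
  )
}

# Assemble the full exposure correlation matrix from block specs and a
# cross-block map ("blockA:blockB" -> r). Constant within and across
# blocks; validated for symmetry/PSD by the caller.
#' @noRd
build_block_correlation <- function(blocks, cross_cor) {
  vars <- unlist(lapply(blocks, `[[`, "vars"))
  if (anyDuplicated(vars)) stopf("duplicate exposure names across blocks")
  p <- length(vars)
  block_of <- rep(vapply(blocks, `[[`, "", "name"),
                  vapply(blocks, function(b) length(b$vars), 0L))
  R <- diag(p)
  dimnames(R) <- list(vars, vars)
  within <- stats::setNames(vapply(blocks, `[[`, 0, "cor"),
                            vapply(blocks, `[[`, "", "name"))
  cross_key <- function(a, b) paste(sort(c(a, b)), collapse = ":")
  cross <- list()
  for (key in names(cross_cor)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !all(parts %in% names(within)))
      stopf("cross-block correlation key '%s' does not name two known blocks", key)
    r <- cross_cor[[key]]
    if (!is.finite(r) || abs(r) >= 1)
      stopf("cross-block correlation '%s' must be in (-1, 1)", key)
    cross[[cross_key(parts[1], parts[2])]] <- r
  }
  for (i in seq_len(p - 1L)) {
    for (j in (i + 1L):p) {
      bi <- block_of[i]; bj <- block_of[j]
      r <- if (bi == bj) within[[bi]] else cross[[cross_key(bi, bj)]] %||% 0
      R[i, j] <- R[j, i] <- r
    }
  }
  list(R = R, block_of = block_of, cross = cross)
}

# PSD check with a diagnostic that names the cross-block pair whose
# removal most repairs the spectrum.
#' @noRd
check_psd <- function(R, blocks, cross) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-8) return(invisible(TRUE))
  worst <- NULL; best_gain <- -Inf
  vars_of <- stats::setNames(lapply(blocks, `[[`, "vars"),
                             vapply(blocks, `[[`, "", "name"))
  for (key in names(cross)) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    R2 <- R
    R2[vars_of[[parts[1]]], vars_of[[parts[2]]]] <- 0
    R2[vars_of[[parts[2]]], vars_of[[parts[1]]]] <- 0
    gain <- min(eigen(R2, symmetric = TRUE, only.values = TRUE)$values)
    if (gain > best_gain) { best_gain <- gain; worst <- key }
  }
  if (is.null(worst))
    stopf("exposure correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
          min(ev))
  stopf(paste0("exposure correlation matrix is not positive semi-definite ",
               "(min eigenvalue %.3g); offending block pair: %s"),
        min(ev), worst)
}

#' Default covariate definitions
#'
#' Age, sex and area deprivation index with the moments of a UK
#' middle-aged population cohort: age Gaussian (56.9, 8.0) years, sex
#' Bernoulli with 45.5% male, deprivation index Gaussian (-1.42, 3.01).
#'
#' @return Named list of covariate definitions.
#' @export
default_covariates <- function() {
  list(
    age         = list(dist = "gaussian", mean = 56.88, sd = 8.02),
    sex         = list(dist = "bernoulli", p = 0.455),
    deprivation = list(dist = "gaussian", mean = -1.42, sd = 3.01)
  )
}

#' Specify a synthetic cohort
#'
#' Bundles exposure blocks, cross-block correlations, covariate
#' definitions, true log-hazard coefficients, the baseline hazard and the
#' administrative censoring horizon into a reproducible generator spec.
#'
#' True effects are expressed on the standardized scale: `coefficients`
#' gives log hazard ratios per SD of the named column (per unit for
#' Bernoulli covariates); `block_effects` gives log hazard ratios per
#' unit of the unit-norm equal-weight combination of a named block's
#' standardized members, i.e. component-level truth for recovery tests.
#'
#' @param n number of subjects.
#' @param blocks list of [exposure_block()] objects.
#' @param cross_cor named list mapping `"blockA:blockB"` to a constant
#'   cross-block correlation; unnamed pairs default to 0.
#' @param covariates named list of covariate definitions
#'   (`list(dist = "gaussian", mean=, sd=)` or
#'   `list(dist = "bernoulli", p=)`).
#' @param coefficients named numeric vector of per-column true log hazard
#'   ratios (standardized scale); default all zero.
#' @param block_effects named numeric vector of per-block component-level
#'   log hazard ratios.
#' @param baseline baseline hazard: `list(family = "exponential", rate=)`
#'   or `list(family = "weibull", rate=, shape=)`; `rate` in events per
#'   person-year.
#' @param censor_time administrative censoring horizon in years.
#' @param seed integer seed; all generation randomness flows from it
#'   through named substreams.
#' @return An object of class `cohort_spec`.
#' @seealso [default_cohort_spec()] for the calibrated 20-exposure spec.
#' @export
cohort_spec <- function(n, blocks, cross_cor = list(),
                        covariates = default_covariates(),
                        coefficients = NULL, block_effects = NULL,
                        baseline = list(family = "exponential", rate = 0.004902),
                        censor_time = 8.22, seed = 1L) {
  stopifnot(is.numeric(n), n >= 1)
  if (inherits(blocks, "exposure_block")) blocks <- list(blocks)
  if (!length(blocks) || !all(vapply(blocks, inherits, TRUE, "exposure_block")))
    stopf("blocks must be a list of exposure_block objects")
  if (!is.finite(censor_time) || censor_time <= 0)
    stopf("censor_time must be a positive number of years")
  baseline$family <- match.arg(baseline$family, c("exponential", "weibull"))
  if (!is.finite(baseline$rate) || baseline$rate <= 0)
    stopf("baseline rate must be positive")
  if (baseline$family == "weibull" &&
      (is.null(baseline$shape) || baseline$shape <= 0))
    stopf("weibull baseline requires a positive shape")
  corr <- build_block_correlation(blocks, cross_cor)
  check_psd(corr$R, blocks, corr$cross)
  all_cols <- c(colnames(corr$R), names(covariates))
  if (!is.null(coefficients)) {
    if (is.null(names(coefficients)) ||
        !all(names(coefficients) %in% all_cols))
      stopf("coefficient names must be a subset of generated column names")
  }
  if (!is.null(block_effects)) {
    bn <- vapply(blocks, `[[`, "", "name")
    if (is.null(names(block_effects)) || !all(names(block_effects) %in% bn))
      stopf("block_effects names must be a subset of block names")
  }
  structure(
    list(n = as.integer(n), blocks = blocks, cross_cor = cross_cor,
         correlation = corr$R, covariates = covariates,
         coefficients = coefficients, block_effects = block_effects,
         baseline = baseline, censor_time = censor_time,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort spec\n")
  cat(sprintf("  subjects: %d; exposures: %d in %d blocks; covariates: %d\n",
              x$n, ncol(x$correlation), length(x$blocks),
              length(x$covariates)))
  cat(sprintf("  baseline: %s (rate %.4g/yr); censoring at %.2f yr; seed %d\n",
              x$baseline$family, x$baseline$rate, x$censor_time, x$seed))
  invisible(x)
}

#' Draw the exposure columns of a cohort
#'
#' Multivariate Gaussian draw with the spec's means, SDs and block
#' correlation structure. Deterministic given `seed`.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to the spec's exposure substream.
#' @return Data frame of raw-unit exposure columns, `spec$n` rows.
#' @export
generate_exposures <- function(spec, seed = seed_for(spec$seed, "exposures")) {
  stopifnot(inherits(spec, "cohort_spec"))
  R <- spec$correlation
  means <- unlist(lapply(spec$blocks, `[[`, "means"))
  sds <- unlist(lapply(spec$blocks, `[[`, "sds"))
  Z <- with_seed(seed, MASS::mvrnorm(spec$n, mu = rep(0, ncol(R)), Sigma = R))
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1L)
  X <- sweep(sweep(Z, 2L, sds, `*`), 2L, means, `+`)
  colnames(X) <- colnames(R)
  as.data.frame(X)
}

#' Draw survival outcomes under proportional hazards
#'
#' Event times follow `h(t) = h0(t) exp(linear_predictor)` with an
#' exponential or Weibull baseline; times beyond the administrative
#' horizon are censored there with `event = 0`.
#'
#' @param linear_predictor numeric vector, one log relative hazard per
#'   subject.
#' @param baseline baseline hazard description as in [cohort_spec()].
#' @param censor_time administrative censoring horizon in years.
#' @param seed integer seed.
#' @return Data frame with columns `time` (years) and `event` (0/1).
#' @export
sample_survival <- function(linear_predictor, baseline, censor_time, seed) {
  if (any(!is.finite(linear_predictor)))
    stopf("linear predictor contains non-finite values")
  if (!is.finite(censor_time) || censor_time <= 0)
    stopf("censor_time must be positive")
  rate <- baseline$rate
  if (!is.finite(rate) || rate <= 0) stopf("baseline rate must be positive")
  family <- match.arg(baseline$family, c("exponential", "weibull"))
  n <- length(linear_predictor)
  u <- with_seed(seed, stats::runif(n))
  cumhaz <- -log(u) / (rate * exp(linear_predictor))
  t_event <- if (family == "exponential") cumhaz else cumhaz^(1 / baseline$shape)
  event <- as.integer(t_event <= censor_time)
  data.frame(time = pmin(t_event, censor_time), event = event)
}

# True linear predictor on the spec's standardized scale.
#' @noRd
true_linear_predictor <- function(spec, exposures, covars) {
  lp <- numeric(spec$n)
  means <- unlist(lapply(spec$blocks, `[[`, "means"))
  sds <- unlist(lapply(spec$blocks, `[[`, "sds"))
  names(means) <- names(sds) <- colnames(spec$correlation)
  std_col <- function(col) {
    if (col %in% names(means))
      return((exposures[[col]] - means[[col]]) / sds[[col]])
    def <- spec$covariates[[col]]
    if (identical(def$dist, "gaussian"))
      return((covars[[col]] - def$mean) / def$sd)
    covars[[col]]  # bernoulli: per-unit coding
  }
  for (col in names(spec$coefficients))
    lp <- lp + spec$coefficients[[col]] * std_col(col)
  for (bn in names(spec$block_effects)) {
    blk <- spec$blocks[[match(bn, vapply(spec$blocks, `[[`, "", "name"))]]
    w <- 1 / sqrt(length(blk$vars))  # unit-norm equal weights
    z <- numeric(spec$n)
    for (col in blk$vars) z <- z + w * std_col(col)
    lp <- lp + spec$block_effects[[bn]] * z
  }
  lp
}

#' Generate a full synthetic cohort
#'
#' Assembles exposures, covariates and survival outcome into a
#' subject-level table. Bit-for-bit reproducible given the spec (which
#' includes the seed).
#'
#' @param spec a [cohort_spec()].
#' @return Data frame with columns `id`, one column per exposure (raw
#'   units) and covariate, `time` (years of follow-up) and `event` (0/1).
#'   The spec is attached as attribute `"spec"`.
#' @examples
#' spec <- cohort_spec(
#'   n = 100,
#'   blocks = exposure_block("noise", c("day", "evening", "night"),
#'                           c(55.37, 51.62, 46.55), rep(4.24, 3), 0.98),
#'   seed = 7
#' )
#' head(generate_cohort(spec))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  exposures <- generate_exposures(spec)
  covars <- with_seed(seed_for(spec$seed, "covariates"), {
    out <- lapply(names(spec$covariates), function(nm) {
      def <- spec$covariates[[nm]]
      switch(def$dist,
        gaussian  = stats::rnorm(spec$n, def$mean, def$sd),
        bernoulli = stats::rbinom(spec$n, 1L, def$p),
        stopf("unknown covariate distribution '%s' for '%s'", def$dist, nm)
      )
    })
    names(out) <- names(spec$covariates)
    as.data.frame(out)
  })
  lp <- true_linear_predictor(spec, exposures, covars)
  surv <- sample_survival(lp, spec$baseline, spec$censor_time,
                          seed = seed_for(spec$seed, "survival"))
  out <- cbind(data.frame(id = seq_len(spec$n)), exposures, covars, surv)
  attr(out, "spec") <- spec
  out
}

#' Calibrated 20-exposure cohort spec
#'
#' The default study-like generator: 20 environmental exposures in seven
#' blocks (noise triplet at within-block r = 0.98, gaseous and
#' particulate pollution, green space, domestic garden, water/coast,
#' traffic), with raw-unit moments matching the descriptive summary of a
#' 379,690-subject UK cohort, standard covariates, and an exponential
#' baseline (rate 0.004902/yr) censored administratively at 8.22 years,
#' which yields a 3.95% event fraction and a mean follow-up of 8.06
#' years in closed form.
#'
#' @param n number of subjects.
#' @param seed integer seed.
#' @param coefficients,block_effects optional true effects, passed to
#'   [cohort_spec()]; the default is the global null.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n = 20000, seed = 1L,
                                coefficients = NULL, block_effects = NULL) {
  blocks <- list(
    exposure_block("noise", c("noise_day", "noise_evening", "noise_night"),
                   c(55.37, 51.62, 46.55), c(4.24, 4.24, 4.24), 0.98),
    exposure_block("gas", c("no2", "nox"),
                   c(26.69, 43.96), c(7.54, 15.36), 0.92),
    exposure_block("pm", c("pm10", "pm_coarse", "pm2_5"),
                   c(16.23, 6.42, 9.98), c(1.87, 0.89, 1.04), 0.88),
    exposure_block("green",
                   c("greenspace_300", "greenspace_1000",
                     "natural_300", "natural_1000"),
                   c(35.45, 45.32, 26.72, 41.33),
                   c(23.14, 21.51, 25.28, 25.63), 0.88),
    exposure_block("garden", c("garden_300", "garden_1000"),
                   c(31.39, 24.36), c(14.68, 11.25), 0.92),
    exposure_block("water", c("water_300", "water_1000", "coastal_dist"),
                   c(0.88, 1.25, 45.60), c(2.89, 2.46, 26.80), 0.80),
    exposure_block("traffic",
                   c("road_length_100m", "traffic_major", "traffic_nearest"),
                   c(27.70, 23474.95, 1496.63),
                   c(76.51, 21299.52, 4958.49), 0.80)
  )
  cross <- list(
    "noise:gas" = 0.35, "noise:pm" = 0.30, "noise:traffic" = 0.40,
    "gas:pm" = 0.60, "gas:traffic" = 0.30, "pm:traffic" = 0.25,
    "green:gas" = -0.35, "green:pm" = -0.30, "green:noise" = -0.25,
    "green:garden" = 0.25, "green:traffic" = -0.20,
    "garden:noise" = -0.15, "garden:gas" = -0.20, "garden:pm" = -0.15,
    "green:water" = 0.15
  )
  cohort_spec(n = n, blocks = blocks, cross_cor = cross,
              coefficients = coefficients, block_effects = block_effects,
              seed = seed)
}

#' Write a cohort table as delimited text
#'
#' Comma-separated, header row, UTF-8, `.` decimal.
#'
#' @param table cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
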