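# Generator calibration: moments, correlation, outcome rates,
# determinism.

noise_triplet_spec <- function(n, r = 0.98, seed = 5,
                               block_effects = NULL) {
  cohort_spec(
    n = n,
    blocks = exposure_block("noise", c("day", "evening", "night"),
                            means = c(55.37, 51.62, 46.55),
                            sds = rep(4.24, 3), cor = r),
    block_effects = block_effects, seed = seed
  )
}

test_that("generated exposures match target moments within 3 standard errors", {
  n <- 50000
  ex <- generate_exposures(noise_triplet_spec(n))
  mu <- c(55.37, 51.62, 46.55)
  for (j in 1:3) {
    se_mean <- 4.24 / sqrt(n)
    expect_lt(abs(mean(ex[[j]]) - mu[j]), 3 * se_mean)
    se_sd <- 4.24 / sqrt(2 * n)
    expect_lt(abs(sd(ex[[j]]) - 4.24), 3 * se_sd)
  }
})

test_that("within-block correlations calibrate at both the null and r = 0.98", {
  n <- 50000
  ex0 <- generate_exposures(noise_triplet_spec(n, r = 0, seed = 9))
  c0 <- cor(ex0)
  expect_true(all(abs(c0[upper.tri(c0)]) < 0.02))
  ex98 <- generate_exposures(noise_triplet_spec(n, r = 0.98, seed = 9))
  c98 <- cor(ex98)
  expect_true(all(abs(c98[upper.tri(c98)] - 0.98) < 0.01))
})

test_that("a non-PSD correlation request fails at construction naming a block pair", {
  blocks <- list(
    exposure_block("a", c("a1", "a2"), c(0, 0), c(1, 1), 0.1),
    exposure_block("b", c("b1", "b2"), c(0, 0), c(1, 1), 0.1),
    exposure_block("c", c("c1", "c2"), c(0, 0), c(1, 1), 0.1)
  )
  cross <- list("a:b" = 0.95, "b:c" = 0.95, "a:c" = -0.95)
  expect_error(cohort_spec(100, blocks, cross),
               "positive semi-definite.*block pair",)
})

test_that("survival sampling reproduces the closed-form event fraction", {
  n <- 100000
  s <- sample_survival(rep(0, n), list(family = "exponential", rate = 0.005),
                       censor_time = 8, seed = 1)
  p_true <- 1 - exp(-0.005 * 8)  # 3.92%
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(mean(s$event) - p_true), 3 * se)
  expect_true(all(s$time <= 8))
  expect_true(all(s$event %in% 0:1))
})

test_that("a log(2) shift in the linear predictor halves exponential event times", {
  n <- 20000
  base <- sample_survival(rep(0, n), list(family = "exponential", rate = 1e-4),
                          censor_time = 1e7, seed = 33)
  shifted <- sample_survival(rep(log(2), n),
                             list(family = "exponential", rate = 1e-4),
                             censor_time = 1e7, seed = 33)
  # same seed, same uniforms: the scaling is exact subject-by-subject
  expect_equal(shifted$time, base$time / 2, tolerance = 1e-12)
  expect_equal(median(shifted$time), median(base$time) / 2, tolerance = 1e-12)
})

test_that("generation is bit-for-bit deterministic given (spec, seed)", {
  spec <- default_cohort_spec(n = 500, seed = 17)
  t1 <- generate_cohort(spec)
  t2 <- generate_cohort(spec)
  attr(t1, "spec") <- attr(t2, "spec") <- NULL
  expect_identical(t1, t2)
  t3 <- generate_cohort(default_cohort_spec(n = 500, seed = 18))
  expect_false(identical(t1$noise_day, t3$noise_day))
})

test_that("the calibrated default spec hits the study's outcome structure", {
  tab <- generate_cohort(default_cohort_spec(n = 100000, seed = 2))
  expect_identical(ncol(tab), 1L + 20L + 3L + 2L)  # id, exposures, covars, outcome
  ev <- mean(tab$event)
  expect_gt(ev, 0.034); expect_lt(ev, 0.045)      # ~3.95% events
  expect_gt(mean(tab$time), 7.9); expect_lt(mean(tab$time), 8.2)
  expect_false(anyNA(tab))
})

test_that("under the global null, single-column Cox fits stay within 3 SE", {
  hits <- 0L
  reps <- 100
  for (r in seq_len(reps)) {
    spec <- noise_triplet_spec(2000, seed = 1000 + r)
    tab <- generate_cohort(spec)
    X <- standardize(tab[, c("day", "evening", "night")])
    f <- fit_cox(survival_design(tab$time, tab$event,
                                 X$values[, 1, drop = FALSE]))
    if (abs(f$table$loghr[1]) < 3 * f$table$se[1]) hits <- hits + 1L
  }
  expect_gte(hits, 0.90 * reps)
})

test_that("block effects load the hazard on the standardized block mean", {
  spec <- noise_triplet_spec(50000, seed = 4,
                             block_effects = c(noise = 0.5))
  tab <- generate_cohort(spec)
  z <- (scale(tab$day, 55.37, 4.24) + scale(tab$evening, 51.62, 4.24) +
          scale(tab$night, 46.55, 4.24)) / sqrt(3)
  f <- fit_cox(survival_design(tab$time, tab$event, cbind(z = drop(z))))
  expect_lt(abs(f$table$loghr[1] - 0.5), 3 * f$table$se[1])
})

test_that("cohorts round-trip through delimited text", {
  tab <- generate_cohort(default_cohort_spec(n = 50, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  back <- utils::read.csv(path)
  expect_equal(back$noise_day, tab$noise_day, tolerance = 1e-6)
  expect_identical(nrow(back), 50L)
})
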