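# Attribution, unit conversion, HR rescaling, composites, deciles.

fake_cox_for <- function(labels, p_values, loghr = 0.02, se = 0.005) {
  zq <- qnorm(0.975)
  tab <- data.frame(
    term = labels, loghr = loghr, se = se, z = loghr / se, p = p_values,
    hr = exp(loghr), ci_low = exp(loghr - zq * se),
    ci_high = exp(loghr + zq * se)
  )
  structure(list(table = tab, loglik = 0, iterations = 1, converged = TRUE,
                 n = 0, n_events = 0), class = "cox_result")
}

test_that("significant sparse components are traced to exactly their support", {
  B <- matrix(0, 5, 2,
              dimnames = list(c("day", "evening", "night", "no2", "pm"),
                              c("SPC1", "SPC2")))
  B[1:3, 1] <- 1 / sqrt(3)
  B[4:5, 2] <- c(0.7, 0.4)
  fit <- list(B = B)
  cox <- fake_cox_for(c("SPC1", "SPC2", "age"), p_values = c(0.01, 0.4, 0.9))
  rep <- trace_attribution(fit, cox, sds = c(day = 4.24, evening = 4.24,
                                             night = 4.24, no2 = 7.5, pm = 1))
  expect_setequal(rep$variable, c("day", "evening", "night"))
  expect_true(all(rep$component == "SPC1"))
  expect_true(all(abs(rep$weight) > 1e-8))
  # raw-unit change of each constituent for a one-unit component change
  expect_equal(rep$raw_unit_change, rep(4.24 / sqrt(3), 3), tolerance = 1e-10)
})

test_that("nothing significant yields an empty report; dense components are refused", {
  B <- matrix(1 / sqrt(5), 5, 1, dimnames = list(letters[1:5], "PC1"))
  cox_ns <- fake_cox_for("PC1", p_values = 0.5)
  expect_identical(nrow(trace_attribution(list(B = B), cox_ns)), 0L)
  cox_sig <- fake_cox_for("PC1", p_values = 0.001)
  expect_error(trace_attribution(list(B = B), cox_sig, max_support = 4),
               "cannot be attributed")
  expect_error(trace_attribution(list(B = B), fake_cox_for("PC9", 0.5)),
               "lacks component term")
})

test_that("one component unit converts to raw units by the loading geometry", {
  # single variable: raw change is just its SD
  one <- pc_unit_in_raw_units(c(1), sds = c(3.7))
  expect_equal(unname(one$per_variable), 3.7)
  expect_equal(one$mean, 3.7)
  # equal weights 1/sqrt(3) on three same-unit variables with SD 4.243
  eq <- pc_unit_in_raw_units(rep(1 / sqrt(3), 3), sds = rep(4.243, 3))
  expect_equal(unname(eq$per_variable), rep(4.243 / sqrt(3), 3),
               tolerance = 1e-12)
  expect_equal(eq$mean, 2.450, tolerance = 1e-3)
  # mixed units: aggregate suppressed, per-variable kept
  mx <- pc_unit_in_raw_units(c(0.7, 0.7), sds = c(4, 10),
                             units = c("dB", "ug/m3"))
  expect_true(is.na(mx$mean))
  expect_length(mx$per_variable, 2)
})

test_that("component-unit statements are invariant to rescaling the weights", {
  w <- c(0.5, 0.4, 0, 0.3)
  sds <- c(4, 5, 6, 7)
  base <- pc_unit_in_raw_units(w, sds)
  for (c0 in c(2, -3, 0.1)) {
    scaled <- pc_unit_in_raw_units(c0 * w, sds)
    expect_equal(scaled$per_variable, base$per_variable / c0, tolerance = 1e-12)
  }
})

test_that("hazard-ratio rescaling is exact, invertible and matches the worked example", {
  r <- rescale_hr(1.017, c(1.004, 1.030), per = 2.47, target = 10)
  expect_equal(round(r$hr, 2), 1.07)
  expect_equal(round(r$ci, 2), c(1.02, 1.13))
  # identity and round trip
  expect_equal(rescale_hr(1.3, c(1.1, 1.5), 5, 5)$hr, 1.3)
  rt <- rescale_hr(r$hr, r$ci, per = 10, target = 2.47)
  expect_equal(rt$hr, 1.017, tolerance = 1e-12)
  expect_equal(rt$ci, c(1.004, 1.030), tolerance = 1e-12)
  expect_error(rescale_hr(-1, c(1, 2), 1, 2), "positive")
})

test_that("composites are row-wise means in raw units", {
  expect_equal(make_composite(data.frame(a = 55, b = 51, c = 46)),
               (55 + 51 + 46) / 3)
  expect_equal(make_composite(cbind(c(55, 51, 46))), c(55, 51, 46))
  expect_error(make_composite(list(1:3, 1:4)), "length")
  # generated at the study's noise means, the composite centres at 51.18
  spec <- cohort_spec(
    n = 50000,
    blocks = exposure_block("noise", c("d", "e", "n"),
                            c(55.37, 51.62, 46.55), rep(4.24, 3), 0.98),
    seed = 61
  )
  comp <- make_composite(generate_exposures(spec))
  se <- sd(comp) / sqrt(length(comp))
  expect_lt(abs(mean(comp) - 51.18), 3 * se)
})

test_that("decile assignment uses half-open intervals and partitions the sample", {
  dr <- decile_exposure_response(1:20, other_exposures = NULL,
                                 covariates = NULL,
                                 time = rep(c(1, 2, 3, 4), 5),
                                 event = rep(c(1, 0), 10))
  expect_identical(dr$counts, rep(2L, 10))
  expect_identical(sum(dr$counts), 20L)
  expect_identical(nrow(dr$boundaries), 10L)
  expect_identical(nrow(dr$table), 9L)
  # lowest decile holds exactly the two smallest values: (a, b] intervals
  expect_equal(dr$boundaries$upper[1], quantile(1:20, 0.1, names = FALSE))
  expect_true(all(diff(dr$boundaries$upper) >= 0))
  expect_error(decile_exposure_response(rep(1:3, 7)[1:20], NULL, NULL,
                                        time = 1:20, event = rep(1, 20)),
               "distinct")
})

test_that("a known monotone composite effect produces an upward decile trend", {
  spec <- default_cohort_spec(n = 60000, seed = 71,
                              block_effects = c(noise = 0.3))
  tab <- generate_cohort(spec)
  comp <- make_composite(tab[, c("noise_day", "noise_evening", "noise_night")])
  dr <- decile_exposure_response(
    comp, tab[, 5:21], tab[, c("age", "sex", "deprivation")],
    tab$time, tab$event)
  expect_gt(cor(1:9, dr$table$loghr, method = "spearman"), 0)
  expect_gt(dr$table$loghr[9], dr$table$loghr[1])
})
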