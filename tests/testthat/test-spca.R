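# Sparse PCA: reduction to PCA, descent, constraint satisfaction,
# support recovery against exhaustive enumeration, explained variance.

test_that("the unpenalized fit reduces exactly to PCA", {
  for (X in list(two_block_matrix(500, seed = 1),
                 standardize(matrix(rnorm(1500), 300, 5)))) {
    k <- 2
    sf <- fit_spca(X, k, lambda = 0)
    pf <- fit_pca(X, k)
    # principal angles between the two k-dim subspaces
    Bn <- sf$B %*% diag(1 / sqrt(colSums(sf$B^2)), k)
    Qb <- qr.Q(qr(Bn)); Qv <- qr.Q(qr(pf$loadings))
    cosines <- svd(crossprod(Qv, Qb))$d
    expect_true(all(acos(pmin(cosines, 1)) < 1e-6))
    # scores agree up to per-component sign
    for (j in seq_len(k))
      expect_lt(min(max(abs(sf$scores[, j] - pf$scores[, j])),
                    max(abs(sf$scores[, j] + pf$scores[, j]))), 1e-6)
  }
})

test_that("every fit satisfies the orthonormality constraint and descends", {
  X <- two_block_matrix(800, seed = 2)
  for (lam in c(0, 0.01, 0.1, 0.5)) {
    f <- fit_spca(X, 2, lam)
    expect_equal(crossprod(f$A), diag(2), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_true(all(diff(f$objective) <= 1e-10))
  }
})

test_that("penalized supports on two-block data match exhaustive enumeration", {
  X <- two_block_matrix(2000, r = 0.9, seed = 71)
  G <- crossprod(X$values) / (nrow(X$values) - 1)
  lam <- 0.3
  f <- fit_spca(X, 2, lam, alpha = 0.95)
  supp <- spca_support(f)
  expect_true(all(lengths(supp) == 2))
  # the fitted support pattern must attain the best objective among all
  # 36 ways of giving each component a 2-variable support
  pairs <- utils::combn(4, 2, simplify = FALSE)
  patterns <- expand.grid(s1 = seq_along(pairs), s2 = seq_along(pairs))
  objs <- apply(patterns, 1, function(pt)
    spca_pattern_objective(list(pairs[[pt[1]]], pairs[[pt[2]]]), G, lam, 0.95))
  best <- patterns[which.min(objs), ]
  best_pattern <- list(pairs[[best$s1]], pairs[[best$s2]])
  # component order/sign is arbitrary: compare as sets of supports
  expect_setequal(lapply(supp, paste, collapse = ","),
                  lapply(best_pattern, paste, collapse = ","))
  # and the blocks are {a1,a2}, {b1,b2}
  expect_setequal(lapply(supp, paste, collapse = ","), list("1,2", "3,4"))
  # the solver's objective is no worse than the enumerated optimum
  f_obj <- spca_objective_of_B(f$B, G, lam, 0.95)
  expect_lte(f_obj, min(objs) + 1e-6)
})

test_that("support size is monotone non-increasing in the penalty on fixtures", {
  for (X in list(two_block_matrix(800, seed = 3),
                 cohort_std_matrix(1500, seed = 13))) {
    k <- if (ncol(X$values) == 4) 2 else 7
    sizes <- vapply(c(0.001, 0.005, 0.02, 0.08, 0.3), function(lam)
      sum(lengths(spca_support(suppressWarnings(fit_spca(X, k, lam))))), 0)
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("sparsity can only worsen reconstruction error", {
  X <- two_block_matrix(600, seed = 4)
  recon <- function(f) {
    R <- X$values - X$values %*% f$B %*% t(f$A)
    0.5 * sum(R^2)
  }
  f0 <- fit_spca(X, 2, 0)
  for (lam in c(0.05, 0.2, 0.6))
    expect_gte(recon(fit_spca(X, 2, lam)), recon(f0) - 1e-8)
})

test_that("supports are read off the weight matrix with exact-zero tolerance", {
  fake <- list(B = cbind(c(0, 0.7, 0.7, 0), c(0, 0, 0, 0)))
  expect_equal(spca_support(fake), list(c(2L, 3L), integer(0)))
  X <- standardize(matrix(rnorm(900), 300, 3))
  expect_true(all(lengths(spca_support(fit_spca(X, 2, 0))) == 3))
})

test_that("adjusted explained variance reduces to PCA ratios at lambda 0", {
  X <- cohort_std_matrix(1000, seed = 19)
  sf <- fit_spca(X, 5, 0)
  pf <- fit_pca(X, 5)
  expect_equal(explained_variance(sf, X), pf$var_ratios, tolerance = 1e-8)
})

test_that("adjusted explained variance equals naive variances for uncorrelated disjoint supports", {
  set.seed(20)
  A1 <- matrix(rnorm(3000), 1000, 3)
  A2 <- matrix(rnorm(2000), 1000, 2)
  A2 <- qr.resid(qr(cbind(1, A1)), A2)  # exactly uncorrelated blocks
  X <- standardize(cbind(A1, A2))
  B <- matrix(0, 5, 2)
  B[1:3, 1] <- c(0.6, 0.5, 0.4)
  B[4:5, 2] <- c(0.8, 0.3)
  fake <- list(B = B)
  Z <- X$values %*% B
  naive <- apply(Z, 2, var) / sum(apply(X$values, 2, var))
  expect_equal(explained_variance(fake, X), unname(naive), tolerance = 1e-6)
})

test_that("explained-variance fractions are proper and cumulative", {
  X <- cohort_std_matrix(1000, seed = 19)
  f <- suppressWarnings(fit_spca(X, 7, 0.02))
  ev <- f$explained_variance
  expect_true(all(ev >= 0 & ev <= 1))
  expect_true(all(diff(cumsum(ev)) >= -1e-12))
  expect_lte(sum(ev), 1 + 1e-8)
})
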