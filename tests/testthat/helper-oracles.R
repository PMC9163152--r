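# Independent oracles and shared fixtures. The Cox oracle below is a
# deliberately naive re-implementation of the Efron partial likelihood
# (explicit risk sets, no shared code with the package) used for
# brute-force verification on small fixtures.

naive_cox_loglik <- function(beta, time, event, X) {
  X <- as.matrix(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    for (l in seq_len(d) - 1)
      ll <- ll - log(sum(w[R]) - (l / d) * sum(w[D]))
  }
  ll
}

# Brute-force maximizer of the naive partial likelihood.
brute_force_cox <- function(time, event, X, start = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  f <- function(b) -naive_cox_loglik(b, time, event, X)
  if (p == 1L) {
    opt <- stats::optimize(function(b) f(b), interval = c(-8, 8), tol = 1e-10)
    return(opt$minimum)
  }
  opt <- stats::optim(start %||% numeric(p), f, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 2000))
  opt$par
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Central-difference gradient of the naive likelihood.
naive_cox_score <- function(beta, time, event, X, h = 1e-6) {
  p <- length(beta)
  vapply(seq_len(p), function(j) {
    e <- numeric(p); e[j] <- h
    (naive_cox_loglik(beta + e, time, event, X) -
       naive_cox_loglik(beta - e, time, event, X)) / (2 * h)
  }, 0)
}

# Small well-posed survival fixtures (<= 8 subjects, finite MLE).
small_cox_fixtures <- function() {
  list(
    interior_3 = list(  # single covariate, interior maximum
      time = c(1, 2, 3), event = c(1, 1, 1),
      X = cbind(x = c(0, 1, 0))
    ),
    censored_6 = list(
      time = c(2, 4, 4.5, 5, 1.5, 6), event = c(1, 0, 1, 1, 1, 0),
      X = cbind(x = c(0.5, -1, 0.2, 1.4, -0.3, 0.8))
    ),
    tied_6 = list(  # one tied event pair exercises the Efron terms
      time = c(1, 2, 2, 3, 4, 5), event = c(1, 1, 1, 0, 1, 0),
      X = cbind(x = c(0.2, 1, -0.5, 0.3, -1.2, 0.7))
    ),
    two_term_8 = list(
      time = c(3, 1, 4, 2, 6, 5, 7, 8),
      event = c(1, 1, 0, 1, 1, 0, 1, 0),
      X = cbind(x1 = c(0.1, -0.4, 1.2, 0.5, -0.9, 0.3, 0.8, -0.2),
                x2 = c(1, 0, 1, 0, 1, 0, 0, 1))
    )
  )
}

# Standardized matrix with two within-correlated, cross-uncorrelated
# variable pairs; the canonical sparse-recovery fixture.
two_block_matrix <- function(n = 2000, r = 0.9, seed = 71) {
  set.seed(seed)
  R <- diag(4)
  R[1, 2] <- R[2, 1] <- r
  R[3, 4] <- R[4, 3] <- r
  X <- MASS::mvrnorm(n, rep(0, 4), R)
  colnames(X) <- c("a1", "a2", "b1", "b2")
  standardize(X)
}

# Small study-like standardized exposure matrix.
cohort_std_matrix <- function(n = 2000, seed = 11) {
  tab <- generate_cohort(default_cohort_spec(n = n, seed = seed))
  winsorize(standardize(tab[, 2:21]))
}

# Sparse-PCA objective evaluated independently of the solver: the A
# minimizing at fixed B has the closed Procrustes form, so the
# objective is a function of B alone.
spca_objective_of_B <- function(B, G, lambda, alpha) {
  s <- svd(G %*% B)
  A <- s$u %*% t(s$v)
  0.5 * (sum(diag(G)) - 2 * sum(A * (G %*% B)) + sum(B * (G %*% B))) +
    lambda * (alpha * sum(abs(B)) + (1 - alpha) / 2 * sum(B^2))
}

# Best achievable objective when each component is restricted to a
# fixed support pattern, by general-purpose optimization over the
# nonzero entries.
spca_pattern_objective <- function(pattern, G, lambda, alpha) {
  p <- nrow(G); k <- length(pattern)
  idx <- unlist(lapply(seq_len(k), function(j) (j - 1) * p + pattern[[j]]))
  f <- function(par) {
    B <- matrix(0, p, k)
    B[idx] <- par
    spca_objective_of_B(B, G, lambda, alpha)
  }
  best <- Inf
  for (s0 in c(0.7, -0.7, 0.3)) {
    opt <- stats::optim(rep(s0, length(idx)), f, method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 5000))
    best <- min(best, opt$value)
  }
  best
}
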