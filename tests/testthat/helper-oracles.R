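# Independent oracles used by the test suite. These deliberately avoid the
# package's Cholesky code paths: densities and solves go through solve()
# and determinant() so a defect in the fast path cannot cancel out.

# Multivariate Gaussian log-density via explicit inverse and determinant.
oracle_logdens <- function(x, mu, sigma) {
  p <- length(mu)
  d <- x - mu
  ld <- as.numeric(determinant(sigma, logarithm = TRUE)$modulus)
  -0.5 * (p * log(2 * pi) + ld + drop(t(d) %*% solve(sigma) %*% d))
}

# Brute-force decision score: difference of the two weighted log-densities.
oracle_score <- function(model, x) {
  s1 <- model$sigma[[1L]]
  s2 <- if (length(model$sigma) == 2L) model$sigma[[2L]] else s1
  log(model$pi1) + oracle_logdens(x, model$mu1, s1) -
    log(model$pi2) - oracle_logdens(x, model$mu2, s2)
}

# Textbook LDA/QDA fitted from first principles: class means, class
# frequencies as priors, pooled (divisor n - 2) or per-class (divisor
# n_k - 1) covariance, scores via solve().
oracle_da_scores <- function(X_tr, y_tr, X_te, quadratic = FALSE) {
  lev <- sort(unique(y_tr))
  X1 <- X_tr[y_tr == lev[1L], , drop = FALSE]
  X2 <- X_tr[y_tr == lev[2L], , drop = FALSE]
  mu1 <- colMeans(X1)
  mu2 <- colMeans(X2)
  pi1 <- nrow(X1) / nrow(X_tr)
  pi2 <- 1 - pi1
  C1 <- crossprod(sweep(X1, 2L, mu1))
  C2 <- crossprod(sweep(X2, 2L, mu2))
  if (quadratic) {
    s1 <- C1 / (nrow(X1) - 1)
    s2 <- C2 / (nrow(X2) - 1)
  } else {
    s1 <- s2 <- (C1 + C2) / (nrow(X_tr) - 2)
  }
  apply(X_te, 1L, function(x) {
    log(pi1) + oracle_logdens(x, mu1, s1) -
      log(pi2) - oracle_logdens(x, mu2, s2)
  })
}

# Symmetric-difference edge count by brute-force enumeration of all pairs.
oracle_shd <- function(g1, g2) {
  A1 <- adjacency_matrix(g1)
  A2 <- adjacency_matrix(g2)
  sum(A1[upper.tri(A1)] != A2[upper.tri(A2)])
}

random_graph <- function(p, prob = 0.2) erdos_renyi_graph(p, prob)

# A fitted model with random dimension/graph/hyperparameters, for
# parameterised oracle checks.
random_fitted_model <- function(flavor = c("linear", "quadratic")) {
  flavor <- match.arg(flavor)
  p <- sample(2:20, 1L)
  n <- sample(seq(3 * p, 4 * p), 1L)
  g1 <- random_graph(p)
  graphs <- if (flavor == "linear") g1 else list(g1, random_graph(p))
  X <- matrix(rnorm(n * p), n)
  y <- sample(rep(1:2, c(ceiling(n / 2), floor(n / 2))))
  X[y == 2L, ] <- X[y == 2L, , drop = FALSE] + runif(1, -1, 1)
  spec <- shrinkage_spec(lambda = runif(1, 0.05, 0.95),
                         eps = runif(1, 0.1, 5))
  gcda_fit(X, y, graphs, flavor = flavor, spec = spec)
}
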