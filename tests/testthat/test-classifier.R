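test_that("decision scores match the Gaussian log-density oracle", {
  set.seed(101)
  for (rep in 1:20) {
    flavor <- sample(c("linear", "quadratic"), 1L)
    m <- random_fitted_model(flavor)
    X <- matrix(rnorm(5 * m$p), 5)
    got <- discriminant_score(m, X)
    want <- apply(X, 1L, function(x) oracle_score(m, x))
    expect_lt(max(abs(got - want)), 1e-8)
  }
})

test_that("symmetric two-class geometry gives sign-symmetric scores", {
  # mu1 = (-1, 0), mu2 = (1, 0), identity covariance, equal priors:
  # the midpoint scores zero and the score is antisymmetric about it
  X <- rbind(c(-1, 0), c(-1, 0), c(1, 0), c(1, 0))
  fit <- gcda_fit(X + 0, c(1, 1, 2, 2), empty_graph(2),
                  spec = shrinkage_spec(lambda = 0, eps = 1))
  expect_equal(discriminant_score(fit, c(0, 0)), 0)
  expect_gt(discriminant_score(fit, c(-2, 0)), 0)
  expect_equal(predict(fit, rbind(c(-2, 0), c(2, 0), c(0, 0))),
               c(1, 2, 2))  # tie at zero goes to class 2
})

test_that("quadratic flavor with equal covariances reproduces linear", {
  set.seed(103)
  m <- random_fitted_model("linear")
  q <- m
  q$flavor <- "quadratic"
  q$sigma <- list(m$sigma[[1L]], m$sigma[[1L]])
  q$chol <- list(m$chol[[1L]], m$chol[[1L]])
  q$logdet <- rep(m$logdet, 2L)
  X <- matrix(rnorm(20 * m$p), 20)
  expect_equal(discriminant_score(q, X), discriminant_score(m, X),
               tolerance = 1e-12)
})

test_that("fit recovers priors, means and the target endpoints", {
  set.seed(107)
  p <- 10
  X <- matrix(rnorm(40 * p), 40)
  y <- rep(c("a", "b"), each = 20)
  g <- random_graph(p)
  fit <- gcda_fit(X, y, g, spec = shrinkage_spec(lambda = 0.5, eps = 1))
  expect_equal(c(fit$pi1, fit$pi2), c(0.5, 0.5))
  expect_equal(fit$mu1, colMeans(X[1:20, ]))
  expect_equal(fit$levels, c("a", "b"))
  # lambda = 0: covariance equals the target no matter the data
  f0 <- gcda_fit(X, y, g, spec = shrinkage_spec(lambda = 0, eps = 1))
  f0b <- gcda_fit(X + rnorm(length(X)), y, g,
                  spec = shrinkage_spec(lambda = 0, eps = 1))
  expect_equal(f0$sigma[[1L]], shrinkage_target(g, 1))
  expect_identical(f0$sigma[[1L]], f0b$sigma[[1L]])
  # lambda = 1 with n <= p cannot be factorized
  expect_error(gcda_fit(matrix(rnorm(8 * p), 8), rep(1:2, each = 4), g,
                        spec = shrinkage_spec(lambda = 1, eps = 1)),
               "lambda < 1")
})

test_that("parameter estimates converge to truth at large n", {
  set.seed(109)
  p <- 5
  mu2 <- c(1, 0, -1, 2, 0)
  Sig <- diag(c(1, 2, 0.5, 1, 1.5))
  n <- 4000
  X <- rbind(matrix(rnorm(n * p), n) %*% chol(Sig),
             sweep(matrix(rnorm(n * p), n) %*% chol(Sig), 2, mu2, "+"))
  y <- rep(1:2, each = n)
  fit <- gcda_fit(X, y, empty_graph(p),
                  spec = shrinkage_spec(lambda = 1, eps = 1))
  expect_lt(max(abs(fit$mu2 - mu2)), 0.1)
  expect_lt(norm(fit$sigma[[1L]] - Sig, "F"), 0.2)
})

test_that("Fisher axis maximizes the Rayleigh quotient", {
  set.seed(113)
  # diagonal covariance worked by hand
  X <- matrix(rnorm(200 * 2), 200)
  y <- rep(1:2, each = 100)
  fit <- gcda_fit(X, y, empty_graph(2),
                  spec = shrinkage_spec(lambda = 0, eps = 1))
  fit$sigma[[1L]] <- diag(c(2, 0.5))
  fit$chol[[1L]] <- chol(fit$sigma[[1L]])
  fit$mu1 <- c(1, 1)
  fit$mu2 <- c(0, 0)
  w <- fisher_axis(fit)
  expect_equal(w, c(0.5, 2) / sqrt(sum(c(0.5, 2)^2)) * sign(w[1]))
  # random PD covariance: no random direction beats it
  m <- random_fitted_model("linear")
  w <- fisher_axis(m)
  expect_equal(sqrt(sum(w^2)), 1)
  d <- m$mu1 - m$mu2
  S <- m$sigma[[1L]]
  rq <- function(v) drop(crossprod(v, d))^2 / drop(crossprod(v, S %*% v))
  others <- replicate(1000, rq(rnorm(m$p)))
  expect_gte(rq(w), max(others))
  qm <- random_fitted_model("quadratic")
  expect_error(fisher_axis(qm), "linear")
})

test_that("predictions are invariant to translation and permutation", {
  set.seed(127)
  sim <- simulate_dataset(simulation_config(p = 15, n = 40, seed = 3))
  fit <- gcda_fit(sim$X, sim$y, sim$graphs[[1L]],
                  spec = shrinkage_spec(lambda = 0.2, eps = 1))
  Xnew <- matrix(rnorm(12 * 15), 12)
  pred <- predict(fit, Xnew)
  shift <- rnorm(15)
  fit2 <- gcda_fit(sweep(sim$X, 2, shift, "+"), sim$y, sim$graphs[[1L]],
                   spec = shrinkage_spec(lambda = 0.2, eps = 1))
  expect_equal(predict(fit2, sweep(Xnew, 2, shift, "+")), pred)
  perm <- sample(12)
  expect_equal(predict(fit, Xnew[perm, ]), pred[perm])
})

test_that("well-separated training data is classified perfectly", {
  set.seed(131)
  cfg <- simulation_config(p = 30, n = 40, mean_shift = 3, seed = 9)
  sim <- simulate_dataset(cfg)
  fit <- gcda_fit(sim$X, sim$y, sim$graphs[[1L]],
                  spec = shrinkage_spec(lambda = 0.05, eps = 1))
  expect_equal(mean(predict(fit, sim$X) == sim$y), 1)
})

test_that("models serialize and reload exactly", {
  set.seed(137)
  for (flavor in c("linear", "quadratic")) {
    m <- random_fitted_model(flavor)
    f <- withr::local_tempfile(fileext = ".txt")
    write_gcda_model(m, f)
    back <- read_gcda_model(f)
    X <- matrix(rnorm(8 * m$p), 8)
    expect_identical(discriminant_score(back, X),
                     discriminant_score(m, X))
    expect_identical(back$sigma, m$sigma)
    expect_identical(as.character(m$levels), back$levels)
  }
})

test_that("fit validates labels, graphs and dimensions", {
  X <- matrix(rnorm(20 * 4), 20)
  expect_error(gcda_fit(X, rep(1, 20), empty_graph(4)), "2 classes")
  expect_error(gcda_fit(X, rep(1:2, 10), empty_graph(5)), "vertices")
  expect_error(gcda_fit(X, c(rep(1, 19), 2), empty_graph(4)),
               "at least 2")
  expect_error(gcda_fit(X, rep(1:2, 10), list(empty_graph(4),
                                              empty_graph(4))),
               "needs 1 graph")
})
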