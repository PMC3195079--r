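test_that("MCCV splits two thirds for training, stratified by class", {
  X <- matrix(rnorm(30 * 3), 30)
  y <- rep(1:2, each = 15)
  seen <- list()
  probe <- function(X_tr, y_tr, X_te) {
    seen[[length(seen) + 1L]] <<- c(n_tr = nrow(X_tr), n_te = nrow(X_te),
                                    n1 = sum(y_tr == 1L))
    rep(1L, nrow(X_te))
  }
  res <- mccv(X, y, probe, n_iter = 5, seed = 1)
  sizes <- do.call(rbind, seen)
  expect_true(all(sizes[, "n_tr"] == 20))
  expect_true(all(sizes[, "n_te"] == 10))
  expect_true(all(sizes[, "n1"] == 10))  # stratified
  expect_equal(res$n_iter, 5)
  expect_equal(length(res$rates), 5)
})

test_that("a consistent classifier on separable data scores 100 +/- 0", {
  X <- cbind(c(rnorm(20, -5), rnorm(20, 5)), matrix(rnorm(40 * 4), 40))
  y <- rep(c("neg", "pos"), each = 20)
  clf <- function(X_tr, y_tr, X_te) {
    thr <- mean(tapply(X_tr[, 1L], y_tr, mean))
    ifelse(X_te[, 1L] < thr, "neg", "pos")
  }
  res <- mccv(X, y, clf, n_iter = 10, seed = 2)
  expect_equal(res$mean, 100)
  expect_equal(res$sd, 0)
})

test_that("a constant classifier recovers the majority test fraction", {
  # 30/20 imbalance with stratified 2/3 splits leaves 10 majority and 7
  # minority test samples every iteration
  X <- matrix(rnorm(50 * 2), 50)
  y <- rep(c("maj", "min"), c(30, 20))
  res <- mccv(X, y, function(X_tr, y_tr, X_te) rep("maj", nrow(X_te)),
              n_iter = 8, seed = 3)
  expect_equal(res$rates, rep(100 * 10 / 17, 8))
})

test_that("MCCV is reproducible under a seed and validates inputs", {
  sim <- simulate_dataset(simulation_config(p = 10, n = 30, seed = 5))
  clf <- gcda_classifier(sim$graphs[[1L]],
                         spec = shrinkage_spec(lambda = 0.1, eps = 1))
  a <- mccv(sim$X, sim$y, clf, n_iter = 4, seed = 11)
  b <- mccv(sim$X, sim$y, clf, n_iter = 4, seed = 11)
  expect_identical(a$rates, b$rates)
  expect_error(mccv(sim$X, sim$y[-1], clf), "one label")
  expect_error(mccv(sim$X, sim$y, clf, train_frac = 1), "train_frac")
  expect_error(mccv(sim$X[1:4, ], sim$y[c(1, 2, 16, 17)], clf,
                    n_iter = 2), "training")
})

test_that("hyperparameter selection is deterministic and honors grids", {
  sim <- simulate_dataset(simulation_config(p = 20, n = 40, seed = 13))
  one <- select_hyperparameters(sim$X, sim$y, sim$graphs[[1L]],
                                spec = shrinkage_spec(lambda_grid = 0.25,
                                                      eps_grid = 0.5),
                                seed = 1)
  expect_equal(one$lambda, 0.25)
  expect_equal(one$eps, 0.5)
  sp <- shrinkage_spec(lambda_grid = c(0, 0.5, 1), eps_grid = c(0.1, 1))
  s1 <- select_hyperparameters(sim$X, sim$y, sim$graphs[[1L]], spec = sp,
                               seed = 7)
  s2 <- select_hyperparameters(sim$X, sim$y, sim$graphs[[1L]], spec = sp,
                               seed = 7)
  expect_identical(s1[c("lambda", "eps")], s2[c("lambda", "eps")])
  expect_equal(dim(s1$accuracy_grid), c(3L, 2L))
})

test_that("accuracy ties prefer the smallest lambda, then eps", {
  # a constant classifier surface: all grid points tie, so the selection
  # must land on the smallest lambda and eps
  set.seed(17)
  X <- cbind(c(rep(-8, 10), rep(8, 10)) + rnorm(20, sd = 0.01),
             matrix(rnorm(20 * 3, sd = 0.01), 20))
  y <- rep(1:2, each = 10)
  sel <- select_hyperparameters(X, y, empty_graph(4),
                                spec = shrinkage_spec(
                                  lambda_grid = c(0, 0.5),
                                  eps_grid = c(0.1, 1)),
                                k_folds = 5, seed = 19)
  expect_equal(sel$cv_accuracy, 100)
  expect_equal(sel$lambda, 0)
  expect_equal(sel$eps, 0.1)
})

test_that("the fitted model never sees held-out data", {
  sim <- simulate_dataset(simulation_config(p = 12, n = 36, seed = 23))
  tr <- c(1:12, 19:30)  # 12 samples per class in training
  te <- c(13:18, 31:36)
  spec <- shrinkage_spec(lambda_grid = c(0, 0.2), eps_grid = 1)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  set.seed(29)
  m1 <- gcda_fit(sim$X[tr, ], sim$y[tr], sim$graphs[[1L]], spec = spec)
  predict(m1, sim$X[te, ])
  write_gcda_model(m1, f1)
  set.seed(29)
  m2 <- gcda_fit(sim$X[tr, ], sim$y[tr], sim$graphs[[1L]], spec = spec)
  predict(m2, sim$X[te, ][sample(12), ])  # perturbed test data
  write_gcda_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("degradation experiment is deterministic per rung", {
  sim <- simulate_dataset(simulation_config(p = 25, n = 30, seed = 31))
  g <- sim$graphs[[1L]]
  lad <- misspecification_ladder(g, c(0, 0), seed = 1)  # identical rungs
  res <- degradation_experiment(sim$X, sim$y, lad,
                                spec = shrinkage_spec(lambda = 0.1,
                                                      eps = 1),
                                n_iter = 3, seed = 41)
  expect_equal(res$table$mean[1L], res$table$mean[2L])
  expect_equal(res$table$sd[1L], res$table$sd[2L])
  expect_equal(res$table$distance, c(0L, 0L))
})

test_that("inner CV reduces folds when a class is too small", {
  X <- matrix(rnorm(12 * 5), 12)
  y <- rep(1:2, each = 6)
  expect_warning(
    select_hyperparameters(X, y, empty_graph(5),
                           spec = shrinkage_spec(lambda_grid = c(0, 0.5),
                                                 eps_grid = 1),
                           k_folds = 10, seed = 43),
    "reducing")
})
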