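# Stratified fold assignment: within each class, fold ids 1..k are dealt
# round-robin to a random permutation of the class samples.
.stratified_folds <- function(y12, k) {
  folds <- integer(length(y12))
  for (cl in c(1L, 2L)) {
    ix <- which(y12 == cl)
    folds[ix] <- sample(rep_len(seq_len(k), length(ix)))
  }
  folds
}

# Mean CV accuracy over the (lambda, eps) grid. Fold statistics are
# computed once per fold and every grid point reuses them, so a grid
# evaluation costs one Cholesky per point, not one covariance estimate.
.grid_cv_accuracy <- function(X, y12, lambda_grid, eps_grid, targets_by_eps,
                              flavor, k_folds, priors) {
  tab <- tabulate(y12, 2L)
  k <- min(k_folds, tab)
  if (k < k_folds) {
    warning(sprintf("reducing inner CV to %d folds (smallest class has %d)",
                    k, min(tab)))
  }
  if (k < 2L) stop("inner CV needs at least 2 samples per class")
  folds <- .stratified_folds(y12, k)
  nl <- length(lambda_grid)
  ne <- length(eps_grid)
  hits <- matrix(0, nl, ne)
  for (f in seq_len(k)) {
    te <- folds == f
    st <- .fit_stats(X[!te, , drop = FALSE], y12[!te], flavor)
    pis <- .class_priors(st$n1, st$n2, priors)
    Xte <- X[te, , drop = FALSE]
    yte <- y12[te]
    for (j in seq_len(ne)) {
      Tj <- targets_by_eps[[j]]
      for (i in seq_len(nl)) {
        lam <- lambda_grid[i]
        sig <- lapply(seq_along(st$S),
                      function(q) lam * st$S[[q]] + (1 - lam) * Tj[[q]])
        sc <- tryCatch(
          .decision_scores(st$mu1, st$mu2, pis[1L], pis[2L], sig, Xte),
          error = function(e) NULL)
        hits[i, j] <- hits[i, j] +
          if (is.null(sc)) -Inf else sum((sc > 0) == (yte == 1L))
      }
    }
  }
  hits / length(y12)
}

.select_engine <- function(X, y12, lambda_grid, eps_grid, targets_by_eps,
                           flavor, k_folds, priors, seed = NULL) {
  acc <- .with_seed(seed,
    .grid_cv_accuracy(X, y12, lambda_grid, eps_grid, targets_by_eps,
                      flavor, k_folds, priors))
  if (!any(is.finite(acc))) {
    stop("no (lambda, eps) grid point yielded a positive-definite covariance")
  }
  best <- which(acc == max(acc), arr.ind = TRUE)
  # ties: smallest lambda, then smallest eps (grids are sorted ascending)
  best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE][1L, ]
  list(lambda = lambda_grid[best[1L]], eps = eps_grid[best[2L]],
       eps_index = unname(best[2L]), cv_accuracy = 100 * max(acc),
       accuracy_grid = acc)
}

#' Inner cross-validated selection of (lambda, eps)
#'
#' Stratified k-fold (default 10-fold) cross-validation on the training
#' data over the full `lambda_grid` x `eps_grid`, maximizing mean
#' held-in-fold accuracy. Accuracy ties are broken toward the smallest
#' `lambda` and then the smallest `eps`, deterministically preferring the
#' graph target over the empirical covariance.
#'
#' @inheritParams gcda_fit
#' @return A list with `lambda`, `eps`, `cv_accuracy` (percent) and the
#'   full `accuracy_grid` (fractions; rows = lambda, cols = eps).
#' @export
select_hyperparameters <- function(X, y, graphs,
                                   flavor = c("linear", "quadratic"),
                                   spec = shrinkage_spec(), k_folds = 10,
                                   priors = c("empirical", "uniform"),
                                   seed = NULL) {
  flavor <- match.arg(flavor)
  priors <- match.arg(priors)
  X <- as.matrix(X)
  graphs <- .as_graph_list(graphs, flavor)
  enc <- .encode_labels(y)
  Ls <- lapply(graphs, graph_laplacian)
  targets <- .targets_for(Ls, spec$eps_grid)
  .select_engine(X, enc$y12, spec$lambda_grid, spec$eps_grid, targets,
                 flavor, k_folds, priors, seed)
}

#' gCDA as a reusable train/predict closure
#'
#' Packages a graph, flavor and hyperparameter specification into a
#' classifier function `f(X_train, y_train, X_test)` returning predicted
#' labels -- the contract expected by [mccv()]. Graph targets for the
#' `eps` grid are computed once and shared across every call, which is
#' what keeps repeated cross-validation affordable. Predictions carry the
#' selected `(lambda, eps)` as the `"hyperparams"` attribute when tuning
#' took place.
#'
#' @inheritParams gcda_fit
#' @return A function of `(X_train, y_train, X_test)`.
#' @export
gcda_classifier <- function(graphs, flavor = c("linear", "quadratic"),
                            spec = shrinkage_spec(), k_folds = 10,
                            priors = c("empirical", "uniform")) {
  flavor <- match.arg(flavor)
  priors <- match.arg(priors)
  graphs <- .as_graph_list(graphs, flavor)
  Ls <- lapply(graphs, graph_laplacian)
  targets <- .targets_for(Ls, spec$eps_grid)
  force(spec)
  function(X_train, y_train, X_test) {
    X_train <- as.matrix(X_train)
    enc <- .encode_labels(y_train)
    fit <- .gcda_engine(X_train, enc$y12, enc$levels, graphs, Ls, flavor,
                        spec, priors, k_folds, seed = NULL,
                        targets_by_eps = targets)
    out <- predict(fit, X_test)
    if (!is.null(fit$selection)) {
      attr(out, "hyperparams") <- c(lambda = fit$lambda, eps = fit$eps)
    }
    out
  }
}

#' Monte Carlo cross-validation
#'
#' Repeatedly splits the data into a stratified training fraction
#' (default two thirds) and a held-out test set, trains the supplied
#' classifier on the training part only -- any hyperparameter selection
#' happens inside the classifier, on the training split -- and records
#' the percentage of correctly classified held-out samples.
#'
#' @param X numeric matrix, samples in rows.
#' @param y binary label vector.
#' @param classifier function `(X_train, y_train, X_test) -> labels`,
#'   e.g. from [gcda_classifier()].
#' @param n_iter number of random splits (default 100).
#' @param train_frac training fraction per class (default 2/3).
#' @param seed optional seed governing every split.
#' @param method_id,setting_id provenance strings carried into the
#'   summary.
#' @return An object of class `performance_summary`: `rates`
#'   (per-iteration percent correct), `mean`, `sd`, `n_iter`, and
#'   `hyperparams` (data frame of per-iteration selections, when the
#'   classifier reports them).
#' @export
mccv <- function(X, y, classifier, n_iter = 100, train_frac = 2 / 3,
                 seed = NULL, method_id = "", setting_id = "") {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("'y' must have one label per row of 'X'")
  if (n_iter < 1) stop("'n_iter' must be at least 1")
  if (train_frac <= 0 || train_frac >= 1) {
    stop("'train_frac' must lie in (0, 1)")
  }
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("'y' must contain exactly two classes")
  idx_by_class <- lapply(lev, function(l) which(y == l))
  n_tr <- vapply(idx_by_class, function(ix) round(train_frac * length(ix)),
                 double(1))
  if (any(n_tr < 2) || any(n_tr >= lengths(idx_by_class))) {
    stop("split leaves a class without >= 2 training or >= 1 test samples")
  }
  .with_seed(seed, {
    rates <- numeric(n_iter)
    hp <- vector("list", n_iter)
    for (it in seq_len(n_iter)) {
      tr <- unlist(mapply(function(ix, k) sample(ix, k), idx_by_class, n_tr,
                          SIMPLIFY = FALSE))
      te <- setdiff(seq_len(nrow(X)), tr)
      pred <- classifier(X[tr, , drop = FALSE], y[tr], X[te, , drop = FALSE])
      rates[it] <- 100 * mean(pred == y[te])
      hp[[it]] <- attr(pred, "hyperparams")
    }
    hyper <- if (all(vapply(hp, is.null, logical(1)))) NULL else {
      as.data.frame(do.call(rbind, hp))
    }
    structure(list(rates = rates, mean = mean(rates), sd = sd(rates),
                   n_iter = n_iter, train_frac = train_frac,
                   method_id = method_id, setting_id = setting_id,
                   hyperparams = hyper),
              class = "performance_summary")
  })
}

#' @export
print.performance_summary <- function(x, ...) {
  id <- paste(c(x$method_id, x$setting_id)[nzchar(c(x$method_id,
                                                    x$setting_id))],
              collapse = " / ")
  cat(sprintf("MCCV%s: %.2f (%.2f) %% correct over %d iterations\n",
              if (nzchar(id)) paste0(" [", id, "]") else "",
              x$mean, if (is.na(x$sd)) 0 else x$sd, x$n_iter))
  invisible(x)
}

#' Classification performance along a misspecification ladder
#'
#' For each rung of a [misspecification_ladder()] -- the truth graph
#' progressively rewired away from itself -- runs an MCCV of gCDA
#' integrating that (possibly wrong) graph on one fixed dataset, tracing
#' how performance degrades with the structural Hamming distance between
#' the integrated graph and the generating truth.
#'
#' @param X,y the dataset (typically from [simulate_dataset()]).
#' @param ladder a `misspec_ladder`.
#' @param flavor,spec,k_folds,priors passed to [gcda_classifier()].
#' @param n_iter,train_frac,seed passed to [mccv()]; the same seed is used
#'   for every rung so all rungs see identical splits.
#' @return A list of class `degradation_result`: `table`
#'   (`data.frame(n_moves, distance, mean, sd)` sorted by distance) and
#'   `summaries` (the per-rung `performance_summary` objects).
#' @export
degradation_experiment <- function(X, y, ladder,
                                   flavor = c("linear", "quadratic"),
                                   spec = shrinkage_spec(), n_iter = 20,
                                   train_frac = 2 / 3, k_folds = 10,
                                   priors = c("empirical", "uniform"),
                                   seed = NULL) {
  stopifnot(inherits(ladder, "misspec_ladder"))
  flavor <- match.arg(flavor)
  priors <- match.arg(priors)
  summaries <- vector("list", length(ladder$graphs))
  for (r in seq_along(ladder$graphs)) {
    clf <- gcda_classifier(ladder$graphs[[r]], flavor = flavor, spec = spec,
                           k_folds = k_folds, priors = priors)
    summaries[[r]] <- mccv(X, y, clf, n_iter = n_iter,
                           train_frac = train_frac, seed = seed,
                           method_id = "gcda",
                           setting_id = sprintf("distance=%d",
                                                ladder$table$distance[r]))
  }
  tab <- data.frame(
    n_moves = ladder$table$n_moves,
    distance = ladder$table$distance,
    mean = vapply(summaries, function(s) s$mean, double(1)),
    sd = vapply(summaries, function(s) s$sd, double(1))
  )
  ord <- order(tab$distance)
  structure(list(table = tab[ord, ], summaries = summaries[ord]),
            class = "degradation_result")
}

#' @export
print.degradation_result <- function(x, ...) {
  cat("gCDA accuracy vs graph misspecification:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
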