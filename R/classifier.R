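# Fitting engine shared by gcda_fit() and the cross-validation loops.
# Works on the internal encoding: y12 in {1L, 2L}, graphs as a list of
# Laplacians (length 1 linear, 2 quadratic), targets precomputed per eps.

.as_graph_list <- function(graphs, flavor) {
  if (inherits(graphs, "grn_graph")) graphs <- list(graphs)
  if (!is.list(graphs) || !all(vapply(graphs, inherits, logical(1),
                                      "grn_graph"))) {
    stop("'graphs' must be a grn_graph or a list of grn_graph objects")
  }
  need <- if (flavor == "linear") 1L else 2L
  if (flavor == "quadratic" && length(graphs) == 1L) {
    graphs <- graphs[c(1L, 1L)]
  }
  if (length(graphs) != need) {
    stop(sprintf("flavor '%s' needs %d graph(s), got %d", flavor, need,
                 length(graphs)))
  }
  p <- unique(vapply(graphs, function(g) g$p, integer(1)))
  if (length(p) != 1L) stop("graphs must share the same vertex count")
  graphs
}

.encode_labels <- function(y) {
  lev <- sort(unique(y))
  if (length(lev) != 2L) {
    stop(sprintf("'y' must have exactly 2 classes, found %d (%s)",
                 length(lev), paste(utils::head(lev, 5), collapse = ", ")))
  }
  list(levels = lev, y12 = ifelse(y == lev[1L], 1L, 2L))
}

.class_priors <- function(n1, n2, mode) {
  if (mode == "uniform") c(0.5, 0.5) else c(n1, n2) / (n1 + n2)
}

# Per-class means and empirical covariance(s) on the training data.
.fit_stats <- function(X, y12, flavor) {
  i1 <- y12 == 1L
  n1 <- sum(i1)
  n2 <- sum(!i1)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least 2 samples")
  X1 <- X[i1, , drop = FALSE]
  X2 <- X[!i1, , drop = FALSE]
  mu1 <- colMeans(X1)
  mu2 <- colMeans(X2)
  A1 <- sweep(X1, 2L, mu1)
  A2 <- sweep(X2, 2L, mu2)
  S <- if (flavor == "linear") {
    list((crossprod(A1) + crossprod(A2)) / (n1 + n2 - 2))
  } else {
    list(crossprod(A1) / (n1 - 1), crossprod(A2) / (n2 - 1))
  }
  list(mu1 = mu1, mu2 = mu2, n1 = n1, n2 = n2, S = S)
}

# Decision scores f(x) = log pi1 phi(x; mu1, Sig1) - log pi2 phi(x; mu2,
# Sig2) for the rows of X. `sig` holds one (shared) or two covariance
# matrices; Cholesky everywhere, no explicit inverses. Errors (non-PD
# covariance) propagate to the caller.
.decision_scores <- function(mu1, mu2, pi1, pi2, sig, X) {
  if (length(sig) == 1L) {
    R <- chol(sig[[1L]])
    d <- mu1 - mu2
    w <- backsolve(R, backsolve(R, d, transpose = TRUE))
    b <- log(pi1 / pi2) - 0.5 * sum(w * (mu1 + mu2))
    drop(X %*% w) + b
  } else {
    R1 <- chol(sig[[1L]])
    R2 <- chol(sig[[2L]])
    Z1 <- backsolve(R1, t(X) - mu1, transpose = TRUE)
    Z2 <- backsolve(R2, t(X) - mu2, transpose = TRUE)
    ld1 <- 2 * sum(log(diag(R1)))
    ld2 <- 2 * sum(log(diag(R2)))
    log(pi1 / pi2) - 0.5 * (ld1 - ld2) -
      0.5 * (colSums(Z1^2) - colSums(Z2^2))
  }
}

# targets_by_eps: list over eps grid; each element a list of target
# matrices parallel to the graph list.
.targets_for <- function(laplacians, eps_grid) {
  lapply(eps_grid, function(e) lapply(laplacians, shrinkage_target, eps = e))
}

#' Fit a graph-constrained discriminant classifier
#'
#' Estimates per-class means and priors, shrinks the within-class
#' (linear) or per-class (quadratic) empirical covariance toward the
#' graph target \eqn{(L + \epsilon I)^{-1}}, and caches the Cholesky
#' factors used by the Bayesian decision rule. When `lambda`/`eps` are not
#' fixed in `spec` they are selected by stratified inner k-fold
#' cross-validation on the training data (ties broken toward the smallest
#' `lambda`, then the smallest `eps`, preferring the graph).
#'
#' @param X numeric matrix, samples in rows, genes in columns.
#' @param y binary label vector; any two distinct values. Classes are
#'   ordered by `sort()`, the first being "class 1" (positive decision
#'   scores).
#' @param graphs a `grn_graph` (linear) or list of two (quadratic; one per
#'   class). A single graph is accepted for the quadratic flavor and used
#'   for both classes.
#' @param flavor `"linear"` (one shared covariance and graph) or
#'   `"quadratic"` (one covariance and graph per class).
#' @param spec a [shrinkage_spec()].
#' @param priors `"empirical"` (class frequencies) or `"uniform"`.
#' @param k_folds folds for the inner hyperparameter CV (default 10;
#'   reduced with a warning when a class is smaller).
#' @param seed optional seed for the inner-CV fold assignment.
#' @return An object of class `gcda_model`.
#' @examples
#' sim <- simulate_dataset(simulation_config(p = 20, n = 40, seed = 1))
#' fit <- gcda_fit(sim$X, sim$y, sim$graphs[[1]],
#'                 spec = shrinkage_spec(lambda = 0.1, eps = 1))
#' table(predict(fit, sim$X), sim$y)
#' @export
gcda_fit <- function(X, y, graphs, flavor = c("linear", "quadratic"),
                     spec = shrinkage_spec(),
                     priors = c("empirical", "uniform"),
                     k_folds = 10, seed = NULL) {
  flavor <- match.arg(flavor)
  priors <- match.arg(priors)
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("'y' must have one label per row of 'X'")
  graphs <- .as_graph_list(graphs, flavor)
  if (graphs[[1L]]$p != ncol(X)) {
    stop(sprintf("graph has %d vertices but X has %d columns",
                 graphs[[1L]]$p, ncol(X)))
  }
  enc <- .encode_labels(y)
  Ls <- lapply(graphs, graph_laplacian)
  .gcda_engine(X, enc$y12, enc$levels, graphs, Ls, flavor, spec, priors,
               k_folds, seed, targets_by_eps = NULL)
}

.gcda_engine <- function(X, y12, levels, graphs, Ls, flavor, spec, priors,
                         k_folds, seed, targets_by_eps = NULL) {
  st <- .fit_stats(X, y12, flavor)
  pis <- .class_priors(st$n1, st$n2, priors)
  selection <- NULL
  if (is.null(spec$lambda) || is.null(spec$eps)) {
    if (is.null(targets_by_eps)) {
      targets_by_eps <- .targets_for(Ls, spec$eps_grid)
    }
    selection <- .select_engine(X, y12, spec$lambda_grid, spec$eps_grid,
                                targets_by_eps, flavor, k_folds, priors,
                                seed)
    lambda <- selection$lambda
    eps <- selection$eps
    targets <- targets_by_eps[[selection$eps_index]]
  } else {
    lambda <- spec$lambda
    eps <- spec$eps
    targets <- if (!is.null(targets_by_eps)) {
      targets_by_eps[[match(eps, spec$eps_grid)]]
    } else {
      lapply(Ls, shrinkage_target, eps = eps)
    }
  }
  sig <- lapply(seq_along(st$S),
                function(k) shrink_covariance(st$S[[k]], targets[[k]], lambda))
  chols <- tryCatch(lapply(sig, chol), error = function(e) {
    stop(paste0("shrunk covariance is not positive definite (lambda = ",
                lambda, "); with n <= p use lambda < 1 so the ",
                "graph target regularizes the estimate"))
  })
  structure(list(
    flavor = flavor,
    levels = levels,
    mu1 = st$mu1, mu2 = st$mu2,
    n1 = st$n1, n2 = st$n2,
    pi1 = pis[1L], pi2 = pis[2L],
    prior_mode = priors,
    lambda = lambda, eps = eps,
    sigma = sig,
    chol = chols,
    logdet = vapply(chols, function(R) 2 * sum(log(diag(R))), double(1)),
    selection = selection,
    graphs = graphs,
    p = ncol(X)
  ), class = "gcda_model")
}

#' @export
print.gcda_model <- function(x, ...) {
  cat(sprintf("gCDA model (%s), p = %d\n", x$flavor, x$p))
  cat(sprintf("  classes: %s (n=%d, pi=%.3f) vs %s (n=%d, pi=%.3f)\n",
              x$levels[1L], x$n1, x$pi1, x$levels[2L], x$n2, x$pi2))
  cat(sprintf("  lambda = %g, eps = %g%s\n", x$lambda, x$eps,
              if (is.null(x$selection)) " (fixed)" else " (inner CV)"))
  cat(sprintf("  graph(s): %s edges\n",
              paste(vapply(x$graphs, function(g) nrow(g$edges), integer(1)),
                    collapse = ", ")))
  invisible(x)
}

#' Bayesian discriminant scores
#'
#' Evaluates the decision function
#' \eqn{f(x) = \log[\pi_1 \phi(x; \mu_1, \Sigma_1)] -
#'             \log[\pi_2 \phi(x; \mu_2, \Sigma_2)]}
#' for each row of `X`. Positive scores vote for class 1 (the first sorted
#' label), negative for class 2; in the linear flavor the score is affine,
#' \eqn{w^\top x + b} with \eqn{w = \hat\Sigma^{-1}(\mu_1 - \mu_2)}.
#'
#' @param model a fitted `gcda_model`.
#' @param X matrix of samples in rows (or a single numeric vector of
#'   length p).
#' @return Numeric vector of scores.
#' @export
discriminant_score <- function(model, X) {
  stopifnot(inherits(model, "gcda_model"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  X <- as.matrix(X)
  if (ncol(X) != model$p) {
    stop(sprintf("'X' has %d columns but the model expects %d", ncol(X),
                 model$p))
  }
  .decision_scores(model$mu1, model$mu2, model$pi1, model$pi2, model$sigma,
                   X)
}

#' Predict class labels
#'
#' Assigns class 1 (first sorted training label) when the discriminant
#' score is strictly positive, class 2 otherwise (ties go to class 2).
#'
#' @param object a fitted `gcda_model`.
#' @param newdata matrix of samples in rows.
#' @param ... unused.
#' @return Vector of predicted labels in the training label encoding.
#' @export
predict.gcda_model <- function(object, newdata, ...) {
  sc <- discriminant_score(object, newdata)
  object$levels[ifelse(sc > 0, 1L, 2L)]
}

#' Fisher discriminant axis
#'
#' The direction maximizing the between- over within-class covariance
#' ratio; for two classes with the shared shrunk covariance this is
#' \eqn{w \propto \hat\Sigma^{-1}(\mu_1 - \mu_2)}, returned with unit
#' Euclidean norm. Defined for the linear flavor only.
#'
#' @param model a fitted linear `gcda_model`.
#' @return Unit-length numeric vector of length p.
#' @export
fisher_axis <- function(model) {
  stopifnot(inherits(model, "gcda_model"))
  if (model$flavor != "linear") {
    stop("the Fisher axis is defined for the linear flavor only")
  }
  R <- model$chol[[1L]]
  w <- backsolve(R, backsolve(R, model$mu1 - model$mu2, transpose = TRUE))
  w / sqrt(sum(w^2))
}

.fmt_num <- function(x) format(x, digits = 17, trim = TRUE, scientific = TRUE)

#' Serialize a fitted model to structured text
#'
#' Writes means, priors, covariances, hyperparameters and graph provenance
#' to a plain-text file that [read_gcda_model()] restores exactly (full
#' double precision). Intended for audit and reload; labels containing tab
#' characters are not supported.
#'
#' @param model a fitted `gcda_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gcda_model <- function(model, path) {
  stopifnot(inherits(model, "gcda_model"))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("gcda_model 1")
  wl("flavor\t", model$flavor)
  wl("levels\t", paste(model$levels, collapse = "\t"))
  wl("p\t", model$p)
  wl("n\t", model$n1, "\t", model$n2)
  wl("pi\t", .fmt_num(model$pi1), "\t", .fmt_num(model$pi2))
  wl("prior_mode\t", model$prior_mode)
  wl("lambda\t", .fmt_num(model$lambda))
  wl("eps\t", .fmt_num(model$eps))
  wl("mu1\t", paste(.fmt_num(model$mu1), collapse = "\t"))
  wl("mu2\t", paste(.fmt_num(model$mu2), collapse = "\t"))
  for (k in seq_along(model$sigma)) {
    wl("sigma\t", k)
    apply(model$sigma[[k]], 1L,
          function(r) wl(paste(.fmt_num(r), collapse = "\t")))
  }
  for (k in seq_along(model$graphs)) {
    g <- model$graphs[[k]]
    wl("graph\t", k, "\t", g$p, "\t", nrow(g$edges))
    if (nrow(g$edges) > 0L) {
      apply(g$edges, 1L, function(e) wl(e[1L], "\t", e[2L]))
    }
  }
  invisible(path)
}

#' Restore a serialized model
#'
#' @param path file written by [write_gcda_model()].
#' @return A `gcda_model`.
#' @export
read_gcda_model <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1L], "gcda_model 1")) {
    stop("not a gcda_model file")
  }
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  i <- 1L
  take <- function() {
    f <- fields[[i]]
    i <<- i + 1L
    f
  }
  kv <- list()
  sigma <- list()
  graphs <- list()
  while (i <= length(fields)) {
    f <- take()
    key <- f[1L]
    if (key == "sigma") {
      p <- as.integer(kv$p)
      M <- matrix(0, p, p)
      for (r in seq_len(p)) M[r, ] <- as.numeric(take())
      sigma[[as.integer(f[2L])]] <- M
    } else if (key == "graph") {
      m <- as.integer(f[4L])
      ed <- if (m > 0L) {
        t(vapply(seq_len(m), function(j) as.integer(take()), integer(2)))
      } else NULL
      graphs[[as.integer(f[2L])]] <- grn_graph(as.integer(f[3L]), ed)
    } else {
      kv[[key]] <- f[-1L]
    }
  }
  chols <- lapply(sigma, chol)
  structure(list(
    flavor = kv$flavor,
    levels = kv$levels,
    mu1 = as.numeric(kv$mu1), mu2 = as.numeric(kv$mu2),
    n1 = as.integer(kv$n[1L]), n2 = as.integer(kv$n[2L]),
    pi1 = as.numeric(kv$pi[1L]), pi2 = as.numeric(kv$pi[2L]),
    prior_mode = kv$prior_mode,
    lambda = as.numeric(kv$lambda), eps = as.numeric(kv$eps),
    sigma = sigma,
    chol = chols,
    logdet = vapply(chols, function(R) 2 * sum(log(diag(R))), double(1)),
    selection = NULL,
    graphs = graphs,
    p = as.integer(kv$p)
  ), class = "gcda_model")
}
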