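#' Shrinkage hyperparameters and their search grids
#'
#' `lambda` is the convex weight on the empirical covariance
#' (\eqn{\hat\Sigma = \lambda S + (1-\lambda) T}): 0 means the graph
#' target alone, 1 the empirical estimate alone, so small selected values
#' indicate that the network is actually being used. `eps` conditions the
#' target \eqn{T = (L + \epsilon I)^{-1}}. When `lambda` or `eps` is
#' `NULL` it is tuned on its grid by inner 10-fold cross-validation at fit
#' time; a supplied scalar fixes it.
#'
#' @param lambda fixed shrinkage intensity in \[0, 1\], or `NULL` to tune.
#' @param eps fixed positive target conditioning, or `NULL` to tune.
#' @param lambda_grid candidate grid for `lambda` (default 0, 0.05, ..., 1).
#' @param eps_grid candidate grid for `eps` (default 0.01, 0.1, 1, 10).
#' @return An object of class `shrinkage_spec`.
#' @export
shrinkage_spec <- function(lambda = NULL, eps = NULL,
                           lambda_grid = seq(0, 1, by = 0.05),
                           eps_grid = c(0.01, 0.1, 1, 10)) {
  if (!is.null(lambda)) {
    if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
        lambda < 0 || lambda > 1) {
      stop("'lambda' must lie in [0, 1]")
    }
    lambda_grid <- lambda
  }
  if (!is.null(eps)) {
    if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) || eps <= 0) {
      stop("'eps' must be a positive real")
    }
    eps_grid <- eps
  }
  lambda_grid <- sort(unique(as.numeric(lambda_grid)))
  eps_grid <- sort(unique(as.numeric(eps_grid)))
  if (length(lambda_grid) == 0L || length(eps_grid) == 0L) {
    stop("hyperparameter grids must be non-empty")
  }
  if (any(lambda_grid < 0 | lambda_grid > 1)) {
    stop("'lambda_grid' values must lie in [0, 1]")
  }
  if (any(eps_grid <= 0)) stop("'eps_grid' values must be positive")
  structure(list(lambda = lambda, eps = eps,
                 lambda_grid = lambda_grid, eps_grid = eps_grid),
            class = "shrinkage_spec")
}

#' @export
print.shrinkage_spec <- function(x, ...) {
  fmt <- function(v, fixed) {
    if (!is.null(fixed)) sprintf("fixed at %g", fixed)
    else sprintf("tuned on {%s}", paste(signif(v, 3), collapse = ", "))
  }
  cat("shrinkage_spec\n")
  cat("  lambda:", fmt(x$lambda_grid, x$lambda), "\n")
  cat("  eps:   ", fmt(x$eps_grid, x$eps), "\n")
  invisible(x)
}

#' Gaussian-graphical-model shrinkage target
#'
#' Builds the structured covariance target \eqn{T = (L + \epsilon I)^{-1}}
#' from a graph Laplacian. \eqn{L} alone is singular (the constant vector
#' is in its null space); adding \eqn{\epsilon I} makes the sum positive
#' definite while leaving the off-diagonal zero pattern intact, so the
#' precision matrix \eqn{T^{-1} = L + \epsilon I} has a zero at (i, j),
#' i != j, exactly when (i, j) is not an edge -- the conditional
#' independence structure of a Gaussian graphical model on the network.
#'
#' @param graph a `grn_graph`, or a symmetric Laplacian matrix.
#' @param eps positive conditioning constant.
#' @return Symmetric positive-definite `p` x `p` matrix.
#' @examples
#' g <- grn_graph(3, rbind(c(1, 2), c(2, 3)))
#' T <- shrinkage_target(g, eps = 1)
#' round(solve(T), 10)  # recovers L + I, zeros off the edges
#' @export
shrinkage_target <- function(graph, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || is.na(eps) || eps <= 0) {
    stop("'eps' must be a positive real")
  }
  L <- if (inherits(graph, "grn_graph")) graph_laplacian(graph)
       else as.matrix(graph)
  if (nrow(L) != ncol(L) || !isSymmetric(unname(L), tol = 1e-10)) {
    stop("'graph' must be a grn_graph or a symmetric Laplacian matrix")
  }
  M <- unname(L)
  diag(M) <- diag(M) + eps
  R <- tryCatch(chol(M), error = function(e) {
    stop("L + eps*I is not positive definite; is L a valid Laplacian?")
  })
  Tm <- chol2inv(R)
  (Tm + t(Tm)) / 2
}

#' Empirical covariance matrix
#'
#' Sample covariance about the sample mean with divisor `n - ddof`
#' (default `ddof = 1`, the unbiased estimator).
#'
#' @param X numeric matrix, samples in rows.
#' @param ddof degrees of freedom subtracted from `n` in the divisor.
#' @return Symmetric positive semi-definite `p` x `p` matrix.
#' @export
empirical_covariance <- function(X, ddof = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("at least 2 samples are required")
  S <- cov(X)
  if (ddof != 1) S <- S * (n - 1) / (n - ddof)
  unname(S)
}

#' Pooled within-class covariance
#'
#' Per-class centered scatter matrices summed and divided by `n - ddof`
#' (default `ddof = 2`: one estimated mean per class), the within-class
#' estimate used by linear gCDA.
#'
#' @param X numeric matrix, samples in rows.
#' @param y binary label vector of length `nrow(X)`.
#' @param ddof divisor offset (default 2).
#' @return Symmetric positive semi-definite `p` x `p` matrix.
#' @export
pooled_within_covariance <- function(X, y, ddof = 2) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("'y' must have one label per row of 'X'")
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("'y' must contain exactly two classes")
  sc <- matrix(0, ncol(X), ncol(X))
  for (l in lev) {
    Xi <- X[y == l, , drop = FALSE]
    if (nrow(Xi) < 2L) stop("each class needs at least 2 samples")
    A <- sweep(Xi, 2L, colMeans(Xi))
    sc <- sc + crossprod(A)
  }
  unname(sc / (nrow(X) - ddof))
}

#' Convex shrinkage of a covariance estimate toward a target
#'
#' \eqn{\hat\Sigma = \lambda S + (1-\lambda) T}. With a positive-definite
#' target the result is positive definite for any `lambda < 1`, which is
#' what regularizes discriminant analysis when `n <= p`.
#'
#' @param S empirical covariance matrix.
#' @param target target matrix of the same dimension.
#' @param lambda weight on `S`, in \[0, 1\].
#' @return Symmetric `p` x `p` matrix.
#' @export
shrink_covariance <- function(S, target, lambda) {
  S <- as.matrix(S)
  target <- as.matrix(target)
  if (!all(dim(S) == dim(target))) {
    stop("'S' and 'target' must have the same dimension")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || is.na(lambda) ||
      lambda < 0 || lambda > 1) {
    stop("'lambda' must lie in [0, 1]")
  }
  lambda * S + (1 - lambda) * target
}

#' Write a covariance matrix as delimited text
#'
#' @param sigma symmetric numeric matrix.
#' @param path output path.
#' @param labels optional row/column labels (gene identifiers).
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_covariance <- function(sigma, path, labels = NULL, sep = "\t") {
  sigma <- as.matrix(sigma)
  if (!is.null(labels)) dimnames(sigma) <- list(labels, labels)
  write.table(format(sigma, digits = 17, trim = TRUE), path, sep = sep,
              quote = FALSE, col.names = NA)
  invisible(path)
}
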