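#' Configuration for graph-structured two-class simulation
#'
#' Bundles the parameters of the generative model used throughout the
#' simulation study: an Erdős–Rényi graph (or one per class) is drawn,
#' each graph is turned into a covariance matrix
#' \eqn{\Sigma(G) = (L_G + \epsilon I)^{-1}} via [shrinkage_target()], and
#' the two classes are sampled as \eqn{N(0, \Sigma(G_1))} and
#' \eqn{N(\mu, \Sigma(G_2))}.
#'
#' Defaults define the study conditions used by the package's experiments:
#' `p = 100` genes, `n = 50` samples split evenly, edge probability 0.05,
#' `eps = 1`. By default (`mean_shift = NULL`) the between-class mean
#' difference is drawn as a random isotropic direction scaled so that the
#' Mahalanobis separation \eqn{\Delta = \sqrt{\mu^\top \Sigma^{-1} \mu}}
#' gives an oracle Bayes accuracy \eqn{\Phi(\Delta/2)} of `bayes_accuracy`
#' (default 90%) -- a realistic, non-saturated operating point. A generic
#' direction matters: a mean difference proportional to the constant
#' vector lies in the Laplacian's null space, making the oracle
#' discriminant direction \eqn{\Sigma^{-1}\mu \propto \mu} independent of
#' the graph, a degenerate regime in which network information cannot
#' help by construction. An explicit `mean_shift` (scalar broadcast or
#' length-`p` vector) is used as given.
#'
#' @param p number of genes.
#' @param n total number of samples (`n >= 4`).
#' @param class_balance fraction of samples in class 1, in (0, 1); both
#'   classes must end up with at least 2 samples.
#' @param edge_prob Erdős–Rényi edge probability.
#' @param eps conditioning of the graph covariance.
#' @param mean_shift `NULL` (random direction at calibrated separation),
#'   a scalar (broadcast to all genes) or a length-`p` vector: the mean
#'   of class 2 (class 1 is centered at zero).
#' @param bayes_accuracy target oracle accuracy in (0.5, 1) used to scale
#'   the default random mean shift; ignored when `mean_shift` is given.
#' @param setting `"shared_graph"` (one graph, equal covariances; the
#'   linear regime) or `"two_graphs"` (independent graph per class; the
#'   quadratic regime).
#' @param seed optional integer making the draw reproducible.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(p = 100, n = 50, class_balance = 0.5,
                              edge_prob = 0.05, eps = 1, mean_shift = NULL,
                              bayes_accuracy = 0.90,
                              setting = c("shared_graph", "two_graphs"),
                              seed = NULL) {
  setting <- match.arg(setting)
  if (!is.numeric(p) || length(p) != 1L || p < 2) stop("'p' must be >= 2")
  if (!is.numeric(n) || length(n) != 1L || n < 4) stop("'n' must be >= 4")
  if (!is.numeric(class_balance) || class_balance <= 0 || class_balance >= 1) {
    stop("'class_balance' must lie in (0, 1)")
  }
  n1 <- round(n * class_balance)
  n2 <- n - n1
  if (n1 < 2 || n2 < 2) stop("both classes need at least 2 samples")
  if (edge_prob < 0 || edge_prob > 1) {
    stop("'edge_prob' must be a probability")
  }
  if (eps <= 0) stop("'eps' must be positive")
  if (!is.null(mean_shift) && !length(mean_shift) %in% c(1L, p)) {
    stop("'mean_shift' must be NULL, a scalar or a length-p vector")
  }
  if (!is.numeric(bayes_accuracy) || length(bayes_accuracy) != 1L ||
      bayes_accuracy <= 0.5 || bayes_accuracy >= 1) {
    stop("'bayes_accuracy' must lie in (0.5, 1)")
  }
  structure(list(p = as.integer(p), n = as.integer(n),
                 n1 = as.integer(n1), n2 = as.integer(n2),
                 class_balance = class_balance, edge_prob = edge_prob,
                 eps = eps, mean_shift = mean_shift,
                 bayes_accuracy = bayes_accuracy, setting = setting,
                 seed = seed),
            class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    "simulation_config: p=%d, n=%d (%d/%d), edge_prob=%g, eps=%g, %s\n",
    x$p, x$n, x$n1, x$n2, x$edge_prob, x$eps, x$setting))
  invisible(x)
}

#' Simulate a graph-structured Gaussian two-class dataset
#'
#' Draws the generating graph(s), builds each class covariance with the
#' very same [shrinkage_target()] code path used by the classifier, and
#' samples class 1 from \eqn{N(0, \Sigma(G_1))} and class 2 from
#' \eqn{N(\mu, \Sigma(G_2))} via the Cholesky factor. Fully reproducible
#' under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return A list with `X` (n x p matrix), `y` (integer labels 1/2,
#'   class 1 first), `graphs` (list of the two generating truth graphs;
#'   identical object in the shared setting), `sigmas` (the generating
#'   covariances), `mean_shift` (the realized length-`p` mean difference)
#'   and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    L1 <- L2 <- graph_laplacian(g1 <- erdos_renyi_graph(config$p,
                                                        config$edge_prob))
    g2 <- g1
    if (config$setting == "two_graphs") {
      g2 <- erdos_renyi_graph(config$p, config$edge_prob)
      L2 <- graph_laplacian(g2)
    }
    s1 <- shrinkage_target(L1, config$eps)
    s2 <- if (config$setting == "two_graphs") {
      shrinkage_target(L2, config$eps)
    } else s1
    mu <- if (is.null(config$mean_shift)) {
      # random direction scaled to the Mahalanobis separation giving the
      # requested oracle Bayes accuracy (average precision across classes)
      z <- rnorm(config$p)
      P <- (L1 + L2) / 2
      diag(P) <- diag(P) + config$eps
      delta <- 2 * stats::qnorm(config$bayes_accuracy)
      z * delta / sqrt(drop(crossprod(z, P %*% z)))
    } else {
      rep_len(config$mean_shift, config$p)
    }
    X1 <- matrix(rnorm(config$n1 * config$p), config$n1) %*% chol(s1)
    X2 <- matrix(rnorm(config$n2 * config$p), config$n2) %*% chol(s2)
    X2 <- sweep(X2, 2L, mu, "+")
    list(X = rbind(X1, X2),
         y = rep(c(1L, 2L), c(config$n1, config$n2)),
         graphs = list(g1, g2),
         sigmas = list(s1, s2),
         mean_shift = mu,
         config = config)
  })
}

#' Ladder of increasingly misspecified graphs
#'
#' Starting from the truth graph, produces rewired copies at increasing
#' numbers of edge moves and measures the achieved structural Hamming
#' distance of each to the truth. Rewiring moves are requested rather
#' than exact distances (a rewired edge can land back on a removed slot,
#' so k moves achieve a distance of at most 2k); the output is sorted by
#' achieved distance.
#'
#' @param g the truth `grn_graph`.
#' @param moves non-negative integers: rewiring moves per ladder rung,
#'   each at most the edge count of `g`.
#' @param seed optional integer seed.
#' @return A data-frame-like list of class `misspec_ladder`: components
#'   `graphs` (list of `grn_graph`) and `table`
#'   (`data.frame(n_moves, distance)` in ladder order).
#' @export
misspecification_ladder <- function(g, moves, seed = NULL) {
  stopifnot(inherits(g, "grn_graph"))
  moves <- as.integer(moves)
  if (any(moves < 0)) stop("'moves' must be non-negative")
  if (any(moves > nrow(g$edges))) {
    stop("'moves' cannot exceed the edge count of the truth graph")
  }
  .with_seed(seed, {
    graphs <- lapply(moves, function(k) rewire_graph(g, k))
    dist <- vapply(graphs, hamming_distance, integer(1), g2 = g)
    ord <- order(dist)
    structure(list(graphs = graphs[ord],
                   table = data.frame(n_moves = moves[ord],
                                      distance = dist[ord])),
              class = "misspec_ladder")
  })
}

#' @export
print.misspec_ladder <- function(x, ...) {
  cat("misspecification ladder:\n")
  print(x$table)
  invisible(x)
}

#' Write a simulated dataset to delimited text
#'
#' Writes the expression matrix, the labels, the truth graphs (edge
#' lists) and the configuration as a small set of plain-text files
#' sharing the `stem` prefix -- the fixture generator for external tools.
#'
#' @param sim result of [simulate_dataset()].
#' @param stem path prefix; files `<stem>_X.tsv`, `<stem>_y.tsv`,
#'   `<stem>_graph1.tsv` (and `_graph2.tsv` in the two-graph setting) and
#'   `<stem>_config.tsv` are produced.
#' @return The character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, stem) {
  ids <- sprintf("s%03d", seq_len(nrow(sim$X)))
  genes <- sprintf("g%03d", seq_len(ncol(sim$X)))
  xp <- paste0(stem, "_X.tsv")
  X <- sim$X
  dimnames(X) <- list(ids, genes)
  write.table(format(X, digits = 17, trim = TRUE), xp, sep = "\t",
              quote = FALSE, col.names = NA)
  yp <- paste0(stem, "_y.tsv")
  write.table(data.frame(sample_id = ids, label = sim$y), yp, sep = "\t",
              quote = FALSE, row.names = FALSE)
  g1 <- sim$graphs[[1L]]
  g1$labels <- genes
  gp <- paste0(stem, "_graph1.tsv")
  write_edgelist(g1, gp)
  paths <- c(xp, yp, gp)
  if (sim$config$setting == "two_graphs") {
    g2 <- sim$graphs[[2L]]
    g2$labels <- genes
    g2p <- paste0(stem, "_graph2.tsv")
    write_edgelist(g2, g2p)
    paths <- c(paths, g2p)
  }
  cp <- paste0(stem, "_config.tsv")
  cfg <- sim$config
  writeLines(sprintf("%s\t%s", c("p", "n", "class_balance", "edge_prob",
                                 "eps", "mean_shift", "setting", "seed"),
                     c(cfg$p, cfg$n, cfg$class_balance, cfg$edge_prob,
                       cfg$eps,
                       paste(format(sim$mean_shift, digits = 17,
                                    trim = TRUE), collapse = ","),
                       cfg$setting,
                       if (is.null(cfg$seed)) "NA" else cfg$seed)), cp)
  invisible(c(paths, cp))
}
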