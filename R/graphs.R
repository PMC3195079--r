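#' Undirected gene-network graph
#'
#' Constructs an unweighted, undirected graph on `p` labelled vertices, the
#' representation used for gene regulatory networks throughout the package.
#' Edges are canonicalized (endpoints ordered, duplicates removed); no
#' self-loops are allowed. Vertices are indexed 1..p; optional `labels`
#' (gene identifiers) map external names onto indices.
#'
#' @param p number of vertices (genes).
#' @param edges two-column matrix (or object coercible to one) of vertex
#'   indices in 1..p, one edge per row; `NULL` for an edgeless graph.
#' @param labels optional character vector of unique vertex labels,
#'   length `p`.
#' @return An object of class `grn_graph` with components `p`, `edges`
#'   (m x 2 integer matrix, first column < second, rows sorted) and
#'   `labels`.
#' @examples
#' g <- grn_graph(3, rbind(c(1, 2), c(2, 3)))
#' graph_laplacian(g)
#' @export
grn_graph <- function(p, edges = NULL, labels = NULL) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 1 ||
      p != as.integer(p)) {
    stop("'p' must be a single positive integer")
  }
  p <- as.integer(p)
  if (is.null(edges) || NROW(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("'edges' must have two columns")
    if (any(is.na(edges)) || any(edges != round(edges))) {
      stop("edge endpoints must be integers")
    }
    storage.mode(edges) <- "integer"
    if (any(edges < 1L) || any(edges > p)) {
      stop("edge endpoints must lie in 1..p")
    }
    if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
    lo <- pmin(edges[, 1L], edges[, 2L])
    hi <- pmax(edges[, 1L], edges[, 2L])
    key <- (as.double(lo) - 1) * p + hi
    keep <- !duplicated(key)
    ord <- order(key[keep])
    edges <- cbind(lo[keep][ord], hi[keep][ord])
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != p) stop("'labels' must have length p")
    if (anyDuplicated(labels)) stop("vertex labels must be unique")
  }
  structure(list(p = p, edges = edges, labels = labels),
            class = "grn_graph")
}

#' @export
print.grn_graph <- function(x, ...) {
  cat(sprintf("grn_graph: %d vertices, %d edges%s\n", x$p, nrow(x$edges),
              if (is.null(x$labels)) "" else " (labelled)"))
  invisible(x)
}

#' Edgeless graph on p vertices
#'
#' The empty graph has a zero Laplacian, so its shrinkage target is the
#' scaled identity \eqn{I/\epsilon}: using it turns gCDA into an
#' identity-target regularized discriminant analysis, the graph-agnostic
#' ablation baseline.
#'
#' @inheritParams grn_graph
#' @return A `grn_graph` with no edges.
#' @export
empty_graph <- function(p, labels = NULL) grn_graph(p, NULL, labels)

.edge_keys <- function(g) {
  if (nrow(g$edges) == 0L) return(double(0))
  (as.double(g$edges[, 1L]) - 1) * g$p + g$edges[, 2L]
}

#' Vertex degrees
#' @param g a `grn_graph`.
#' @return Integer vector of length `p`.
#' @export
graph_degrees <- function(g) {
  stopifnot(inherits(g, "grn_graph"))
  tabulate(c(g$edges[, 1L], g$edges[, 2L]), nbins = g$p)
}

#' Adjacency matrix
#' @param g a `grn_graph`.
#' @return Symmetric 0/1 matrix with zero diagonal; labelled dimnames when
#'   the graph is labelled.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "grn_graph"))
  A <- matrix(0, g$p, g$p)
  if (nrow(g$edges) > 0L) {
    A[g$edges] <- 1
    A[g$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  if (!is.null(g$labels)) dimnames(A) <- list(g$labels, g$labels)
  A
}

#' Graph Laplacian
#'
#' Returns \eqn{L = D - A}: vertex degrees on the diagonal, -1 on edges,
#' 0 elsewhere. `L` is symmetric, positive semi-definite, with zero row
#' sums; every zero off-diagonal entry corresponds to an absent edge, which
#' is what lets the Laplacian act as the precision-matrix skeleton of the
#' shrinkage target.
#'
#' @param g a `grn_graph`.
#' @return A symmetric `p` x `p` numeric matrix.
#' @seealso [shrinkage_target()]
#' @export
graph_laplacian <- function(g) {
  stopifnot(inherits(g, "grn_graph"))
  L <- -adjacency_matrix(g)
  diag(L) <- graph_degrees(g)
  L
}

#' Erdős–Rényi random graph
#'
#' Each of the p(p-1)/2 vertex pairs is included as an edge independently
#' with probability `edge_prob` (the G(n, p) model), delegated to
#' [igraph::sample_gnp()]. This is the generator used for the simulated
#' two-class datasets.
#'
#' @param p number of vertices.
#' @param edge_prob edge-inclusion probability in \[0, 1\].
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @param labels optional vertex labels.
#' @return A `grn_graph`.
#' @export
erdos_renyi_graph <- function(p, edge_prob, seed = NULL, labels = NULL) {
  if (!is.numeric(edge_prob) || length(edge_prob) != 1L || is.na(edge_prob) ||
      edge_prob < 0 || edge_prob > 1) {
    stop("'edge_prob' must be a probability in [0, 1]")
  }
  if (!is.numeric(p) || length(p) != 1L || p < 1) {
    stop("'p' must be a positive integer")
  }
  ed <- .with_seed(seed, {
    ig <- igraph::sample_gnp(as.integer(p), edge_prob)
    igraph::as_edgelist(ig, names = FALSE)
  })
  grn_graph(p, ed, labels)
}

# Uniform draw of one absent vertex pair by rejection sampling against the
# key set `present` (numeric keys (i-1)*p + j, i < j).
.draw_absent_pair <- function(p, present) {
  repeat {
    ij <- sort.int(sample.int(p, 2L))
    key <- (as.double(ij[1L]) - 1) * p + ij[2L]
    if (!(key %in% present)) return(ij)
  }
}

#' Randomly rewire edges of a graph
#'
#' Removes `n_moves` distinct edges chosen uniformly at random and replaces
#' each with a uniformly drawn, currently absent vertex pair (rejection
#' sampling), so the vertex and edge counts are preserved exactly. This is
#' the perturbation used to build graphs at increasing structural Hamming
#' distance from a reference graph.
#'
#' @param g a `grn_graph`.
#' @param n_moves number of edges to reassign; at most `|E|`.
#' @param seed optional integer seed.
#' @return A rewired `grn_graph` with the same `p`, `labels` and edge
#'   count. Each move changes at most 2 entries of the edge-set symmetric
#'   difference, so `hamming_distance(g, rewire_graph(g, k)) <= 2k`.
#' @export
rewire_graph <- function(g, n_moves, seed = NULL) {
  stopifnot(inherits(g, "grn_graph"))
  m <- nrow(g$edges)
  if (!is.numeric(n_moves) || length(n_moves) != 1L || n_moves < 0 ||
      n_moves != round(n_moves)) {
    stop("'n_moves' must be a single non-negative integer")
  }
  n_moves <- as.integer(n_moves)
  if (n_moves > m) stop("'n_moves' exceeds the number of edges")
  if (n_moves == 0L) return(g)
  .with_seed(seed, {
    drop_idx <- sample.int(m, n_moves)
    kept <- g$edges[-drop_idx, , drop = FALSE]
    keys <- (as.double(kept[, 1L]) - 1) * g$p + kept[, 2L]
    new_edges <- matrix(0L, n_moves, 2L)
    for (k in seq_len(n_moves)) {
      ij <- .draw_absent_pair(g$p, keys)
      new_edges[k, ] <- ij
      keys <- c(keys, (as.double(ij[1L]) - 1) * g$p + ij[2L])
    }
    grn_graph(g$p, rbind(kept, new_edges), g$labels)
  })
}

#' Structural Hamming distance between two graphs
#'
#' The number of vertex pairs on which the two edge sets disagree:
#' \eqn{|E_1 \cup E_2| - |E_1 \cap E_2|}, i.e. the size of the symmetric
#' difference of the edge sets. Zero iff the graphs are identical;
#' symmetric; satisfies the triangle inequality.
#'
#' @param g1,g2 `grn_graph`s on the same number of vertices.
#' @return A non-negative integer.
#' @export
hamming_distance <- function(g1, g2) {
  stopifnot(inherits(g1, "grn_graph"), inherits(g2, "grn_graph"))
  if (g1$p != g2$p) stop("graphs must have the same number of vertices")
  k1 <- .edge_keys(g1)
  k2 <- .edge_keys(g2)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Restrict a graph to a subset of vertices
#'
#' Keeps the listed vertices (by index) and the edges whose two endpoints
#' both survive; vertices are re-indexed to 1..length(keep) in the order
#' given.
#'
#' @param g a `grn_graph`.
#' @param keep integer vector of vertex indices to retain.
#' @return The induced `grn_graph`.
#' @export
subgraph_on <- function(g, keep) {
  stopifnot(inherits(g, "grn_graph"))
  keep <- as.integer(keep)
  if (any(keep < 1L) || any(keep > g$p) || anyDuplicated(keep)) {
    stop("'keep' must be distinct vertex indices in 1..p")
  }
  map <- rep(NA_integer_, g$p)
  map[keep] <- seq_along(keep)
  e <- g$edges
  ok <- !is.na(map[e[, 1L]]) & !is.na(map[e[, 2L]])
  grn_graph(length(keep), cbind(map[e[ok, 1L]], map[e[ok, 2L]]),
            if (is.null(g$labels)) NULL else g$labels[keep])
}

#' Read an edge list from delimited text
#'
#' Expects two columns of vertex labels, one edge per line; lines starting
#' with `#` are comments. The vertex set is `vertex_labels` when supplied
#' (labels in the file but absent from it are an error), otherwise the
#' sorted set of labels appearing in the file.
#'
#' @param path file path.
#' @param vertex_labels optional character vector fixing the vertex
#'   universe and its order.
#' @param sep field separator (default tab; any whitespace also accepted).
#' @return A labelled `grn_graph`.
#' @export
read_edgelist <- function(path, vertex_labels = NULL, sep = "\t") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L && is.null(vertex_labels)) {
    stop("empty edge list and no 'vertex_labels' given")
  }
  parts <- strsplit(lines, if (sep == "\t") "[\t ]+" else sep)
  bad <- vapply(parts, function(x) length(x) != 2L, logical(1))
  if (any(bad)) {
    stop(sprintf("line(s) without exactly two fields: %s",
                 paste(which(bad), collapse = ", ")))
  }
  a <- vapply(parts, `[`, character(1), 1L)
  b <- vapply(parts, `[`, character(1), 2L)
  if (is.null(vertex_labels)) vertex_labels <- sort(unique(c(a, b)))
  ia <- match(a, vertex_labels)
  ib <- match(b, vertex_labels)
  if (anyNA(ia) || anyNA(ib)) {
    unk <- unique(c(a[is.na(ia)], b[is.na(ib)]))
    stop(sprintf("edge endpoints not in vertex set: %s",
                 paste(unk, collapse = ", ")))
  }
  grn_graph(length(vertex_labels), cbind(ia, ib), vertex_labels)
}

#' Write a graph as an edge list
#'
#' @param g a labelled `grn_graph` (unlabelled graphs are written with
#'   indices as labels).
#' @param path output file path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path, sep = "\t") {
  stopifnot(inherits(g, "grn_graph"))
  labs <- if (is.null(g$labels)) as.character(seq_len(g$p)) else g$labels
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d vertices, %d edges", g$p, nrow(g$edges)), con)
  if (nrow(g$edges) > 0L) {
    writeLines(paste(labs[g$edges[, 1L]], labs[g$edges[, 2L]], sep = sep),
               con)
  }
  invisible(path)
}

#' Read a graph from a square adjacency matrix file
#'
#' Delimited numeric matrix with a header row and a first column of vertex
#' labels. The matrix must be symmetric and, unless `binarize = TRUE`,
#' contain only 0/1 entries: weighted adjacency is rejected rather than
#' silently thresholded. With `binarize = TRUE` any nonzero entry becomes
#' an edge.
#'
#' @param path file path.
#' @param binarize accept weighted entries and threshold nonzero -> edge.
#' @param sep field separator.
#' @return A labelled `grn_graph`.
#' @export
read_adjacency <- function(path, binarize = FALSE, sep = "\t") {
  A <- as.matrix(read.table(path, header = TRUE, row.names = 1L, sep = sep,
                            check.names = FALSE))
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (!identical(rownames(A), colnames(A))) {
    stop("row and column labels of the adjacency matrix differ")
  }
  if (!is.numeric(A) || anyNA(A)) stop("adjacency entries must be numeric")
  if (!binarize && any(!(A %in% c(0, 1)))) {
    stop("weighted adjacency rejected; use binarize = TRUE to threshold")
  }
  B <- (A != 0) * 1
  if (any(B != t(B))) stop("adjacency matrix must be symmetric")
  diag(B) <- 0
  idx <- which(B == 1 & upper.tri(B), arr.ind = TRUE)
  grn_graph(nrow(B), idx, rownames(A))
}
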