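#' Directed graph container
#'
#' A minimal directed-graph value used throughout the package: `n` neurons and
#' a set of directed edges `i -> j` meaning neuron `i`'s membrane potential
#' enters neuron `j`'s gap-junction sum. Indices are 1-based.
#'
#' @param n Number of nodes.
#' @param edges Two-column integer matrix, one row per directed edge
#'   (`from`, `to`), 1-based, no self-loops, no duplicates.
#' @return An object of class `directed_graph` with elements `n`, `edges`.
#' @export
directed_graph <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("from", "to")))
  stopifnot(n >= 1)
  if (nrow(edges) > 0) {
    stopifnot(all(edges >= 1L), all(edges <= n))
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed in a directed_graph")
    key <- (edges[, 1] - 1) * n + edges[, 2]
    if (anyDuplicated(key)) stop("duplicate directed edges")
    edges <- edges[order(key), , drop = FALSE]
  }
  structure(list(n = as.integer(n), edges = edges), class = "directed_graph")
}

#' @export
print.directed_graph <- function(x, ...) {
  cat(sprintf("directed_graph: %d nodes, %d directed edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' Number of directed edges
#' @param graph A `directed_graph`.
#' @return Integer edge count.
#' @export
edge_count <- function(graph) nrow(graph$edges)

#' Sparse adjacency matrix of a directed graph
#'
#' Returns the binary adjacency `C` with `C[i, j] = 1` iff there is an edge
#' `i -> j` (row = source, column = target).
#'
#' @param graph A `directed_graph`.
#' @return A sparse `Matrix::sparseMatrix` of dimension `n x n`.
#' @export
adjacency <- function(graph) {
  Matrix::sparseMatrix(i = graph$edges[, 1], j = graph$edges[, 2], x = 1,
                       dims = c(graph$n, graph$n))
}

# Linear index of the ordered off-diagonal pairs of an n x n matrix, used to
# sample directed non-self edges uniformly without replacement.
.pair_from_index <- function(idx, n) {
  idx <- idx - 1L
  i <- idx %/% (n - 1L)
  j <- idx %% (n - 1L)
  j <- ifelse(j >= i, j + 1L, j)
  cbind(from = i + 1L, to = j + 1L)
}

.edge_key <- function(edges, n) (edges[, 1] - 1) * n + (edges[, 2] - 1)

# Add or delete uniformly random directed edges so the graph has exactly
# `target` edges; used to pin BA (and oriented) graphs to the edge budget.
.adjust_edge_count <- function(edges, n, target) {
  m <- nrow(edges)
  if (m > target) {
    keep <- sample.int(m, target)
    return(edges[keep, , drop = FALSE])
  }
  if (m < target) {
    have <- .edge_key(edges, n)
    all_idx <- seq_len(n * (n - 1L))
    pool <- .pair_from_index(all_idx, n)
    pool_key <- .edge_key(pool, n)
    free <- which(!(pool_key %in% have))
    if (length(free) < target - m)
      stop("target_edges unreachable: graph cannot hold that many edges")
    add <- pool[sample(free, target - m), , drop = FALSE]
    edges <- rbind(edges, add)
  }
  edges
}

#' Directed Erdos-Renyi G(n, m) graph
#'
#' Draws exactly `target_edges` distinct directed non-self edges uniformly
#' without replacement (fixed-edge-count construction, so the edge budget is
#' met exactly rather than in expectation).
#'
#' @param n Node count.
#' @param target_edges Exact number of directed edges, at most `n * (n - 1)`.
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments including the seed.
#' @return A [directed_graph()].
#' @export
generate_er <- function(n, target_edges, seed) {
  if (target_edges <= 0 || target_edges > n * (n - 1))
    stop("target_edges must be in 1..n(n-1)")
  set.seed(seed)
  idx <- sample.int(n * (n - 1L), target_edges)
  directed_graph(n, .pair_from_index(idx, n))
}

#' Directed Watts-Strogatz small-world graph
#'
#' Builds the classical undirected ring lattice (each node linked to its
#' `neighbors` nearest neighbours) with rewiring probability `rewire_prob`,
#' then symmetrizes: every undirected edge contributes both directions, giving
#' `n * neighbors` directed edges (rewiring preserves the count).
#'
#' @param n Node count.
#' @param neighbors Even lattice degree (`< n`).
#' @param rewire_prob Rewiring probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [directed_graph()].
#' @export
generate_ws <- function(n, neighbors, rewire_prob = 0.1, seed = 1L) {
  if (neighbors %% 2 != 0) stop("neighbors must be even")
  if (neighbors >= n) stop("neighbors must be < n")
  if (rewire_prob < 0 || rewire_prob > 1) stop("rewire_prob must be in [0,1]")
  set.seed(seed)
  g <- igraph::sample_smallworld(1, n, neighbors / 2, rewire_prob,
                                 loops = FALSE, multiple = FALSE)
  und <- igraph::as_edgelist(g, names = FALSE)
  edges <- rbind(und, und[, 2:1])
  directed_graph(n, edges)
}

#' Directed Barabasi-Albert scale-free graph
#'
#' Grows an undirected preferential-attachment graph (each new node attaches
#' to `attach` existing nodes), orients every edge in a uniformly random
#' direction, then adds or deletes uniformly random directed edges to reach
#' `target_edges` exactly. The heavy-tailed degree distribution of the BA
#' skeleton survives the adjustment.
#'
#' @param n Node count.
#' @param attach Edges brought in by each new node (`1 <= attach < n`).
#' @param target_edges Exact directed edge count.
#' @param seed Integer seed.
#' @return A [directed_graph()].
#' @export
generate_ba <- function(n, attach, target_edges, seed) {
  if (attach < 1 || attach >= n) stop("attach must be in 1..n-1")
  if (target_edges <= 0 || target_edges > n * (n - 1))
    stop("target_edges unreachable: must be in 1..n(n-1)")
  set.seed(seed)
  g <- igraph::sample_pa(n, m = attach, directed = FALSE)
  und <- igraph::as_edgelist(g, names = FALSE)
  flip <- runif(nrow(und)) < 0.5
  edges <- cbind(ifelse(flip, und[, 2], und[, 1]),
                 ifelse(flip, und[, 1], und[, 2]))
  edges <- unique(edges)
  edges <- .adjust_edge_count(edges, n, target_edges)
  directed_graph(n, edges)
}

#' Load a connectome from an edge list or adjacency CSV
#'
#' Edge-list format: whitespace/tab-separated `source target` per line,
#' comment lines starting with `#`; indices 0-based by default
#' (`one_based = TRUE` for 1-based files). Adjacency format: CSV of an
#' `n x n` 0/1 matrix, row = source, column = target. Self-loops are dropped
#' with a warning; non-binary adjacency entries are an error (synaptic
#' weights are not modeled).
#'
#' @param path File path.
#' @param format `"edge_list"` or `"adjacency_csv"`.
#' @param one_based Edge-list indices are 1-based (default 0-based).
#' @param n Optional node count for edge lists (default: max index seen).
#' @return A [directed_graph()].
#' @export
load_connectome <- function(path, format = c("edge_list", "adjacency_csv"),
                            one_based = FALSE, n = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "edge_list") {
    tab <- read.table(path, comment.char = "#",
                      col.names = c("from", "to"),
                      colClasses = "integer")
    edges <- as.matrix(tab)
    if (!one_based) edges <- edges + 1L
    if (is.null(n)) n <- max(edges)
  } else {
    A <- as.matrix(read.csv(path, header = FALSE))
    if (nrow(A) != ncol(A))
      stop("adjacency matrix must be square: got ",
           nrow(A), " x ", ncol(A))
    if (!all(A %in% c(0, 1)))
      stop("adjacency entries must be binary 0/1 (weights are not modeled)")
    n <- nrow(A)
    edges <- which(A == 1, arr.ind = TRUE)
    colnames(edges) <- c("from", "to")
  }
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- directed_graph(n, edges)
  message(sprintf("loaded connectome: %d nodes, %d directed edges",
                  g$n, edge_count(g)))
  g
}

#' Write a directed graph to disk
#'
#' Emits either the edge-list or adjacency-CSV format accepted by
#' [load_connectome()]; a written graph re-reads bit-identically.
#'
#' @param graph A `directed_graph`.
#' @param path Output path.
#' @param format `"edge_list"` or `"adjacency_csv"`.
#' @param one_based Write 1-based edge-list indices (default 0-based).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path,
                             format = c("edge_list", "adjacency_csv"),
                             one_based = FALSE) {
  format <- match.arg(format)
  if (format == "edge_list") {
    edges <- graph$edges
    if (!one_based) edges <- edges - 1L
    write.table(edges, path, row.names = FALSE, col.names = FALSE,
                sep = "\t", quote = FALSE)
  } else {
    A <- as.matrix(adjacency(graph))
    write.table(A, path, row.names = FALSE, col.names = FALSE, sep = ",",
                quote = FALSE)
  }
  invisible(path)
}

#' Draw per-neuron constant stimulus currents
#'
#' Independent uniform draws on `[lo, hi]` microamperes (per 1 cm^2 membrane
#' area), one constant current per neuron for the whole run.
#'
#' @param n Number of neurons.
#' @param lo,hi Range in microamperes; defaults 7-30.
#' @param seed Integer seed.
#' @return Numeric vector of length `n`.
#' @export
draw_stimulus <- function(n, lo = 7, hi = 30, seed = 1L) {
  if (lo >= hi) stop("stimulus range degenerate: need lo < hi")
  set.seed(seed)
  runif(n, lo, hi)
}

#' Validate the directed-graph invariants
#'
#' Checks: no self-loops, all indices in range, no duplicate edges, binary
#' adjacency. Called by tests; errors on violation.
#'
#' @param graph A `directed_graph`.
#' @return `TRUE` invisibly.
#' @export
validate_graph <- function(graph) {
  stopifnot(inherits(graph, "directed_graph"))
  e <- graph$edges
  if (nrow(e) > 0) {
    stopifnot(all(e >= 1L), all(e <= graph$n), all(e[, 1] != e[, 2]))
    stopifnot(!anyDuplicated(.edge_key(e, graph$n)))
  }
  A <- adjacency(graph)
  stopifnot(all(A@x %in% c(0, 1)), sum(A) == nrow(e))
  invisible(TRUE)
}
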