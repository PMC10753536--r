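# Graph data model shared by all layers.
#
# A molecular graph is stored with DIRECTED edges: every undirected bond
# e(i,j) appears as the ordered pair i->j and j->i, each with its own feature
# row. Undirected quantities are derived from the pair via `rev_index`.
# Node indices are 1-based and dense per graph. Edges are kept sorted
# lexicographically by (src, dst) so identical graphs are bitwise identical
# regardless of construction order.

#' Construct a molecular graph
#'
#' @param node_count number of nodes `n` (>= 0).
#' @param edges integer matrix with columns `src`, `dst`; one row per directed
#'   edge. For every row `i -> j` the reverse `j -> i` must be present
#'   (a self-loop is its own reverse). Rows are re-sorted lexicographically.
#' @param node_features numeric matrix, `node_count` rows.
#' @param edge_features numeric matrix, one row per directed edge (aligned
#'   with `edges` before sorting).
#' @param node_provenance list of integer vectors: for each node, the original
#'   atom indices it represents. Defaults to singletons `1..n`. The sets must
#'   partition their union.
#' @param validate check invariants (disable only in hot paths).
#' @return An object of class `molgraph` with fields `n`, `edges`,
#'   `node_features`, `edge_features`, `rev_index` (position of each directed
#'   edge's reverse), `node_provenance`.
#' @examples
#' g <- make_path(3, d_v = 2, d_e = 2, seed = 1)
#' g$n
#' neighbors(g, 2)
#' @export
molgraph <- function(node_count, edges, node_features, edge_features,
                     node_provenance = NULL, validate = TRUE) {
  n <- as.integer(node_count)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), 0L, 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  colnames(edges) <- c("src", "dst")
  if (!is.matrix(node_features)) node_features <- matrix(node_features, nrow = n)
  if (nrow(edges) == 0L && (is.null(edge_features) || length(edge_features) == 0L)) {
    edge_features <- matrix(numeric(0), 0L, ncol = max(1L, ncol(edge_features %||% matrix(0, 0, 1))))
  }
  if (!is.matrix(edge_features)) edge_features <- matrix(edge_features, nrow = nrow(edges))
  ord <- order(edges[, 1L], edges[, 2L])
  edges <- edges[ord, , drop = FALSE]
  edge_features <- edge_features[ord, , drop = FALSE]
  if (is.null(node_provenance)) node_provenance <- as.list(seq_len(n))
  node_provenance <- lapply(node_provenance, function(v) sort(as.integer(v)))
  g <- structure(
    list(n = n, edges = edges,
         node_features = node_features, edge_features = edge_features,
         rev_index = .rev_index(edges),
         node_provenance = node_provenance),
    class = "molgraph")
  if (validate) validate_molgraph(g)
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.rev_index <- function(edges) {
  if (nrow(edges) == 0L) return(integer(0))
  key <- paste(edges[, 1L], edges[, 2L])
  rkey <- paste(edges[, 2L], edges[, 1L])
  idx <- match(rkey, key)
  if (anyNA(idx)) stop("every directed edge i->j must have its reverse j->i")
  idx
}

#' Validate molecular-graph invariants
#'
#' Checks index ranges, reverse pairing, feature-matrix shapes, and that the
#' provenance sets are pairwise disjoint (they partition the original atoms).
#'
#' @param g `molgraph`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_molgraph <- function(g) {
  stopifnot(inherits(g, "molgraph"))
  if (g$n < 0L) stop("node_count must be nonnegative")
  if (nrow(g$edges) > 0L) {
    if (any(g$edges < 1L) || any(g$edges > g$n)) {
      stop("edge endpoint outside [1, n]")
    }
  }
  if (nrow(g$node_features) != g$n) {
    stop("node_features must have node_count rows")
  }
  if (nrow(g$edge_features) != nrow(g$edges)) {
    stop("edge_features must have one row per directed edge")
  }
  if (length(g$node_provenance) != g$n) {
    stop("node_provenance must have one entry per node")
  }
  prov <- unlist(g$node_provenance, use.names = FALSE)
  if (anyDuplicated(prov)) stop("node_provenance sets must be pairwise disjoint")
  invisible(g)
}

#' Number of undirected edges of a graph
#'
#' Self-loops (their own reverse) count once.
#'
#' @param g `molgraph`.
#' @return Integer count `m`.
#' @export
n_undirected <- function(g) {
  if (nrow(g$edges) == 0L) return(0L)
  loops <- sum(g$edges[, 1L] == g$edges[, 2L])
  as.integer((nrow(g$edges) - loops) / 2L + loops)
}

# index of one canonical directed representative per undirected edge
# (src <= dst; self-loops included once)
.undirected_reps <- function(g) {
  which(g$edges[, 1L] <= g$edges[, 2L])
}

#' Neighbor set of a node
#'
#' Returns `{j : directed edge j->i exists}`; a self-loop contributes `i`
#' itself.
#'
#' @param g `molgraph`.
#' @param i node index in 1..n.
#' @return Sorted integer vector (possibly empty) of unique neighbors.
#' @export
neighbors <- function(g, i) {
  i <- as.integer(i)
  if (i < 1L || i > g$n) stop("node index out of range")
  sort(unique(g$edges[g$edges[, 2L] == i, 1L]))
}

#' Connected components of a node/edge subset
#'
#' Partitions `node_subset` into the connected components of the subgraph
#' induced by `edge_subset` (plain union-find; pooled subgraphs always carry
#' both directions of every edge, so weak and strong connectivity coincide).
#'
#' @param node_subset integer vector of node ids.
#' @param edge_subset integer matrix with 2 columns (or NULL/empty); every
#'   endpoint must lie in `node_subset`.
#' @return List of sorted integer vectors, ordered by smallest member;
#'   pairwise disjoint with union `node_subset`.
#' @export
connected_subsets <- function(node_subset, edge_subset = NULL) {
  nodes <- sort(unique(as.integer(node_subset)))
  if (length(nodes) == 0L) return(list())
  if (is.null(edge_subset) || length(edge_subset) == 0L) {
    edge_subset <- matrix(integer(0), 0L, 2L)
  }
  edge_subset <- matrix(as.integer(edge_subset), ncol = 2L)
  if (nrow(edge_subset) > 0L && !all(edge_subset %in% nodes)) {
    stop("edge endpoint outside node_subset")
  }
  parent <- seq_along(nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  a <- match(edge_subset[, 1L], nodes)
  b <- match(edge_subset[, 2L], nodes)
  for (k in seq_len(nrow(edge_subset))) {
    ra <- find(a[k]); rb <- find(b[k])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comps <- split(nodes, roots)
  comps <- unname(comps)
  comps[order(vapply(comps, min, integer(1)))]
}

#' Relabel the nodes of a graph
#'
#' Node `i` of the input becomes node `perm[i]` of the output; features,
#' edges and provenance move consistently. Mainly test support for
#' permutation-equivariance properties.
#'
#' @param g `molgraph`.
#' @param perm integer vector, a bijection on `1..n`.
#' @return The permuted `molgraph`.
#' @export
permute_graph <- function(g, perm) {
  perm <- as.integer(perm)
  if (length(perm) != g$n || !setequal(perm, seq_len(g$n))) {
    stop("perm must be a bijection on 1..n")
  }
  inv <- integer(g$n)
  inv[perm] <- seq_len(g$n)
  edges <- cbind(perm[g$edges[, 1L]], perm[g$edges[, 2L]])
  molgraph(g$n, edges,
           g$node_features[inv, , drop = FALSE],
           g$edge_features,   # rows re-sorted by the constructor
           node_provenance = g$node_provenance[inv])
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d nodes, %d undirected edges (%d directed rows)\n",
              x$n, n_undirected(x), nrow(x$edges)))
  cat(sprintf("  node features: %d x %d; edge features: %d x %d\n",
              nrow(x$node_features), ncol(x$node_features),
              nrow(x$edge_features), ncol(x$edge_features)))
  n_super <- sum(lengths(x$node_provenance) > 1L)
  if (n_super > 0L) cat(sprintf("  supernodes: %d\n", n_super))
  invisible(x)
}

# ---- batching ---------------------------------------------------------------

#' Combine graphs into one disjoint-union batch
#'
#' Node indices are offset so member graphs occupy disjoint ranges. Per-graph
#' readouts over a batch equal the readouts of the members processed singly.
#'
#' @param graphs list of `molgraph` objects with equal feature widths.
#' @return An object of class `molgraph_batch`: a `molgraph` plus
#'   `graph_of_node` (node index -> graph index) and `n_graphs`.
#' @export
batch_graphs <- function(graphs) {
  stopifnot(length(graphs) > 0L)
  ns <- vapply(graphs, function(g) g$n, integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(k) {
    e <- graphs[[k]]$edges
    if (nrow(e) == 0L) return(matrix(integer(0), 0L, 2L))
    e + offs[k]
  }))
  nf <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  ef <- do.call(rbind, lapply(graphs, `[[`, "edge_features"))
  prov <- unlist(lapply(seq_along(graphs), function(k) {
    lapply(graphs[[k]]$node_provenance, function(v) v)  # atom ids stay per-molecule
  }), recursive = FALSE)
  b <- molgraph(sum(ns), edges, nf, ef, node_provenance = NULL, validate = FALSE)
  b$node_provenance <- prov
  b$graph_of_node <- rep.int(seq_along(graphs), ns)
  b$n_graphs <- length(graphs)
  class(b) <- c("molgraph_batch", "molgraph")
  b
}

# graph membership helper that also works for a single (unbatched) graph
.graph_of_node <- function(g) {
  g$graph_of_node %||% rep.int(1L, g$n)
}

.n_graphs <- function(g) g$n_graphs %||% 1L

#' Summation readout
#'
#' Graph-level representation: the sum of node feature vectors per graph
#' (a zero vector for an empty graph).
#'
#' @param g `molgraph` or `molgraph_batch`.
#' @param node_features optional override (matrix or adnode) for the node
#'   feature matrix, e.g. hidden features mid-model.
#' @return `n_graphs x d` matrix (or adnode).
#' @export
readout_sum <- function(g, node_features = NULL) {
  h <- node_features %||% g$node_features
  ad_scatter_sum(h, .graph_of_node(g), .n_graphs(g))
}
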