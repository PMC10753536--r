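# Independent oracles and shared test utilities. These deliberately avoid the
# package's own code paths: dense adjacency algebra, BFS flood fill, and
# direct per-element evaluation of the layer equations.

# dense adjacency matrix (counts parallel/self entries) from a molgraph
dense_adjacency <- function(g) {
  A <- matrix(0, g$n, g$n)
  for (k in seq_len(nrow(g$edges))) {
    A[g$edges[k, 1L], g$edges[k, 2L]] <- A[g$edges[k, 1L], g$edges[k, 2L]] + 1
  }
  A
}

# BFS flood fill components, independent of the union-find implementation
bfs_components <- function(nodes, edges) {
  nodes <- sort(unique(as.integer(nodes)))
  adj <- lapply(stats::setNames(vector("list", length(nodes)), nodes), c)
  if (!is.null(edges) && nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      a <- as.character(edges[k, 1L]); b <- as.character(edges[k, 2L])
      adj[[a]] <- c(adj[[a]], edges[k, 2L])
      adj[[b]] <- c(adj[[b]], edges[k, 1L])
    }
  }
  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  comps <- list()
  for (start in nodes) {
    if (seen[[as.character(start)]]) next
    queue <- start
    comp <- integer(0)
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      key <- as.character(v)
      if (seen[[key]]) next
      seen[[key]] <- TRUE
      comp <- c(comp, v)
      queue <- c(queue, adj[[key]])
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# direct per-edge evaluation of the EGIN edge update (relu(W (he||hsrc) + b))
oracle_edge_update <- function(g, W, b, he = g$edge_features,
                               hv = g$node_features, act = identity) {
  out <- matrix(0, nrow(g$edges), ncol(W))
  for (k in seq_len(nrow(g$edges))) {
    z <- c(he[k, ], hv[g$edges[k, 1L], ]) %*% W + b
    out[k, ] <- act(z)
  }
  out
}

# direct per-node evaluation of the EGIN node update with identity MLP
oracle_node_update <- function(g, he_updated, hv = g$node_features) {
  d_e <- ncol(he_updated)
  out <- matrix(0, g$n, ncol(hv) + d_e)
  for (i in seq_len(g$n)) {
    incoming <- which(g$edges[, 2L] == i)
    msg <- if (length(incoming)) colSums(he_updated[incoming, , drop = FALSE])
           else numeric(d_e)
    out[i, ] <- c(hv[i, ], msg)
  }
  out
}

# direct per-edge evaluation of the selection message propagation
# (identity MLP): h_p(i->j) = h(i->j) + sum_k h(k->i); h_und = h_p + h_p(rev)
oracle_propagate <- function(g, he = g$edge_features) {
  h_p <- matrix(0, nrow(g$edges), ncol(he))
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges[k, 1L]
    into_i <- which(g$edges[, 2L] == i)
    agg <- if (length(into_i)) colSums(he[into_i, , drop = FALSE])
           else numeric(ncol(he))
    h_p[k, ] <- he[k, ] + agg
  }
  h_p + h_p[g$rev_index, , drop = FALSE]
}

# Mann-Whitney rank-statistic AUC
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  comp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(comp)
}

# identity-configured EGIN parameters: edge update is a passthrough of the
# edge feature block (W = [I; 0], identity activation), node MLP is identity
identity_egin_params <- function(d_v, d_e) {
  W <- rbind(diag(d_e), matrix(0, d_v, d_e))
  list(edge = list(W = W, b = matrix(0, 1L, d_e), act = "identity"),
       node = list(mlp = NULL))
}

random_molgraphs <- function(n_graphs, max_n = 30L, d_v = 4L, d_e = 4L,
                             seed = 1) {
  lapply(seq_len(n_graphs), function(k) {
    set.seed(seed + 7L * k)
    n <- sample(3:max_n, 1L)
    p <- stats::runif(1, 0.1, 0.6)
    make_random_graph(n, p, d_v = d_v, d_e = d_e, seed = seed + 7L * k + 1L)
  })
}
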