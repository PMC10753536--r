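# The edge-shrinkage pooling layer, in the selection / reduction / connection
# decomposition:
#   selection  — propagate edge messages, score undirected edges with a
#                sigmoid-squashed linear form, split at
#                threshold = min(lambda, mean score);
#   reduction  — find connected components of the pooled subgraph, refine their
#                features with a dedicated EGIN pass, sum members into
#                supernode features;
#   connection — remap preserved edges onto the new node set and merge
#                repeated edges (including self-loops) by summing their rows.
#
# The mean-score cap guarantees the top-scoring edge always survives, so a
# graph is never contracted to a single point in one step. On a batch,
# the mean and threshold are computed per member graph.

#' Edge message propagation for scoring
#'
#' Computes `h^p_{i->j} = MLP(h_{i->j} + sum_{k in N(i)} h_{k->i})` for every
#' directed edge, then the symmetric undirected feature
#' `h_{e(i,j)} = h^p_{i->j} + h^p_{j->i}`. The sum over `k` runs over all
#' edges into the starting node `i`, including `j->i`.
#'
#' @param g `molgraph`.
#' @param p list with `mlp` ([mlp_params()] or `NULL` for identity).
#' @param edge_features optional override for `g$edge_features`.
#' @param train,coll,path training-mode plumbing.
#' @return List with `h_p` (directed rows) and `h_und` (one row per directed
#'   edge, equal for the two directions of a bond).
#' @export
propagate_edge_messages <- function(g, p, edge_features = NULL,
                                    train = FALSE, coll = NULL,
                                    path = "pool.prop") {
  he <- edge_features %||% g$edge_features
  agg <- ad_scatter_sum(he, g$edges[, 2L], g$n)       # incoming sums per node
  msg <- ad_add(he, ad_rows(agg, g$edges[, 1L]))      # + sums at starting node
  h_p <- mlp_apply(p$mlp %||% NULL, msg, train, coll, path)
  h_und <- ad_add(h_p, ad_rows(h_p, g$rev_index))
  list(h_p = h_p, h_und = h_und)
}

#' Score undirected edges
#'
#' `s_e = sigmoid(s^T h_e)`, one score per directed row; the two directions of
#' a bond share their score because `h_und` is symmetric.
#'
#' @param h_und undirected edge features (matrix or adnode), one row per
#'   directed edge.
#' @param svec scoring vector (d_e x 1 matrix or adnode).
#' @return Column of scores in (0, 1) (matrix or adnode).
#' @export
score_edges <- function(h_und, svec) {
  if (!is.matrix(ad_value(svec))) svec <- matrix(as.numeric(svec), ncol = 1L)
  if (ncol(ad_value(h_und)) != nrow(ad_value(svec))) {
    stop("scoring vector width does not match edge features")
  }
  ad_sigmoid(ad_matmul(h_und, svec))
}

#' Scale directed edge features by their bond score
#'
#' `h'_{i->j} = s_{e(i,j)} * h^p_{i->j}` — both directions scaled by the same
#' score; this is the path through which the scoring vector receives gradient.
#'
#' @param h_p directed edge features (matrix or adnode).
#' @param scores per-directed-edge score column (matrix or adnode).
#' @return Scaled features (matrix or adnode).
#' @export
scale_edge_features <- function(h_p, scores) {
  ad_scale_rows(h_p, scores)
}

#' Pooling threshold
#'
#' `min(lambda, mean(scores))` over the undirected edge scores of one graph.
#'
#' @param scores numeric vector of undirected edge scores (>= 1).
#' @param lambda hyperparameter in (0, 1].
#' @return Scalar threshold.
#' @export
compute_threshold <- function(scores, lambda) {
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  if (length(scores) == 0L) stop("threshold undefined for an empty score list")
  min(lambda, mean(scores))
}

#' Select the pooled edge and node sets
#'
#' An undirected edge is pooled when its score is strictly below
#' `min(lambda, s_mean)`; ties at the threshold survive. On a
#' `molgraph_batch`, means and thresholds are computed per member graph.
#' Because the maximum score is never below the mean, at least one edge
#' always survives.
#'
#' @param g `molgraph` or `molgraph_batch`.
#' @param scores per-directed-edge score column (matrix, adnode, or vector).
#' @param lambda hyperparameter in (0, 1].
#' @return Object of class `pooling_selection`: `scores` (undirected, named by
#'   representative directed row), `threshold` (per graph), `pooled_dir`
#'   (directed row indices), `pooled_und` (representative rows), `v_pool`
#'   (endpoint node ids), `lambda`.
#' @export
select_edges <- function(g, scores, lambda) {
  if (lambda <= 0 || lambda > 1) stop("lambda must lie in (0, 1]")
  s <- as.numeric(ad_value(scores))
  stopifnot(length(s) == nrow(g$edges))
  reps <- .undirected_reps(g)
  gon <- .graph_of_node(g)
  ngr <- .n_graphs(g)
  rep_graph <- gon[g$edges[reps, 1L]]
  thr <- rep(NA_real_, ngr)
  means <- tapply(s[reps], rep_graph, mean)
  thr[as.integer(names(means))] <- pmin(lambda, means)
  sel_rep <- reps[s[reps] < thr[rep_graph]]
  pooled_dir <- sort(unique(c(sel_rep, g$rev_index[sel_rep])))
  v_pool <- sort(unique(as.integer(g$edges[pooled_dir, ])))
  structure(list(scores = s[reps], threshold = thr,
                 pooled_dir = pooled_dir, pooled_und = sel_rep,
                 v_pool = v_pool, lambda = lambda),
            class = "pooling_selection")
}

#' @export
print.pooling_selection <- function(x, ...) {
  cat(sprintf("<pooling_selection> %d/%d undirected edges pooled, %d nodes; threshold %s\n",
              length(x$pooled_und), length(x$scores), length(x$v_pool),
              paste(signif(x$threshold, 4), collapse = ", ")))
  invisible(x)
}

#' Reduction: shrink pooled substructures into supernodes
#'
#' Finds the connected components of the pooled subgraph, refines it with a
#' dedicated EGIN pass consuming the score-scaled edge features, and sums the
#' refined member features into one supernode feature per component. With
#' `p = NULL` the EGIN pass is the identity and each supernode feature is the
#' plain sum of its members' features.
#'
#' @param g `molgraph`.
#' @param sel [select_edges()] result; must be nonempty.
#' @param p EGIN parameters for the pooled subgraph ([egin_params()] layout),
#'   or `NULL` for the identity configuration.
#' @param edge_features_scaled score-scaled directed edge features (the
#'   [scale_edge_features()] output; matrix or adnode), aligned with `g$edges`.
#' @param node_features optional override.
#' @param train,coll,path training-mode plumbing.
#' @return List with `components` (list of member-id vectors, ordered by
#'   smallest member), `h_super` (K x d matrix/adnode), `provenance` (list of
#'   original-atom sets per supernode).
#' @export
reduce_selection <- function(g, sel, p, edge_features_scaled,
                             node_features = NULL, train = FALSE,
                             coll = NULL, path = "pool.reduce") {
  stopifnot(length(sel$pooled_und) > 0L)
  hv <- node_features %||% g$node_features
  pooled_edges <- g$edges[sel$pooled_dir, , drop = FALSE]
  components <- connected_subsets(sel$v_pool, pooled_edges)
  # pooled subgraph in local indices
  sub_nodes <- sel$v_pool
  loc <- integer(g$n)
  loc[sub_nodes] <- seq_along(sub_nodes)
  sub_g <- list(n = length(sub_nodes),
                edges = cbind(loc[pooled_edges[, 1L]], loc[pooled_edges[, 2L]]))
  he_sub <- ad_rows(edge_features_scaled, sel$pooled_dir)
  hv_sub <- ad_rows(hv, sub_nodes)
  if (!is.null(p)) {
    he_new <- egin_edge_update(sub_g, p$edge, he_sub, hv_sub)
    hv_sub <- egin_node_update(sub_g, p$node, he_new, hv_sub, train, coll,
                               paste0(path, ".node.mlp"))
  }
  comp_of <- integer(length(sub_nodes))
  for (k in seq_along(components)) comp_of[loc[components[[k]]]] <- k
  h_super <- ad_scatter_sum(hv_sub, comp_of, length(components))
  provenance <- lapply(components, function(members) {
    sort(unlist(g$node_provenance[members], use.names = FALSE))
  })
  list(components = components, h_super = h_super, provenance = provenance)
}

#' Connection: rebuild the pooled graph
#'
#' Survivor nodes keep their identity (in original order), followed by the
#' supernodes (in component order). Every preserved directed edge has its
#' endpoints remapped; repeated directed edges with identical remapped
#' endpoints are merged by summing their feature rows. An edge whose endpoints
#' land in the same supernode becomes a self-loop and is kept.
#'
#' @param g `molgraph` (or batch).
#' @param sel [select_edges()] result.
#' @param red [reduce_selection()] result.
#' @param node_features,edge_features current features (matrix or adnode);
#'   defaults to the graph's own.
#' @return Object of class `pooled_graph`: `graph` (the new `molgraph`, plain
#'   numeric), `node_features`/`edge_features` (possibly adnodes, aligned with
#'   `graph`), `node_map` (old node -> new node), `premerge_edges` and
#'   `premerge_features` (remapped preserved edges before merging),
#'   `components`, `selection`.
#' @export
reconnect <- function(g, sel, red, node_features = NULL, edge_features = NULL) {
  hv <- node_features %||% g$node_features
  he <- edge_features %||% g$edge_features
  survivors <- setdiff(seq_len(g$n), sel$v_pool)
  K <- length(red$components)
  n_new <- length(survivors) + K
  node_map <- integer(g$n)
  node_map[survivors] <- seq_along(survivors)
  for (k in seq_len(K)) node_map[red$components[[k]]] <- length(survivors) + k

  hv_new <- if (K > 0L) {
    if (length(survivors) > 0L) ad_rbind(ad_rows(hv, survivors), red$h_super)
    else red$h_super
  } else ad_rows(hv, survivors)

  preserved <- setdiff(seq_len(nrow(g$edges)), sel$pooled_dir)
  pre_edges <- cbind(node_map[g$edges[preserved, 1L]],
                     node_map[g$edges[preserved, 2L]])
  pre_feat <- ad_rows(he, preserved)

  if (nrow(pre_edges) > 0L) {
    key <- paste(pre_edges[, 1L], pre_edges[, 2L])
    uniq <- !duplicated(key)
    new_edges <- pre_edges[uniq, , drop = FALSE]
    ord <- order(new_edges[, 1L], new_edges[, 2L])
    new_edges <- new_edges[ord, , drop = FALSE]
    group <- match(key, paste(new_edges[, 1L], new_edges[, 2L]))
    he_new <- ad_scatter_sum(pre_feat, group, nrow(new_edges))
  } else {
    new_edges <- matrix(integer(0), 0L, 2L)
    he_new <- ad_rows(he, integer(0))
  }

  prov_new <- c(g$node_provenance[survivors], red$provenance)
  gn <- molgraph(n_new, new_edges, ad_value(hv_new), ad_value(he_new),
                 node_provenance = prov_new, validate = FALSE)
  if (!is.null(g$graph_of_node)) {
    owners <- c(survivors, vapply(red$components, `[`, integer(1), 1L))
    gn$graph_of_node <- g$graph_of_node[owners]
    gn$n_graphs <- g$n_graphs
    class(gn) <- class(g)
  }
  # constructor sorts rows; keep features aligned with the (already sorted)
  # edge order used to build he_new
  structure(list(graph = gn, node_features = hv_new, edge_features = he_new,
                 node_map = node_map, premerge_edges = pre_edges,
                 premerge_features = pre_feat,
                 components = red$components, selection = sel),
            class = "pooled_graph")
}

#' @export
print.pooled_graph <- function(x, ...) {
  cat(sprintf("<pooled_graph> %d -> %d nodes, %d supernode(s)\n",
              length(x$node_map), x$graph$n, length(x$components)))
  invisible(x)
}

#' Fresh pooling-layer parameters
#'
#' @param d_e,d_v incoming edge / node widths.
#' @param use_norm batch normalization inside the MLPs.
#' @return List with `prop` (message MLP), `svec` (scoring vector), `egin`
#'   (reduction EGIN, its own parameters).
#' @export
mespool_params <- function(d_v, d_e, use_norm = TRUE) {
  list(prop = list(mlp = mlp_params(d_e, d_e, d_e, use_norm)),
       svec = .init_mat(d_e, 1L),
       egin = egin_params(d_v, d_e, d_v, use_norm))
}

#' One full edge-shrinkage pooling layer
#'
#' Runs selection (message propagation, scoring, threshold split), reduction
#' (component finding, EGIN refinement, member summation) and connection
#' (remapping and merging of preserved edges). If the graph has no edges, or
#' no edge scores below the threshold, the input is returned unchanged with an
#' empty selection.
#'
#' @param g `molgraph` or `molgraph_batch`.
#' @param params [mespool_params()] list; `NULL` gives the identity
#'   configuration (identity message MLP, zero scoring vector, identity
#'   reduction EGIN) used by structural tests.
#' @param lambda split hyperparameter in (0, 1] (default 0.5).
#' @param node_features,edge_features optional overrides (matrix or adnode).
#' @param scores optional externally supplied per-directed-edge scores
#'   (skips propagation/scoring; used to probe specific selections).
#' @param train,coll,path training-mode plumbing.
#' @return List with `graph` (pooled `molgraph`), `selection`
#'   (`pooling_selection` or `NULL` when the layer was a no-op),
#'   `node_features`, `edge_features` (aligned with `graph`; adnodes when the
#'   inputs were), and `pooled` (the full `pooled_graph`, or `NULL`).
#' @export
mespool_layer <- function(g, params = NULL, lambda = 0.5,
                          node_features = NULL, edge_features = NULL,
                          scores = NULL, train = FALSE, coll = NULL,
                          path = "pool") {
  stopifnot(g$n >= 1L)
  hv <- node_features %||% g$node_features
  he <- edge_features %||% g$edge_features
  if (nrow(g$edges) == 0L) {
    return(list(graph = g, selection = NULL, node_features = hv,
                edge_features = he, pooled = NULL))
  }
  if (is.null(scores)) {
    prop <- propagate_edge_messages(g, params$prop %||% list(mlp = NULL), he,
                                    train, coll, paste0(path, ".prop.mlp"))
    svec <- params$svec %||% matrix(0, ncol(ad_value(prop$h_und)), 1L)
    scr <- score_edges(prop$h_und, svec)
    h_p <- prop$h_p
  } else {
    scr <- scores
    h_p <- he
  }
  sel <- select_edges(g, scr, lambda)
  h_scaled <- scale_edge_features(h_p, scr)
  if (length(sel$pooled_und) == 0L) {
    return(list(graph = g, selection = sel, node_features = hv,
                edge_features = h_scaled, pooled = NULL))
  }
  red <- reduce_selection(g, sel, params$egin %||% NULL, h_scaled, hv,
                          train, coll, paste0(path, ".egin"))
  pg <- reconnect(g, sel, red, hv, h_scaled)
  list(graph = pg$graph, selection = sel, node_features = pg$node_features,
       edge_features = pg$edge_features, pooled = pg)
}
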