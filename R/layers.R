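# Graph convolution layers: the GIN baseline and the edge-featured EGIN,
# which alternates a directed-edge update with a node update.
#
# All layer functions accept plain matrices or adnodes for the feature
# arguments, so the same code path serves numeric tests and training.

.ACTIVATIONS <- c("relu", "identity", "sigmoid")

.apply_act <- function(x, act) {
  switch(act,
         relu = ad_relu(x),
         identity = x,
         sigmoid = ad_sigmoid(x),
         stop("unknown activation: ", act))
}

.init_mat <- function(d_in, d_out) {
  matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / max(1, d_in))), d_in, d_out)
}

#' Two-layer MLP parameters (Linear -> norm -> ReLU -> Linear)
#'
#' Batch normalization sits between the first linear map and the
#' nonlinearity; `use_norm = FALSE` removes it. Running mean/variance buffers
#' are carried alongside the trainable weights and used at evaluation time.
#'
#' @param d_in,d_hidden,d_out layer widths.
#' @param use_norm include batch normalization.
#' @return Named list of parameter matrices and buffers.
#' @export
mlp_params <- function(d_in, d_hidden, d_out, use_norm = TRUE) {
  p <- list(W1 = .init_mat(d_in, d_hidden), b1 = matrix(0, 1L, d_hidden),
            W2 = .init_mat(d_hidden, d_out), b2 = matrix(0, 1L, d_out),
            use_norm = use_norm)
  if (use_norm) {
    p$gamma <- matrix(1, 1L, d_hidden)
    p$beta <- matrix(0, 1L, d_hidden)
    p$rmean <- matrix(0, 1L, d_hidden)   # buffer, not trained
    p$rvar <- matrix(1, 1L, d_hidden)    # buffer, not trained
  }
  p
}

# Apply an MLP. `p = NULL` means identity (test configuration).
# In training mode batch statistics are used and reported through the
# collector environment `coll` under `path` for running-buffer updates.
mlp_apply <- function(p, x, train = FALSE, coll = NULL, path = "") {
  if (is.null(p)) return(x)
  h <- ad_add_bias(ad_matmul(x, p$W1), p$b1)
  if (isTRUE(p$use_norm) && nrow(ad_value(h)) > 0L) {
    if (train && nrow(ad_value(h)) > 1L) {
      mu <- ad_colmeans(h)
      xc <- ad_sub_rowvec(h, mu)
      v <- ad_colmeans(ad_mul(xc, xc))
      xhat <- ad_mul_rowvec(xc, ad_rsqrt(v, 1e-5))
      if (!is.null(coll)) {
        coll$stats[[path]] <- list(mean = ad_value(mu), var = ad_value(v))
      }
    } else {
      istd <- 1 / sqrt(as.numeric(p$rvar) + 1e-5)
      xhat <- ad_mul_rowvec(ad_sub_rowvec(h, p$rmean), matrix(istd, 1L))
    }
    h <- ad_add_bias(ad_mul_rowvec(xhat, p$gamma), p$beta)
  }
  ad_add_bias(ad_matmul(ad_relu(h), p$W2), p$b2)
}

# sum of incoming directed-edge feature rows per node:
# agg[i, ] = sum over edges k->i of edge_features[row, ]
.aggregate_incoming <- function(g, edge_features) {
  ad_scatter_sum(edge_features, g$edges[, 2L], g$n)
}

#' GIN convolution layer
#'
#' Node update `h_i <- MLP((1 + eps) * h_i + sum_{j in N(i)} h_j)`; edge
#' features are untouched. A self-loop contributes the node's own feature once
#' to its aggregation.
#'
#' @param g `molgraph`.
#' @param p list with `eps` (scalar or 1x1 matrix/adnode) and `mlp`
#'   ([mlp_params()] list, or `NULL` for the identity configuration).
#' @param node_features optional override for `g$node_features`.
#' @param train,coll,path training-mode plumbing (see [mlp_params()]).
#' @return Updated node feature matrix (or adnode).
#' @export
gin_layer <- function(g, p, node_features = NULL, train = FALSE,
                      coll = NULL, path = "gin") {
  x <- node_features %||% g$node_features
  if (!is.null(p$mlp) && ncol(ad_value(x)) != nrow(ad_value(p$mlp$W1))) {
    stop("node feature width does not match layer parameters")
  }
  eps <- p$eps %||% 0
  if (!is_adnode(eps) && !is.matrix(eps)) eps <- matrix(eps, 1L, 1L)
  agg <- ad_scatter_sum(ad_rows(x, g$edges[, 1L]), g$edges[, 2L], g$n)
  z <- ad_add(ad_scale_by_scalar(x, ad_make(ad_value(eps) + 1,
                                            list(eps), function(g_) list(g_))),
              agg)
  mlp_apply(p$mlp, z, train, coll, path)
}

#' EGIN edge update
#'
#' `h_{i->j} <- act(W (h_{i->j} || h_i) + b)`: each directed edge is updated
#' with its starting node, so the two directions of a bond diverge.
#'
#' @param g `molgraph`.
#' @param p list with `W` ((d_e + d_v) x d_out), `b` (1 x d_out), and optional
#'   `act` (`"relu"` default, `"identity"`, `"sigmoid"`).
#' @param edge_features,node_features optional overrides.
#' @return Updated directed edge feature matrix (or adnode).
#' @export
egin_edge_update <- function(g, p, edge_features = NULL, node_features = NULL) {
  he <- edge_features %||% g$edge_features
  hv <- node_features %||% g$node_features
  if (ncol(ad_value(he)) + ncol(ad_value(hv)) != nrow(ad_value(p$W))) {
    stop("feature widths do not match edge-update parameters")
  }
  z <- ad_add_bias(ad_matmul(ad_cbind(he, ad_rows(hv, g$edges[, 1L])), p$W), p$b)
  .apply_act(z, p$act %||% "relu")
}

#' EGIN node update
#'
#' `h_i <- MLP(h_i || sum_{k in N(i)} h_{k->i})`: the central feature and the
#' aggregated incoming-edge message are concatenated (they are different kinds
#' of features), then transformed. A node with no incoming edges receives a
#' zero message block.
#'
#' @param g `molgraph`.
#' @param p list with `mlp` ([mlp_params()] or `NULL` for identity).
#' @param edge_features updated directed edge features (post
#'   [egin_edge_update()]).
#' @param node_features optional override.
#' @param train,coll,path training-mode plumbing.
#' @return Updated node feature matrix (or adnode).
#' @export
egin_node_update <- function(g, p, edge_features, node_features = NULL,
                             train = FALSE, coll = NULL, path = "egin_node") {
  hv <- node_features %||% g$node_features
  agg <- .aggregate_incoming(g, edge_features)
  mlp_apply(p$mlp, ad_cbind(hv, agg), train, coll, path)
}

#' One EGIN layer (edge update, then node update)
#'
#' @param g `molgraph`.
#' @param p list with components `edge` (for [egin_edge_update()]) and `node`
#'   (for [egin_node_update()]).
#' @param edge_features,node_features optional overrides.
#' @param train,coll,path training-mode plumbing.
#' @return List with `edge_features` and `node_features`.
#' @export
egin_layer <- function(g, p, edge_features = NULL, node_features = NULL,
                       train = FALSE, coll = NULL, path = "egin") {
  he <- egin_edge_update(g, p$edge, edge_features, node_features)
  hv <- egin_node_update(g, p$node, he, node_features, train, coll,
                         paste0(path, ".node.mlp"))
  list(edge_features = he, node_features = hv)
}

#' Fresh EGIN layer parameters
#'
#' @param d_v,d_e input node / edge widths.
#' @param hidden output width for both streams.
#' @param use_norm batch normalization inside the node MLP.
#' @return Parameter list for [egin_layer()].
#' @export
egin_params <- function(d_v, d_e, hidden, use_norm = TRUE) {
  list(edge = list(W = .init_mat(d_e + d_v, hidden),
                   b = matrix(0, 1L, hidden), act = "relu"),
       node = list(mlp = mlp_params(d_v + hidden, hidden, hidden, use_norm)))
}
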