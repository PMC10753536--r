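# Three-block hierarchical model: each block is an EGIN convolution followed
# by an edge-shrinkage pooling layer and a summation readout; the block
# readouts are concatenated and passed through a single linear head. With
# pooling disabled the blocks are convolution + readout only.

#' Model configuration
#'
#' @param n_tasks number of prediction tasks (label columns).
#' @param task_type `"classification"` (binary, possibly multitask) or
#'   `"regression"`.
#' @param blocks number of convolution(+pooling) blocks (>= 1, default 3).
#' @param hidden_dim hidden width shared by the node and edge streams.
#' @param lambda pooling split parameter in (0, 1]; scalar or one per block.
#' @param dropout dropout rate applied before the linear head (training only).
#' @param pooling include the pooling layers (`FALSE` gives the pooling-free
#'   baseline architecture).
#' @param use_norm batch normalization inside the MLPs.
#' @return Object of class `mespool_config`.
#' @export
mespool_config <- function(n_tasks = 1L,
                           task_type = c("classification", "regression"),
                           blocks = 3L, hidden_dim = 32L, lambda = 0.5,
                           dropout = 0.1, pooling = TRUE, use_norm = TRUE) {
  task_type <- match.arg(task_type)
  blocks <- as.integer(blocks)
  stopifnot(blocks >= 1L, n_tasks >= 1L)
  lambda <- rep_len(lambda, blocks)
  if (any(lambda <= 0 | lambda > 1)) stop("lambda must lie in (0, 1]")
  structure(list(n_tasks = as.integer(n_tasks), task_type = task_type,
                 blocks = blocks, hidden_dim = as.integer(hidden_dim),
                 lambda = lambda, dropout = dropout,
                 pooling = isTRUE(pooling), use_norm = isTRUE(use_norm),
                 d_atom = 120L, d_bond = 13L),
            class = "mespool_config")
}

#' Initialize model parameters
#'
#' @param config [mespool_config()].
#' @param seed RNG seed for the weight draws.
#' @return Nested named list of parameter matrices.
#' @export
init_params <- function(config, seed = 1) {
  .with_seed(seed, {
    hid <- config$hidden_dim
    blocks <- lapply(seq_len(config$blocks), function(b) {
      d_v <- if (b == 1L) config$d_atom else hid
      d_e <- if (b == 1L) config$d_bond else hid
      blk <- list(egin = egin_params(d_v, d_e, hid, config$use_norm))
      if (config$pooling) {
        blk$pool <- mespool_params(hid, hid, config$use_norm)
      }
      blk
    })
    names(blocks) <- paste0("block", seq_len(config$blocks))
    list(blocks = blocks,
         head = list(W = .init_mat(config$blocks * hid, config$n_tasks),
                     b = matrix(0, 1L, config$n_tasks)))
  })
}

#' Forward pass of the hierarchical model
#'
#' @param batch `molgraph` or `molgraph_batch` (featurized molecules).
#' @param params parameter list from [init_params()] (matrices may be
#'   adnodes during training).
#' @param config [mespool_config()].
#' @param train training mode (dropout active, batch statistics used).
#' @param coll collector environment for batch-norm statistics (training).
#' @param trace record pooling structure per block (see [pooling_trace()]).
#' @return List with `logits` (n_graphs x n_tasks; adnode when params are),
#'   `readouts`, and when `trace = TRUE` a `trace` list per block.
#' @export
forward_model <- function(batch, params, config, train = FALSE, coll = NULL,
                          trace = FALSE) {
  g <- batch
  hv <- g$node_features
  he <- g$edge_features
  readouts <- vector("list", config$blocks)
  trace_info <- if (trace) vector("list", config$blocks) else NULL
  for (b in seq_len(config$blocks)) {
    pb <- params$blocks[[b]]
    conv <- egin_layer(g, pb$egin, he, hv, train, coll,
                       sprintf("blocks.block%d.egin", b))
    he <- conv$edge_features
    hv <- conv$node_features
    if (config$pooling && !is.null(pb$pool)) {
      pl <- mespool_layer(g, pb$pool, config$lambda[b], hv, he,
                          train = train, coll = coll,
                          path = sprintf("blocks.block%d.pool", b))
      if (trace) {
        trace_info[[b]] <- list(
          selection = pl$selection,
          pooled = pl$pooled,
          graph_before = g,
          graph_after = pl$graph)
      }
      g <- pl$graph
      hv <- pl$node_features
      he <- pl$edge_features
    }
    readouts[[b]] <- readout_sum(g, hv)
  }
  rep_cat <- Reduce(ad_cbind, readouts)
  if (train && config$dropout > 0) {
    keep <- matrix(stats::rbinom(length(ad_value(rep_cat)), 1L,
                                 1 - config$dropout) / (1 - config$dropout),
                   nrow(ad_value(rep_cat)))
    rep_cat <- ad_mul(rep_cat, keep)
  }
  logits <- ad_add_bias(ad_matmul(rep_cat, params$head$W), params$head$b)
  out <- list(logits = logits, readouts = readouts)
  if (trace) out$trace <- trace_info
  out
}

# ---- parameter flattening (training support) --------------------------------

.BUFFER_NAMES <- c("rmean", "rvar")
.NONPARAM_NAMES <- c("use_norm", "act")

# flatten nested parameter list to a named list of matrices (trainable only)
flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    x <- params[[nm]]
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (nm %in% c(.BUFFER_NAMES, .NONPARAM_NAMES)) next
    if (is.list(x)) {
      out <- c(out, flatten_params(x, key))
    } else if (is.matrix(x)) {
      out[[key]] <- x
    }
  }
  out
}

# write a named flat list back into the nested structure
unflatten_params <- function(params, flat) {
  for (key in names(flat)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1L]]
    params[[path]] <- flat[[key]]
  }
  params
}

# replace each trainable matrix with an ad_leaf; returns list(params, leaves)
.params_to_leaves <- function(params) {
  flat <- flatten_params(params)
  leaves <- lapply(names(flat), function(k) ad_leaf(flat[[k]], name = k))
  names(leaves) <- names(flat)
  list(params = unflatten_params(params, leaves), leaves = leaves)
}

# momentum update of batch-norm running buffers from collected statistics
.apply_bn_updates <- function(params, coll, momentum = 0.1) {
  for (path in names(coll$stats)) {
    st <- coll$stats[[path]]
    p <- strsplit(path, ".", fixed = TRUE)[[1L]]
    node <- params[[p]]
    if (is.null(node$rmean)) next
    node$rmean <- (1 - momentum) * node$rmean + momentum * st$mean
    node$rvar <- (1 - momentum) * node$rvar + momentum * st$var
    params[[p]] <- node
  }
  params
}

# ---- checkpoints -------------------------------------------------------------

#' Save a fitted model (or bare config + parameters) to a checkpoint file
#'
#' @param model `mespool_model`, or a list with `config` and `params`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(format = "mespool_checkpoint", version = 1L,
              config = model$config, params = model$params,
              history = model$history, split = model$split)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a checkpoint written by [save_checkpoint()]
#'
#' @param path checkpoint file.
#' @return A `mespool_model` object (untrained fields may be `NULL`).
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mespool_checkpoint")) {
    stop(path, " is not a model checkpoint")
  }
  structure(list(config = obj$config, params = obj$params,
                 history = obj$history, split = obj$split),
            class = "mespool_model")
}
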