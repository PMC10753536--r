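# The modelling surface: one fitting function returning a classed object with
# print / summary / predict / plot methods.

#' Fit a hierarchical edge-shrinkage pooling model
#'
#' Featurizes the molecules, splits them by Bemis-Murcko scaffold (by
#' default), and trains the block architecture (EGIN convolution +
#' edge-shrinkage pooling + summation readout per block, concatenated into a
#' linear head) with Adam and early stopping on the validation metric.
#'
#' @param data a [task_table()], or a data frame with a SMILES column and
#'   label columns, or a path to a MoleculeNet-style CSV.
#' @param task_type `"classification"` (binary labels, possibly multitask,
#'   missing entries allowed) or `"regression"`.
#' @param smiles_col SMILES column name when `data` is a data frame or CSV.
#' @param blocks,hidden_dim,lambda,dropout,pooling,use_norm architecture
#'   options, see [mespool_config()].
#' @param split a [split_spec()] or a precomputed list of `train`/`valid`/
#'   `test` indices.
#' @param epochs,patience,lr,batch_size training options, see [train_model()].
#' @param seed master seed: derives the weight initialization, split shuffle
#'   and batch order.
#' @param verbose print per-epoch progress.
#' @return Object of class `mespool_model` with fields `config`, `params`
#'   (early-stopping best), `history`, `split`, `metrics` (validation and test
#'   metrics of the best parameters), `best_epoch`.
#' @examples
#' \donttest{
#' tab <- make_synthetic_task(60, seed = 7)
#' fit <- mespool_fit(tab, epochs = 3, hidden_dim = 8, seed = 1)
#' print(fit)
#' predict(fit, c("c1ccccc1CC", "CCCC"))
#' }
#' @export
mespool_fit <- function(data, task_type = c("classification", "regression"),
                        smiles_col = "smiles", blocks = 3L, hidden_dim = 32L,
                        lambda = 0.5, dropout = 0.1, pooling = TRUE,
                        use_norm = TRUE, split = NULL, epochs = 100L,
                        patience = 30L, lr = 1e-3, batch_size = 64L,
                        seed = 1, verbose = FALSE) {
  task_type <- match.arg(task_type)
  table <- .as_task_table(data, smiles_col)
  config <- mespool_config(n_tasks = ncol(table$labels), task_type = task_type,
                           blocks = blocks, hidden_dim = hidden_dim,
                           lambda = lambda, dropout = dropout,
                           pooling = pooling, use_norm = use_norm)
  graphs <- smiles_to_graphs(table$smiles)
  if (is.null(split)) split <- split_spec(seed = seed)
  idx <- if (inherits(split, "split_spec")) scaffold_split(table, split) else split
  stopifnot(all(c("train", "valid", "test") %in% names(idx)))
  params <- init_params(config, seed = seed)
  res <- train_model(params, config, graphs, table, idx, epochs = epochs,
                     patience = patience, lr = lr, batch_size = batch_size,
                     seed = seed + 1L, verbose = verbose)
  metrics <- list()
  for (part in c("valid", "test")) {
    ii <- idx[[part]]
    if (length(ii) == 0L) next
    preds <- .predict_graphs(graphs[ii], res$params, config)
    metrics[[part]] <- suppressWarnings(evaluate_predictions(
      preds, table$labels[ii, , drop = FALSE],
      table$mask[ii, , drop = FALSE], task_type))
  }
  structure(list(config = config, params = res$params,
                 history = res$history, split = idx, metrics = metrics,
                 best_epoch = res$best_epoch, seed = seed,
                 task_names = colnames(table$labels)),
            class = "mespool_model")
}

.as_task_table <- function(data, smiles_col = "smiles") {
  if (inherits(data, "task_table")) return(data)
  if (is.character(data) && length(data) == 1L && file.exists(data)) {
    return(read_task_table(data, smiles_col))
  }
  if (is.data.frame(data)) {
    if (!smiles_col %in% names(data)) stop("no '", smiles_col, "' column")
    lab <- as.matrix(data[setdiff(names(data), smiles_col)])
    storage.mode(lab) <- "double"
    return(task_table(data[[smiles_col]], lab))
  }
  stop("cannot interpret 'data' as a task table")
}

#' @export
print.mespool_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Edge-shrinkage pooling model (%s, %d task%s)\n",
              cfg$task_type, cfg$n_tasks, if (cfg$n_tasks > 1L) "s" else ""))
  cat(sprintf("  %d block(s), hidden width %d, lambda %s, pooling %s\n",
              cfg$blocks, cfg$hidden_dim,
              paste(cfg$lambda, collapse = "/"),
              if (cfg$pooling) "on" else "off"))
  if (!is.null(x$best_epoch) && x$best_epoch > 0L) {
    mname <- names(x$history)[3L]
    cat(sprintf("  trained %d epoch(s); best %s %.4f at epoch %d\n",
                nrow(x$history), sub("^val_", "validation ", mname),
                x$history[[mname]][x$best_epoch], x$best_epoch))
  }
  invisible(x)
}

#' @export
summary.mespool_model <- function(object, ...) {
  print(object)
  np <- sum(vapply(flatten_params(object$params), length, integer(1)))
  cat(sprintf("  parameters: %d\n", np))
  if (!is.null(object$split)) {
    cat(sprintf("  split sizes: train %d / valid %d / test %d\n",
                length(object$split$train), length(object$split$valid),
                length(object$split$test)))
  }
  for (part in names(object$metrics)) {
    m <- object$metrics[[part]]
    vals <- m[setdiff(names(m), "per_task")]
    cat(sprintf("  %s: %s\n", part,
                paste(sprintf("%s %.4f", names(vals), unlist(vals)),
                      collapse = ", ")))
  }
  invisible(object)
}

#' Predict molecular properties
#'
#' @param object fitted `mespool_model` (or checkpoint loaded with
#'   [load_checkpoint()]).
#' @param newdata character vector of SMILES, a [task_table()], a data frame
#'   with a SMILES column, or a list of pre-featurized [molgraph()]s.
#' @param type `"response"` (probabilities for classification, values for
#'   regression) or `"link"` (raw logits).
#' @param smiles_col SMILES column name for data-frame input.
#' @param ... unused.
#' @return Numeric matrix, one row per molecule, one column per task.
#' @export
predict.mespool_model <- function(object, newdata,
                                  type = c("response", "link"),
                                  smiles_col = "smiles", ...) {
  type <- match.arg(type)
  graphs <- if (is.list(newdata) && all(vapply(newdata, inherits, logical(1),
                                               "molgraph"))) {
    newdata
  } else if (is.character(newdata)) {
    smiles_to_graphs(newdata)
  } else {
    smiles_to_graphs(.as_task_table(newdata, smiles_col)$smiles)
  }
  z <- .predict_graphs(graphs, object$params, object$config)
  colnames(z) <- object$task_names
  if (type == "response" && object$config$task_type == "classification") {
    z <- 1 / (1 + exp(-z))
  }
  z
}

#' Plot training history
#'
#' Training loss and validation metric per epoch; the early-stopping epoch is
#' marked.
#'
#' @param x fitted `mespool_model`.
#' @param ... passed to [plot()].
#' @export
plot.mespool_model <- function(x, ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0L) stop("model has no training history")
  mname <- names(h)[3L]
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
       ylab = "training loss", main = "loss", ...)
  plot(h$epoch, h[[mname]], type = "l", xlab = "epoch",
       ylab = sub("^val_", "validation ", mname), main = "validation", ...)
  graphics::abline(v = x$best_epoch, lty = 2)
  invisible(x)
}
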