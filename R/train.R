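# Training: masked multitask objectives, evaluation metrics, Adam, and the
# optimization loop with early stopping on the validation metric.

#' Masked multitask loss
#'
#' Binary cross-entropy on logits (classification) or squared error
#' (regression), averaged over unmasked entries only; tasks with no labels in
#' the batch contribute nothing.
#'
#' @param predictions n x t matrix: logits (classification) or raw values
#'   (regression).
#' @param labels n x t matrix; masked entries may be NA.
#' @param mask logical n x t matrix, TRUE = labelled.
#' @param task_type `"classification"` or `"regression"`.
#' @return Scalar loss.
#' @export
masked_loss <- function(predictions, labels, mask,
                        task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  if (!is.matrix(predictions)) predictions <- as.matrix(predictions)
  if (!is.matrix(labels)) labels <- as.matrix(labels)
  if (!is.matrix(mask)) mask <- as.matrix(mask)
  if (sum(mask) == 0) stop("masked loss undefined: no unmasked entries")
  v <- if (task_type == "classification") {
    ad_masked_bce(predictions, labels, mask)
  } else {
    ad_masked_mse(predictions, labels, mask)
  }
  as.numeric(ad_value(v))
}

# average precision (area under the precision-recall curve, step integration)
.auc_prc <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  npos <- sum(y == 1)
  if (npos == 0) return(NA_real_)
  tp <- cumsum(y == 1)
  prec <- tp / seq_along(y)
  sum(prec[y == 1]) / npos
}

.auc_roc <- function(labels, scores) {
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' Evaluate predictions against labels
#'
#' Classification: AUC-ROC and AUC-PRC per task on unmasked entries, averaged
#' over tasks (tasks with a single observed class are skipped with a warning).
#' Regression: RMSE per task, averaged.
#'
#' @inheritParams masked_loss
#' @return Named list of metrics (`auc_roc`, `auc_prc` or `rmse`), plus
#'   `per_task` with the task-level values.
#' @export
evaluate_predictions <- function(predictions, labels, mask,
                                 task_type = c("classification", "regression")) {
  task_type <- match.arg(task_type)
  if (!is.matrix(predictions)) predictions <- as.matrix(predictions)
  if (!is.matrix(labels)) labels <- as.matrix(labels)
  if (!is.matrix(mask)) mask <- as.matrix(mask)
  t_n <- ncol(labels)
  if (task_type == "regression") {
    rmse <- vapply(seq_len(t_n), function(t) {
      m <- mask[, t]
      if (!any(m)) return(NA_real_)
      sqrt(mean((predictions[m, t] - labels[m, t])^2))
    }, numeric(1))
    return(list(rmse = mean(rmse, na.rm = TRUE),
                per_task = list(rmse = rmse)))
  }
  roc <- prc <- rep(NA_real_, t_n)
  for (t in seq_len(t_n)) {
    m <- mask[, t]
    y <- labels[m, t]
    if (length(unique(y)) < 2L) {
      warning("task ", t, " has a single observed class; skipped")
      next
    }
    roc[t] <- .auc_roc(y, predictions[m, t])
    prc[t] <- .auc_prc(y, predictions[m, t])
  }
  list(auc_roc = mean(roc, na.rm = TRUE), auc_prc = mean(prc, na.rm = TRUE),
       per_task = list(auc_roc = roc, auc_prc = prc))
}

# ---- Adam --------------------------------------------------------------------

.adam_init <- function(flat) {
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0),
       t = 0L)
}

.adam_step <- function(flat, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (k in names(flat)) {
    gk <- grads[[k]]
    if (is.null(gk)) next
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * gk
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * gk^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    flat[[k]] <- flat[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

# ---- training loop -----------------------------------------------------------

# numeric predictions for a list of graphs (evaluation mode, minibatched)
.predict_graphs <- function(graphs, params, config, batch_size = 128L) {
  out <- matrix(NA_real_, length(graphs), config$n_tasks)
  for (start in seq(1L, length(graphs), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, length(graphs))
    b <- batch_graphs(graphs[idx])
    out[idx, ] <- ad_value(forward_model(b, params, config)$logits)
  }
  out
}

#' Train a model on a task table
#'
#' Adam optimization of the masked multitask objective with early stopping on
#' the validation metric (AUC-ROC for classification, RMSE for regression).
#' Deterministic given `seed`.
#'
#' @param params parameter list ([init_params()]).
#' @param config [mespool_config()].
#' @param graphs list of featurized [molgraph()]s, aligned with `table`.
#' @param table [task_table()].
#' @param split list with `train` and `valid` index vectors
#'   ([scaffold_split()]).
#' @param epochs maximum epochs.
#' @param patience epochs without validation improvement before stopping
#'   (0 stops at the first non-improvement).
#' @param lr Adam learning rate.
#' @param batch_size molecules per gradient step.
#' @param seed RNG seed (batch order, dropout).
#' @param verbose print one line per epoch.
#' @return List with `params` (best by validation metric), `history` (one row
#'   per epoch: epoch, train_loss, val_metric), `best_epoch`, `best_metric`.
#' @export
train_model <- function(params, config, graphs, table, split,
                        epochs = 100L, patience = 30L, lr = 1e-3,
                        batch_size = 64L, seed = 1, verbose = FALSE) {
  classification <- config$task_type == "classification"
  metric_name <- if (classification) "auc_roc" else "rmse"
  better <- if (classification) `>` else `<`
  tr <- split$train
  va <- split$valid
  stopifnot(length(tr) > 0L, length(va) > 0L)
  flat <- flatten_params(params)
  opt <- .adam_init(flat)
  best_metric <- if (classification) -Inf else Inf
  best_flat <- flat
  best_params <- params
  best_epoch <- 0L
  bad_epochs <- 0L
  history <- data.frame()
  .with_seed(seed, {
    for (epoch in seq_len(epochs)) {
      ord <- sample(tr)
      losses <- numeric(0)
      for (start in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, length(ord))]
        if (sum(table$mask[idx, , drop = FALSE]) == 0) next
        bat <- batch_graphs(graphs[idx])
        params <- unflatten_params(params, flat)
        wrapped <- .params_to_leaves(params)
        coll <- new.env(parent = emptyenv())
        coll$stats <- list()
        fw <- forward_model(bat, wrapped$params, config, train = TRUE,
                            coll = coll)
        loss <- if (classification) {
          ad_masked_bce(fw$logits, table$labels[idx, , drop = FALSE],
                        table$mask[idx, , drop = FALSE])
        } else {
          ad_masked_mse(fw$logits, table$labels[idx, , drop = FALSE],
                        table$mask[idx, , drop = FALSE])
        }
        lval <- as.numeric(ad_value(loss))
        if (!is.finite(lval)) {
          stop("training diverged: non-finite loss at epoch ", epoch)
        }
        losses <- c(losses, lval)
        ad_backward(loss)
        grads <- lapply(wrapped$leaves, ad_grad)
        stepped <- .adam_step(flat, grads, opt, lr = lr)
        flat <- stepped$flat
        opt <- stepped$state
        params <- .apply_bn_updates(unflatten_params(params, flat), coll)
        flat <- flatten_params(params)
      }
      preds <- .predict_graphs(graphs[va], params, config)
      vm <- if (classification) {
        suppressWarnings(evaluate_predictions(
          preds, table$labels[va, , drop = FALSE],
          table$mask[va, , drop = FALSE], "classification")$auc_roc)
      } else {
        evaluate_predictions(preds, table$labels[va, , drop = FALSE],
                             table$mask[va, , drop = FALSE],
                             "regression")$rmse
      }
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = mean(losses),
                                  val_metric = vm))
      if (verbose) {
        message(sprintf("epoch %3d  loss %.4f  val %s %.4f",
                        epoch, mean(losses), metric_name, vm))
      }
      if (is.finite(vm) && better(vm, best_metric)) {
        best_metric <- vm
        best_params <- params
        best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs > patience) break
      }
    }
  })
  names(history)[3L] <- paste0("val_", metric_name)
  list(params = best_params, history = history,
       best_epoch = best_epoch, best_metric = best_metric)
}
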