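# Scaffold splitting, masked objectives, metrics and the optimization loop.

test_that("scaffold keys group molecules by framework", {
  # same scaffold regardless of side chains or atom order
  expect_equal(murcko_scaffold_key("c1ccccc1CC"),
               murcko_scaffold_key("CCCc1ccccc1"))
  expect_false(murcko_scaffold_key("c1ccccc1") ==
                 murcko_scaffold_key("c1ccncc1"))
  # acyclic molecules share the empty scaffold
  expect_equal(murcko_scaffold_key("CCCC"), "")
  expect_equal(murcko_scaffold_key("CCO"), "")
  # ring + linker frameworks differ from the bare ring
  expect_false(murcko_scaffold_key("c1ccccc1Cc1ccccc1") ==
                 murcko_scaffold_key("c1ccccc1"))
})

test_that("scaffold_split honours the 8:1:1 contract and group atomicity", {
  ring_sizes <- 3:12
  smis <- c(vapply(ring_sizes, function(n) {
    paste0("C1", paste(rep("C", n - 1), collapse = ""), "1")
  }, character(1)))
  tab <- task_table(smis, matrix(rep(0:1, 5), ncol = 1))
  idx <- scaffold_split(tab, split_spec(seed = 3))
  expect_equal(lengths(idx[c("train", "valid", "test")]),
               c(train = 8L, valid = 1L, test = 1L))
  all_idx <- sort(unname(unlist(idx)))
  expect_equal(all_idx, 1:10)

  # molecules sharing a scaffold are never separated
  smis2 <- c("c1ccccc1CC", "CCCc1ccccc1", "c1ccncc1C", "C1CCCCC1",
             "CC1CCCCC1", "c1ccc2ccccc2c1", "CCCC", "CCO", "C1CC1", "C1CCC1")
  tab2 <- task_table(smis2, matrix(0, 10, 1))
  for (seed in 1:5) {
    idx2 <- scaffold_split(tab2, split_spec(seed = seed))
    part_of <- integer(10)
    for (p in 1:3) part_of[idx2[[p]]] <- p
    expect_equal(part_of[1], part_of[2])   # both plain-benzene scaffold
    expect_equal(part_of[7], part_of[8])   # both empty scaffold
    expect_equal(sort(unname(unlist(idx2))), 1:10)
    # seed-reproducible
    expect_identical(idx2, scaffold_split(tab2, split_spec(seed = seed)))
  }

  # all one scaffold: cannot form three nonempty sets
  tab3 <- task_table(c("c1ccccc1C", "c1ccccc1CC", "Cc1ccccc1C"),
                     matrix(0, 3, 1))
  expect_error(scaffold_split(tab3, split_spec()), "scaffold groups")

  # random mode partitions with the right sizes
  idxr <- scaffold_split(tab2, split_spec(seed = 1, mode = "random"))
  expect_equal(sort(unname(unlist(idxr))), 1:10)
  expect_equal(length(idxr$train), 8L)
})

test_that("masked_loss averages over unmasked entries only", {
  pred <- matrix(c(2, -3, 1, 0), 2, 2)
  lab <- matrix(c(1, 0, 1, 0), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  # perfect regression predictions -> 0
  expect_equal(masked_loss(lab, lab, mask, "regression"), 0)
  # an all-FALSE task column contributes nothing
  m2 <- mask; m2[, 2] <- FALSE
  expect_equal(masked_loss(pred, lab, m2, "regression"),
               mean((pred[, 1] - lab[, 1])^2))
  # hand-computed 2x2 classification case
  bce <- function(z, y) max(z, 0) - z * y + log1p(exp(-abs(z)))
  expect_equal(masked_loss(pred, lab, mask, "classification"),
               mean(c(bce(2, 1), bce(-3, 0), bce(1, 1), bce(0, 0))))
  expect_error(masked_loss(pred, lab, mask & FALSE, "classification"),
               "no unmasked")
})

test_that("evaluation metrics match their oracles", {
  y <- c(0, 0, 1, 1)
  s <- c(0.1, 0.2, 0.8, 0.9)
  m <- matrix(TRUE, 4, 1)
  ev <- evaluate_predictions(matrix(s), matrix(y), m, "classification")
  expect_equal(ev$auc_roc, 1.0)
  expect_equal(evaluate_predictions(matrix(y), matrix(y), m,
                                    "regression")$rmse, 0)
  # 6-point hand case vs Mann-Whitney rank statistic
  y6 <- c(1, 0, 1, 0, 0, 1)
  s6 <- c(0.9, 0.8, 0.3, 0.4, 0.1, 0.7)
  ev6 <- evaluate_predictions(matrix(s6), matrix(y6), matrix(TRUE, 6, 1),
                              "classification")
  expect_equal(ev6$auc_roc, oracle_auc(y6, s6))
  # single-class task skipped with warning
  expect_warning(
    ev1 <- evaluate_predictions(matrix(s, 4, 2), cbind(y, rep(1, 4)),
                                matrix(TRUE, 4, 2), "classification"),
    "single observed class")
  expect_equal(ev1$auc_roc, 1.0)
})

test_that("training runs, logs history and stops early", {
  tab <- make_synthetic_task(20, seed = 6)
  graphs <- smiles_to_graphs(tab$smiles)
  config <- mespool_config(1, "classification", hidden_dim = 6)
  params <- init_params(config, seed = 1)
  split <- list(train = 1:16, valid = 17:20)
  res <- train_model(params, config, graphs, tab, split, epochs = 2,
                     patience = 5, batch_size = 8, seed = 2)
  expect_equal(nrow(res$history), 2L)
  expect_true(all(is.finite(res$history$train_loss)))
  # patience = 0 stops at the first non-improvement
  res0 <- train_model(params, config, graphs, tab, split, epochs = 30,
                      patience = 0, batch_size = 8, seed = 2)
  nh <- nrow(res0$history)
  expect_lt(nh, 30L)
  expect_lte(res0$best_epoch, nh - 1L)
  # loss decreases over the first epochs
  res3 <- train_model(params, config, graphs, tab, split, epochs = 6,
                      patience = 10, batch_size = 8, seed = 2)
  expect_lt(min(res3$history$train_loss), res3$history$train_loss[1])
})
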