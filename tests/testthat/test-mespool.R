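# Selection / reduction / connection of the edge-shrinkage pooling layer.

# undirected scores as a per-directed-edge vector, by bond (sorted pair)
scores_by_bond <- function(g, bond_scores) {
  vapply(seq_len(nrow(g$edges)), function(k) {
    key <- paste(sort(g$edges[k, ]), collapse = "-")
    bond_scores[[key]]
  }, numeric(1))
}

test_that("edge message propagation is symmetric and matches its oracle", {
  # single undirected edge, identity MLP: h_e(1,2) = 2 (h_{1->2} + h_{2->1})
  g <- molgraph(2, rbind(c(1, 2), c(2, 1)), matrix(0, 2, 2),
                rbind(c(1, 2), c(10, 20)))
  pr <- propagate_edge_messages(g, list(mlp = NULL))
  expect_equal(pr$h_und[1, ], 2 * (g$edge_features[1, ] + g$edge_features[2, ]))
  expect_equal(pr$h_und[1, ], pr$h_und[2, ])
  for (seed in 1:4) {
    gr <- make_random_graph(8, 0.5, d_e = 3, seed = seed)
    pr <- propagate_edge_messages(gr, list(mlp = NULL))
    expect_equal(pr$h_und, oracle_propagate(gr), tolerance = 1e-12)
    # symmetry under i <-> j
    expect_equal(pr$h_und, pr$h_und[gr$rev_index, , drop = FALSE])
  }
})

test_that("score_edges is a sigmoid-squashed linear form", {
  h <- matrix(rnorm(12), 4, 3)
  expect_equal(as.numeric(score_edges(h, rep(0, 3))), rep(0.5, 4))
  s <- c(0.2, -1, 0.4)
  sc1 <- as.numeric(score_edges(h, s))
  sc2 <- as.numeric(score_edges(h, 3 * s))
  expect_equal(order(sc1), order(sc2))  # positive scaling keeps the order
  # s^T h = 1 -> 1 / (1 + e^-1)
  expect_equal(as.numeric(score_edges(matrix(1, 1, 1), 1)),
               1 / (1 + exp(-1)))
  expect_error(score_edges(h, rep(0, 5)), "width")
})

test_that("scale_edge_features multiplies rows by their score", {
  h <- matrix(rnorm(8), 4, 2)
  expect_equal(scale_edge_features(h, rep(1, 4)), h)
  expect_equal(scale_edge_features(h, rep(0.5, 4)), h / 2)
  sc <- runif(4)
  expect_equal(scale_edge_features(h, sc), h * sc)
})

test_that("compute_threshold is min(lambda, mean)", {
  expect_equal(compute_threshold(c(0.2, 0.4, 0.6), 0.5), 0.4)
  expect_equal(compute_threshold(c(0.5, 0.5), 0.3), 0.3)
  # all scores equal c: threshold min(lambda, c); strict < empties selection
  expect_equal(compute_threshold(rep(0.3, 5), 0.5), 0.3)
  expect_error(compute_threshold(numeric(0), 0.5), "empty")
  expect_error(compute_threshold(0.5, 0), "lambda")
  expect_error(compute_threshold(0.5, 1.2), "lambda")
})

test_that("select_edges applies the strict threshold split", {
  g <- make_path(4, seed = 3)  # bonds 1-2, 2-3, 3-4
  sc <- scores_by_bond(g, list(`1-2` = 0.1, `2-3` = 0.9, `3-4` = 0.1))
  sel <- select_edges(g, sc, lambda = 0.5)
  expect_equal(sel$threshold, min(0.5, mean(c(0.1, 0.9, 0.1))))
  expect_equal(length(sel$pooled_und), 2L)   # the two low edges
  expect_equal(sel$v_pool, c(1L, 2L, 3L, 4L))
  mid <- which(g$edges[, 1L] == 2 & g$edges[, 2L] == 3)
  expect_false(mid %in% sel$pooled_dir)      # middle edge preserved
  # all scores at/above threshold: empty selection (ties survive)
  sel2 <- select_edges(g, rep(0.4, nrow(g$edges)), lambda = 0.5)
  expect_equal(length(sel2$pooled_und), 0L)
  # survival guarantee on random graphs: |E_pool| < m always
  for (seed in 1:200) {
    gr <- make_random_graph(sample(3:15, 1), runif(1, 0.2, 0.9), seed = seed)
    if (nrow(gr$edges) == 0L) next
    sc <- runif(n_undirected(gr))
    scd <- numeric(nrow(gr$edges))
    reps <- which(gr$edges[, 1L] <= gr$edges[, 2L])
    scd[reps] <- sc
    scd[gr$rev_index[reps]] <- sc
    sel <- select_edges(gr, scd, lambda = runif(1, 0.05, 1))
    expect_lt(length(sel$pooled_und), n_undirected(gr))
  }
})

test_that("reduction sums member features and finds components", {
  # two disjoint pooled bonds -> K = 2 supernodes
  g <- make_path(5, d_v = 2, seed = 4)
  sc <- scores_by_bond(g, list(`1-2` = 0.1, `2-3` = 0.9, `3-4` = 0.9,
                               `4-5` = 0.1))
  sel <- select_edges(g, sc, lambda = 0.9)
  red <- reduce_selection(g, sel, NULL, g$edge_features)
  expect_equal(red$components, list(1:2, 4:5))
  expect_equal(ad_value(red$h_super)[1, ], colSums(g$node_features[1:2, ]))
  expect_equal(red$provenance, list(1:2, 4:5))
  # pooled 4-cycle (all but one bond pooled, which still spans all 4 nodes):
  # one supernode whose provenance is all 4 atoms
  cyc <- make_cycle(4, d_v = 3, seed = 5)
  scc <- scores_by_bond(cyc, list(`1-2` = 0.1, `2-3` = 0.1, `3-4` = 0.1,
                                  `1-4` = 0.9))
  sel_c <- select_edges(cyc, scc, lambda = 1)
  red_c <- reduce_selection(cyc, sel_c, NULL, cyc$edge_features)
  expect_equal(length(red_c$components), 1L)
  expect_equal(red_c$provenance[[1L]], 1:4)
  expect_equal(ad_value(red_c$h_super)[1, ], colSums(cyc$node_features))
})

test_that("reconnect reproduces the ring special cases", {
  # 6-cycle preserving two adjacent bonds: after shrinkage two nodes joined
  # by two parallel edges; merged into one undirected edge
  g <- make_cycle(6, d_v = 2, d_e = 2, seed = 6)
  bonds <- list(`1-2` = 0.9, `2-3` = 0.9, `3-4` = 0.1, `4-5` = 0.1,
                `5-6` = 0.1, `1-6` = 0.1)
  out <- mespool_layer(g, params = NULL, lambda = 0.5,
                       scores = scores_by_bond(g, bonds))
  expect_equal(out$graph$n, 2L)
  pre <- out$pooled$premerge_edges
  expect_equal(nrow(pre), 4L)  # two undirected parallels = 4 directed rows
  expect_true(all(pre[, 1L] != pre[, 2L]))
  expect_equal(nrow(out$graph$edges), 2L)  # merged: one undirected edge
  expect_equal(sort(lengths(out$graph$node_provenance)), c(1L, 5L))
  # merged feature row is the sum of the two parallel rows
  kept <- setdiff(seq_len(nrow(g$edges)), out$selection$pooled_dir)
  expect_equal(colSums(out$graph$edge_features),
               colSums(out$pooled$premerge_features), tolerance = 1e-12)

  # cycle preserving one bond: a supernode with two directed self-loops
  # before merging, one after
  bonds1 <- list(`1-2` = 0.9, `2-3` = 0.1, `3-4` = 0.1, `4-5` = 0.1,
                 `5-6` = 0.1, `1-6` = 0.1)
  out1 <- mespool_layer(g, params = NULL, lambda = 0.5,
                        scores = scores_by_bond(g, bonds1))
  expect_equal(out1$graph$n, 1L)
  pre1 <- out1$pooled$premerge_edges
  expect_equal(nrow(pre1), 2L)
  expect_true(all(pre1[, 1L] == pre1[, 2L]))   # two directed self-loops
  expect_equal(nrow(out1$graph$edges), 1L)     # merged to one
  expect_equal(unname(out1$graph$edges[1, 1L]),
               unname(out1$graph$edges[1, 2L]))
  expect_equal(out1$graph$node_provenance[[1L]], 1:6)

  # empty selection: structurally identical graph
  out_e <- mespool_layer(g, params = NULL, lambda = 0.5,
                         scores = rep(0.9, nrow(g$edges)))
  expect_identical(out_e$graph$edges, g$edges)
  expect_null(out_e$pooled)
})

test_that("pooling preserves node count algebra, components, provenance and mass", {
  set.seed(123)
  p <- mespool_params(3, 3, use_norm = FALSE)
  for (k in 1:120) {
    g <- random_molgraphs(1, max_n = 30L, d_v = 3, d_e = 3, seed = 3000 + k)[[1]]
    out <- mespool_layer(g, p, lambda = 0.6)
    sel <- out$selection
    K <- if (is.null(out$pooled)) 0L else length(out$pooled$components)
    # node conservation
    expect_equal(out$graph$n, g$n - length(sel$v_pool) + K)
    # component count preserved
    before <- length(connected_subsets(seq_len(g$n), g$edges))
    after <- length(connected_subsets(seq_len(out$graph$n), out$graph$edges))
    expect_equal(after, before)
    # provenance still partitions the atom set
    expect_equal(sort(unlist(out$graph$node_provenance)), seq_len(g$n))
    # identity reduction conserves the summation readout
    out_id <- mespool_layer(g, params = NULL, lambda = 0.6,
                            scores = ad_value(score_edges(
                              propagate_edge_messages(g, p$prop)$h_und,
                              p$svec)))
    expect_equal(colSums(out_id$graph$node_features), colSums(g$node_features),
                 tolerance = 1e-8)
  }
})

test_that("the pooling layer is permutation equivariant", {
  set.seed(77)
  p <- mespool_params(3, 3, use_norm = FALSE)
  for (k in 1:20) {
    g <- random_molgraphs(1, max_n = 15L, d_v = 3, d_e = 3, seed = 500 + k)[[1]]
    out <- mespool_layer(g, p, lambda = 0.7)
    perm <- sample(g$n)
    gp <- permute_graph(g, perm)
    # permuted provenance: original atom i is now called perm[i]
    gp$node_provenance <- lapply(seq_len(g$n), function(j) j)
    outp <- mespool_layer(gp, p, lambda = 0.7)
    # match new nodes by provenance (translated through perm)
    key <- function(prov) paste(sort(prov), collapse = ",")
    map_orig <- vapply(out$graph$node_provenance,
                       function(v) key(perm[v]), character(1))
    map_perm <- vapply(outp$graph$node_provenance, key, character(1))
    expect_setequal(map_orig, map_perm)
    reord <- match(map_orig, map_perm)
    expect_equal(out$graph$node_features,
                 outp$graph$node_features[reord, , drop = FALSE],
                 tolerance = 1e-8)
  }
})

test_that("edgeless and single-node graphs pass through unchanged", {
  iso <- molgraph(1, NULL, matrix(1, 1, 3), matrix(0, 0, 3))
  out <- mespool_layer(iso, NULL, 0.5)
  expect_identical(out$graph, iso)
  expect_null(out$selection)
})
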