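# Convolution layers: GIN closed form, EGIN edge/node updates vs per-element
# oracles, equivariance and determinism.

test_that("gin_layer matches hand cases and the dense closed form", {
  # path 1-2-3 with scalar features (1,2,3), eps = 0, identity MLP
  g <- make_path(3, d_v = 1, d_e = 1, seed = 1)
  g$node_features <- matrix(c(1, 2, 3), 3, 1)
  h <- gin_layer(g, list(eps = 0, mlp = NULL))
  expect_equal(as.numeric(h), c(1 + 2, 2 + 1 + 3, 3 + 2))
  # isolated node, eps = 0.5: (1 + eps) * h
  iso <- molgraph(1, NULL, matrix(2, 1, 1), matrix(0, 0, 1))
  expect_equal(as.numeric(gin_layer(iso, list(eps = 0.5, mlp = NULL))), 3)
  # random graph: ((1 + eps) I + A) H via dense oracle
  for (seed in 1:5) {
    gr <- make_random_graph(10, 0.4, d_v = 3, seed = seed)
    eps <- 0.3
    A <- dense_adjacency(gr)
    expected <- ((1 + eps) * diag(gr$n) + t(A)) %*% gr$node_features
    expect_equal(gin_layer(gr, list(eps = eps, mlp = NULL)), expected,
                 tolerance = 1e-12)
  }
})

test_that("egin_edge_update matches the per-edge formula", {
  g <- make_path(3, d_v = 1, d_e = 1, seed = 2)
  # W = 0 -> all edges map to act(b); relu(0) = 0
  h0 <- egin_edge_update(g, list(W = matrix(0, 2, 1), b = matrix(0, 1, 1)))
  expect_true(all(ad_value(h0) == 0))
  # scalar case W = (1,1)^T, identity act: h_{i->j} + h_i
  W <- matrix(1, 2, 1)
  h1 <- egin_edge_update(g, list(W = W, b = matrix(0, 1, 1),
                                 act = "identity"))
  expect_equal(h1, g$edge_features + g$node_features[g$edges[, 1L], ,
                                                     drop = FALSE])
  # random graph vs scripted oracle
  for (seed in 1:4) {
    gr <- make_random_graph(8, 0.4, d_v = 3, d_e = 2, seed = seed)
    set.seed(seed)
    W <- matrix(rnorm(5 * 4), 5, 4)
    b <- matrix(rnorm(4), 1, 4)
    got <- egin_edge_update(gr, list(W = W, b = b))
    expect_equal(got, oracle_edge_update(gr, W, b, act = function(z) pmax(z, 0)),
                 tolerance = 1e-12)
  }
  expect_error(egin_edge_update(g, list(W = matrix(0, 5, 1),
                                        b = matrix(0, 1, 1))), "width")
})

test_that("egin_node_update concatenates central feature and message sum", {
  # single directed pair 1<->2, identity MLP: node 2 contains h_{1->2}
  g <- molgraph(2, rbind(c(1, 2), c(2, 1)), matrix(c(5, 7), 2, 1),
                matrix(c(11, 13), 2, 1))
  he <- g$edge_features
  h <- egin_node_update(g, list(mlp = NULL), he)
  expect_equal(h[2, ], c(7, he[1, ]))  # second block holds h_{1->2}
  # node with no incoming edges: zero message block
  iso <- molgraph(2, NULL, matrix(c(1, 2), 2, 1), matrix(0, 0, 2))
  hiso <- egin_node_update(iso, list(mlp = NULL), iso$edge_features)
  expect_equal(hiso, cbind(c(1, 2), 0, 0))
  # random graph vs scripted oracle
  for (seed in 1:4) {
    gr <- make_random_graph(8, 0.5, d_v = 2, d_e = 3, seed = seed)
    he <- matrix(rnorm(nrow(gr$edges) * 3), ncol = 3)
    expect_equal(egin_node_update(gr, list(mlp = NULL), he),
                 oracle_node_update(gr, he), tolerance = 1e-12)
  }
})

test_that("egin_layer composes the two updates and is equivariant", {
  g <- make_random_graph(9, 0.4, d_v = 3, d_e = 3, seed = 6)
  set.seed(6)
  p <- egin_params(3, 3, 5, use_norm = FALSE)
  out <- egin_layer(g, p)
  he <- egin_edge_update(g, p$edge)
  hv <- egin_node_update(g, p$node, he)
  expect_identical(out$edge_features, he)
  expect_identical(out$node_features, hv)
  # determinism: bitwise identical across runs
  out2 <- egin_layer(g, p)
  expect_identical(out$node_features, out2$node_features)
  # permutation equivariance
  set.seed(7)
  perm <- sample(g$n)
  gp <- permute_graph(g, perm)
  outp <- egin_layer(gp, p)
  expect_equal(outp$node_features[perm, , drop = FALSE], out$node_features,
               tolerance = 1e-12)
})

test_that("self-loops contribute once to their node's aggregation", {
  g <- molgraph(2, rbind(c(1, 1), c(1, 2), c(2, 1)),
                matrix(c(1, 2), 2, 1), matrix(c(10, 20, 30), 3, 1))
  h <- egin_node_update(g, list(mlp = NULL), g$edge_features)
  # node 1 receives its self-loop (10) plus 2->1 (30)
  expect_equal(h[1, 2], 40)
  expect_equal(h[2, 2], 20)
})

test_that("mlp batch normalization trains on batch stats, evaluates on buffers", {
  set.seed(9)
  p <- mlp_params(3, 4, 2, use_norm = TRUE)
  X <- matrix(rnorm(30), 10, 3)
  coll <- new.env(); coll$stats <- list()
  leafW <- ad_leaf(p$W1)
  ptrain <- p; ptrain$W1 <- leafW
  out_tr <- mespool:::mlp_apply(ptrain, X, train = TRUE, coll = coll,
                                path = "mlp")
  expect_true(inherits(out_tr, "adnode"))
  expect_named(coll$stats, "mlp")
  # eval path is a fixed affine map of the first linear output
  out_ev <- mespool:::mlp_apply(p, X, train = FALSE)
  expect_false(inherits(out_ev, "adnode"))
  expect_equal(dim(out_ev), c(10L, 2L))
})
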