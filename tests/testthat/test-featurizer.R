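# Table-driven featurization: 120-wide atom vectors, 13-wide bond vectors.

test_that("schemas have the documented block widths", {
  a <- atom_feature_schema()
  expect_equal(sum(a$width), 120L)
  expect_equal(a$width[a$block == "atom_type"], 100L)
  b <- bond_feature_schema()
  expect_equal(sum(b$width), 13L)
  expect_equal(b$width[b$block == "stereo"], 6L)
})

test_that("featurize_atom encodes blocks at the expected positions", {
  # nitrogen, +1 formal charge, sp3, 0 bonded H, no chirality:
  # expected active indices enumerated by hand from the schema layout
  v <- featurize_atom(list(atomic_number = 7, aromatic = FALSE, n_h = 0,
                           formal_charge = 1, chirality = "unspecified",
                           hybridization = "sp3"))
  expect_length(v, 120L)
  expect_equal(which(v == 1), c(7L,          # atomic number 7
                                102L,        # 0 hydrogens (block at 102..106)
                                110L,        # charge +1 (block at 107..111)
                                112L,        # chirality unspecified (112..115)
                                118L))       # sp3 (116..120)
  # non-aromatic atom: aromatic bit (position 101) off, exactly 5 ones
  expect_equal(v[101L], 0)
  expect_equal(sum(v), 5)
  # aromatic carbon: 6 ones
  va <- featurize_atom(list(atomic_number = 6, aromatic = TRUE, n_h = 1,
                            formal_charge = 0, chirality = "unspecified",
                            hybridization = "sp2"))
  expect_equal(sum(va), 6)
  expect_equal(va[101L], 1)
  # clamping: z >= 100 -> last atom-type slot; charge and H counts clamp
  vz <- featurize_atom(list(atomic_number = 104, aromatic = FALSE, n_h = 9,
                            formal_charge = -5, chirality = "junk",
                            hybridization = "sp3d2"))
  expect_equal(which(vz[1:100] == 1), 100L)
  expect_equal(which(vz[102:106] == 1), 5L)   # >= 4 H
  expect_equal(which(vz[107:111] == 1), 1L)   # clamped to -2
  expect_equal(which(vz[112:115] == 1), 4L)   # unknown chirality -> other
  expect_equal(which(vz[116:120] == 1), 5L)   # unknown hybridization -> other
  expect_error(featurize_atom(list(atomic_number = 0)), "atomic number")
})

test_that("featurize_bond encodes blocks at the expected positions", {
  v <- featurize_bond(list(bond_type = "single", conjugated = FALSE,
                           in_ring = FALSE, stereo = "none"))
  expect_length(v, 13L)
  expect_equal(sum(v), 2)  # type one-hot + stereo "none"
  expect_equal(which(v == 1), c(1L, 8L))
  va <- featurize_bond(list(bond_type = "aromatic", conjugated = TRUE,
                            in_ring = TRUE, stereo = "none"))
  expect_equal(sum(va), 4)
  expect_equal(va[6L], 1)  # conjugation flag
  expect_equal(va[7L], 1)  # ring flag
  expect_error(featurize_bond(list(bond_type = "")), "bond type")
})

test_that("smiles_to_graph builds the expected graphs", {
  g1 <- smiles_to_graph("C")
  expect_equal(g1$n, 1L)
  expect_equal(nrow(g1$edges), 0L)
  expect_equal(g1$node_provenance, list(1L))

  g2 <- smiles_to_graph("CC")
  expect_equal(g2$n, 2L)
  expect_equal(nrow(g2$edges), 2L)
  expect_equal(g2$edge_features[1, ], g2$edge_features[2, ])

  benz <- smiles_to_graph("c1ccccc1")
  expect_equal(benz$n, 6L)
  expect_equal(nrow(benz$edges), 12L)
  expect_equal(sum(benz$node_features[, 101L]), 6)        # all aromatic
  expect_true(all(benz$edge_features[, 4L] == 1))         # aromatic bond type
  expect_true(all(benz$edge_features[, 6L] == 1))         # conjugated
  expect_true(all(benz$edge_features[, 7L] == 1))         # in ring
  expect_error(smiles_to_graph("not_a_smiles"), "not_a_smiles")
})

test_that("perception handles charge, H counts and chirality", {
  g <- smiles_to_graph("C[N+](C)(C)C")   # tetramethylammonium
  n_row <- 2L
  expect_equal(which(g$node_features[n_row, 1:100] == 1), 7L)
  expect_equal(which(g$node_features[n_row, 107:111] == 1), 4L)  # +1
  expect_equal(which(g$node_features[n_row, 102:106] == 1), 1L)  # 0 H
  gc <- smiles_to_graph("C[C@H](N)O")
  expect_equal(which(gc$node_features[2L, 112:115] == 1), 3L)    # @ -> ccw
  gcc <- smiles_to_graph("C[C@@H](N)O")
  expect_equal(which(gcc$node_features[2L, 112:115] == 1), 2L)   # @@ -> cw
  # ethene carbons are sp2, ethyne sp
  expect_equal(which(smiles_to_graph("C=C")$node_features[1L, 116:120] == 1), 2L)
  expect_equal(which(smiles_to_graph("C#C")$node_features[1L, 116:120] == 1), 1L)
})

test_that("feature widths and ones-counts hold across a random molecule set", {
  tab <- make_synthetic_task(100, seed = 21)
  graphs <- smiles_to_graphs(tab$smiles)
  for (g in graphs) {
    expect_equal(ncol(g$node_features), 120L)
    expect_equal(ncol(g$edge_features), 13L)
    # atom ones-count: 5 + aromatic flag
    expect_equal(rowSums(g$node_features), 5 + g$node_features[, 101L])
    # bond ones-count: 2 + conjugation + ring
    if (nrow(g$edges) > 0) {
      expect_equal(rowSums(g$edge_features),
                   2 + g$edge_features[, 6L] + g$edge_features[, 7L])
      # reversal symmetry of initial features
      expect_equal(g$edge_features, g$edge_features[g$rev_index, ,
                                                    drop = FALSE])
    }
  }
})

test_that("read_task_table handles masks, bad SMILES and round-trips", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("smiles,t1,t2", "CCO,1,0", "CC,,1", "c1ccccc1,0,0"), csv)
  tab <- read_task_table(csv)
  expect_equal(length(tab$smiles), 3L)
  expect_equal(sum(!tab$mask), 1L)
  expect_true(is.na(tab$labels[2, 1]))

  writeLines(c("smiles,t1", "CCO,1", "xyz@!bad,0", "CC,0"), csv)
  expect_warning(tab2 <- read_task_table(csv), "unparseable")
  expect_equal(length(tab2$smiles), 2L)
  expect_equal(tab2$n_dropped, 1L)

  expect_error(read_task_table(csv, smiles_col = "smi"), "smi")

  tab3 <- make_synthetic_task(12, seed = 5)
  out <- tempfile(fileext = ".csv")
  write_task_table(tab3, out)
  back <- read_task_table(out)
  expect_equal(back$smiles, tab3$smiles)
  expect_equal(unname(back$labels), unname(tab3$labels))
  expect_equal(unname(back$mask), unname(tab3$mask))
})
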