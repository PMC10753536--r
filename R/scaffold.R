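# Bemis-Murcko scaffold grouping and scaffold-based dataset splitting.
#
# The scaffold (framework) of a molecule is what remains after iteratively
# pruning all degree-1 heavy atoms: the ring systems plus the linkers between
# them. Acyclic molecules have an empty scaffold and share one group, matching
# the usual cheminformatics convention. Scaffold identity is decided by a
# canonical graph key: BLISS canonicalization (igraph) of the scaffold graph
# with atoms colored by element and bond orders encoded as colored
# edge-subdivision vertices, so the key is invariant to input atom order.

# canonical key of one scaffold graph (atoms z[], bonds matrix a,b,order)
.scaffold_key <- function(z, bonds) {
  n <- length(z)
  if (n == 0L) return("")
  nb <- nrow(bonds)
  # subdivision vertex per bond, colored by 1000 + bond order
  colors <- c(z, if (nb > 0L) 1000L + bonds[, 3L] else integer(0))
  edges <- if (nb > 0L) {
    mid <- n + seq_len(nb)
    rbind(cbind(bonds[, 1L], mid), cbind(mid, bonds[, 2L]))
  } else matrix(integer(0), 0L, 2L)
  ig <- igraph::make_empty_graph(n + nb, directed = FALSE)
  if (nrow(edges) > 0L) ig <- igraph::add_edges(ig, t(edges))
  perm <- igraph::canonical_permutation(ig, colors = as.integer(colors))$labeling
  canon <- igraph::permute(ig, perm)
  ccol <- integer(length(colors))
  ccol[perm] <- colors
  el <- igraph::as_edgelist(canon, names = FALSE)
  el <- cbind(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]))
  el <- el[order(el[, 1L], el[, 2L]), , drop = FALSE]
  paste0(paste(ccol, collapse = ","), "|",
         paste(el[, 1L], el[, 2L], sep = "-", collapse = ","))
}

#' Bemis-Murcko scaffold key of a molecule
#'
#' @param smiles one SMILES string.
#' @return Character key; `""` for acyclic molecules (empty scaffold). Keys are
#'   equal iff the scaffold graphs are isomorphic (elements and bond orders
#'   included).
#' @export
murcko_scaffold_key <- function(smiles) {
  g <- smiles_to_graph(smiles)
  reps <- .undirected_reps(g)
  bonds <- g$edges[reps, , drop = FALSE]
  z <- match(attr(g, "symbols"), .element_symbols)
  # bond order from the feature block (single/double/triple/aromatic/other)
  bt <- if (length(reps) > 0L) {
    apply(g$edge_features[reps, 1:5, drop = FALSE], 1L, which.max)
  } else integer(0)
  order3 <- c(1L, 2L, 3L, 4L, 1L)[bt]   # aromatic -> its own color (4)
  keep <- rep(TRUE, g$n)
  repeat {
    kept_bond <- keep[bonds[, 1L]] & keep[bonds[, 2L]]
    deg <- tabulate(bonds[kept_bond, 1L], g$n) +
      tabulate(bonds[kept_bond, 2L], g$n)
    leaf <- which(keep & deg <= 1L)
    if (length(leaf) == 0L) break
    keep[leaf] <- FALSE
  }
  if (!any(keep)) return("")
  idx <- which(keep)
  remap <- integer(g$n)
  remap[idx] <- seq_along(idx)
  kb <- bonds[keep[bonds[, 1L]] & keep[bonds[, 2L]], , drop = FALSE]
  ko <- order3[keep[bonds[, 1L]] & keep[bonds[, 2L]]]
  .scaffold_key(z[idx], cbind(remap[kb[, 1L]], remap[kb[, 2L]], ko))
}

#' Split specification
#'
#' @param train,valid,test fractions; must sum to 1.
#' @param seed RNG seed for the group shuffle.
#' @param mode `"scaffold"` (scaffold groups in seeded random order),
#'   `"scaffold_deterministic"` (groups ordered by decreasing size, key as
#'   tie-break), or `"random"` (plain molecule-level shuffle).
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(train = 0.8, valid = 0.1, test = 0.1, seed = 1,
                       mode = c("scaffold", "scaffold_deterministic", "random")) {
  mode <- match.arg(mode)
  if (abs(train + valid + test - 1) > 1e-8) stop("fractions must sum to 1")
  structure(list(train = train, valid = valid, test = test,
                 seed = as.integer(seed), mode = mode),
            class = "split_spec")
}

#' Scaffold-grouped train/validation/test split
#'
#' Molecules are grouped by Bemis-Murcko scaffold; whole groups are assigned
#' greedily to the training set until it holds at least `train` of the
#' molecules, then to validation until at least `valid`, and the remainder to
#' test. A scaffold group is never split across partitions. In `"random"` mode
#' molecules are shuffled individually instead.
#'
#' @param table [task_table()].
#' @param spec [split_spec()].
#' @return List with integer index vectors `train`, `valid`, `test`; every
#'   molecule appears exactly once.
#' @export
scaffold_split <- function(table, spec = split_spec()) {
  n <- length(table$smiles)
  stopifnot(n > 0L)
  if (spec$mode == "random") {
    idx <- .with_seed(spec$seed, sample.int(n))
    n_train <- floor(spec$train * n)
    n_valid <- floor(spec$valid * n)
    return(list(train = sort(idx[seq_len(n_train)]),
                valid = sort(idx[n_train + seq_len(n_valid)]),
                test = sort(idx[-seq_len(n_train + n_valid)])))
  }
  keys <- vapply(table$smiles, murcko_scaffold_key, character(1),
                 USE.NAMES = FALSE)
  groups <- split(seq_len(n), keys)
  if (length(groups) < 3L) {
    stop("need at least 3 scaffold groups to form three nonempty sets (got ",
         length(groups), ")")
  }
  ord <- if (spec$mode == "scaffold") {
    .with_seed(spec$seed, sample(length(groups)))
  } else {
    order(-lengths(groups), names(groups))
  }
  groups <- lapply(groups[ord], unname)
  train <- integer(0); valid <- integer(0); test <- integer(0)
  n_groups <- length(groups)
  for (gi in seq_along(groups)) {
    grp <- groups[[gi]]
    left_after <- n_groups - gi
    # keep enough whole groups in reserve so validation and test are nonempty
    need <- (length(valid) == 0L) + (length(test) == 0L)
    if (length(train) < spec$train * n && left_after >= need) {
      train <- c(train, grp)
    } else if ((length(valid) < spec$valid * n || length(valid) == 0L) &&
               left_after >= (length(test) == 0L)) {
      valid <- c(valid, grp)
    } else {
      test <- c(test, grp)
    }
  }
  stopifnot(length(train) > 0L, length(valid) > 0L, length(test) > 0L)
  list(train = sort(train), valid = sort(valid), test = sort(test))
}
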