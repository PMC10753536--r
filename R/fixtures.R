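# Synthetic graph and dataset generators. Everything is deterministic given
# `seed`, so test fixtures are built in code rather than shipped as files.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Cycle graph with random features
#'
#' @param n number of nodes (>= 3).
#' @param d_v,d_e node / edge feature widths.
#' @param seed RNG seed; same arguments give an identical graph.
#' @return `molgraph` with `n` nodes and `n` undirected edges; reverse edge
#'   pairs share their initial feature row.
#' @export
make_cycle <- function(n, d_v = 4, d_e = 4, seed = 1) {
  n <- as.integer(n)
  if (n < 3L) stop("a cycle needs n >= 3")
  und <- cbind(seq_len(n), c(seq_len(n)[-1L], 1L))
  .random_featured_graph(n, und, d_v, d_e, seed)
}

#' Path graph with random features
#'
#' @inheritParams make_cycle
#' @param n number of nodes (>= 1).
#' @return `molgraph` with `n` nodes and `n - 1` undirected edges.
#' @export
make_path <- function(n, d_v = 4, d_e = 4, seed = 1) {
  n <- as.integer(n)
  if (n < 1L) stop("a path needs n >= 1")
  und <- if (n > 1L) cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L) else matrix(integer(0), 0L, 2L)
  .random_featured_graph(n, und, d_v, d_e, seed)
}

#' Erdos-Renyi random graph stored as directed pairs
#'
#' @inheritParams make_cycle
#' @param edge_prob probability of each undirected edge, in \[0, 1\].
#' @return `molgraph`; `edge_prob = 1` gives the complete graph with
#'   `n(n-1)/2` undirected edges.
#' @export
make_random_graph <- function(n, edge_prob = 0.3, d_v = 4, d_e = 4, seed = 1) {
  n <- as.integer(n)
  if (edge_prob < 0 || edge_prob > 1) stop("edge_prob must lie in [0, 1]")
  .with_seed(seed, {
    und <- if (n >= 2L) {
      pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(pairs)) < edge_prob
      unname(pairs[keep, , drop = FALSE])
    } else matrix(integer(0), 0L, 2L)
    .featured_graph(n, und, d_v, d_e)
  })
}

.random_featured_graph <- function(n, und, d_v, d_e, seed) {
  .with_seed(seed, .featured_graph(n, und, d_v, d_e))
}

# build a molgraph from an undirected edge list; reverse pairs share features
.featured_graph <- function(n, und, d_v, d_e) {
  m <- nrow(und)
  nf <- matrix(stats::rnorm(n * d_v), n, d_v)
  und_f <- matrix(stats::rnorm(m * d_e), m, d_e)
  edges <- rbind(und, und[, 2:1, drop = FALSE])
  ef <- rbind(und_f, und_f)
  molgraph(n, edges, nf, ef)
}

# fragment vocabulary for synthetic molecules; `aromatic` marks units whose
# insertion makes the ring-label positive
.synth_vocab <- list(
  list(smi = "C",             aromatic = FALSE, terminal = FALSE),
  list(smi = "CC",            aromatic = FALSE, terminal = FALSE),
  list(smi = "CCC",           aromatic = FALSE, terminal = FALSE),
  list(smi = "C(C)C",         aromatic = FALSE, terminal = FALSE),
  list(smi = "C(=O)N",        aromatic = FALSE, terminal = FALSE),  # amide
  list(smi = "O",             aromatic = FALSE, terminal = FALSE),  # ether / -OH at end
  list(smi = "C1CCCC1",       aromatic = FALSE, terminal = FALSE),  # cyclopentane
  list(smi = "c1ccccc1",      aromatic = TRUE,  terminal = FALSE),  # benzene
  list(smi = "c1ccncc1",      aromatic = TRUE,  terminal = FALSE),  # pyridine
  list(smi = "[N+](=O)[O-]",  aromatic = FALSE, terminal = TRUE)    # nitro (chain end)
)

#' Synthetic molecular task table
#'
#' Assembles valid SMILES from a small fragment vocabulary (alkyl chains,
#' amide, ether/hydroxyl, cyclopentane, benzene, pyridine, nitro) and labels
#' each molecule by a computable structural rule: label 1 if the molecule
#' contains an aromatic ring. Classes are approximately balanced because the
#' class is drawn first and the fragment pool restricted accordingly.
#'
#' @param n_molecules number of molecules (>= 10).
#' @param seed RNG seed.
#' @param task_name label column name.
#' @return A [task_table()] with one binary task and a complete mask.
#' @export
make_synthetic_task <- function(n_molecules, seed = 1, task_name = "aromatic_ring") {
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 10L) stop("n_molecules must be at least 10")
  .with_seed(seed, {
    vocab <- .synth_vocab
    arom <- vapply(vocab, `[[`, logical(1), "aromatic")
    term <- vapply(vocab, `[[`, logical(1), "terminal")
    smis <- character(n_molecules)
    labels <- integer(n_molecules)
    for (i in seq_len(n_molecules)) {
      positive <- (i %% 2L == 0L)  # alternate classes: balanced by construction
      n_units <- sample(2:5, 1L)
      pool <- which(!term & (if (positive) TRUE else !arom))
      units <- sample(pool, n_units, replace = TRUE)
      if (positive && !any(arom[units])) {
        units[sample(n_units, 1L)] <- sample(which(arom), 1L)
      }
      parts <- vapply(vocab[units], `[[`, character(1), "smi")
      # optional terminal nitro on negatives stays negative; allow either class
      if (stats::runif(1) < 0.2) parts <- c(parts, "[N+](=O)[O-]")
      smis[i] <- paste(parts, collapse = "")
      labels[i] <- as.integer(positive)
    }
    lab <- matrix(as.numeric(labels), ncol = 1L,
                  dimnames = list(NULL, task_name))
    task_table(smiles = smis, labels = lab)
  })
}
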