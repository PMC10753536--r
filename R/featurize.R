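# SMILES -> attributed molecular graph.
#
# Parsing, 2D coordinates and aromatic-ring perception are delegated to
# ChemmineR/ChemmineOB (OpenBabel). Per-atom chemistry that the backend does
# not expose here (implicit hydrogen counts, hybridization, conjugation,
# chirality tags, double-bond cis/trans) is perceived in-package from the
# kekulized connection table; the rules are documented in the methods
# vignette. Hydrogens are implicit: the graph contains heavy atoms only, with
# the bonded-H count encoded as an atom feature.

.element_symbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr")

.default_valence <- c(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                      S = 2, Cl = 1, Br = 1, I = 1, As = 3, Se = 2, H = 1)

.chirality_levels <- c("unspecified", "cw", "ccw", "other")
.hybridization_levels <- c("sp", "sp2", "sp3", "sp3d", "other")
.bond_type_levels <- c("single", "double", "triple", "aromatic", "other")
.stereo_levels <- c("none", "any", "Z", "E", "cis", "trans")

#' Atom feature schema
#'
#' Block layout of the 120-dimensional initial atom vector: atomic-number
#' one-hot over 1..99 with position 100 = other (100), aromaticity flag (1),
#' bonded-H count 0..3 with position 5 = ">=4" (5), formal charge -2..+2
#' clamped (5), chirality tag (4), hybridization tag (5).
#'
#' @return Data frame with columns `block`, `width`, and `categories`
#'   (comma-separated category labels, or "" for flags/one-hots over numbers).
#' @export
atom_feature_schema <- function() {
  data.frame(
    block = c("atom_type", "aromaticity", "n_hydrogens", "formal_charge",
              "chirality", "hybridization"),
    width = c(100L, 1L, 5L, 5L, 4L, 5L),
    categories = c("atomic number 1..99, 100 = other", "flag",
                   "0,1,2,3,>=4", "-2,-1,0,+1,+2 (clamped)",
                   paste(.chirality_levels, collapse = ","),
                   paste(.hybridization_levels, collapse = ",")),
    stringsAsFactors = FALSE)
}

#' Bond feature schema
#'
#' Block layout of the 13-dimensional initial bond vector: bond type (5),
#' conjugation flag (1), in-ring flag (1), stereo tag (6).
#'
#' @return Data frame as in [atom_feature_schema()].
#' @export
bond_feature_schema <- function() {
  data.frame(
    block = c("bond_type", "conjugation", "in_ring", "stereo"),
    width = c(5L, 1L, 1L, 6L),
    categories = c(paste(.bond_type_levels, collapse = ","), "flag", "flag",
                   paste(.stereo_levels, collapse = ",")),
    stringsAsFactors = FALSE)
}

.one_hot <- function(pos, width) {
  v <- numeric(width)
  v[pos] <- 1
  v
}

# categorical index with the block's last position as fallback
.cat_index <- function(value, levels) {
  i <- match(value, levels)
  if (is.na(i)) length(levels) else i
}

#' Featurize one atom
#'
#' @param atom list (or one-row data frame) with fields `atomic_number`,
#'   `aromatic` (logical), `n_h` (bonded hydrogens), `formal_charge`,
#'   `chirality` (one of `"unspecified"`, `"cw"`, `"ccw"`, `"other"`),
#'   `hybridization` (one of `"sp"`, `"sp2"`, `"sp3"`, `"sp3d"`, `"other"`).
#'   Out-of-range categorical values map to the block's last position.
#' @return Numeric 0/1 vector of length 120.
#' @export
featurize_atom <- function(atom) {
  z <- as.integer(atom$atomic_number)
  if (is.na(z) || z < 1L) stop("atomic number must be >= 1")
  c(.one_hot(min(z, 100L), 100L),
    as.numeric(isTRUE(as.logical(atom$aromatic))),
    .one_hot(min(max(as.integer(atom$n_h), 0L), 4L) + 1L, 5L),
    .one_hot(min(max(as.integer(atom$formal_charge), -2L), 2L) + 3L, 5L),
    .one_hot(.cat_index(as.character(atom$chirality), .chirality_levels), 4L),
    .one_hot(.cat_index(as.character(atom$hybridization), .hybridization_levels), 5L))
}

#' Featurize one bond
#'
#' @param bond list with fields `bond_type` (one of `"single"`, `"double"`,
#'   `"triple"`, `"aromatic"`, `"other"`), `conjugated`, `in_ring` (logicals),
#'   `stereo` (one of `"none"`, `"any"`, `"Z"`, `"E"`, `"cis"`, `"trans"`).
#' @return Numeric 0/1 vector of length 13.
#' @export
featurize_bond <- function(bond) {
  bt <- as.character(bond$bond_type)
  if (is.na(bt) || !nzchar(bt)) stop("bond type missing")
  c(.one_hot(.cat_index(bt, .bond_type_levels), 5L),
    as.numeric(isTRUE(as.logical(bond$conjugated))),
    as.numeric(isTRUE(as.logical(bond$in_ring))),
    .one_hot(.cat_index(as.character(bond$stereo), .stereo_levels), 6L))
}

# ---- perception -------------------------------------------------------------

# chirality tags lexed from the SMILES text, in atom order of appearance
# (OpenBabel preserves input atom order in the connection table)
.smiles_chirality <- function(smiles) {
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  tags <- character(0)
  i <- 1L
  n <- length(chars)
  organic <- c("B", "C", "N", "O", "P", "S", "F", "I",
               "b", "c", "n", "o", "p", "s", "*")
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      content <- paste(chars[i:j], collapse = "")
      tags <- c(tags, if (grepl("@@", content, fixed = TRUE)) "cw"
                      else if (grepl("@", content, fixed = TRUE)) "ccw"
                      else "unspecified")
      i <- j + 1L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r")) {
      tags <- c(tags, "unspecified")  # Cl / Br
      i <- i + 2L
    } else if (ch %in% organic) {
      tags <- c(tags, "unspecified")
      i <- i + 1L
    } else if (ch == "%") {
      i <- i + 3L  # two-digit ring closure
    } else {
      i <- i + 1L
    }
  }
  tags
}

# perceive atoms/bonds of one ChemmineR SDF; returns list(atoms=, bonds=)
# with bonds as an undirected table (a < b not enforced; one row per bond)
.perceive_sdf <- function(sdf, smiles = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (n == 0L) stop("empty atom block")
  symbols <- gsub("_.*$", "", rownames(ab))
  z <- match(symbols, .element_symbols)
  if (anyNA(z)) stop("unknown element symbol: ",
                     paste(unique(symbols[is.na(z)]), collapse = ", "))
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  code_map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                `6` = -2, `7` = -3)
  charge <- unname(code_map[as.character(charge_code)])
  charge[is.na(charge)] <- 0

  nb <- if (is.null(bb) || nrow(bb) == 0L) {
    matrix(integer(0), 0L, 3L)
  } else {
    cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]), as.integer(bb[, 3L]))
  }
  nbonds <- nrow(nb)
  order_num <- ifelse(nb[, 3L] %in% c(1L, 2L, 3L), nb[, 3L], 1L)

  # aromatic rings (sizes bounded; aromatic systems of interest are small)
  arom_atom <- rep(FALSE, n)
  arom_bond <- rep(FALSE, nbonds)
  if (nbonds > 0L && n >= 3L) {
    rr <- tryCatch(
      ChemmineR::rings(sdf, upper = 12, type = "all", arom = TRUE),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    arings <- if (is.null(rr$RINGS)) list() else rr$RINGS[which(rr$AROMATIC)]
    bond_key <- paste(pmin(nb[, 1L], nb[, 2L]), pmax(nb[, 1L], nb[, 2L]))
    for (ring in arings) {
      idx <- as.integer(gsub("^.*_", "", ring))
      arom_atom[idx] <- TRUE
      ringpairs <- cbind(idx, c(idx[-1L], idx[1L]))
      rkey <- paste(pmin(ringpairs[, 1L], ringpairs[, 2L]),
                    pmax(ringpairs[, 1L], ringpairs[, 2L]))
      arom_bond[bond_key %in% rkey] <- TRUE
    }
  }

  # in-ring bonds = non-bridge edges
  in_ring <- rep(FALSE, nbonds)
  if (nbonds > 0L) {
    ig <- igraph::graph_from_edgelist(nb[, 1:2, drop = FALSE], directed = FALSE)
    if (igraph::vcount(ig) < n) ig <- igraph::add_vertices(ig, n - igraph::vcount(ig))
    br <- igraph::bridges(ig)
    in_ring <- !(seq_len(nbonds) %in% as.integer(br))
  }

  # bond-order sums per atom (kekulized table: aromatic bonds are 1/2)
  bosum <- numeric(n)
  deg <- integer(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  for (k in seq_len(nbonds)) {
    a <- nb[k, 1L]; b <- nb[k, 2L]; o <- order_num[k]
    bosum[a] <- bosum[a] + o; bosum[b] <- bosum[b] + o
    deg[a] <- deg[a] + 1L; deg[b] <- deg[b] + 1L
    if (o == 2L) { n_double[a] <- n_double[a] + 1L; n_double[b] <- n_double[b] + 1L }
    if (o == 3L) { n_triple[a] <- n_triple[a] + 1L; n_triple[b] <- n_triple[b] + 1L }
  }

  # implicit hydrogens from a standard valence model
  n_h <- integer(n)
  for (i in seq_len(n)) {
    val <- .default_valence[symbols[i]]
    if (is.na(val)) { n_h[i] <- 0L; next }
    eff <- if (symbols[i] == "C") val - abs(charge[i]) else val + charge[i]
    n_h[i] <- max(0L, as.integer(round(eff - bosum[i])))
  }

  # hybridization heuristic from multiplicities and coordination
  hyb <- character(n)
  total_conn <- deg + n_h
  for (i in seq_len(n)) {
    hyb[i] <- if (n_triple[i] >= 1L || n_double[i] >= 2L) "sp"
      else if (arom_atom[i] || n_double[i] == 1L) "sp2"
      else if (total_conn[i] <= 4L) "sp3"
      else if (total_conn[i] == 5L) "sp3d"
      else "other"
  }

  # pi system membership: aromatic, multiple-bonded, or an N/O/S/P lone-pair
  # donor adjacent to a multiple-bonded or aromatic atom
  multi <- arom_atom | n_double > 0L | n_triple > 0L
  pi_atom <- multi
  if (nbonds > 0L) {
    for (k in seq_len(nbonds)) {
      a <- nb[k, 1L]; b <- nb[k, 2L]
      if (symbols[a] %in% c("N", "O", "S", "P") && multi[b]) pi_atom[a] <- TRUE
      if (symbols[b] %in% c("N", "O", "S", "P") && multi[a]) pi_atom[b] <- TRUE
    }
  }
  adj <- vector("list", n)
  for (k in seq_len(nbonds)) {
    adj[[nb[k, 1L]]] <- c(adj[[nb[k, 1L]]], nb[k, 2L])
    adj[[nb[k, 2L]]] <- c(adj[[nb[k, 2L]]], nb[k, 1L])
  }
  conj <- rep(FALSE, nbonds)
  for (k in seq_len(nbonds)) {
    a <- nb[k, 1L]; b <- nb[k, 2L]
    if (arom_bond[k]) { conj[k] <- TRUE; next }
    if (!(pi_atom[a] && pi_atom[b])) next
    if (order_num[k] == 1L) { conj[k] <- TRUE; next }
    others <- c(setdiff(adj[[a]], b), setdiff(adj[[b]], a))
    conj[k] <- length(others) > 0L && any(pi_atom[others])
  }

  # double-bond cis/trans from the generated 2D depiction
  stereo <- rep("none", nbonds)
  xy <- ab[, 1:2, drop = FALSE]
  for (k in seq_len(nbonds)) {
    if (order_num[k] != 2L || arom_bond[k]) next
    a <- nb[k, 1L]; b <- nb[k, 2L]
    na_ <- setdiff(adj[[a]], b); nb_ <- setdiff(adj[[b]], a)
    if (length(na_) == 0L || length(nb_) == 0L) next
    ra <- min(na_); rb <- min(nb_)
    v <- xy[b, ] - xy[a, ]
    sa <- v[1L] * (xy[ra, 2L] - xy[a, 2L]) - v[2L] * (xy[ra, 1L] - xy[a, 1L])
    sb <- v[1L] * (xy[rb, 2L] - xy[b, 2L]) - v[2L] * (xy[rb, 1L] - xy[b, 1L])
    if (abs(sa) < 1e-8 || abs(sb) < 1e-8) next
    stereo[k] <- if (sign(sa) == sign(sb)) "cis" else "trans"
  }

  chir <- rep("unspecified", n)
  if (!is.null(smiles)) {
    tags <- .smiles_chirality(smiles)
    if (length(tags) == n) chir <- tags
  }

  btype <- ifelse(arom_bond, "aromatic",
                  c("single", "double", "triple")[pmin(order_num, 3L)])
  list(
    atoms = data.frame(atomic_number = z, aromatic = arom_atom, n_h = n_h,
                       formal_charge = charge, chirality = chir,
                       hybridization = hyb, symbol = symbols,
                       stringsAsFactors = FALSE),
    bonds = data.frame(
      a = if (nbonds) nb[, 1L] else integer(0),
      b = if (nbonds) nb[, 2L] else integer(0),
      bond_type = if (nbonds) btype else character(0),
      conjugated = conj, in_ring = in_ring, stereo = stereo,
      stringsAsFactors = FALSE))
}

.molgraph_from_perception <- function(per, smiles) {
  n <- nrow(per$atoms)
  nf <- t(vapply(seq_len(n),
                 function(i) featurize_atom(per$atoms[i, ]),
                 numeric(120L)))
  nb <- nrow(per$bonds)
  if (nb > 0L) {
    bf <- t(vapply(seq_len(nb),
                   function(k) featurize_bond(per$bonds[k, ]),
                   numeric(13L)))
    edges <- rbind(cbind(per$bonds$a, per$bonds$b),
                   cbind(per$bonds$b, per$bonds$a))
    ef <- rbind(bf, bf)  # h(i->j) = h(j->i) = h(e(i,j)) initially
  } else {
    edges <- matrix(integer(0), 0L, 2L)
    ef <- matrix(numeric(0), 0L, 13L)
  }
  g <- molgraph(n, edges, nf, ef)
  attr(g, "smiles") <- smiles
  attr(g, "symbols") <- per$atoms$symbol
  g
}

# Fallback for molecules the bulk SDF reader cannot represent (notably
# bond-less molecules such as single heavy atoms): convert one SMILES with
# OpenBabel directly and read the V2000 atom lines. Ring perception is moot
# here (no bonds), so only atom-level fields are derived.
.perceive_single_fallback <- function(smiles) {
  txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\tmol\n"))
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 4L) stop("conversion produced no molecule")
  counts <- strsplit(trimws(lines[4L]), "\\s+")[[1L]]
  n <- as.integer(counts[1L])
  nb <- as.integer(counts[2L])
  if (is.na(n) || n < 1L || is.na(nb) || nb > 0L) {
    stop("fallback reader handles bond-less molecules only")
  }
  fields <- lapply(4L + seq_len(n), function(i) {
    strsplit(trimws(lines[i]), "\\s+")[[1L]]
  })
  symbols <- vapply(fields, `[`, character(1), 4L)
  z <- match(symbols, .element_symbols)
  if (anyNA(z)) stop("unknown element symbol")
  code_map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1,
                `6` = -2, `7` = -3)
  charge <- unname(code_map[vapply(fields, `[`, character(1), 6L)])
  charge[is.na(charge)] <- 0
  n_h <- vapply(seq_len(n), function(i) {
    val <- .default_valence[symbols[i]]
    if (is.na(val)) return(0L)
    eff <- if (symbols[i] == "C") val - abs(charge[i]) else val + charge[i]
    max(0L, as.integer(round(eff)))
  }, integer(1))
  chir <- rep("unspecified", n)
  if (!is.null(smiles)) {
    tags <- .smiles_chirality(smiles)
    if (length(tags) == n) chir <- tags
  }
  list(
    atoms = data.frame(atomic_number = z, aromatic = FALSE, n_h = n_h,
                       formal_charge = charge, chirality = chir,
                       hybridization = "sp3", symbol = symbols,
                       stringsAsFactors = FALSE),
    bonds = data.frame(a = integer(0), b = integer(0),
                       bond_type = character(0), conjugated = logical(0),
                       in_ring = logical(0), stereo = character(0),
                       stringsAsFactors = FALSE))
}

# parse one SMILES through every available route; NULL when unparseable
.parse_one <- function(smiles) {
  per <- tryCatch({
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m")))
    .perceive_sdf(sdf[[1L]], smiles)
  }, error = function(e) NULL)
  if (is.null(per)) {
    per <- tryCatch(.perceive_single_fallback(smiles), error = function(e) NULL)
  }
  per
}

#' Parse a batch of SMILES into molecular graphs
#'
#' @param smiles character vector.
#' @param on_error `"error"` (default): stop at the first unparseable string,
#'   naming it; `"drop"`: return `NULL` for failures and attach the failed
#'   indices as attribute `"failed"`.
#' @return List of [molgraph()] objects (with attributes `smiles`, `symbols`).
#' @export
smiles_to_graphs <- function(smiles, on_error = c("error", "drop")) {
  on_error <- match.arg(on_error)
  stopifnot(is.character(smiles), length(smiles) > 0L)
  ids <- sprintf("m%08d", seq_along(smiles))
  names(smiles) <- ids
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  got <- if (is.null(sdfset)) character(0) else ChemmineR::cid(sdfset)
  out <- vector("list", length(smiles))
  failed <- integer(0)
  for (i in seq_along(smiles)) {
    k <- match(ids[i], got)
    per <- if (!is.na(k)) {
      tryCatch(.perceive_sdf(sdfset[[k]], smiles[[i]]),
               error = function(e) NULL)
    } else NULL
    # an unparseable molecule earlier in the batch can abort the bulk
    # conversion; retry individually before declaring failure
    if (is.null(per)) per <- .parse_one(unname(smiles[[i]]))
    if (!is.null(per)) {
      out[[i]] <- .molgraph_from_perception(per, unname(smiles[[i]]))
    } else if (on_error == "error") {
      stop("unparseable SMILES: '", unname(smiles[[i]]), "'", call. = FALSE)
    } else {
      failed <- c(failed, i)
    }
  }
  attr(out, "failed") <- failed
  out
}

#' Parse a single SMILES into a molecular graph
#'
#' One node per heavy atom; each bond stored as both directed copies sharing
#' the initial 13-dimensional bond feature row; node features are the
#' 120-dimensional vectors of [featurize_atom()]; provenance sets start as
#' singletons.
#'
#' @param smiles one SMILES string.
#' @return A [molgraph()].
#' @examples
#' g <- smiles_to_graph("c1ccccc1")  # benzene: 6 nodes, 12 directed edges
#' @export
smiles_to_graph <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  smiles_to_graphs(smiles, on_error = "error")[[1L]]
}

# ---- task tables ------------------------------------------------------------

#' Construct a task table (SMILES + label matrix + missing mask)
#'
#' @param smiles character vector.
#' @param labels numeric matrix (rows = molecules, columns = tasks), NA =
#'   missing label.
#' @param mask optional logical matrix; defaults to `!is.na(labels)`.
#' @param n_dropped count of rows removed upstream (unparseable SMILES).
#' @return Object of class `task_table`.
#' @export
task_table <- function(smiles, labels, mask = NULL, n_dropped = 0L) {
  if (!is.matrix(labels)) labels <- matrix(labels, ncol = 1L)
  stopifnot(length(smiles) == nrow(labels))
  if (is.null(mask)) mask <- !is.na(labels)
  stopifnot(identical(dim(mask), dim(labels)))
  labels[!mask] <- NA_real_
  structure(list(smiles = as.character(smiles), labels = labels,
                 mask = mask, n_dropped = as.integer(n_dropped)),
            class = "task_table")
}

#' @export
print.task_table <- function(x, ...) {
  cat(sprintf("<task_table> %d molecules, %d task(s), %d missing label(s)",
              length(x$smiles), ncol(x$labels), sum(!x$mask)))
  if (x$n_dropped > 0L) cat(sprintf(", %d row(s) dropped at read", x$n_dropped))
  cat("\n")
  invisible(x)
}

#' @export
length.task_table <- function(x) length(x$smiles)

#' Subset a task table by molecule indices
#' @param x `task_table`.
#' @param i integer indices.
#' @param ... unused.
#' @export
`[.task_table` <- function(x, i, ...) {
  task_table(x$smiles[i], x$labels[i, , drop = FALSE],
             x$mask[i, , drop = FALSE], x$n_dropped)
}

#' Read a MoleculeNet-style CSV into a task table
#'
#' Expects a header row, one SMILES column, and one or more numeric label
#' columns; empty cells are missing labels. Rows whose SMILES cannot be parsed
#' are dropped with a warning and counted in `n_dropped`.
#'
#' @param path CSV file path.
#' @param smiles_col name of the SMILES column (default `"smiles"`).
#' @return A [task_table()].
#' @export
read_task_table <- function(path, smiles_col = "smiles") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!smiles_col %in% names(df)) {
    stop("no '", smiles_col, "' column in ", path)
  }
  smis <- as.character(df[[smiles_col]])
  labcols <- setdiff(names(df), smiles_col)
  if (length(labcols) == 0L) stop("no label columns in ", path)
  labels <- as.matrix(df[labcols])
  storage.mode(labels) <- "double"
  gs <- smiles_to_graphs(smis, on_error = "drop")
  failed <- attr(gs, "failed")
  if (length(failed) > 0L) {
    warning(length(failed), " row(s) with unparseable SMILES dropped: ",
            paste(utils::head(smis[failed], 5L), collapse = ", "),
            if (length(failed) > 5L) ", ..." else "")
    keep <- setdiff(seq_along(smis), failed)
    smis <- smis[keep]
    labels <- labels[keep, , drop = FALSE]
  }
  task_table(smis, labels, n_dropped = length(failed))
}

#' Write a task table as a MoleculeNet-style CSV
#'
#' @param x `task_table`.
#' @param path output file.
#' @param smiles_col name for the SMILES column.
#' @return `path`, invisibly.
#' @export
write_task_table <- function(x, path, smiles_col = "smiles") {
  df <- data.frame(x$smiles, stringsAsFactors = FALSE)
  names(df) <- smiles_col
  labs <- as.data.frame(x$labels)
  labs[!x$mask] <- NA
  df <- cbind(df, labs)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
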