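# Pooling traces: a machine-readable record of which original atoms each
# pooled node represents at every depth, plus the surviving bonds in original
# atom coordinates. This is the interpretability surface: after training, the
# groups correspond to contracted substructures (rings, functional groups) and
# the preserved bonds to the connections the model chose to keep.

#' Trace the pooling decisions of a model on one molecule
#'
#' Runs a forward pass and records, after every pooling layer, the partition
#' of the original atoms into current nodes (`groups`), the subsets contracted
#' at that layer (`new_groups`, the reduction stage), and the surviving bonds
#' expressed as original atom pairs (`preserved_bonds`, the connection stage).
#'
#' @param model fitted or freshly initialized `mespool_model` (or a list with
#'   `config` and `params`).
#' @param smiles one SMILES string.
#' @return Object of class `pooling_trace` with fields `smiles`, `n_atoms`,
#'   `layers` (one entry per pooling layer).
#' @export
pooling_trace <- function(model, smiles) {
  stopifnot(!is.null(model$config), !is.null(model$params))
  if (!model$config$pooling) stop("model has no pooling layers to trace")
  g <- smiles_to_graph(smiles)
  fw <- forward_model(g, model$params, model$config, trace = TRUE)
  reps0 <- .undirected_reps(g)
  # per directed edge: the set of original bonds it aggregates (k x 2, a < b)
  origin <- lapply(seq_len(nrow(g$edges)), function(k) {
    cbind(min(g$edges[k, ]), max(g$edges[k, ]))
  })
  layers <- vector("list", length(fw$trace))
  for (l in seq_along(fw$trace)) {
    ti <- fw$trace[[l]]
    gb <- ti$graph_before
    ga <- ti$graph_after
    if (!is.null(ti$pooled)) {
      sel <- ti$selection
      node_map <- ti$pooled$node_map
      preserved <- setdiff(seq_len(nrow(gb$edges)), sel$pooled_dir)
      pre <- cbind(node_map[gb$edges[preserved, 1L]],
                   node_map[gb$edges[preserved, 2L]])
      grp <- match(paste(pre[, 1L], pre[, 2L]),
                   paste(ga$edges[, 1L], ga$edges[, 2L]))
      new_origin <- vector("list", nrow(ga$edges))
      for (k in seq_along(preserved)) {
        tgt <- grp[k]
        new_origin[[tgt]] <- rbind(new_origin[[tgt]], origin[[preserved[k]]])
      }
      origin <- lapply(new_origin, function(m) unique(m))
      new_groups <- ti$pooled$components
      new_groups <- lapply(seq_along(new_groups), function(k) {
        sort(unlist(gb$node_provenance[new_groups[[k]]], use.names = FALSE))
      })
    } else {
      new_groups <- list()
    }
    reps <- .undirected_reps(ga)
    bonds <- unique(do.call(rbind, c(list(matrix(integer(0), 0L, 2L)),
                                     origin[reps])))
    bonds <- bonds[order(bonds[, 1L], bonds[, 2L]), , drop = FALSE]
    layers[[l]] <- list(
      groups = lapply(ga$node_provenance, sort),
      new_groups = new_groups,
      preserved_bonds = bonds)
  }
  structure(list(smiles = smiles, n_atoms = g$n, layers = layers),
            class = "pooling_trace")
}

#' @export
print.pooling_trace <- function(x, ...) {
  cat(sprintf("<pooling_trace> %s (%d atoms), %d pooling layer(s)\n",
              x$smiles, x$n_atoms, length(x$layers)))
  for (l in seq_along(x$layers)) {
    ly <- x$layers[[l]]
    multi <- Filter(function(v) length(v) > 1L, ly$groups)
    cat(sprintf("  layer %d: %d node(s), %d supernode group(s), %d preserved bond(s)\n",
                l, length(ly$groups), length(multi), nrow(ly$preserved_bonds)))
  }
  invisible(x)
}

.trace_canonical <- function(trace) {
  trace$layers <- lapply(trace$layers, function(ly) {
    g <- lapply(ly$groups, function(v) sort(as.integer(v)))
    ng <- lapply(ly$new_groups, function(v) sort(as.integer(v)))
    pb <- matrix(as.integer(ly$preserved_bonds), ncol = 2L)
    pb <- pb[order(pb[, 1L], pb[, 2L]), , drop = FALSE]
    list(groups = g[order(vapply(g, min, integer(1)))],
         new_groups = if (length(ng)) ng[order(vapply(ng, min, integer(1)))] else list(),
         preserved_bonds = pb)
  })
  trace
}

#' Export a pooling trace as JSON
#'
#' Writes the schema documented in `system.file("schema",
#' "pooling_trace.schema.json", package = "mespool")`; [read_trace()] restores
#' it losslessly.
#'
#' @param trace [pooling_trace()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  stopifnot(inherits(trace, "pooling_trace"))
  trace <- .trace_canonical(trace)
  obj <- list(
    format = "mespool_pooling_trace",
    version = 1L,
    smiles = trace$smiles,
    n_atoms = trace$n_atoms,
    layers = lapply(trace$layers, function(ly) {
      list(groups = lapply(ly$groups, as.integer),
           new_groups = lapply(ly$new_groups, as.integer),
           preserved_bonds = lapply(seq_len(nrow(ly$preserved_bonds)),
                                    function(i) as.integer(ly$preserved_bonds[i, ])))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pooling trace written by [export_trace()]
#'
#' @param path JSON file.
#' @return A `pooling_trace` object.
#' @export
read_trace <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "mespool_pooling_trace")) {
    stop(path, " is not a pooling trace file")
  }
  layers <- lapply(obj$layers, function(ly) {
    pb <- if (length(ly$preserved_bonds)) {
      do.call(rbind, lapply(ly$preserved_bonds, function(p) {
        as.integer(unlist(p))
      }))
    } else matrix(integer(0), 0L, 2L)
    list(groups = lapply(ly$groups, function(v) as.integer(unlist(v))),
         new_groups = lapply(ly$new_groups, function(v) as.integer(unlist(v))),
         preserved_bonds = pb)
  })
  structure(list(smiles = obj$smiles, n_atoms = as.integer(obj$n_atoms),
                 layers = layers),
            class = "pooling_trace")
}

#' Validate a pooling trace (structure and invariants)
#'
#' Checks the JSON-schema structure (required fields and types) and the
#' scientific invariants: at every layer the groups partition the atom set,
#' and every group at layer l+1 is a union of layer-l groups (refinement in
#' reverse).
#'
#' @param trace `pooling_trace` object or a path to a trace JSON file.
#' @return `TRUE`, invisibly; errors with a message on the first violation.
#' @export
validate_trace <- function(trace) {
  if (is.character(trace)) trace <- read_trace(trace)
  stopifnot(inherits(trace, "pooling_trace"))
  if (!is.character(trace$smiles) || trace$n_atoms < 1L) {
    stop("trace header malformed")
  }
  atoms <- seq_len(trace$n_atoms)
  prev <- as.list(atoms)
  for (l in seq_along(trace$layers)) {
    ly <- trace$layers[[l]]
    all_atoms <- sort(unlist(ly$groups, use.names = FALSE))
    if (!identical(as.integer(all_atoms), as.integer(atoms))) {
      stop("layer ", l, ": groups do not partition the atom set")
    }
    for (grp in ly$groups) {
      covered <- Filter(function(p) any(p %in% grp), prev)
      if (!setequal(unlist(covered), grp)) {
        stop("layer ", l, ": group not a union of previous-layer groups")
      }
    }
    if (nrow(ly$preserved_bonds) > 0L &&
        (any(ly$preserved_bonds < 1L) || any(ly$preserved_bonds > trace$n_atoms))) {
      stop("layer ", l, ": preserved bond references an unknown atom")
    }
    prev <- ly$groups
  }
  invisible(TRUE)
}
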