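# Reverse-mode automatic differentiation over dense matrices.
#
# Every differentiable quantity is an `adnode`: an environment holding a value
# (always a numeric matrix; scalars are 1x1), its parent nodes, and a backward
# closure mapping the node's output gradient to parent gradients. Operations
# accept plain matrices as well; when no input is an adnode the op returns a
# plain matrix, so the same layer code serves both numeric evaluation (tests,
# prediction) and training.

.ad_env <- new.env(parent = emptyenv())
.ad_env$counter <- 0L

#' Wrap a matrix as a differentiable leaf
#'
#' Creates a leaf node on the automatic-differentiation tape. After a backward
#' pass the accumulated gradient is available via [ad_grad()].
#'
#' @param x numeric matrix (or vector, coerced to a one-column matrix).
#' @param name optional label, used in error messages.
#' @return An object of class `adnode`.
#' @seealso [ad_backward()], [ad_value()], [ad_grad()]
#' @export
ad_leaf <- function(x, name = NULL) {
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  node <- new.env(parent = emptyenv())
  node$val <- x
  node$grad <- NULL
  node$parents <- list()
  node$backfn <- NULL
  node$name <- name
  .ad_env$counter <- .ad_env$counter + 1L
  node$id <- .ad_env$counter
  class(node) <- "adnode"
  node
}

is_adnode <- function(x) inherits(x, "adnode")

#' Numeric value of a node (or pass-through for plain matrices)
#' @param x adnode or matrix.
#' @return The underlying numeric matrix.
#' @export
ad_value <- function(x) if (is_adnode(x)) x$val else x

#' Accumulated gradient of a node after [ad_backward()]
#' @param x adnode.
#' @return Gradient matrix (zeros if the node did not receive gradient).
#' @export
ad_grad <- function(x) {
  stopifnot(is_adnode(x))
  if (is.null(x$grad)) array(0, dim = dim(x$val)) else x$grad
}

# Internal node builder: computes val eagerly; records parents + backward.
# `backfn(g)` must return a list of gradients aligned with `parents`
# (NULL entries allowed for non-differentiable parents).
ad_make <- function(val, parents, backfn) {
  if (!any(vapply(parents, is_adnode, logical(1)))) return(val)
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- Filter(is_adnode, parents)
  node$parent_mask <- vapply(parents, is_adnode, logical(1))
  node$backfn <- backfn
  .ad_env$counter <- .ad_env$counter + 1L
  node$id <- .ad_env$counter
  class(node) <- "adnode"
  node
}

#' Run a backward pass from a scalar node
#'
#' Accumulates gradients into every reachable leaf. `root` must hold a 1x1
#' value (a scalar loss).
#'
#' @param root adnode with a 1x1 value.
#' @export
ad_backward <- function(root) {
  stopifnot(is_adnode(root), length(root$val) == 1L)
  # topological order by DFS (iterative; graphs can be deep)
  order <- vector("list", 64L)
  n_ord <- 0L
  visited <- new.env(parent = emptyenv())
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$stage == 1L) {
      if (!is.null(visited[[key]])) next
      visited[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, stage = 2L)
      for (p in node$parents) {
        if (is.null(visited[[as.character(p$id)]])) {
          stack[[length(stack) + 1L]] <- list(node = p, stage = 1L)
        }
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
    }
  }
  for (i in seq_len(n_ord)) order[[i]]$grad <- NULL
  root$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_len(n_ord))) {
    node <- order[[i]]
    if (is.null(node$backfn) || is.null(node$grad)) next
    pgrads <- node$backfn(node$grad)
    j <- 0L
    for (k in seq_along(node$parent_mask)) {
      if (!node$parent_mask[k]) next
      j <- j + 1L
      g <- pgrads[[k]]
      if (is.null(g)) next
      p <- node$parents[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

# ---- primitive operations -------------------------------------------------

#' Matrix product of two nodes/matrices
#' @param a,b conformable matrices or adnodes.
#' @return adnode (or matrix if both inputs are plain).
#' @export
ad_matmul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

#' Elementwise sum of two same-shape nodes/matrices
#' @param a,b same-shape matrices or adnodes.
#' @export
ad_add <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(av + bv, list(a, b), function(g) list(g, g))
}

#' Elementwise difference
#' @param a,b same-shape matrices or adnodes.
#' @export
ad_sub <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(av - bv, list(a, b), function(g) list(g, -g))
}

#' Elementwise (Hadamard) product
#' @param a,b same-shape matrices or adnodes.
#' @export
ad_mul <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  ad_make(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' Add a bias row vector to every row
#' @param a n x d matrix/adnode.
#' @param b length-d vector or 1 x d matrix/adnode.
#' @export
ad_add_bias <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  val <- sweep(av, 2L, as.numeric(bv), `+`)
  ad_make(val, list(a, b), function(g) {
    list(g, matrix(colSums(g), 1L))
  })
}

#' Subtract a row vector from every row
#' @param a n x d matrix/adnode.
#' @param v length-d vector or 1 x d matrix/adnode.
#' @export
ad_sub_rowvec <- function(a, v) {
  av <- ad_value(a); vv <- ad_value(v)
  val <- sweep(av, 2L, as.numeric(vv), `-`)
  ad_make(val, list(a, v), function(g) {
    list(g, matrix(-colSums(g), 1L))
  })
}

#' Multiply each column by the entries of a row vector
#' @param a n x d matrix/adnode.
#' @param v length-d vector or 1 x d matrix/adnode.
#' @export
ad_mul_rowvec <- function(a, v) {
  av <- ad_value(a); vv <- as.numeric(ad_value(v))
  val <- sweep(av, 2L, vv, `*`)
  ad_make(val, list(a, v), function(g) {
    list(sweep(g, 2L, vv, `*`), matrix(colSums(g * av), 1L))
  })
}

#' Scale each row by a per-row scalar
#' @param a n x d matrix/adnode.
#' @param s length-n vector or n x 1 matrix/adnode of row scales.
#' @export
ad_scale_rows <- function(a, s) {
  av <- ad_value(a); sv <- as.numeric(ad_value(s))
  val <- av * sv
  ad_make(val, list(a, s), function(g) {
    list(g * sv, matrix(rowSums(g * av), ncol = 1L))
  })
}

#' Rectified linear unit
#' @param a matrix or adnode.
#' @export
ad_relu <- function(a) {
  av <- ad_value(a)
  val <- pmax(av, 0)
  ad_make(val, list(a), function(g) list(g * (av > 0)))
}

#' Logistic sigmoid
#' @param a matrix or adnode.
#' @export
ad_sigmoid <- function(a) {
  av <- ad_value(a)
  val <- 1 / (1 + exp(-av))
  ad_make(val, list(a), function(g) list(g * val * (1 - val)))
}

#' Column-wise binding of two nodes/matrices
#' @param a,b matrices or adnodes with equal row counts.
#' @export
ad_cbind <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  da <- ncol(av)
  ad_make(cbind(av, bv), list(a, b), function(g) {
    list(g[, seq_len(da), drop = FALSE], g[, -seq_len(da), drop = FALSE])
  })
}

#' Row-wise binding of two nodes/matrices
#' @param a,b matrices or adnodes with equal column counts.
#' @export
ad_rbind <- function(a, b) {
  av <- ad_value(a); bv <- ad_value(b)
  na <- nrow(av)
  ad_make(rbind(av, bv), list(a, b), function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

#' Gather rows by index (duplicates allowed)
#' @param a n x d matrix/adnode.
#' @param idx integer vector of row indices in 1..n.
#' @export
ad_rows <- function(a, idx) {
  av <- ad_value(a)
  idx <- as.integer(idx)
  val <- av[idx, , drop = FALSE]
  n <- nrow(av)
  ad_make(val, list(a), function(g) {
    out <- matrix(0, n, ncol(g))
    if (length(idx) > 0L) {
      agg <- rowsum(g, group = idx)
      out[as.integer(rownames(agg)), ] <- agg
    }
    list(out)
  })
}

#' Scatter-sum rows into a target of `nout` rows
#'
#' Row `i` of `a` is added into output row `idx[i]`. Output rows receiving no
#' input are zero. The workhorse of neighborhood aggregation and of the
#' per-graph summation readout.
#'
#' @param a n x d matrix/adnode.
#' @param idx integer vector (length n) of target rows in 1..nout.
#' @param nout number of output rows.
#' @export
ad_scatter_sum <- function(a, idx, nout) {
  av <- ad_value(a)
  idx <- as.integer(idx)
  nout <- as.integer(nout)
  val <- matrix(0, nout, ncol(av))
  if (nrow(av) > 0L) {
    agg <- rowsum(av, group = idx)
    val[as.integer(rownames(agg)), ] <- agg
  }
  ad_make(val, list(a), function(g) list(g[idx, , drop = FALSE]))
}

#' Column means as a 1 x d node
#' @param a n x d matrix/adnode, n >= 1.
#' @export
ad_colmeans <- function(a) {
  av <- ad_value(a)
  n <- nrow(av)
  val <- matrix(colMeans(av), 1L)
  ad_make(val, list(a), function(g) {
    list(matrix(rep(as.numeric(g) / n, each = n), n))
  })
}

#' Elementwise reciprocal square root, `1/sqrt(x + eps)`
#' @param a matrix or adnode with entries >= 0.
#' @param eps numerical floor added before the square root.
#' @export
ad_rsqrt <- function(a, eps = 1e-5) {
  av <- ad_value(a)
  val <- 1 / sqrt(av + eps)
  ad_make(val, list(a), function(g) list(g * (-0.5) * (av + eps)^(-1.5)))
}

#' Sum of all entries as a 1 x 1 node
#' @param a matrix or adnode.
#' @export
ad_sum <- function(a) {
  av <- ad_value(a)
  dims <- dim(av)
  ad_make(matrix(sum(av), 1L, 1L), list(a), function(g) {
    matrix(as.numeric(g), dims[1L], dims[2L]) |> list()
  })
}

#' Scale a node by a fixed scalar constant
#' @param a matrix or adnode.
#' @param k plain numeric scalar (not differentiated).
#' @export
ad_scalar_mul <- function(a, k) {
  av <- ad_value(a)
  ad_make(av * k, list(a), function(g) list(g * k))
}

#' Scale a node by a trainable 1 x 1 scalar node
#' @param a matrix or adnode.
#' @param s 1 x 1 matrix or adnode (e.g. a learnable layer weight).
#' @export
ad_scale_by_scalar <- function(a, s) {
  av <- ad_value(a); sv <- as.numeric(ad_value(s))
  ad_make(av * sv, list(a, s), function(g) {
    list(g * sv, matrix(sum(g * av), 1L, 1L))
  })
}

#' Masked binary cross-entropy with logits
#'
#' Numerically stable BCE, `max(z,0) - z*y + log(1 + exp(-|z|))`, averaged over
#' unmasked entries only. Implemented as one fused op with analytic gradient.
#'
#' @param z logits matrix/adnode (n x t).
#' @param y 0/1 labels (n x t); masked entries may hold any finite value.
#' @param mask logical/0-1 matrix (n x t); TRUE = labelled.
#' @return 1 x 1 node (or scalar matrix) with the mean loss.
#' @export
ad_masked_bce <- function(z, y, mask) {
  zv <- ad_value(z)
  m <- (mask != 0) * 1
  nm <- sum(m)
  if (nm == 0) stop("masked_bce: no unmasked entries")
  yz <- ifelse(m > 0, y, 0)
  lossmat <- (pmax(zv, 0) - zv * yz + log1p(exp(-abs(zv)))) * m
  val <- matrix(sum(lossmat) / nm, 1L, 1L)
  ad_make(val, list(z), function(g) {
    p <- 1 / (1 + exp(-zv))
    list(as.numeric(g) * (p - yz) * m / nm)
  })
}

#' Masked mean squared error
#' @param z predictions matrix/adnode (n x t).
#' @param y targets (n x t).
#' @param mask logical/0-1 matrix; TRUE = labelled.
#' @return 1 x 1 node (or scalar matrix) with the mean squared error.
#' @export
ad_masked_mse <- function(z, y, mask) {
  zv <- ad_value(z)
  m <- (mask != 0) * 1
  nm <- sum(m)
  if (nm == 0) stop("masked_mse: no unmasked entries")
  yz <- ifelse(m > 0, y, 0)
  d <- (zv - yz) * m
  val <- matrix(sum(d * d) / nm, 1L, 1L)
  ad_make(val, list(z), function(g) list(as.numeric(g) * 2 * d / nm))
}
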