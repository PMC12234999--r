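# Minimal tape-based reverse-mode automatic differentiation over matrices.
#
# Every forward pass builds a fresh tape: nodes are environments holding a
# value, parent links, and a backward closure. Operations are coarse matrix
# primitives (matmul, broadcasts, grouped sums/softmax, gathers), so tape
# overhead is negligible next to the BLAS work. The backward sweep walks the
# tape in reverse creation order, which is a valid topological order by
# construction.
#
# Internal: the training loop, the encoder and the propagation module are
# written against this API; user-facing functions only ever see plain
# matrices.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, val, parents = list(), back = NULL, req = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$val <- val
  nd$parents <- parents
  nd$back <- back
  nd$req <- if (is.null(req)) {
    any(vapply(parents, function(p) p$req, logical(1)))
  } else {
    req
  }
  nd$tape <- tape
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

ad_const <- function(tape, val) ad_node(tape, val, req = FALSE)
ad_param <- function(tape, val) ad_node(tape, val, req = TRUE)

is_ad <- function(x) is.environment(x)

.ad_wrap <- function(x, like) {
  if (is_ad(x)) x else ad_const(like$tape, x)
}

ad_value <- function(x) x$val

# --- backward sweep --------------------------------------------------------

ad_backward <- function(root) {
  tape <- root$tape
  n <- tape$n
  for (i in seq_len(n)) tape$nodes[[i]]$grad <- NULL
  root$grad <- 1
  for (i in rev(seq_len(n))) {
    nd <- tape$nodes[[i]]
    if (!nd$req || is.null(nd$grad) || is.null(nd$back)) next
    gs <- nd$back(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      g <- gs[[j]]
      if (!p$req || is.null(g)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(root)
}

ad_grad <- function(node) {
  if (is.null(node$grad)) node$val * 0 else node$grad
}

# --- broadcasting helpers --------------------------------------------------
# supported shapes for elementwise binary ops: equal dims; 1 x k row against
# n x k; n x 1 column against n x k; scalar against anything

.bc_expand <- function(v, dims) {
  dv <- dim(v)
  if (is.null(dv)) {
    if (length(v) == 1L) return(matrix(v, dims[1], dims[2]))
    stop("vector operand must be a matrix", call. = FALSE)
  }
  if (identical(dv, dims)) return(v)
  if (dv[1] == 1L && dv[2] == dims[2]) return(matrix(v, dims[1], dims[2], byrow = TRUE))
  if (dv[2] == 1L && dv[1] == dims[1]) return(matrix(v, dims[1], dims[2]))
  if (all(dv == c(1L, 1L))) return(matrix(v[1], dims[1], dims[2]))
  stop("non-conformable operands", call. = FALSE)
}

.bc_back <- function(g, src_dims) {
  if (is.null(dim(g))) g <- matrix(g, 1L, 1L)
  dg <- dim(g)
  if (is.null(src_dims)) return(sum(g))
  if (identical(dg, src_dims)) return(g)
  if (src_dims[1] == 1L && src_dims[2] == dg[2]) return(matrix(colSums(g), 1L))
  if (src_dims[2] == 1L && src_dims[1] == dg[1]) return(matrix(rowSums(g), ncol = 1L))
  if (all(src_dims == c(1L, 1L))) return(matrix(sum(g), 1L, 1L))
  stop("non-conformable gradient", call. = FALSE)
}

.out_dims <- function(a, b) {
  da <- dim(a); db <- dim(b)
  if (is.null(da)) da <- c(1L, 1L)
  if (is.null(db)) db <- c(1L, 1L)
  c(max(da[1], db[1]), max(da[2], db[2]))
}

.ad_binary <- function(a, b, fwd, bwd_a, bwd_b) {
  tape <- if (is_ad(a)) a$tape else b$tape
  a <- .ad_wrap(a, list(tape = tape))
  b <- .ad_wrap(b, list(tape = tape))
  dims <- .out_dims(a$val, b$val)
  av <- .bc_expand(a$val, dims)
  bv <- .bc_expand(b$val, dims)
  da <- dim(a$val); db <- dim(b$val)
  ad_node(tape, fwd(av, bv), parents = list(a, b), back = function(g) {
    list(.bc_back(bwd_a(g, av, bv), da), .bc_back(bwd_b(g, av, bv), db))
  })
}

ad_add <- function(a, b) {
  .ad_binary(a, b, function(x, y) x + y,
             function(g, x, y) g, function(g, x, y) g)
}

ad_sub <- function(a, b) {
  .ad_binary(a, b, function(x, y) x - y,
             function(g, x, y) g, function(g, x, y) -g)
}

ad_mul <- function(a, b) {
  .ad_binary(a, b, function(x, y) x * y,
             function(g, x, y) g * y, function(g, x, y) g * x)
}

# --- linear algebra --------------------------------------------------------

ad_matmul <- function(a, b) {
  tape <- if (is_ad(a)) a$tape else b$tape
  a <- .ad_wrap(a, list(tape = tape))
  b <- .ad_wrap(b, list(tape = tape))
  ad_node(tape, as.matrix(a$val %*% b$val), parents = list(a, b), back = function(g) {
    list(
      if (a$req) as.matrix(g %*% Matrix::t(b$val)) else NULL,
      if (b$req) as.matrix(Matrix::t(a$val) %*% g) else NULL
    )
  })
}

# a %*% t(b)
ad_tcrossprod <- function(a, b) {
  tape <- if (is_ad(a)) a$tape else b$tape
  a <- .ad_wrap(a, list(tape = tape))
  b <- .ad_wrap(b, list(tape = tape))
  ad_node(tape, as.matrix(a$val %*% t(b$val)), parents = list(a, b), back = function(g) {
    list(
      if (a$req) as.matrix(g %*% b$val) else NULL,
      if (b$req) as.matrix(t(g) %*% a$val) else NULL
    )
  })
}

# --- elementwise nonlinearities -------------------------------------------

.ad_unary <- function(x, fwd, bwd) {
  ad_node(x$tape, fwd(x$val), parents = list(x),
          back = function(g) list(bwd(g, x$val)))
}

ad_relu <- function(x) .ad_unary(x, function(v) pmax(v, 0),
                                 function(g, v) g * (v > 0))

ad_leakyrelu <- function(x, alpha = 0.2) {
  .ad_unary(x, function(v) ifelse(v > 0, v, alpha * v),
            function(g, v) g * ifelse(v > 0, 1, alpha))
}

ad_tanh_ <- function(x) {
  tv <- tanh(x$val)
  ad_node(x$tape, tv, parents = list(x), back = function(g) list(g * (1 - tv^2)))
}

ad_sigmoid <- function(x) {
  sv <- 1 / (1 + exp(-x$val))
  ad_node(x$tape, sv, parents = list(x), back = function(g) list(g * sv * (1 - sv)))
}

ad_square <- function(x) .ad_unary(x, function(v) v^2, function(g, v) 2 * g * v)

ad_sqrt_ <- function(x, eps = 0) {
  sv <- sqrt(x$val + eps)
  ad_node(x$tape, sv, parents = list(x), back = function(g) list(g * 0.5 / sv))
}

ad_scale <- function(x, s) .ad_unary(x, function(v) v * s, function(g, v) g * s)

ad_addc <- function(x, c) .ad_unary(x, function(v) v + c, function(g, v) g)

# --- reductions and indexing ----------------------------------------------

ad_sum <- function(x) {
  dims <- dim(x$val)
  ad_node(x$tape, sum(x$val), parents = list(x),
          back = function(g) list(matrix(g, dims[1], dims[2])))
}

ad_rowsums <- function(x) {
  k <- ncol(x$val)
  ad_node(x$tape, matrix(rowSums(x$val), ncol = 1L), parents = list(x),
          back = function(g) list(matrix(g, nrow(g), k)))
}

ad_gather <- function(x, idx) {
  n <- nrow(x$val)
  ad_node(x$tape, x$val[idx, , drop = FALSE], parents = list(x), back = function(g) {
    acc <- rowsum(g, group = idx)
    out <- matrix(0, n, ncol(g))
    out[as.integer(rownames(acc)), ] <- acc
    list(out)
  })
}

ad_group_sum <- function(x, group, ngroups) {
  acc <- rowsum(x$val, group = group)
  out <- matrix(0, ngroups, ncol(x$val))
  out[as.integer(rownames(acc)), ] <- acc
  ad_node(x$tape, out, parents = list(x),
          back = function(g) list(g[group, , drop = FALSE]))
}

# column-wise max within groups; subgradient flows to the first argmax row
ad_group_max <- function(x, group, ngroups) {
  v <- x$val
  k <- ncol(v)
  out <- matrix(-Inf, ngroups, k)
  arg <- matrix(NA_integer_, ngroups, k)
  sp <- split(seq_len(nrow(v)), group)
  for (j in seq_len(k)) {
    for (gname in names(sp)) {
      gi <- as.integer(gname)
      rows <- sp[[gname]]
      w <- rows[which.max(v[rows, j])]
      out[gi, j] <- v[w, j]
      arg[gi, j] <- w
    }
  }
  out[is.infinite(out)] <- 0
  ad_node(x$tape, out, parents = list(x), back = function(g) {
    gx <- matrix(0, nrow(v), k)
    for (j in seq_len(k)) {
      ok <- !is.na(arg[, j])
      gx[cbind(arg[ok, j], j)] <- gx[cbind(arg[ok, j], j)] + g[ok, j]
    }
    list(gx)
  })
}

# softmax of a column vector within groups (numerically stabilized)
ad_group_softmax <- function(x, group) {
  s <- as.numeric(x$val)
  m <- stats::ave(s, group, FUN = max)
  e <- exp(s - m)
  den <- stats::ave(e, group, FUN = sum)
  p <- e / den
  ad_node(x$tape, matrix(p, ncol = 1L), parents = list(x), back = function(g) {
    gv <- as.numeric(g)
    dot <- stats::ave(p * gv, group, FUN = sum)
    list(matrix(p * (gv - dot), ncol = 1L))
  })
}

ad_cbind2 <- function(a, b) {
  ka <- ncol(a$val)
  ad_node(a$tape, cbind(a$val, b$val), parents = list(a, b), back = function(g) {
    list(g[, seq_len(ka), drop = FALSE], g[, -seq_len(ka), drop = FALSE])
  })
}

ad_slice_cols <- function(x, cols) {
  k <- ncol(x$val)
  ad_node(x$tape, x$val[, cols, drop = FALSE], parents = list(x), back = function(g) {
    out <- matrix(0, nrow(g), k)
    out[, cols] <- g
    list(out)
  })
}

ad_vcat2 <- function(a, b) {
  na <- nrow(a$val)
  ad_node(a$tape, rbind(a$val, b$val), parents = list(a, b), back = function(g) {
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  })
}

# reshape a (n*k) x d matrix of k-row blocks into an n x (k*d) matrix
ad_blockflat <- function(x, k) {
  nk <- nrow(x$val); d <- ncol(x$val); n <- nk %/% k
  fwd <- function(v) {
    arr <- array(v, dim = c(k, n, d))
    matrix(aperm(arr, c(3, 1, 2)), nrow = n, byrow = TRUE)
  }
  ad_node(x$tape, fwd(x$val), parents = list(x), back = function(g) {
    arr <- aperm(array(t(g), dim = c(d, k, n)), c(2, 3, 1))
    list(matrix(arr, nrow = nk, ncol = d))
  })
}

# outer sum of two column vectors: out[i, j] = u[i] + v[j]
ad_outer_add <- function(u, v) {
  n <- nrow(u$val); m <- nrow(v$val)
  ad_node(u$tape, matrix(u$val, n, m) + matrix(v$val, n, m, byrow = TRUE),
          parents = list(u, v), back = function(g) {
    list(matrix(rowSums(g), ncol = 1L), matrix(colSums(g), ncol = 1L))
  })
}
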