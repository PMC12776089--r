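# Minimal reverse-mode automatic differentiation over dense vectors/matrices.
#
# The synthesis network is expressed in terms of a small set of coarse-grained
# primitives (gather/im2col, GEMM, pointwise nonlinearities, instance
# normalization, channel concatenation, softmax-weighted kernel mixtures).
# Each forward pass records nodes on a tape; ad_backward() walks the tape in
# reverse, accumulating gradients.  Values are numeric vectors or matrices;
# volumes with channels are stored as (n_voxels x channels) matrices, so all
# spatial structure lives in precomputed index tables (see layers.R).

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = list(), bw = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$parents <- parents
  nd$bw <- bw
  nd$grad <- NULL
  nd$tape <- tape
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  nd$idx <- tape$n
  tape$nodes[[tape$n]] <- nd
  nd
}

ad_leaf <- function(tape, value) ad_node(tape, value)

is_ad_node <- function(x) is.environment(x) && !is.null(x$value)

ad_value <- function(x) if (is_ad_node(x)) x$value else x

#' @noRd
ad_backward <- function(tape, root, seed_grad = 1) {
  root$grad <- seed_grad
  for (i in seq(root$idx, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd) || is.null(nd$grad) || is.null(nd$bw)) next
    gs <- nd$bw(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      g <- gs[[j]]
      if (is.null(g) || !is_ad_node(p)) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

# -- arithmetic ---------------------------------------------------------------

ad_add <- function(a, b) {
  an <- is_ad_node(a); bn <- is_ad_node(b)
  tape <- if (an) attr_tape(a) else attr_tape(b)
  va <- ad_value(a); vb <- ad_value(b)
  parents <- list(if (an) a else NULL, if (bn) b else NULL)
  ad_node(tape, va + vb, parents, function(g) list(if (an) g else NULL,
                                                   if (bn) g else NULL))
}

ad_sub <- function(a, b) {
  an <- is_ad_node(a); bn <- is_ad_node(b)
  tape <- if (an) attr_tape(a) else attr_tape(b)
  ad_node(tape, ad_value(a) - ad_value(b),
          list(if (an) a else NULL, if (bn) b else NULL),
          function(g) list(if (an) g else NULL, if (bn) -g else NULL))
}

# elementwise product; either operand may be a plain constant of the same
# shape (or scalar)
ad_mul <- function(a, b) {
  an <- is_ad_node(a); bn <- is_ad_node(b)
  tape <- if (an) attr_tape(a) else attr_tape(b)
  va <- ad_value(a); vb <- ad_value(b)
  ad_node(tape, va * vb,
          list(if (an) a else NULL, if (bn) b else NULL),
          function(g) list(if (an) sum_to_shape(g * vb, va) else NULL,
                           if (bn) sum_to_shape(g * va, vb) else NULL))
}

# reduce a gradient to the shape of x (handles scalar broadcasting)
sum_to_shape <- function(g, x) {
  if (length(x) == 1L && length(g) > 1L) sum(g) else g
}

# the tape a node was recorded on: recovered from the node environment
attr_tape <- function(nd) {
  # nodes do not carry a tape pointer; ops always receive at least one node
  # argument created by the caller, so we stash the tape at leaf creation time
  nd$tape
}

# -- linear algebra -----------------------------------------------------------

ad_matmul <- function(A, B) {
  an <- is_ad_node(A); bn <- is_ad_node(B)
  tape <- if (an) attr_tape(A) else attr_tape(B)
  vA <- ad_value(A); vB <- ad_value(B)
  ad_node(tape, vA %*% vB,
          list(if (an) A else NULL, if (bn) B else NULL),
          function(g) list(if (an) g %*% t(vB) else NULL,
                           if (bn) crossprod(vA, g) else NULL))
}

# y = x + bias replicated over rows (x: n x C, bias: length C)
ad_add_bias <- function(x, b) {
  tape <- attr_tape(x)
  vx <- ad_value(x); vb <- ad_value(b)
  bn <- is_ad_node(b)
  ad_node(tape, sweep_add(vx, vb),
          list(x, if (bn) b else NULL),
          function(g) list(g, if (bn) colSums(g) else NULL))
}

sweep_add <- function(x, b) x + rep(b, each = nrow(x))

# -- gather / scatter ---------------------------------------------------------

# precompute a gather/scatter plan for repeated use of one index table:
# idx entries index a flat source vector, 0 = "outside" (zero padding)
gather_plan <- function(idx, out_dim = NULL) {
  idx <- as.integer(idx)
  ord <- order(idx)
  ord <- ord[idx[ord] > 0L]              # positions, sorted by target index
  tgt <- idx[ord]
  ends <- c(which(diff(tgt) != 0L), length(tgt))
  list(idx1 = idx + 1L, out_dim = out_dim,
       ord = ord, ends = ends, ids = tgt[ends])
}

# y[i] = x[idx[i]] (0 -> 0) using a precomputed plan; backward scatters by
# sorted-run prefix sums (no hashing)
ad_gather0 <- function(x, plan, out_dim = NULL) {
  if (!is.list(plan)) plan <- gather_plan(plan, out_dim)
  tape <- attr_tape(x)
  vx <- ad_value(x)
  xp <- c(0, vx)
  y <- xp[plan$idx1]
  if (!is.null(plan$out_dim)) dim(y) <- plan$out_dim
  nx <- length(vx); dx <- dim(vx)
  ad_node(tape, y, list(x), function(g) {
    cs <- cumsum(g[plan$ord])
    sums <- cs[plan$ends] - c(0, cs[utils::head(plan$ends, -1L)])
    out <- numeric(nx)
    out[plan$ids] <- sums
    if (!is.null(dx)) dim(out) <- dx
    list(out)
  })
}

# -- nonlinearities -----------------------------------------------------------

ad_relu <- function(x) {
  tape <- attr_tape(x)
  vx <- ad_value(x)
  pos <- vx > 0
  ad_node(tape, vx * pos, list(x), function(g) list(g * pos))
}

# PReLU with a single learned slope per layer
ad_prelu <- function(x, alpha) {
  tape <- attr_tape(x)
  vx <- ad_value(x); va <- ad_value(alpha)
  an <- is_ad_node(alpha)
  pos <- vx > 0
  y <- ifelse(pos, vx, va * vx)
  if (!is.null(dim(vx))) dim(y) <- dim(vx)
  ad_node(tape, y, list(x, if (an) alpha else NULL),
          function(g) list(g * ifelse(pos, 1, va),
                           if (an) sum(g * vx * !pos) else NULL))
}

ad_sigmoid <- function(x) {
  tape <- attr_tape(x)
  s <- 1 / (1 + exp(-ad_value(x)))
  ad_node(tape, s, list(x), function(g) list(g * s * (1 - s)))
}

# softmax over a plain vector
ad_softmax <- function(x) {
  tape <- attr_tape(x)
  vx <- ad_value(x)
  e <- exp(vx - max(vx))
  s <- e / sum(e)
  ad_node(tape, s, list(x), function(g) list(s * (g - sum(g * s))))
}

# -- normalization ------------------------------------------------------------

# instance normalization: per column (channel) of an n x C matrix,
# (x - mean) / sqrt(var + eps), population variance, no affine parameters
ad_instnorm <- function(x, eps = 1e-5) {
  tape <- attr_tape(x)
  vx <- ad_value(x)
  n <- nrow(vx)
  mu <- colMeans(vx)
  xc <- sweep_add(vx, -mu)
  v <- colMeans(xc * xc)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv_sd, each = n)
  ad_node(tape, xhat, list(x), function(g) {
    gm <- colMeans(g)
    gx <- colMeans(g * xhat)
    list((g - rep(gm, each = n) - xhat * rep(gx, each = n)) *
           rep(inv_sd, each = n))
  })
}

# -- structure ----------------------------------------------------------------

# concatenate n x C_j matrices along the channel (column) dimension
ad_cbind <- function(...) {
  args <- list(...)
  tape <- NULL
  for (a in args) if (is_ad_node(a)) { tape <- attr_tape(a); break }
  vals <- lapply(args, ad_value)
  vals <- lapply(vals, function(v) if (is.null(dim(v))) matrix(v, ncol = 1L) else v)
  nc <- vapply(vals, ncol, 1L)
  ends <- cumsum(nc); starts <- c(1L, head(ends, -1L) + 1L)
  nodes <- vapply(args, is_ad_node, TRUE)
  ad_node(tape, do.call(cbind, vals), args, function(g) {
    lapply(seq_along(args), function(j) {
      if (!nodes[j]) return(NULL)
      gj <- g[, starts[j]:ends[j], drop = FALSE]
      if (is.null(dim(ad_value(args[[j]])))) gj <- as.vector(gj)
      gj
    })
  })
}

ad_sum <- function(x) {
  tape <- attr_tape(x)
  vx <- ad_value(x)
  ad_node(tape, sum(vx), list(x), function(g) {
    gx <- rep(g, length(vx)); dim(gx) <- dim(vx)
    list(gx)
  })
}

ad_mean <- function(x) {
  tape <- attr_tape(x)
  vx <- ad_value(x)
  n <- length(vx)
  ad_node(tape, sum(vx) / n, list(x), function(g) {
    gx <- rep(g / n, n); dim(gx) <- dim(vx)
    list(gx)
  })
}

# weighted sum of a fixed bank of same-shaped arrays: sum_k r_k W_k
# (the conditionally parameterized convolution kernel mixture)
ad_mix <- function(bank, r) {
  rn <- is_ad_node(r)
  tape <- if (rn) attr_tape(r) else attr_tape(bank[[1]])
  vr <- ad_value(r)
  vals <- lapply(bank, ad_value)
  acc <- vals[[1]] * vr[1]
  if (length(bank) > 1L) for (k in 2:length(bank)) acc <- acc + vals[[k]] * vr[k]
  nodes <- vapply(bank, is_ad_node, TRUE)
  ad_node(tape, acc, c(bank, list(if (rn) r else NULL)), function(g) {
    gs <- lapply(seq_along(bank), function(k) if (nodes[k]) g * vr[k] else NULL)
    gr <- if (rn) vapply(vals, function(w) sum(w * g), 0) else NULL
    c(gs, list(gr))
  })
}

ad_input <- ad_leaf
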