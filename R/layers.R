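# Network layers built on the autodiff primitives.
#
# Volumes with channels are (n_voxels x channels) matrices, column-major over
# the spatial grid.  Convolutions are im2col gathers followed by a GEMM; the
# im2col index tables are precomputed per (grid, kernel, stride, channels)
# and cached on the model object.

# neighbour index table: rows = output voxels, cols = kernel taps,
# entries = linear voxel index into the input grid (0 = outside, zero-padded)
nbr_idx <- function(grid, kernel = 3L, stride = 1L) {
  p <- as.integer(grid)
  out <- if (stride == 1L) p else p %/% stride
  half <- (kernel - 1L) %/% 2L
  offs <- seq.int(-half, half)
  centers <- lapply(1:3, function(d) stride * (seq_len(out[d]) - 1L) + 1L +
                      (if (stride > 1L) half else 0L))
  # coordinate grids for output voxels (column-major order)
  ci <- rep(centers[[1]], times = out[2] * out[3])
  cj <- rep(rep(centers[[2]], each = out[1]), times = out[3])
  ck <- rep(centers[[3]], each = out[1] * out[2])
  n_out <- prod(out)
  K <- kernel^3
  idx <- matrix(0L, n_out, K)
  col <- 0L
  for (dz in offs) for (dy in offs) for (dx in offs) {
    col <- col + 1L
    i <- ci + dx; j <- cj + dy; k <- ck + dz
    ok <- i >= 1L & i <= p[1] & j >= 1L & j <= p[2] & k >= 1L & k <= p[3]
    lin <- i + (j - 1L) * p[1] + (k - 1L) * p[1] * p[2]
    lin[!ok] <- 0L
    idx[, col] <- lin
  }
  list(idx = idx, out_grid = out, K = K)
}

# expand a voxel index table over input channels: x is stored as an
# (n_in x C) matrix, flat index (c-1)*n_in + v
expand_idx <- function(idx, n_in, C) {
  K <- ncol(idx)
  full <- matrix(0L, nrow(idx), K * C)
  for (c in seq_len(C)) {
    block <- idx + (c - 1L) * n_in
    block[idx == 0L] <- 0L
    full[, ((c - 1L) * K + 1L):(c * K)] <- block
  }
  full
}

# nearest-neighbour 2x upsampling index: fine voxel -> parent coarse voxel
upsample2_idx <- function(coarse_grid) {
  p <- as.integer(coarse_grid)
  fine <- 2L * p
  fi <- rep(seq_len(fine[1]), times = fine[2] * fine[3])
  fj <- rep(rep(seq_len(fine[2]), each = fine[1]), times = fine[3])
  fk <- rep(seq_len(fine[3]), each = fine[1] * fine[2])
  ci <- (fi + 1L) %/% 2L; cj <- (fj + 1L) %/% 2L; ck <- (fk + 1L) %/% 2L
  ci + (cj - 1L) * p[1] + (ck - 1L) * p[1] * p[2]
}

net_cache <- function(net, key, builder) {
  if (is.null(net$cache[[key]])) net$cache[[key]] <- builder()
  net$cache[[key]]
}

# im2col indices for a conv layer, cached
conv_cache <- function(net, grid, C_in, kernel, stride) {
  key <- paste0("c", paste(grid, collapse = "x"), "_", C_in, "_", kernel,
                "_", stride)
  net_cache(net, key, function() {
    nb <- nbr_idx(grid, kernel, stride)
    n_in <- prod(grid)
    n_out <- prod(nb$out_grid)
    list(plan = gather_plan(expand_idx(nb$idx, n_in, C_in),
                            out_dim = c(n_out, nb$K * C_in)),
         out_grid = nb$out_grid, n_out = n_out, K = nb$K)
  })
}

# -- parameters ---------------------------------------------------------------

# fetch (or create) the tape-local node for a named parameter, so that a
# parameter used twice on one tape accumulates both gradient contributions
pnode <- function(net, tape, name) {
  if (is.null(tape$pnodes)) tape$pnodes <- new.env(parent = emptyenv())
  nd <- tape$pnodes[[name]]
  if (is.null(nd)) {
    v <- net$params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    nd <- ad_leaf(tape, v)
    tape$pnodes[[name]] <- nd
  }
  nd
}

# collect parameter gradients from a tape after ad_backward()
collect_grads <- function(tape) {
  out <- list()
  if (is.null(tape$pnodes)) return(out)
  for (nm in ls(tape$pnodes)) {
    g <- tape$pnodes[[nm]]$grad
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

init_param <- function(net, name, value) {
  if (is.null(net$params[[name]])) net$params[[name]] <- value
  invisible(net)
}

# He-style initialization for a conv weight ((K*C_in) x C_out)
init_conv <- function(net, name, fan_in, C_out, zero = FALSE) {
  if (!is.null(net$params[[paste0(name, ".W")]])) return(invisible(net))
  W <- if (zero) matrix(0, fan_in, C_out) else
    matrix(stats::rnorm(fan_in * C_out, sd = sqrt(2 / fan_in)), fan_in, C_out)
  net$params[[paste0(name, ".W")]] <- W
  net$params[[paste0(name, ".b")]] <- numeric(C_out)
  invisible(net)
}

# -- layers -------------------------------------------------------------------

# one 3D convolution (same padding); x: node (n_in x C_in), returns node
# (n_out x C_out) plus the output grid as an attribute on the net call site
conv3d <- function(net, tape, x, grid, C_in, C_out, name,
                   kernel = 3L, stride = 1L) {
  cc <- conv_cache(net, grid, C_in, kernel, stride)
  init_conv(net, name, cc$K * C_in, C_out)
  col <- ad_gather0(x, cc$plan)
  y <- ad_add_bias(ad_matmul(col, pnode(net, tape, paste0(name, ".W"))),
                   pnode(net, tape, paste0(name, ".b")))
  attr(y, "out_grid") <- cc$out_grid
  y
}

# dropout (inverted); active only in training mode
net_dropout <- function(net, x) {
  rate <- net$config$dropout_rate
  if (!isTRUE(net$training) || rate <= 0) return(x)
  v <- ad_value(x)
  mask <- matrix(stats::rbinom(length(v), 1L, 1 - rate) / (1 - rate),
                 nrow(v), ncol(v))
  ad_mul(x, mask)
}

# conv -> PReLU -> dropout -> instance norm, repeated n_convs times.
# zero_last zero-initializes the final conv (residual-identity start).
conv_block_stack <- function(net, tape, x, grid, C_in, C_out, name,
                             n_convs = 3L, zero_last = FALSE) {
  cin <- C_in
  for (i in seq_len(n_convs)) {
    nm <- paste0(name, ".conv", i)
    if (zero_last && i == n_convs) {
      cc <- conv_cache(net, grid, cin, 3L, 1L)
      init_conv(net, nm, cc$K * cin, C_out, zero = TRUE)
    }
    x <- conv3d(net, tape, x, grid, cin, C_out, nm)
    init_param(net, paste0(nm, ".alpha"), net$config$negative_slope)
    x <- ad_prelu(x, pnode(net, tape, paste0(nm, ".alpha")))
    x <- net_dropout(net, x)
    x <- ad_instnorm(x)
    cin <- C_out
  }
  x
}

# additive attention gate: skip s (fine grid, C_s ch) gated by coarser g
attention_gate <- function(net, tape, s, g, grid_s, grid_g, C_s, C_g, name) {
  if (!all(grid_g * 2L == grid_s)) {
    stop("attention_gate: gate must be one level coarser than the skip")
  }
  F_int <- max(C_s %/% 2L, 1L)
  a_g <- conv3d(net, tape, g, grid_g, C_g, F_int, paste0(name, ".Wg"),
                kernel = 1L)
  a_g <- ad_gather0(a_g, upsample2_plan(net, grid_g, F_int))
  a_x <- conv3d(net, tape, s, grid_s, C_s, F_int, paste0(name, ".Wx"),
                kernel = 1L)
  init_param(net, paste0(name, ".alpha"), net$config$negative_slope)
  a <- ad_prelu(ad_add(a_g, a_x), pnode(net, tape, paste0(name, ".alpha")))
  psi <- ad_sigmoid(conv3d(net, tape, a, grid_s, F_int, 1L,
                           paste0(name, ".psi"), kernel = 1L))
  # broadcast the (n x 1) coefficient map over skip channels
  gated <- ad_mul(s, ad_matmul(psi, matrix(1, 1L, C_s)))
  list(gated = gated, psi = psi)
}

upsample2_cache <- function(net, coarse_grid) {
  key <- paste0("u", paste(coarse_grid, collapse = "x"))
  cache <- net_cache(net, key, function() {
    idx <- upsample2_idx(coarse_grid)
    list(idx = idx, n_fine = length(idx), n_coarse = prod(coarse_grid),
         full_by_C = list())
  })
  cache
}

upsample2_plan <- function(net, coarse_grid, C) {
  key <- paste0("u", paste(coarse_grid, collapse = "x"))
  cache <- upsample2_cache(net, coarse_grid)
  keyC <- as.character(C)
  if (is.null(cache$full_by_C[[keyC]])) {
    full <- expand_idx(matrix(cache$idx, ncol = 1L), cache$n_coarse, C)
    cache$full_by_C[[keyC]] <- gather_plan(full,
                                           out_dim = c(cache$n_fine, C))
    net$cache[[key]] <- cache   # cache list is copied on modify
  }
  net$cache[[key]]$full_by_C[[keyC]]
}

# conditionally parameterized up-sampling convolution: nearest 2x upsample,
# then a 3^3 conv whose kernel is a softmax mixture over a bank of experts
# routed by the conditioning vector.  With cond_mode = "film" the kernel is
# fixed and the output receives a per-channel scale/shift from the
# conditioning vector instead.
conditional_upsample <- function(net, tape, x, coarse_grid, C_in, C_out,
                                 cond, name) {
  fine_grid <- coarse_grid * 2L
  xu <- ad_gather0(x, upsample2_plan(net, coarse_grid, C_in))
  cc <- conv_cache(net, fine_grid, C_in, 3L, 1L)
  d <- net$config$conditioning_dim
  if (length(ad_value(cond)) != d) {
    stop("conditional_upsample: conditioning vector has length ",
         length(ad_value(cond)), ", expected ", d)
  }
  if (identical(net$config$cond_mode, "film")) {
    init_conv(net, name, cc$K * C_in, C_out)
    y <- ad_add_bias(ad_matmul(ad_gather0(xu, cc$plan),
                               pnode(net, tape, paste0(name, ".W"))),
                     pnode(net, tape, paste0(name, ".b")))
    init_param(net, paste0(name, ".Ws"), matrix(0, d, C_out))
    init_param(net, paste0(name, ".Wh"), matrix(0, d, C_out))
    cond_row <- matrix(ad_value(cond), 1L, d)
    scale <- ad_matmul(cond_row, pnode(net, tape, paste0(name, ".Ws")))
    shift <- ad_matmul(cond_row, pnode(net, tape, paste0(name, ".Wh")))
    ones <- matrix(1, cc$n_out, 1L)
    y <- ad_add(ad_mul(y, ad_add(ad_matmul(ones, scale), 1)),
                ad_matmul(ones, shift))
    attr(y, "out_grid") <- fine_grid
    return(y)
  }
  K_exp <- net$config$n_experts
  fan <- cc$K * C_in
  for (k in seq_len(K_exp)) {
    init_conv(net, paste0(name, ".e", k), fan, C_out)
  }
  init_param(net, paste0(name, ".R"), matrix(stats::rnorm(K_exp * d, sd = 0.1),
                                             K_exp, d))
  init_param(net, paste0(name, ".Rb"), numeric(K_exp))
  logits <- ad_add(ad_matmul(pnode(net, tape, paste0(name, ".R")),
                             matrix(ad_value(cond), ncol = 1L)),
                   pnode_vec_as_col(net, tape, paste0(name, ".Rb")))
  r <- ad_softmax(logits)
  W_eff <- ad_mix(lapply(seq_len(K_exp), function(k)
    pnode(net, tape, paste0(name, ".e", k, ".W"))), r)
  b_eff <- ad_mix(lapply(seq_len(K_exp), function(k)
    pnode(net, tape, paste0(name, ".e", k, ".b"))), r)
  col <- ad_gather0(xu, cc$plan)
  y <- ad_add_bias(ad_matmul(col, W_eff), b_eff)
  attr(y, "out_grid") <- fine_grid
  attr(y, "routing") <- ad_value(r)
  y
}

pnode_vec_as_col <- function(net, tape, name) {
  nd <- pnode(net, tape, name)
  # view the vector parameter as a column matrix on the tape
  ad_node(attr_tape(nd), matrix(ad_value(nd), ncol = 1L), list(nd),
          function(g) list(as.vector(g)))
}
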