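#' Construct a covariate-modulated attention U-Net synthesis model
#'
#' The synthesis network maps a structural MRI volume to a tau-PET SUVR
#' volume in three coupled pieces: (1) a convolutional encoder/decoder
#' backbone with additive attention gates on the skip connections; (2)
#' conditional up-sampling in the decoder, where every up-sampling
#' convolution is a conditionally parameterized convolution — a per-subject
#' softmax-routed mixture over a small bank of expert kernels, routed by the
#' standardized conditioning vector (age, sex, education, predicted MMSE,
#' predicted MetaTempTau); and (3) a dynamic-prompt modulation head: a
#' learned base prompt F is adjusted per subject as
#' `F_mod = F + ConvBlocks(F_c (+) S_hat (+) Gamma_hat)` where `F_c` is a
#' prompt selected by predicted amyloid status, `Gamma_hat`/`S_hat` carry
#' the boosted regional tau means/SDs painted into their ROI masks, and
#' `(+)` is channel concatenation.  The final prediction is
#' `ReLU(Conv(Z (+) ConvBlocks(F_mod (+) Z)))` with Z the backbone output,
#' so synthesized volumes are non-negative by construction.
#'
#' `ConvBlocks` is three repetitions of convolution, PReLU, dropout and
#' instance normalization.  The last convolution of each modulation branch
#' is zero-initialized, so at step 0 the head is an exact no-op
#' (`F_mod = F`) and early training is driven by the backbone alone.
#'
#' @param grid voxel counts (p1, p2, p3); each divisible by
#'   `2^(length(encoder_channels) - 1)`.
#' @param encoder_channels channel widths per resolution level.
#' @param conditioning_dim length of the conditioning vector (5:
#'   age, sex, education, predicted MMSE, predicted MetaTempTau).
#' @param prompt_bank_size number of covariate-indexed prompts (2, one per
#'   amyloid status).
#' @param prompt_channels channels of the learned prompt tensors.
#' @param n_experts expert kernels per conditional convolution.
#' @param dropout_rate dropout probability inside conv blocks.
#' @param negative_slope initial PReLU slope.
#' @param cond_mode `"condconv"` (expert-kernel mixture, default) or
#'   `"film"` (per-channel scale/shift from the conditioning vector).
#' @param gamma_in_modulation if TRUE (default) the regional-tau tensor
#'   enters the prompt modulation branch alongside the uncertainty tensor.
#' @param zero_init_modulation if TRUE (default) the final convolution of
#'   each modulation branch starts at zero (exact residual identity at
#'   step 0); disable to make every branch active from the first step.
#' @param ablate_conditioning if TRUE, the conditioning vector is replaced
#'   by zeros and the prompt is not subject-modulated, reducing the model to
#'   a plain attention U-Net whose output is independent of covariates.
#' @param seed parameter-initialization seed.
#' @return an object of class `coma_unet`.
#' @export
coma_unet <- function(grid,
                      encoder_channels = c(16L, 32L, 64L, 128L),
                      conditioning_dim = 5L,
                      prompt_bank_size = 2L,
                      prompt_channels = 4L,
                      n_experts = 4L,
                      dropout_rate = 0.1,
                      negative_slope = 0.25,
                      cond_mode = c("condconv", "film"),
                      gamma_in_modulation = TRUE,
                      zero_init_modulation = TRUE,
                      ablate_conditioning = FALSE,
                      seed = 1L) {
  grid <- as.integer(grid)
  levels <- length(encoder_channels)
  if (any(grid %% 2L^(levels - 1L) != 0L)) {
    stop("grid dims must be divisible by 2^(levels - 1) = ",
         2L^(levels - 1L))
  }
  if (prompt_bank_size < 1L) stop("prompt_bank_size must be >= 1")
  net <- new.env(parent = emptyenv())
  net$config <- list(grid = grid, encoder_channels = as.integer(encoder_channels),
                     levels = levels, conditioning_dim = as.integer(conditioning_dim),
                     prompt_bank_size = as.integer(prompt_bank_size),
                     prompt_channels = as.integer(prompt_channels),
                     n_experts = as.integer(n_experts),
                     dropout_rate = dropout_rate,
                     negative_slope = negative_slope,
                     cond_mode = match.arg(cond_mode),
                     gamma_in_modulation = isTRUE(gamma_in_modulation),
                     zero_init_modulation = isTRUE(zero_init_modulation),
                     ablate_conditioning = isTRUE(ablate_conditioning),
                     seed = as.integer(seed))
  net$params <- list()
  net$cache <- new.env(parent = emptyenv())
  net$training <- FALSE
  net$cond_stats <- NULL
  class(net) <- "coma_unet"
  with_seed(seed, {
    n_vox <- prod(grid)
    pc <- net$config$prompt_channels
    net$params[["prompt.F"]] <- matrix(stats::rnorm(n_vox * pc, sd = 0.01),
                                       n_vox, pc)
    for (b in seq_len(prompt_bank_size)) {
      net$params[[paste0("prompt.Fc", b)]] <-
        matrix(stats::rnorm(n_vox * pc, sd = 0.01), n_vox, pc)
    }
    # materialize all remaining parameters with a dummy forward pass
    dummy <- list(gamma_hat = array(0, grid), s_hat = array(0, grid),
                  covariate_index = 0L)
    invisible(coma_forward(net, array(0, grid), numeric(conditioning_dim),
                           dummy))
  })
  net
}

#' @export
print.coma_unet <- function(x, ...) {
  cfg <- x$config
  np <- sum(vapply(x$params, length, 0L))
  cat("Covariate-modulated attention U-Net\n")
  cat("  grid: ", paste(cfg$grid, collapse = " x "),
      "; levels: ", cfg$levels,
      " (channels ", paste(cfg$encoder_channels, collapse = "/"), ")\n",
      sep = "")
  cat("  conditioning: ", if (cfg$ablate_conditioning) "ABLATED" else
    paste0(cfg$cond_mode, ", dim ", cfg$conditioning_dim,
           ", ", cfg$n_experts, " experts"),
    "; prompt bank: ", cfg$prompt_bank_size, " x ", cfg$prompt_channels,
    " channels\n", sep = "")
  cat("  parameters: ", format(np, big.mark = ","), "\n", sep = "")
  if (!is.null(x$history)) {
    cat("  trained: ", nrow(x$history), " epochs, best val loss ",
        signif(min(x$history$val_loss), 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.coma_unet <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history (last 5 epochs):\n")
    print(utils::tail(object$history, 5L), row.names = FALSE)
  }
  invisible(object)
}

#' Plot the training history of a fitted synthesis model
#' @param x a trained `coma_unet`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.coma_unet <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "ROI-weighted MSE", ...)
  graphics::legend("topright", c("train", "validation"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

# -- forward pass -------------------------------------------------------------

# full forward pass; returns list(pred = output node, tape).  mri is a 3D
# array on the model grid, cond a numeric conditioning vector, regional a
# list(gamma_hat, s_hat, covariate_index).
coma_forward <- function(net, mri, cond, regional) {
  cfg <- net$config
  grid <- cfg$grid
  if (!all(dim(mri) == grid)) {
    stop("encoder: MRI shape ", paste(dim(mri), collapse = "x"),
         " does not match model grid")
  }
  if (cfg$ablate_conditioning) cond <- numeric(cfg$conditioning_dim)
  ci <- regional$covariate_index
  if (ci < 0L || ci >= cfg$prompt_bank_size) {
    stop("covariate_index ", ci, " outside the prompt bank [0, ",
         cfg$prompt_bank_size - 1L, ")")
  }
  tape <- ad_tape()
  ch <- cfg$encoder_channels
  L <- cfg$levels
  grids <- lapply(seq_len(L) - 1L, function(l) grid %/% (2L^l))

  x <- ad_leaf(tape, matrix(as.vector(mri), ncol = 1L))
  cond_node <- ad_leaf(tape, cond)

  # encoder with strided-conv downsampling
  enc <- vector("list", L)
  enc[[1]] <- conv_block_stack(net, tape, x, grids[[1]], 1L, ch[1], "enc1",
                               n_convs = 2L)
  for (l in 2:L) {
    d <- conv3d(net, tape, enc[[l - 1L]], grids[[l - 1L]], ch[l - 1L], ch[l],
                paste0("down", l), stride = 2L)
    init_param(net, paste0("down", l, ".alpha"), cfg$negative_slope)
    d <- ad_prelu(d, pnode(net, tape, paste0("down", l, ".alpha")))
    enc[[l]] <- conv_block_stack(net, tape, d, grids[[l]], ch[l], ch[l],
                                 paste0("enc", l), n_convs = 2L)
  }

  # decoder: conditional up-sampling + attention-gated skips
  dcur <- enc[[L]]
  for (l in seq(L - 1L, 1L)) {
    up <- conditional_upsample(net, tape, dcur, grids[[l + 1L]], ch[l + 1L],
                               ch[l], cond_node, paste0("up", l))
    att <- attention_gate(net, tape, enc[[l]], dcur, grids[[l]],
                          grids[[l + 1L]], ch[l], ch[l + 1L],
                          paste0("att", l))
    dcur <- conv_block_stack(net, tape, ad_cbind(up, att$gated), grids[[l]],
                             2L * ch[l], ch[l], paste0("dec", l),
                             n_convs = 2L)
  }
  z <- conv3d(net, tape, dcur, grid, ch[1], 1L, "zhead", kernel = 1L)

  pred <- final_prediction(net, tape, z, cond_node, regional, ci)
  list(pred = pred, z = z, tape = tape)
}

# dynamic-prompt modulation: F_mod = F + ConvBlocks(F_c (+) S (+) Gamma)
modulate_prompt <- function(net, tape, regional, ci) {
  cfg <- net$config
  f <- pnode(net, tape, "prompt.F")
  if (cfg$ablate_conditioning) return(f)
  fc <- pnode(net, tape, paste0("prompt.Fc", ci + 1L))
  s_hat <- matrix(as.vector(regional$s_hat), ncol = 1L)
  g_hat <- matrix(as.vector(regional$gamma_hat), ncol = 1L)
  inp <- if (cfg$gamma_in_modulation) {
    ad_cbind(fc, ad_leaf(tape, s_hat), ad_leaf(tape, g_hat))
  } else {
    ad_cbind(fc, ad_leaf(tape, s_hat))
  }
  cin <- cfg$prompt_channels + if (cfg$gamma_in_modulation) 2L else 1L
  mod <- conv_block_stack(net, tape, inp, cfg$grid, cin,
                          cfg$prompt_channels, "prompt.mod", n_convs = 3L,
                          zero_last = cfg$zero_init_modulation)
  ad_add(f, mod)
}

# output head: P = ReLU(Conv(Z (+) ConvBlocks(F_mod (+) Z)))
final_prediction <- function(net, tape, z, cond_node, regional, ci) {
  cfg <- net$config
  pc <- cfg$prompt_channels
  f_mod <- modulate_prompt(net, tape, regional, ci)
  inner <- conv_block_stack(net, tape, ad_cbind(f_mod, z), cfg$grid,
                            pc + 1L, pc, "head.inner", n_convs = 3L,
                            zero_last = cfg$zero_init_modulation)
  stage <- conv3d(net, tape, ad_cbind(z, inner), cfg$grid, pc + 1L, pc,
                  "head.conv")
  init_param(net, "head.conv.alpha", cfg$negative_slope)
  stage <- ad_prelu(stage, pnode(net, tape, "head.conv.alpha"))
  stage <- net_dropout(net, stage)
  stage <- ad_instnorm(stage)
  proj <- conv3d(net, tape, stage, cfg$grid, pc, 1L, "head.proj",
                 kernel = 1L)
  ad_relu(proj)
}

# evaluation-mode forward returning a plain 3D array
coma_synthesize_one <- function(net, mri, cond, regional) {
  was <- net$training
  net$training <- FALSE
  on.exit(net$training <- was)
  fw <- coma_forward(net, mri, cond, regional)
  out <- as.vector(ad_value(fw$pred))
  dim(out) <- net$config$grid
  out
}

# -- model inputs -------------------------------------------------------------

#' Preprocess an MRI volume to the model grid
#'
#' Nearest-neighbour resampling of the in-plane axes to (p1, p2), then
#' symmetric zero-padding (if short) or central cropping (if long) along
#' the axial axis to p3.  A volume already on the grid passes through
#' unchanged.
#'
#' @param volume 3D numeric array with positive intensities.
#' @param grid target (p1, p2, p3).
#' @return 3D array of shape `grid`.
#' @export
preprocess_mri <- function(volume, grid) {
  if (length(dim(volume)) != 3L || all(dim(volume) == 0L)) {
    stop("volume must be a non-empty 3D array")
  }
  grid <- as.integer(grid)
  d <- dim(volume)
  nn_idx <- function(n, p) pmin(n, pmax(1L, floor((seq_len(p) - 0.5) * n / p) + 1L))
  out <- volume[nn_idx(d[1], grid[1]), nn_idx(d[2], grid[2]), , drop = FALSE]
  nz <- dim(out)[3]
  if (nz < grid[3]) {
    pad_lo <- (grid[3] - nz) %/% 2L
    pad_hi <- grid[3] - nz - pad_lo
    padded <- array(0, c(grid[1], grid[2], grid[3]))
    padded[, , pad_lo + seq_len(nz)] <- out
    out <- padded
  } else if (nz > grid[3]) {
    lo <- (nz - grid[3]) %/% 2L
    out <- out[, , lo + seq_len(grid[3]), drop = FALSE]
  }
  out
}

#' Paint auxiliary regional estimates into prompt tensors
#'
#' Builds the voxel tensors consumed by the modulation head: `gamma_hat`
#' holds the predicted regional tau mean at every voxel of its ROI and 0 on
#' background; `s_hat` the predicted SD likewise; `covariate_index` is the
#' predicted amyloid status (selects the prompt from the bank).
#'
#' @param estimates a `coma_aux_estimates` (see [predict_auxiliary()]).
#' @param atlas a `coma_atlas`.
#' @param row subject row of `estimates` to use.
#' @return list(gamma_hat, s_hat, covariate_index).
#' @export
build_regional_tensors <- function(estimates, atlas, row = 1L) {
  ids <- atlas$roi_table$id
  have <- colnames(estimates$tau_hat)
  miss <- setdiff(as.character(ids), have)
  if (length(miss)) {
    stop("estimates missing ROI(s): ", paste(miss, collapse = ", "))
  }
  lab <- as.vector(atlas$label_volume)
  tau <- estimates$tau_hat[row, as.character(ids)]
  sg <- estimates$sigma_hat[row, as.character(ids)]
  gamma <- numeric(length(lab)); s <- numeric(length(lab))
  inside <- lab > 0L
  gamma[inside] <- tau[lab[inside]]
  s[inside] <- sg[lab[inside]]
  dim(gamma) <- dim(s) <- atlas$grid
  list(gamma_hat = gamma, s_hat = s,
       covariate_index = as.integer(estimates$abeta_status[row]))
}

#' Conditioning vector for one subject
#'
#' Raw covariates (age, sex, education) and stage-1 estimates (predicted
#' MMSE and MetaTempTau), standardized with the training-set statistics
#' stored on the model; sex is coded +/-1.
#'
#' @param model a `coma_unet` with conditioning statistics (set during
#'   training, or via `set_cond_stats()`).
#' @param covariates one-row data.frame with age, sex, education.
#' @param estimates a `coma_aux_estimates`.
#' @param row subject row.
#' @return numeric vector of length `conditioning_dim`.
#' @export
conditioning_vector <- function(model, covariates, estimates, row = 1L) {
  st <- model$cond_stats
  if (is.null(st)) stop("model has no conditioning statistics; train it or ",
                        "call set_cond_stats()")
  cr <- if (nrow(covariates) == 1L) 1L else row
  raw <- c(age = as.numeric(covariates$age[cr]),
           sex = ifelse(as.numeric(covariates$sex[cr]) > 0, 1, -1),
           education = as.numeric(covariates$education[cr]),
           mmse_hat = estimates$mmse_hat[row],
           meta_temp_hat = estimates$meta_temp_hat[row])
  z <- (raw - st$center) / st$scale
  # a missing raw covariate (e.g. education) falls back to the training
  # mean, i.e. 0 after standardization
  z[is.na(z)] <- 0
  z
}

#' @rdname conditioning_vector
#' @param cov_table covariate data.frame of the training split.
#' @export
set_cond_stats <- function(model, cov_table, estimates) {
  raw <- cbind(age = as.numeric(cov_table$age),
               sex = ifelse(as.numeric(cov_table$sex) > 0, 1, -1),
               education = as.numeric(cov_table$education),
               mmse_hat = estimates$mmse_hat,
               meta_temp_hat = estimates$meta_temp_hat)
  ctr <- colMeans(raw, na.rm = TRUE)
  sc <- apply(raw, 2, stats::sd, na.rm = TRUE)
  sc[sc == 0 | is.na(sc)] <- 1
  model$cond_stats <- list(center = ctr, scale = sc)
  invisible(model)
}

#' Synthesize tau-PET volumes for subjects of a cohort
#'
#' Evaluation-mode forward passes (deterministic): for each requested
#' subject the preprocessed MRI, conditioning vector and regional prompt
#' tensors are assembled and pushed through the network.
#'
#' @param object a trained `coma_unet`.
#' @param cohort a `coma_cohort` (or list of `coma_subject`).
#' @param estimates `coma_aux_estimates` aligned with the cohort entries.
#' @param atlas a `coma_atlas`.
#' @param rows which cohort entries to synthesize (default all).
#' @param ... unused.
#' @return list of 3D synthetic SUVR arrays.
#' @export
predict.coma_unet <- function(object, cohort, estimates, atlas,
                              rows = NULL, ...) {
  subs <- if (inherits(cohort, "coma_cohort")) cohort$subjects else cohort
  if (is.null(rows)) rows <- seq_along(subs)
  lapply(rows, function(i) {
    s <- subs[[i]]
    mri <- preprocess_mri(s$mri, object$config$grid)
    cond <- conditioning_vector(object, s$covariates, estimates, row = i)
    reg <- build_regional_tensors(estimates, atlas, row = i)
    coma_synthesize_one(object, mri, cond, reg)
  })
}

#' Serialize / restore a synthesis model
#'
#' The checkpoint is a single JSON file carrying the configuration,
#' conditioning statistics and all parameters (flattened, with shapes),
#' plus a format-version tag.
#'
#' @param model a `coma_unet`.
#' @param path file path (`.json`).
#' @return `save_coma_unet`: the path, invisibly; `load_coma_unet`: the
#'   restored model.
#' @export
save_coma_unet <- function(model, path) {
  pk <- lapply(model$params, function(p) {
    list(dim = if (is.null(dim(p))) length(p) else dim(p),
         data = as.vector(p))
  })
  cs <- if (!is.null(model$cond_stats)) {
    lapply(model$cond_stats, as.list)   # keep names through JSON
  }
  obj <- list(format = "coma_unet-v1", config = model$config,
              cond_stats = cs, params = pk,
              history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_coma_unet
#' @export
load_coma_unet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "coma_unet-v1")) {
    stop("not a coma_unet checkpoint: ", path)
  }
  cfg <- obj$config
  net <- coma_unet(grid = cfg$grid, encoder_channels = cfg$encoder_channels,
                   conditioning_dim = cfg$conditioning_dim,
                   prompt_bank_size = cfg$prompt_bank_size,
                   prompt_channels = cfg$prompt_channels,
                   n_experts = cfg$n_experts,
                   dropout_rate = cfg$dropout_rate,
                   negative_slope = cfg$negative_slope,
                   cond_mode = cfg$cond_mode,
                   gamma_in_modulation = cfg$gamma_in_modulation,
                   zero_init_modulation = cfg$zero_init_modulation,
                   ablate_conditioning = cfg$ablate_conditioning,
                   seed = cfg$seed)
  for (nm in names(obj$params)) {
    p <- obj$params[[nm]]
    v <- as.numeric(p$data)
    if (length(p$dim) > 1L) dim(v) <- p$dim
    net$params[[nm]] <- v
  }
  if (!is.null(obj$cond_stats)) {
    net$cond_stats <- list(center = unlist(obj$cond_stats$center),
                           scale = unlist(obj$cond_stats$scale))
  }
  if (!is.null(obj$history)) net$history <- as.data.frame(obj$history)
  net
}
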