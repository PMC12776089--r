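test_that("preprocess_mri resamples, pads and crops to the model grid", {
  g <- c(16L, 16L, 16L)
  v <- random_volume(g, 10)
  expect_identical(preprocess_mri(v, g), v)          # already on grid
  short <- v[, , 1:12]
  out <- preprocess_mri(short, g)
  expect_equal(dim(out), g)
  expect_equal(out[, , 3:14], short)                  # symmetric pad
  long <- random_volume(c(16, 16, 20), 11)
  expect_equal(dim(preprocess_mri(long, g)), g)
  # nearest-neighbour property: resampled values come from the input
  big <- random_volume(c(23, 19, 16), 12)
  out2 <- preprocess_mri(big, g)
  expect_true(all(out2 %in% big))
  expect_error(preprocess_mri(array(1, c(4, 4)), g), "3D")
})

test_that("conv blocks preserve spatial shape and are deterministic in
           evaluation mode", {
  net <- small_net()
  grid <- net$config$grid
  x <- matrix(rnorm(prod(grid) * 2), prod(grid), 2)
  t1 <- tausynth:::ad_tape()
  y1 <- tausynth:::conv_block_stack(net, t1, tausynth:::ad_leaf(t1, x),
                                    grid, 2L, 4L, "enc1b", n_convs = 3L)
  expect_equal(dim(tausynth:::ad_value(y1)), c(prod(grid), 4L))
  t2 <- tausynth:::ad_tape()
  y2 <- tausynth:::conv_block_stack(net, t2, tausynth:::ad_leaf(t2, x),
                                    grid, 2L, 4L, "enc1b", n_convs = 3L)
  expect_lt(max(abs(tausynth:::ad_value(y1) - tausynth:::ad_value(y2))),
            1e-7)
})

test_that("attention gate coefficients lie in [0,1] and bound the skip", {
  net <- small_net()
  grid_s <- net$config$grid
  grid_g <- grid_s %/% 2L
  s <- matrix(rnorm(prod(grid_s) * 4), prod(grid_s), 4)
  g <- matrix(rnorm(prod(grid_g) * 8), prod(grid_g), 8)
  tape <- tausynth:::ad_tape()
  att <- tausynth:::attention_gate(net, tape, tausynth:::ad_leaf(tape, s),
                                   tausynth:::ad_leaf(tape, g),
                                   grid_s, grid_g, 4L, 8L, "attx")
  psi <- tausynth:::ad_value(att$psi)
  expect_true(all(psi >= 0 & psi <= 1))
  gated <- tausynth:::ad_value(att$gated)
  expect_true(all(abs(gated) <= abs(s) + 1e-12))
  expect_error(
    tausynth:::attention_gate(net, tape, tausynth:::ad_leaf(tape, s),
                              tausynth:::ad_leaf(tape, g),
                              grid_s, grid_s, 4L, 8L, "attx"),
    "coarser")
})

test_that("conditional upsampling routes experts by the conditioning vector", {
  net <- small_net()
  gc <- net$config$grid %/% 2L
  x <- matrix(rnorm(prod(gc) * 4), prod(gc), 4)
  run <- function(cond) {
    tape <- tausynth:::ad_tape()
    y <- tausynth:::conditional_upsample(net, tape,
                                         tausynth:::ad_leaf(tape, x), gc,
                                         4L, 4L,
                                         tausynth:::ad_leaf(tape, cond),
                                         "upx")
    y
  }
  y1 <- run(c(0.5, -1, 0.3, 0.2, 1))
  r <- attr(y1, "routing")
  expect_equal(sum(r), 1, tolerance = 1e-12)      # softmax normalization
  expect_true(all(r >= 0))
  expect_equal(dim(tausynth:::ad_value(y1)), c(prod(gc) * 8L, 4L))
  # identical conditioning acts as a fixed convolution
  y2 <- run(c(0.5, -1, 0.3, 0.2, 1))
  expect_equal(tausynth:::ad_value(y1), tausynth:::ad_value(y2))
  # different conditioning changes the output
  y3 <- run(c(-2, 1, 0, 0, -1))
  expect_gt(max(abs(tausynth:::ad_value(y1) - tausynth:::ad_value(y3))), 0)
  expect_error(run(c(1, 2)), "conditioning vector")
})

test_that("regional prompt tensors paint estimates into ROI masks", {
  atl <- small_atlas()
  est <- small_estimates()
  reg <- build_regional_tensors(est, atl, row = 2L)
  lab <- atl$label_volume
  expect_true(all(reg$gamma_hat[lab == 0] == 0))
  expect_true(all(reg$s_hat[lab == 0] == 0))
  for (r in c(1L, 5L)) {
    expect_true(all(reg$gamma_hat[lab == r] == est$tau_hat[2, as.character(r)]))
    # regional_suvr round-trip: ROI mean of the painted tensor is tau_hat
    expect_equal(unname(regional_suvr(reg$gamma_hat, atl)[as.character(r)]),
                 unname(est$tau_hat[2, as.character(r)]))
  }
  expect_true(reg$covariate_index %in% c(0L, 1L))
  bad <- est
  bad$tau_hat <- bad$tau_hat[, -1, drop = FALSE]
  expect_error(build_regional_tensors(bad, atl), "missing ROI")
})

test_that("prompt modulation is an exact residual identity at zero init and
           responds to the prompt bank", {
  net <- small_net()
  atl <- small_atlas()
  est <- small_estimates()
  reg <- build_regional_tensors(est, atl, row = 1L)
  tape <- tausynth:::ad_tape()
  fm <- tausynth:::modulate_prompt(net, tape, reg, 0L)
  expect_identical(tausynth:::ad_value(fm), net$params[["prompt.F"]])
  expect_equal(dim(tausynth:::ad_value(fm)), dim(net$params[["prompt.F"]]))
  # after perturbing the zero-initialized layer, the two bank entries give
  # different modulated prompts
  net2 <- coma_unet(net$config$grid, encoder_channels = c(6, 12, 24),
                    seed = 9, zero_init_modulation = FALSE)
  t2 <- tausynth:::ad_tape()
  f0 <- tausynth:::ad_value(tausynth:::modulate_prompt(net2, t2, reg, 0L))
  t3 <- tausynth:::ad_tape()
  f1 <- tausynth:::ad_value(tausynth:::modulate_prompt(net2, t3, reg, 1L))
  expect_gt(max(abs(f0 - f1)), 0)
  # out-of-range prompt index is rejected at the forward entry
  bad <- reg
  bad$covariate_index <- 5L
  s <- small_cohort()$subjects[[1]]
  expect_error(tausynth:::coma_forward(net, s$mri, numeric(5), bad),
               "prompt bank")
})

test_that("forward output is non-negative, on-grid, deterministic, and
           sensitive to conditioning unless ablated", {
  net <- small_net()
  atl <- small_atlas()
  co <- small_cohort()
  est <- small_estimates()
  s <- co$subjects[[1]]
  cond <- conditioning_vector(net, s$covariates, est, row = 1)
  reg <- build_regional_tensors(est, atl, row = 1)
  out <- tausynth:::coma_synthesize_one(net, s$mri, cond, reg)
  expect_equal(dim(out), net$config$grid)
  expect_true(all(out >= 0))
  expect_identical(out, tausynth:::coma_synthesize_one(net, s$mri, cond, reg))
  # conditioning sensitivity (full model)
  cond2 <- cond + c(0, 0, 0, 0, 1)
  expect_gt(max(abs(tausynth:::coma_synthesize_one(net, s$mri, cond2, reg) -
                      out)), 0)
  # gamma sensitivity through the covariate index (non-zero-init model)
  netz <- coma_unet(net$config$grid, encoder_channels = c(6, 12, 24),
                    seed = 3, zero_init_modulation = FALSE)
  netz$cond_stats <- net$cond_stats
  reg2 <- reg
  reg2$gamma_hat <- reg$gamma_hat * 1.5
  expect_gt(max(abs(tausynth:::coma_synthesize_one(netz, s$mri, cond, reg2) -
                      tausynth:::coma_synthesize_one(netz, s$mri, cond, reg))),
            0)
  # ablated variant ignores covariates entirely
  neta <- coma_unet(net$config$grid, encoder_channels = c(6, 12, 24),
                    seed = 2, ablate_conditioning = TRUE)
  neta$cond_stats <- net$cond_stats
  o1 <- tausynth:::coma_synthesize_one(neta, s$mri, cond, reg)
  o2 <- tausynth:::coma_synthesize_one(neta, s$mri, cond2, reg2)
  expect_identical(o1, o2)
})

test_that("gradients reach the regional-prompt parameters", {
  net <- coma_unet(c(16, 16, 16), encoder_channels = c(6, 12, 24), seed = 5,
                   zero_init_modulation = FALSE)
  atl <- small_atlas()
  est <- small_estimates()
  co <- small_cohort()
  set_cond_stats(net, cohort_covariates(co), est)
  s <- co$subjects[[1]]
  cond <- conditioning_vector(net, s$covariates, est, row = 1)
  reg <- build_regional_tensors(est, atl, row = 1)
  fw <- tausynth:::coma_forward(net, s$mri, cond, reg)
  loss <- tausynth:::ad_mean(fw$pred)
  tausynth:::ad_backward(fw$tape, loss)
  g <- tausynth:::collect_grads(fw$tape)
  expect_gt(max(abs(g[["prompt.mod.conv1.W"]])), 0)
  expect_gt(max(abs(g[["prompt.F"]])), 0)
})

test_that("checkpoints round-trip through JSON", {
  net <- small_net()
  path <- tempfile(fileext = ".json")
  save_coma_unet(net, path)
  net2 <- load_coma_unet(path)
  expect_equal(net2$params, net$params, tolerance = 1e-12)
  expect_equal(net2$cond_stats$center, net$cond_stats$center)
  atl <- small_atlas()
  est <- small_estimates()
  s <- small_cohort()$subjects[[1]]
  cond <- conditioning_vector(net, s$covariates, est, row = 1)
  reg <- build_regional_tensors(est, atl, row = 1)
  expect_equal(tausynth:::coma_synthesize_one(net, s$mri, cond, reg),
               tausynth:::coma_synthesize_one(net2, s$mri, cond, reg),
               tolerance = 1e-8)
  unlink(path)
})
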