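test_that("build_atlas produces a valid, deterministic parcellation", {
  atl <- build_atlas(c(16, 16, 16), n_rois = 8, seed = 1)
  expect_s3_class(atl, "coma_atlas")
  labs <- unique(as.vector(atl$label_volume))
  expect_true(all(labs %in% 0:8))
  expect_identical(atl$label_volume,
                   build_atlas(c(16, 16, 16), n_rois = 8, seed = 1)$label_volume)
  # exhaustive voxel scan: every ROI non-empty, ROI union inside the mask
  counts <- integer(8)
  mask <- tausynth:::brain_mask_vec(c(16L, 16L, 16L))
  lab <- as.vector(atl$label_volume)
  outside <- 0L
  for (v in seq_along(lab)) {
    if (lab[v] > 0) {
      counts[lab[v]] <- counts[lab[v]] + 1L
      if (!mask[v]) outside <- outside + 1L
    }
  }
  expect_identical(outside, 0L)
  expect_true(all(counts >= 1L))
  # bilateral pairs are name-matched and equally sized (mirror symmetry)
  tab <- atl$roi_table
  left <- tab[tab$hemisphere == "left", ]
  right <- tab[tab$hemisphere == "right", ]
  expect_equal(sub("_left$", "", left$name), sub("_right$", "", right$name))
  expect_equal(left$n_voxels, right$n_voxels)
})

test_that("atlas construction fails cleanly on impossible requests", {
  expect_error(build_atlas(c(4, 4, 4), 8, 1), "grid")
  expect_error(build_atlas(c(16, 16, 16), 7, 1), "even")
  expect_error(build_atlas(c(8, 8, 8), 600, 1), "too small")
})

test_that("regional_suvr matches an independent voxel-loop accumulation", {
  atl <- small_atlas()
  # constant volume: every ROI mean equals the constant
  expect_true(all(regional_suvr(array(2, atl$grid), atl) == 2))
  set.seed(4)
  vol <- array(rnorm(prod(atl$grid)), dim = atl$grid)
  means <- regional_suvr(vol, atl)
  # label-indexed accumulation oracle
  sums <- numeric(8); counts <- numeric(8)
  lab <- as.vector(atl$label_volume); v <- as.vector(vol)
  for (i in seq_along(lab)) {
    if (lab[i] > 0) {
      sums[lab[i]] <- sums[lab[i]] + v[i]
      counts[lab[i]] <- counts[lab[i]] + 1
    }
  }
  expect_lt(max(abs(means - sums / counts)), 1e-12)
  expect_error(regional_suvr(array(1, c(8, 8, 8)), atl), "grid")
})

test_that("meta_temp_tau is the voxel-count-weighted member average", {
  atl <- small_atlas()
  ids <- atl$roi_table$id
  m <- stats::setNames(rep(1.5, length(ids)), ids)
  expect_equal(meta_temp_tau(m, atl), 1.5)
  # hand-weighted two-member case: sizes 10/30, means 1/2 -> 1.75
  toy <- atl
  toy$meta_temp_members <- c(1L, 2L)
  toy$roi_table$n_voxels[1:2] <- c(10L, 30L)
  mm <- stats::setNames(c(1, 2, rep(9, 6)), ids)
  expect_equal(meta_temp_tau(mm, toy), 1.75)
  # convexity
  set.seed(5)
  r <- stats::setNames(runif(length(ids), 1, 3), ids)
  mem <- r[as.character(atl$meta_temp_members)]
  expect_gte(meta_temp_tau(r, atl), min(mem))
  expect_lte(meta_temp_tau(r, atl), max(mem))
  expect_error(meta_temp_tau(r[-1], atl), "missing")
})

test_that("noise-free degenerate subject equals the baseline field", {
  atl <- small_atlas()
  pp <- phantom_params(atl, stage_probs = c(1, 0, 0, 0), noise_sd = 0,
                       severity_sd = 0, mri_noise_sd = 0)
  s <- simulate_subject(atl, pp, seed = 7)
  expect_identical(s$truth$braak_group, 0L)
  expect_equal(s$truth$diagnosis, "CN")
  expect_equal(unname(regional_suvr(s$tau, atl)),
               unname(pp$tau_baseline), tolerance = 1e-12)
  # stored truth equals the ROI means of the noise-free field, and the
  # composite round-trips through regional_suvr + meta_temp_tau
  expect_lt(max(abs(regional_suvr(s$tau, atl) - s$truth$roi_mean_tau)), 1e-10)
  expect_lt(abs(meta_temp_tau(regional_suvr(s$tau, atl), atl) -
                  s$truth$meta_temp_tau), 1e-10)
})

test_that("subjects are deterministic and tau is positive in the mask", {
  atl <- small_atlas()
  pp <- small_params()
  s1 <- simulate_subject(atl, pp, seed = 42)
  s2 <- simulate_subject(atl, pp, seed = 42)
  expect_identical(s1$tau, s2$tau)
  expect_identical(s1$covariates, s2$covariates)
  expect_true(all(s1$tau[atlas_mask(atl)] > 0))
  expect_true(all(s1$mri >= 0))
})

test_that("mean regional tau is monotone in Braak group (noise-free)", {
  atl <- small_atlas()
  for (stage in 0:2) {
    p_lo <- phantom_params(atl, severity_sd = 0)
    m_lo <- tausynth:::subject_roi_means(p_lo, stage, 1)
    m_hi <- tausynth:::subject_roi_means(p_lo, stage + 1L, 1)
    expect_true(all(m_hi >= m_lo))
  }
})

test_that("ptau coupling matches the closed-form linear-Gaussian correlation", {
  atl <- small_atlas()
  pp <- small_params()
  co <- simulate_cohort(atl, pp, n = 500, seed = 21)
  tru <- cohort_truth(co)
  cov <- cohort_covariates(co)
  ok <- !is.na(cov$ptau217)
  r_obs <- cor(cov$ptau217[ok], tru$meta_temp_tau[ok])
  # closed form: enumerate (apoe, stage), lognormal severity moments
  cp <- pp$covariate_coupling
  meta_w <- atl$roi_table$n_voxels[match(atl$meta_temp_members,
                                         atl$roi_table$id)]
  base_meta <- sum(meta_w * pp$tau_baseline[as.character(atl$meta_temp_members)]) /
    sum(meta_w)
  amp <- function(stage) {
    inc <- pp$tau_increment[as.character(atl$meta_temp_members)]
    reached <- pmax(0L, stage - pp$onset_group[as.character(atl$meta_temp_members)] + 1L)
    sum(meta_w * inc * reached) / sum(meta_w)
  }
  Eg <- 1                                  # severity has mean 1
  Eg2 <- exp(pp$severity_sd^2)             # lognormal second moment
  # joint probabilities of (apoe, stage) with the APOE tilt
  p_as <- outer(cp$apoe_freq, 0:3, function(pa, s) pa) * 0
  for (a in 0:2) {
    tilt <- pp$stage_probs * exp(cp$apoe_stage_shift * a * (0:3))
    p_as[a + 1, ] <- cp$apoe_freq[a + 1] * tilt / sum(tilt)
  }
  ps <- colSums(p_as)
  A <- vapply(0:3, amp, 0)
  EM <- base_meta + sum(ps * A) * Eg
  EM2 <- sum(ps * (base_meta^2 + 2 * base_meta * A * Eg + A^2 * Eg2))
  varM <- EM2 - EM^2
  r_theory <- cp$ptau_slope * sqrt(varM) /
    sqrt(cp$ptau_slope^2 * varM + cp$ptau_sd^2)
  expect_lt(abs(r_obs - r_theory), 0.1)
})

test_that("configured coupling signs are recovered across 500 subjects", {
  atl <- small_atlas()
  co <- simulate_cohort(atl, small_params(), n = 500, seed = 21)
  tru <- cohort_truth(co)
  cov <- cohort_covariates(co)
  ok <- !is.na(cov$ptau217)
  expect_gt(cor(cov$ptau217[ok], tru$meta_temp_tau[ok]), 0)
  drv_ids <- small_params()$mmse_driver
  drv <- rowMeans(tru[, paste0("tau_", drv_ids), drop = FALSE])
  expect_lt(cor(tru$mmse, drv), 0)
})

test_that("longitudinal cohorts share identity and accumulate by the slope", {
  atl <- small_atlas()
  # zero-slope case: identical regional truth across visits
  pp0 <- phantom_params(atl, longitudinal = list(n_visits = 3L,
                                                 visit_interval = 1,
                                                 slope_mean = 0,
                                                 slope_sd = 0))
  co0 <- simulate_cohort(atl, pp0, n = 4, seed = 5, longitudinal = TRUE)
  expect_length(co0$subjects, 12L)
  tr0 <- cohort_truth(co0)
  for (id in 1:4) {
    rows <- tr0[tr0$subject_id == id, ]
    expect_equal(rows$meta_temp_tau, rep(rows$meta_temp_tau[1], 3))
  }
  # mean within-subject OLS slope of the composite ~ slope * affected
  # meta-ROI voxel fraction (closed-form expectation of the construction)
  pp <- phantom_params(atl, longitudinal = list(n_visits = 3L,
                                                visit_interval = 1,
                                                slope_mean = 0.05,
                                                slope_sd = 0))
  co <- simulate_cohort(atl, pp, n = 200, seed = 6, longitudinal = TRUE)
  tr <- cohort_truth(co)
  slopes <- vapply(unique(tr$subject_id), function(id) {
    rows <- tr[tr$subject_id == id, ]
    stats::coef(stats::lm(meta_temp_tau ~ visit_time, rows))[2]
  }, 0)
  meta_ids <- atl$meta_temp_members
  w <- atl$roi_table$n_voxels[match(meta_ids, atl$roi_table$id)]
  frac <- vapply(unique(tr$subject_id), function(id) {
    stage <- tr$braak_group[tr$subject_id == id][1]
    onset <- pp$onset_group[as.character(meta_ids)]
    sum(w[onset <= stage]) / sum(w)
  }, 0)
  expect_lt(abs(mean(slopes) - 0.05 * mean(frac)), 0.01)
})

test_that("distinct subjects in a cohort get distinct randomness", {
  co <- small_cohort()
  taus <- vapply(co$subjects, function(s) mean(s$tau), 0)
  expect_gt(length(unique(taus)), 1)
  co2 <- simulate_cohort(small_atlas(),
                         phantom_params(small_atlas(),
                                        missingness_rates = c(none = 0)),
                         n = 8L, seed = 11L)
  expect_equal(co$subjects[[3]]$tau, co2$subjects[[3]]$tau)
})
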