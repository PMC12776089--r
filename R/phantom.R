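#' Parameters of the synthetic paired MRI/tau phantom cohort
#'
#' Defines the generative model the phantom cohorts follow.  A subject draws
#' a latent Braak group (0, I/II, III/IV, V/VI) from `stage_probs`, tilted
#' toward higher groups by APOE4 allele count; regional mean tau is
#' `baseline + severity * increment * (group - onset_group + 1)` for regions
#' whose Braak onset group has been reached, so tau accumulates monotonically
#' along the entorhinal-to-neocortex sequence.  The tau volume is the
#' regional mean field plus Gaussian voxel noise (floored at 0.05 SUVR); the
#' MRI is a smooth tissue template minus `atrophy_gain` times the local tau
#' excess, plus noise.  Plasma p-tau217 is linear in true meta-temporal tau;
#' MMSE declines linearly with association-cortex (onset stage >= 3) tau;
#' APOE shifts the stage distribution; covariates other than age/sex are
#' masked at the configured missingness rates.
#'
#' @param atlas a `coma_atlas`; per-ROI baselines/increments are derived from
#'   its ROI table (increments 0.35/0.30/0.22 SUVR per reached stage group
#'   for medial-temporal/temporal/other ROIs).
#' @param stage_probs probability vector over the four Braak groups
#'   (0, I/II, III/IV, V/VI); must sum to 1.
#' @param noise_sd tau voxel noise SD (SUVR).
#' @param severity_sd SD (log scale) of the subject-level lognormal severity
#'   factor multiplying the increments (mean 1); 0 disables heterogeneity.
#' @param atrophy_gain MRI intensity reduction per unit of local tau excess.
#' @param mri_noise_sd MRI voxel noise SD.
#' @param covariate_coupling list of coupling coefficients; see Details.
#' @param missingness_rates named per-covariate missing probabilities.
#' @param longitudinal list(n_visits, visit_interval, slope_mean, slope_sd):
#'   per-subject annual accumulation (SUVR/year) added to the mean tau of
#'   already-affected ROIs at each visit.
#' @return a `phantom_params` list.
#' @export
phantom_params <- function(atlas,
                           stage_probs = c(0.40, 0.25, 0.20, 0.15),
                           noise_sd = 0.08,
                           severity_sd = 0.25,
                           atrophy_gain = 0.3,
                           mri_noise_sd = 0.02,
                           covariate_coupling = list(),
                           missingness_rates = NULL,
                           longitudinal = list(n_visits = 1L,
                                               visit_interval = 1,
                                               slope_mean = 0.05,
                                               slope_sd = 0.02)) {
  stopifnot(inherits(atlas, "coma_atlas"))
  if (!all(atlas$roi_table$id == seq_len(nrow(atlas$roi_table)))) {
    stop("phantom simulation requires consecutive ROI ids 1..R")
  }
  if (length(stage_probs) != 4L || abs(sum(stage_probs) - 1) > 1e-8 ||
      any(stage_probs < 0)) {
    stop("stage_probs must be 4 non-negative probabilities summing to 1")
  }
  tab <- atlas$roi_table
  inc_by_lobe <- c(medial_temporal = 0.35, temporal = 0.30)
  increment <- ifelse(tab$lobe %in% names(inc_by_lobe),
                      inc_by_lobe[tab$lobe], 0.22)
  baseline <- 1.02 + 0.02 * ((tab$id - 1) %% 5)
  if (any(baseline <= 0) || any(increment < 0)) {
    stop("SUVR baselines must be > 0 and increments >= 0")
  }
  coupling <- utils::modifyList(list(
    apoe_stage_shift = 0.6,
    apoe_freq = c(0.60, 0.35, 0.05),
    ptau_intercept = -0.35, ptau_slope = 0.55, ptau_sd = 0.08,
    mmse_ceiling = 29.3, mmse_slope = 12, mmse_sd = 0.8,
    abeta_b0 = -1.2, abeta_b1 = 1.1
  ), covariate_coupling)
  if (is.null(missingness_rates)) {
    missingness_rates <- c(education = 0.03, marital_status = 0.05,
                           race = 0.05, height = 0.05, weight = 0.05,
                           systolic_bp = 0.08, diastolic_bp = 0.08,
                           pulse = 0.08, respiratory_rate = 0.08,
                           temperature = 0.08, apoe4_count = 0.10,
                           ptau217 = 0.25, nfl = 0.25, gfap = 0.25,
                           abeta40 = 0.25, abeta42 = 0.25)
  }
  if (any(missingness_rates < 0 | missingness_rates > 1)) {
    stop("missingness rates must lie in [0, 1]")
  }
  structure(list(
    n_rois = nrow(tab),
    grid = atlas$grid,
    stage_probs = stage_probs,
    tau_baseline = stats::setNames(baseline, tab$id),
    tau_increment = stats::setNames(increment, tab$id),
    onset_group = stats::setNames(ceiling(tab$braak_onset_stage / 2), tab$id),
    # association-cortex ROIs driving cognition; for very small atlases
    # without stage >= 3 regions, fall back to the latest-onset ROIs present
    mmse_driver = if (any(tab$braak_onset_stage >= 3L)) {
      tab$id[tab$braak_onset_stage >= 3L]
    } else {
      tab$id[tab$braak_onset_stage == max(tab$braak_onset_stage)]
    },
    noise_sd = noise_sd,
    severity_sd = severity_sd,
    atrophy_gain = atrophy_gain,
    mri_noise_sd = mri_noise_sd,
    covariate_coupling = coupling,
    missingness_rates = missingness_rates,
    longitudinal = longitudinal
  ), class = "phantom_params")
}

# smooth MRI tissue template on the atlas grid: bright centre, darker rim,
# near-zero background
mri_template <- function(atlas) {
  grid <- atlas$grid
  coords <- voxel_coords(grid)
  ctr <- (grid + 1) / 2
  semi <- 0.45 * grid
  rho <- sqrt(rowSums(sweep(sweep(coords, 2, ctr), 2, semi, "/")^2))
  tmpl <- ifelse(rho <= 1, 0.6 + 0.4 * cos(pmin(rho, 1) * pi / 2), 0.02)
  array(tmpl, dim = grid)
}

# latent regional mean tau for one subject
subject_roi_means <- function(params, stage, severity) {
  reached <- pmax(0L, stage - params$onset_group + 1L)
  params$tau_baseline + severity * params$tau_increment * reached
}

#' Simulate one phantom subject
#'
#' Draws a latent Braak group, regional mean tau, paired tau/MRI volumes,
#' and a covariate record under the generative model of [phantom_params()].
#' Deterministic for a fixed (atlas, params, seed).
#'
#' @param atlas a `coma_atlas`.
#' @param params a `phantom_params` built from the same atlas.
#' @param seed integer seed.
#' @param subject_id identifier stored with the subject.
#' @return a `coma_subject`: list(mri, tau, covariates, truth, subject_id,
#'   visit, visit_time).  `truth` holds the latent Braak group (0-3), the
#'   noise-free per-ROI mean tau, the meta-temporal composite, diagnosis
#'   (CN/MCI/Dem from noise-free MMSE at thresholds 27/24), amyloid status,
#'   observed and noise-free MMSE.
#' @export
simulate_subject <- function(atlas, params, seed, subject_id = 1L) {
  check_params_atlas(atlas, params)
  with_seed(seed, {
    draw <- draw_latents(params)
    out <- render_visit(atlas, params, draw, visit = 1L, visit_time = 0)
  })
  out$subject_id <- subject_id
  out
}

check_params_atlas <- function(atlas, params) {
  stopifnot(inherits(atlas, "coma_atlas"), inherits(params, "phantom_params"))
  if (params$n_rois != nrow(atlas$roi_table) ||
      !all(params$grid == atlas$grid)) {
    stop("params were built for a different atlas")
  }
}

# latent state + covariates (shared across visits of one subject)
draw_latents <- function(params) {
  cp <- params$covariate_coupling
  apoe <- sample(0:2, 1L, prob = cp$apoe_freq)
  s <- 0:3
  tilt <- params$stage_probs * exp(cp$apoe_stage_shift * apoe * s)
  stage <- sample(s, 1L, prob = tilt / sum(tilt))
  severity <- if (params$severity_sd > 0) {
    stats::rlnorm(1L, meanlog = -params$severity_sd^2 / 2,
                  sdlog = params$severity_sd)
  } else 1
  slope <- stats::rnorm(1L, params$longitudinal$slope_mean,
                        params$longitudinal$slope_sd)
  abeta <- stats::rbinom(1L, 1L, stats::plogis(cp$abeta_b0 + cp$abeta_b1 * stage))
  base_cov <- list(
    age = round(min(95, max(55, stats::rnorm(1L, 73, 7))), 1),
    sex = sample(0:1, 1L),
    education = round(min(22, max(8, stats::rnorm(1L, 16.4, 2.6)))),
    marital_status = sample(1:4, 1L, prob = c(0.6, 0.2, 0.15, 0.05)),
    race = sample(1:5, 1L, prob = c(0.7, 0.12, 0.08, 0.06, 0.04)),
    height = round(stats::rnorm(1L, 168, 10), 1),
    weight = round(stats::rnorm(1L, 75, 14), 1),
    systolic_bp = round(stats::rnorm(1L, 131, 16)),
    diastolic_bp = round(stats::rnorm(1L, 74, 10)),
    pulse = round(stats::rnorm(1L, 68, 10)),
    respiratory_rate = round(stats::rnorm(1L, 16, 2)),
    temperature = round(stats::rnorm(1L, 36.7, 0.3), 1),
    apoe4_count = apoe,
    nfl = round(20 + 6 * stage + stats::rnorm(1L, 0, 5), 2),
    gfap = round(180 + 40 * abeta + 15 * stage + stats::rnorm(1L, 0, 30), 1),
    abeta40 = round(stats::rnorm(1L, 230, 30), 1),
    abeta42 = round(40 - 8 * abeta + stats::rnorm(1L, 0, 4), 1)
  )
  list(stage = stage, severity = severity, slope = slope, abeta = abeta,
       base_cov = base_cov)
}

# realize volumes, covariates and truth at one visit (RNG already seeded)
render_visit <- function(atlas, params, draw, visit, visit_time) {
  cp <- params$covariate_coupling
  means <- subject_roi_means(params, draw$stage, draw$severity)
  affected <- (draw$stage - params$onset_group + 1L) > 0L
  means <- means + draw$slope * visit_time * affected

  lab <- as.vector(atlas$label_volume)
  field <- numeric(length(lab))
  field[lab > 0L] <- means[lab[lab > 0L]]
  field[lab == 0L] <- 0.25
  tau <- field + stats::rnorm(length(field), 0, params$noise_sd)
  tau <- pmax(tau, 0.05)
  dim(tau) <- atlas$grid

  tmpl <- as.vector(mri_template(atlas))
  excess <- numeric(length(lab))
  excess[lab > 0L] <- (field - rep(0, length(field)))[lab > 0L] -
    params$tau_baseline[lab[lab > 0L]]
  mri <- tmpl - params$atrophy_gain * excess +
    stats::rnorm(length(tmpl), 0, params$mri_noise_sd)
  mri <- pmax(mri, 0)
  dim(mri) <- atlas$grid

  meta <- meta_temp_tau(stats::setNames(means, atlas$roi_table$id), atlas)
  ptau <- cp$ptau_intercept + cp$ptau_slope * meta +
    stats::rnorm(1L, 0, cp$ptau_sd)
  driver <- mean(means[as.character(params$mmse_driver)])
  driver0 <- mean(params$tau_baseline[as.character(params$mmse_driver)])
  mmse_true <- min(30, max(0, cp$mmse_ceiling - cp$mmse_slope *
                             (driver - driver0)))
  mmse_obs <- min(30, max(0, mmse_true + stats::rnorm(1L, 0, cp$mmse_sd)))
  diagnosis <- if (mmse_true >= 27) "CN" else if (mmse_true >= 24) "MCI"
  else "Dem"

  cov <- draw$base_cov
  cov$ptau217 <- round(ptau, 4)
  cov <- as.data.frame(cov)
  for (nm in names(params$missingness_rates)) {
    if (nm %in% names(cov) &&
        stats::runif(1L) < params$missingness_rates[[nm]]) {
      cov[[nm]] <- NA
    }
  }

  structure(list(
    mri = mri, tau = tau, covariates = cov,
    truth = list(braak_group = draw$stage,
                 roi_mean_tau = stats::setNames(means, atlas$roi_table$id),
                 meta_temp_tau = meta,
                 diagnosis = diagnosis,
                 abeta_status = draw$abeta,
                 mmse = mmse_obs,
                 mmse_noisefree = mmse_true,
                 visit_time = visit_time),
    subject_id = NA_integer_, visit = visit, visit_time = visit_time
  ), class = "coma_subject")
}

#' Simulate a phantom cohort
#'
#' Independent subjects, each a pure function of the cohort seed; with
#' `longitudinal = TRUE` each subject contributes
#' `params$longitudinal$n_visits` visits sharing the same latent identity,
#' with regional mean tau of already-affected ROIs incremented by the
#' subject's annual slope times visit time.
#'
#' @inheritParams simulate_subject
#' @param n number of subjects (>= 1).
#' @param longitudinal logical; simulate repeated visits.
#' @return a `coma_cohort`: list with `subjects` (flat list of
#'   `coma_subject`, one per subject-visit), `n_subjects`, `atlas_grid`.
#' @export
simulate_cohort <- function(atlas, params, n, seed, longitudinal = FALSE) {
  check_params_atlas(atlas, params)
  stopifnot(n >= 1L)
  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  n_visits <- if (longitudinal) params$longitudinal$n_visits else 1L
  dt <- if (longitudinal) params$longitudinal$visit_interval else 0
  subjects <- vector("list", n * n_visits)
  k <- 0L
  for (i in seq_len(n)) {
    with_seed(sub_seeds[i], {
      draw <- draw_latents(params)
      for (v in seq_len(n_visits)) {
        k <- k + 1L
        s <- render_visit(atlas, params, draw, visit = v,
                          visit_time = (v - 1L) * dt)
        s$subject_id <- i
        subjects[[k]] <- s
      }
    })
  }
  structure(list(subjects = subjects, n_subjects = n,
                 atlas_grid = atlas$grid, longitudinal = longitudinal),
            class = "coma_cohort")
}

#' @export
print.coma_cohort <- function(x, ...) {
  cat("Phantom cohort: ", x$n_subjects, " subjects, ",
      length(x$subjects), " observations (grid ",
      paste(x$atlas_grid, collapse = " x "), ")\n", sep = "")
  dg <- table(vapply(x$subjects, function(s) s$truth$diagnosis, ""))
  cat("  diagnoses: ", paste(names(dg), dg, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Extract the covariate table of a cohort
#'
#' One row per subject-visit, with subject_id/visit/visit_time key columns;
#' missing covariates are NA.
#' @param cohort a `coma_cohort`.
#' @return data.frame.
#' @export
cohort_covariates <- function(cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    cbind(data.frame(subject_id = s$subject_id, visit = s$visit,
                     visit_time = s$visit_time), s$covariates)
  })
  do.call(rbind, rows)
}

#' Extract the latent truth table of a cohort
#'
#' One row per subject-visit with Braak group, diagnosis, amyloid status,
#' MMSE, the meta-temporal composite, and the per-ROI noise-free mean tau in
#' columns `tau_<roi id>`.
#' @param cohort a `coma_cohort`.
#' @return data.frame.
#' @export
cohort_truth <- function(cohort) {
  rows <- lapply(cohort$subjects, function(s) {
    tr <- s$truth
    taus <- as.data.frame(as.list(tr$roi_mean_tau))
    names(taus) <- paste0("tau_", names(tr$roi_mean_tau))
    cbind(data.frame(subject_id = s$subject_id, visit = s$visit,
                     visit_time = s$visit_time,
                     braak_group = tr$braak_group,
                     diagnosis = tr$diagnosis,
                     abeta_status = tr$abeta_status,
                     mmse = tr$mmse, mmse_noisefree = tr$mmse_noisefree,
                     meta_temp_tau = tr$meta_temp_tau), taus)
  })
  do.call(rbind, rows)
}

#' Write a phantom cohort to disk
#'
#' Per-visit NIfTI pairs (`sub<id>_v<visit>_mri.nii.gz`, `..._tau.nii.gz`)
#' plus a covariates CSV and a truth CSV keyed by subject id and visit.
#' @param cohort a `coma_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$subjects) {
    stem <- file.path(dir, sprintf("sub%03d_v%02d", s$subject_id, s$visit))
    write_volume(s$mri, paste0(stem, "_mri.nii.gz"))
    write_volume(s$tau, paste0(stem, "_tau.nii.gz"))
  }
  utils::write.csv(cohort_covariates(cohort),
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  utils::write.csv(cohort_truth(cohort),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a phantom cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param atlas the `coma_atlas` the cohort was simulated on.
#' @return a `coma_cohort`.
#' @export
read_cohort <- function(dir, atlas) {
  cov <- read_covariates(file.path(dir, "covariates.csv"),
                         required = ID_COLS)
  tru <- read_covariates(file.path(dir, "truth.csv"), required = ID_COLS)
  tau_cols <- grep("^tau_", names(tru), value = TRUE)
  subjects <- lapply(seq_len(nrow(cov)), function(i) {
    stem <- file.path(dir, sprintf("sub%03d_v%02d", cov$subject_id[i],
                                   cov$visit[i]))
    means <- as.numeric(tru[i, tau_cols])
    names(means) <- sub("^tau_", "", tau_cols)
    structure(list(
      mri = read_volume(paste0(stem, "_mri.nii.gz"))$data,
      tau = read_volume(paste0(stem, "_tau.nii.gz"))$data,
      covariates = cov[i, setdiff(names(cov), ID_COLS), drop = FALSE],
      truth = list(braak_group = tru$braak_group[i],
                   roi_mean_tau = means,
                   meta_temp_tau = tru$meta_temp_tau[i],
                   diagnosis = tru$diagnosis[i],
                   abeta_status = tru$abeta_status[i],
                   mmse = tru$mmse[i],
                   mmse_noisefree = tru$mmse_noisefree[i],
                   visit_time = tru$visit_time[i]),
      subject_id = cov$subject_id[i], visit = cov$visit[i],
      visit_time = cov$visit_time[i]), class = "coma_subject")
  })
  structure(list(subjects = subjects,
                 n_subjects = length(unique(cov$subject_id)),
                 atlas_grid = atlas$grid,
                 longitudinal = any(cov$visit > 1L)),
            class = "coma_cohort")
}
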