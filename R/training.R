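#' Per-ROI loss weights
#'
#' ROI-weighted MSE weights: background voxels always weigh 1; ROI voxels
#' weigh `w_r`.  By default the meta-temporal ROIs weigh 2 and all others 1,
#' emphasizing the composite most downstream analyses use; any positive
#' weights may be supplied.
#'
#' @param atlas a `coma_atlas`.
#' @param values optional named numeric vector (names = ROI ids) of
#'   weights; unnamed scalar recycles over all ROIs.
#' @param meta_weight default weight of meta-temporal ROIs.
#' @return a `roi_weights` object (named per-ROI weights).
#' @export
roi_weights <- function(atlas, values = NULL, meta_weight = 2) {
  ids <- atlas$roi_table$id
  w <- stats::setNames(rep(1, length(ids)), ids)
  w[as.character(atlas$meta_temp_members)] <- meta_weight
  if (!is.null(values)) {
    if (is.null(names(values))) {
      w[] <- values
    } else {
      w[names(values)] <- values
    }
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("ROI weights must be finite and > 0")
  }
  structure(w, class = "roi_weights")
}

# per-voxel weight vector on the atlas grid (background = 1)
voxel_weights <- function(atlas, weights) {
  lab <- as.vector(atlas$label_volume)
  w <- rep(1, length(lab))
  inside <- lab > 0L
  w[inside] <- unclass(weights)[lab[inside]]
  w
}

#' ROI-weighted mean squared error
#'
#' The generator training loss: the voxel-mean of
#' `w(v) * (truth_v - pred_v)^2`, where `w(v)` is the ROI weight of the
#' voxel's region and 1 on background.  Zero iff the volumes agree
#' everywhere.
#'
#' @param pred,truth 3D arrays on the atlas grid (or lists of them, in
#'   which case the batch mean is returned).
#' @param atlas a `coma_atlas`.
#' @param weights a [roi_weights()] object (default: all meta-temporal
#'   ROIs at weight 2).
#' @return scalar loss.
#' @export
roi_weighted_mse <- function(pred, truth, atlas, weights = roi_weights(atlas)) {
  if (!inherits(weights, "roi_weights")) weights <- roi_weights(atlas, weights)
  w <- voxel_weights(atlas, weights)
  one <- function(p, t) {
    if (!all(dim(p) == atlas$grid) || !all(dim(t) == atlas$grid)) {
      stop("volumes must be on the atlas grid")
    }
    mean(w * (as.vector(t) - as.vector(p))^2)
  }
  if (is.list(pred)) {
    mean(mapply(one, pred, truth))
  } else {
    one(pred, truth)
  }
}

#' Balanced five-fold assignment
#'
#' Stratified partition of subjects into `k` folds balanced for amyloid
#' status and meta-temporal tau burden: within each (status x MetaTempTau
#' quantile bin) stratum, subjects are ordered by tau burden and dealt into
#' folds in randomized blocks, so per-stratum fold counts differ by at most
#' one and fold means of the tau burden stay close to the cohort mean.
#'
#' @param subjects data.frame with columns `subject_id`, `meta_temp_tau`,
#'   `abeta_status` (one row per subject; longitudinal visits share the
#'   subject's fold).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @param n_bins MetaTempTau quantile bins per status stratum.
#' @return a `fold_assignment`: data.frame (subject_id, fold) plus a
#'   per-fold summary attribute.
#' @export
make_folds <- function(subjects, k = 5L, seed = 1L, n_bins = 3L) {
  stopifnot(all(c("subject_id", "meta_temp_tau", "abeta_status") %in%
                  names(subjects)))
  subjects <- subjects[!duplicated(subjects$subject_id), ]
  n <- nrow(subjects)
  if (k > n) stop("k = ", k, " folds but only ", n, " subjects")
  fold <- integer(n)
  with_seed(seed, {
    for (ab in unique(subjects$abeta_status)) {
      rows <- which(subjects$abeta_status == ab)
      m <- subjects$meta_temp_tau[rows]
      nb <- max(1L, min(n_bins, length(rows) %/% k))
      if (nb > 1L) {
        qs <- stats::quantile(m, probs = seq_len(nb - 1L) / nb, type = 7)
        bin <- findInterval(m, qs) + 1L
      } else {
        bin <- rep(1L, length(rows))
      }
      for (b in unique(bin)) {
        rws <- rows[bin == b][order(m[bin == b])]
        nf <- length(rws)
        f <- integer(nf)
        for (blk in seq_len(ceiling(nf / k))) {
          lo <- (blk - 1L) * k + 1L
          hi <- min(blk * k, nf)
          f[lo:hi] <- sample(k)[seq_len(hi - lo + 1L)]
        }
        fold[rws] <- f
      }
    }
  })
  out <- data.frame(subject_id = subjects$subject_id, fold = fold)
  summ <- do.call(rbind, lapply(seq_len(k), function(fd) {
    sel <- fold == fd
    data.frame(fold = fd, n = sum(sel),
               mean_meta_temp_tau = mean(subjects$meta_temp_tau[sel]),
               abeta_pos_frac = mean(subjects$abeta_status[sel]))
  }))
  structure(out, class = c("fold_assignment", "data.frame"),
            summary = summ, k = k)
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("Balanced fold assignment (k = ", attr(x, "k"), ", n = ", nrow(x),
      " subjects)\n", sep = "")
  print(attr(x, "summary"), row.names = FALSE)
  invisible(x)
}

#' Training configuration
#'
#' AdamW optimization of the ROI-weighted MSE with a reduce-on-plateau
#' learning-rate schedule and early stopping on a held-out validation
#' subset of the training split.
#'
#' @param learning_rate initial AdamW learning rate.
#' @param weight_decay decoupled weight decay.
#' @param batch_size subjects per gradient step.
#' @param max_epochs upper bound on epochs.
#' @param sched_factor,sched_patience reduce-on-plateau multiplier and
#'   patience (epochs without validation improvement).
#' @param early_stop_patience consecutive epochs without validation
#'   improvement before stopping.
#' @param val_fraction fraction of training subjects held out for
#'   validation (when no explicit validation set is given).
#' @param improve_tol relative improvement below which an epoch does not
#'   count as better.
#' @param seed seed for shuffling and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.001,
                         batch_size = 2L, max_epochs = 30L,
                         sched_factor = 0.5, sched_patience = 2L,
                         early_stop_patience = 5L, val_fraction = 0.1,
                         improve_tol = 1e-4, seed = 1L) {
  stopifnot(batch_size >= 1L, early_stop_patience >= 1L, sched_patience >= 1L)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 sched_factor = sched_factor,
                 sched_patience = as.integer(sched_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, improve_tol = improve_tol,
                 seed = as.integer(seed)),
            class = "train_config")
}

# assemble per-entry network inputs once (preprocessed MRI, conditioning,
# prompt tensors, truth volume, weight vector)
prepare_samples <- function(net, cohort, estimates, atlas, rows) {
  lapply(rows, function(i) {
    s <- cohort$subjects[[i]]
    list(mri = preprocess_mri(s$mri, net$config$grid),
         cond = conditioning_vector(net, s$covariates, estimates, row = i),
         regional = build_regional_tensors(estimates, atlas, row = i),
         truth = as.vector(s$tau),
         id = s$subject_id)
  })
}

# mean ROI-weighted MSE of the network over prepared samples (eval mode)
eval_loss <- function(net, samples, wvox) {
  mean(vapply(samples, function(sm) {
    out <- coma_synthesize_one(net, sm$mri, sm$cond, sm$regional)
    mean(wvox * (sm$truth - as.vector(out))^2)
  }, 0))
}

#' Train the synthesis network
#'
#' AdamW minimization of the ROI-weighted MSE.  The validation subset is
#' carved from the training subjects (stratified sampling by subject);
#' the learning rate halves after `sched_patience` epochs without
#' validation improvement and training stops after `early_stop_patience`
#' such epochs, restoring the best-validation parameters.
#'
#' @param model a `coma_unet` (modified in place and returned).
#' @param cohort a `coma_cohort`.
#' @param estimates `coma_aux_estimates` aligned with the cohort entries
#'   (fitted on the training subjects only).
#' @param atlas a `coma_atlas`.
#' @param config a [train_config()].
#' @param weights a [roi_weights()] (default meta-temporal emphasis).
#' @param train_rows,val_rows cohort entry indices; by default all entries
#'   are used and `val_fraction` subjects are held out for validation.
#' @return the trained model, with `$history` (epoch, train_loss,
#'   val_loss, lr) and `$best_val_loss`.
#' @export
coma_train <- function(model, cohort, estimates, atlas,
                       config = train_config(), weights = roi_weights(atlas),
                       train_rows = NULL, val_rows = NULL) {
  stopifnot(inherits(model, "coma_unet"), inherits(cohort, "coma_cohort"))
  all_rows <- seq_along(cohort$subjects)
  if (is.null(train_rows)) train_rows <- all_rows
  if (is.null(val_rows)) {
    ids <- vapply(cohort$subjects[train_rows], function(s) s$subject_id, 1L)
    uid <- unique(ids)
    n_val <- max(1L, round(config$val_fraction * length(uid)))
    val_ids <- with_seed(config$seed + 1L, sample(uid, n_val))
    val_rows <- train_rows[ids %in% val_ids]
    train_rows <- setdiff(train_rows, val_rows)
  }
  if (!length(val_rows)) stop("validation subset is empty")
  if (length(intersect(train_rows, val_rows))) {
    stop("training and validation subsets overlap")
  }
  if (is.null(model$cond_stats)) {
    cov_tab <- cohort_covariates(cohort)[train_rows, , drop = FALSE]
    set_cond_stats(model, cov_tab, subset_estimates(estimates, train_rows))
  }
  train_samples <- prepare_samples(model, cohort, estimates, atlas,
                                   train_rows)
  val_samples <- prepare_samples(model, cohort, estimates, atlas, val_rows)
  wvox <- voxel_weights(atlas, weights)

  opt <- adamw_state(model$params)
  lr <- config$learning_rate
  best <- Inf; best_params <- model$params; bad_epochs <- 0L; sched_bad <- 0L
  history <- NULL
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      model$training <- TRUE
      ord <- sample(length(train_samples))
      ep_loss <- 0; nb <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        batch <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        acc <- NULL; bl <- 0
        for (i in batch) {
          sm <- train_samples[[i]]
          fw <- coma_forward(model, sm$mri, sm$cond, sm$regional)
          d <- ad_sub(fw$pred, matrix(sm$truth, ncol = 1L))
          loss <- ad_mean(ad_mul(ad_mul(d, d), matrix(wvox, ncol = 1L)))
          ad_backward(fw$tape, loss)
          g <- collect_grads(fw$tape)
          bl <- bl + loss$value
          acc <- if (is.null(acc)) g else accumulate_grads(acc, g)
        }
        nbatch <- length(batch)
        acc <- lapply(acc, function(x) x / nbatch)
        adamw_step(model, opt, acc, lr, config$weight_decay)
        ep_loss <- ep_loss + bl / nbatch; nb <- nb + 1L
      }
      model$training <- FALSE
      vl <- eval_loss(model, val_samples, wvox)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                  val_loss = vl, lr = lr))
      if (vl < best * (1 - config$improve_tol)) {
        best <- vl; best_params <- model$params
        bad_epochs <- 0L; sched_bad <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L; sched_bad <- sched_bad + 1L
        if (sched_bad >= config$sched_patience) {
          lr <- lr * config$sched_factor; sched_bad <- 0L
        }
        if (bad_epochs >= config$early_stop_patience) break
      }
    }
  })
  model$params <- best_params
  model$history <- history
  model$best_val_loss <- best
  invisible(model)
}

subset_estimates <- function(est, rows) {
  structure(list(tau_hat = est$tau_hat[rows, , drop = FALSE],
                 sigma_hat = est$sigma_hat[rows, , drop = FALSE],
                 meta_temp_hat = est$meta_temp_hat[rows],
                 abeta_prob = est$abeta_prob[rows],
                 abeta_status = est$abeta_status[rows],
                 mmse_hat = est$mmse_hat[rows]),
            class = "coma_aux_estimates")
}

adamw_state <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

adamw_step <- function(model, st, grads, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  b1t <- 1 - beta1^st$t; b2t <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    mhat <- st$m[[nm]] / b1t
    vhat <- st$v[[nm]] / b2t
    p <- model$params[[nm]]
    model$params[[nm]] <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
  }
  invisible(NULL)
}

accumulate_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

#' Cross-validated synthesis and evaluation
#'
#' For each fold: the auxiliary models and the network are fitted on the
#' other folds only (the auxiliary bundle carries an out-of-sample guard),
#' synthetic volumes are generated for the held-out subjects, and fidelity
#' metrics are computed per fold.  A leakage guard fails if any held-out
#' subject id appears in a training split.
#'
#' @param cohort a `coma_cohort`.
#' @param atlas a `coma_atlas`.
#' @param folds a [make_folds()] assignment.
#' @param model_args list of arguments to [coma_unet()] (grid is taken
#'   from the atlas).
#' @param config a [train_config()].
#' @param weights a [roi_weights()].
#' @param aux_nrounds boosting rounds for the auxiliary models.
#' @param aux_min_rows minimum training rows for the auxiliary models.
#' @return a `coma_cv` list: `pred` (out-of-fold synthetic volumes, in
#'   cohort order), `estimates` (out-of-fold auxiliary estimates),
#'   `fold_metrics` (per-fold fidelity data.frame), `folds`.
#' @export
cross_validate <- function(cohort, atlas, folds, model_args = list(),
                           config = train_config(),
                           weights = roi_weights(atlas),
                           aux_nrounds = 100L, aux_min_rows = 20L) {
  subs <- cohort$subjects
  ids <- vapply(subs, function(s) s$subject_id, 1L)
  dup <- unique(folds$subject_id[duplicated(folds$subject_id)])
  for (d in dup) {
    if (length(unique(folds$fold[folds$subject_id == d])) > 1L) {
      stop("leakage guard: subject ", d, " assigned to multiple folds")
    }
  }
  fold_of <- folds$fold[match(ids, folds$subject_id)]
  if (anyNA(fold_of)) stop("fold assignment does not cover the cohort")
  k <- attr(folds, "k")
  pred <- vector("list", length(subs))
  oof <- data.frame(row = seq_along(subs), fold = fold_of,
                    meta_temp_hat = NA_real_, abeta_prob = NA_real_,
                    abeta_status = NA_integer_, mmse_hat = NA_real_)
  fold_metrics <- NULL
  cov_all <- cohort_covariates(cohort)
  for (fd in seq_len(k)) {
    test_rows <- which(fold_of == fd)
    train_rows <- which(fold_of != fd)
    if (length(intersect(ids[test_rows], ids[train_rows]))) {
      stop("leakage guard: held-out subject present in the training split")
    }
    aux <- fit_cohort_auxiliary(cohort, atlas, rows = train_rows,
                                cv_guard = TRUE, nrounds = aux_nrounds,
                                min_rows = aux_min_rows)
    est_all <- predict_auxiliary(aux, strip_ids(cov_all))
    # out-of-sample guard: trips if any held-out id was used in fitting
    predict_auxiliary(aux, strip_ids(cov_all[test_rows, , drop = FALSE]),
                      subject_ids = ids[test_rows])
    net <- do.call(coma_unet, c(list(grid = atlas$grid,
                                     seed = config$seed + fd), model_args))
    coma_train(net, cohort, est_all, atlas, config = config,
               weights = weights, train_rows = train_rows)
    vols <- predict(net, cohort, est_all, atlas, rows = test_rows)
    for (j in seq_along(test_rows)) pred[[test_rows[j]]] <- vols[[j]]
    oof$meta_temp_hat[test_rows] <- est_all$meta_temp_hat[test_rows]
    oof$abeta_prob[test_rows] <- est_all$abeta_prob[test_rows]
    oof$abeta_status[test_rows] <- est_all$abeta_status[test_rows]
    oof$mmse_hat[test_rows] <- est_all$mmse_hat[test_rows]
    truth_vols <- lapply(subs[test_rows], function(s) s$tau)
    fr <- fidelity_report(vols, truth_vols, atlas)
    fold_metrics <- rbind(fold_metrics,
                          data.frame(fold = fd, n = length(test_rows),
                                     corr_avg = fr$corr_avg, mape = fr$mape,
                                     mae = fr$mae, ssim = fr$ssim))
  }
  structure(list(pred = pred, estimates = oof, fold_metrics = fold_metrics,
                 folds = folds),
            class = "coma_cv")
}

#' Fit the auxiliary bundle from a cohort's observed tau volumes
#'
#' Convenience wrapper: extracts per-ROI SUVR and the meta-temporal
#' composite from the actual tau volumes of the selected cohort entries and
#' fits the full stage-1 bundle ([fit_auxiliary()]) on them.
#'
#' @param cohort a `coma_cohort`.
#' @param atlas a `coma_atlas`.
#' @param rows cohort entry indices to train on (default all).
#' @param cv_guard enable the out-of-sample prediction guard.
#' @param nrounds boosting rounds.
#' @param meta_mode how MetaTempTau is predicted (see [fit_auxiliary()]).
#' @param min_rows minimum training rows for the boosted models.
#' @return a `coma_aux` bundle.
#' @export
fit_cohort_auxiliary <- function(cohort, atlas, rows = NULL,
                                 cv_guard = FALSE, nrounds = 100L,
                                 meta_mode = "direct", min_rows = 20L) {
  if (is.null(rows)) rows <- seq_along(cohort$subjects)
  subs <- cohort$subjects[rows]
  suvr <- t(vapply(subs, function(s) regional_suvr(s$tau, atlas),
                   numeric(nrow(atlas$roi_table))))
  targets <- as.data.frame(suvr)
  names(targets) <- paste0("tau_", atlas$roi_table$id)
  targets$meta_temp_tau <- vapply(subs, function(s)
    meta_temp_tau(regional_suvr(s$tau, atlas), atlas), 0)
  cov_tab <- cohort_covariates(cohort)[rows, , drop = FALSE]
  fit_auxiliary(strip_ids(cov_tab), targets,
                abeta_labels = vapply(subs, function(s) s$truth$abeta_status, 0L),
                mmse = vapply(subs, function(s) s$truth$mmse, 0),
                atlas = atlas,
                subject_ids = vapply(subs, function(s) s$subject_id, 1L),
                meta_mode = meta_mode, cv_guard = cv_guard,
                nrounds = nrounds, min_rows = min_rows)
}

strip_ids <- function(tab) tab[, setdiff(names(tab), ID_COLS), drop = FALSE]
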