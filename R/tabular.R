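# Stage-1 auxiliary models: KNN imputation, gradient-boosted regional tau
# regression with a Gaussian (mean, log-SD) head, amyloid-status
# classification, and KNN MMSE prediction.  These produce the conditioning
# inputs consumed by the synthesis network.

ID_COLS <- c("subject_id", "visit", "visit_time")

# neighbourhood size rule shared by imputation and the MMSE regressor:
# k = round(sqrt(number of features)), at least 1
knn_k <- function(p) max(1L, as.integer(round(sqrt(p))))

# numeric feature matrix: one-hot encodes factor/character columns,
# passes numeric columns through; NA preserved
feature_matrix <- function(table, feature_cols = NULL) {
  if (is.null(feature_cols)) feature_cols <- setdiff(names(table), ID_COLS)
  cols <- list()
  for (nm in feature_cols) {
    v <- table[[nm]]
    if (is.null(v)) stop("feature table is missing column: ", nm)
    if (is.numeric(v) || is.logical(v)) {
      cols[[nm]] <- as.numeric(v)
    } else {
      v <- as.factor(v)
      for (lv in levels(v)) {
        cols[[paste0(nm, ".", lv)]] <- as.numeric(v == lv)
      }
    }
  }
  do.call(cbind, cols)
}

# pairwise distances under arbitrary missingness: root mean squared
# difference over mutually observed standardized columns; Inf when two rows
# share no observed column
masked_dist <- function(Z) {
  M <- (!is.na(Z)) * 1
  Z0 <- Z; Z0[is.na(Z0)] <- 0
  A <- Z0^2
  shared <- M %*% t(M)
  S <- A %*% t(M) + M %*% t(A) - 2 * Z0 %*% t(Z0)
  D <- sqrt(pmax(S, 0) / pmax(shared, 1))
  D[shared == 0] <- Inf
  D
}

#' K-nearest-neighbour imputation of a covariate table
#'
#' Missing entries are replaced by the unweighted mean of the k nearest
#' rows (Euclidean distance on mutually observed, z-scored columns), with
#' `k = round(sqrt(p))` for p feature columns.  Observed entries are
#' unchanged; a table without missing values is returned as-is.
#'
#' @param table data.frame; columns `subject_id`, `visit`, `visit_time` are
#'   treated as identifiers and ignored.
#' @param k neighbourhood size; default `round(sqrt(p))`.
#' @return the table with missing feature entries filled in.
#' @export
knn_impute <- function(table, k = NULL) {
  feature_cols <- setdiff(names(table), ID_COLS)
  all_missing <- feature_cols[vapply(feature_cols,
                                     function(nm) all(is.na(table[[nm]])),
                                     TRUE)]
  if (length(all_missing)) {
    stop("column(s) missing in every row: ",
         paste(all_missing, collapse = ", "))
  }
  X <- feature_matrix(table, feature_cols)
  if (!anyNA(X)) return(table)
  if (is.null(k)) k <- knn_k(ncol(X))
  mu <- colMeans(X, na.rm = TRUE)
  sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
  sdv[is.na(sdv) | sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  D <- masked_dist(Z)
  diag(D) <- Inf
  out <- table
  for (nm in feature_cols) {
    v <- table[[nm]]
    miss <- which(is.na(v))
    if (!length(miss) || !is.numeric(v)) next
    donors_all <- which(!is.na(v))
    for (i in miss) {
      d <- D[i, donors_all]
      ord <- donors_all[order(d)]
      ord <- ord[is.finite(D[i, ord])]
      use <- ord[seq_len(min(k, length(ord)))]
      if (!length(use)) next
      out[[nm]][i] <- mean(v[use])
    }
  }
  out
}

# standardized design matrix + schema for the boosted/KNN models
build_design <- function(table, schema = NULL) {
  if (is.null(schema)) {
    X <- feature_matrix(table)
    mu <- colMeans(X, na.rm = TRUE)
    sdv <- apply(X, 2, stats::sd, na.rm = TRUE)
    sdv[is.na(sdv) | sdv == 0] <- 1
    schema <- list(cols = colnames(X), center = mu, scale = sdv,
                   raw_cols = setdiff(names(table), ID_COLS))
  } else {
    miss <- setdiff(schema$raw_cols, names(table))
    if (length(miss)) {
      stop("feature table does not match the fitted schema; missing: ",
           paste(miss, collapse = ", "))
    }
    X <- feature_matrix(table, schema$raw_cols)
    bad <- setdiff(schema$cols, colnames(X))
    if (length(bad)) {
      add <- matrix(0, nrow(X), length(bad), dimnames = list(NULL, bad))
      X <- cbind(X, add)
    }
    X <- X[, schema$cols, drop = FALSE]
  }
  Z <- sweep(sweep(X, 2, schema$center), 2, schema$scale, "/")
  list(Z = Z, schema = schema)
}

xgb_params_mean <- function() {
  # no row subsampling and a fixed seed: fits are pure functions of the data
  list(objective = "reg:squarederror", max_depth = 3, eta = 0.1,
       subsample = 1, seed = 0, nthread = 1)
}

# Gaussian negative log-likelihood objective in s = log(sigma), residuals r
# fixed from the mean model: NLL = s + r^2 exp(-2s) / 2
gauss_sd_objective <- function(r) {
  force(r)
  function(preds, dtrain) {
    w <- r^2 * exp(-2 * preds)
    # hessian floored at 1: damped Newton steps, stable when residuals -> 0
    list(grad = 1 - w, hess = pmax(2 * w, 1))
  }
}

fit_xgb_gaussian <- function(Z, y, nrounds) {
  dm <- xgboost::xgb.DMatrix(Z, label = y)
  mean_fit <- xgboost::xgb.train(params = xgb_params_mean(), data = dm,
                                 nrounds = nrounds, verbose = 0)
  r <- y - stats::predict(mean_fit, dm)
  ds <- xgboost::xgb.DMatrix(Z, label = numeric(length(y)))
  sd_fit <- xgboost::xgb.train(
    params = list(max_depth = 2, eta = 0.1, base_score = 0, seed = 0,
                  nthread = 1),
    data = ds, nrounds = max(50L, nrounds %/% 2L), verbose = 0,
    obj = gauss_sd_objective(r))
  list(mean = mean_fit, sd = sd_fit)
}

#' Fit gradient-boosted regional tau models with Gaussian uncertainty
#'
#' One boosted regressor per target column under a Gaussian error model:
#' the mean is fit by squared-error boosting, then a second boosted model
#' fits log-SD by maximizing the Gaussian likelihood of the residuals, so
#' each prediction carries a regional uncertainty estimate.
#'
#' @param features data.frame of covariates (missingness allowed; KNN
#'   imputation is applied first).
#' @param targets data.frame/matrix of per-ROI SUVR columns (conventionally
#'   `tau_<roi id>`), optionally including a `meta_temp_tau` column.
#' @param min_rows minimum training rows (default 20).
#' @param nrounds boosting rounds per model.
#' @param sigma_floor lower bound for predicted SDs.
#' @return a `regional_tau_model`.
#' @export
fit_regional_tau <- function(features, targets, min_rows = 20L,
                             nrounds = 150L, sigma_floor = 1e-3) {
  targets <- as.data.frame(targets)
  if (nrow(features) != nrow(targets)) stop("features/targets row mismatch")
  if (nrow(features) < min_rows) {
    stop("fewer than ", min_rows, " training rows")
  }
  imp <- knn_impute(features)
  des <- build_design(imp)
  fits <- lapply(names(targets), function(nm) {
    fit_xgb_gaussian(des$Z, targets[[nm]], nrounds)
  })
  names(fits) <- names(targets)
  structure(list(fits = fits, schema = des$schema,
                 target_cols = names(targets), sigma_floor = sigma_floor),
            class = "regional_tau_model")
}

#' @export
predict.regional_tau_model <- function(object, newdata, ...) {
  des <- build_design(knn_impute(newdata), object$schema)
  dm <- xgboost::xgb.DMatrix(des$Z)
  mu <- vapply(object$fits, function(f) stats::predict(f$mean, dm),
               numeric(nrow(des$Z)))
  sg <- vapply(object$fits, function(f)
    pmax(exp(stats::predict(f$sd, dm)), object$sigma_floor),
    numeric(nrow(des$Z)))
  if (nrow(des$Z) == 1L) {
    mu <- matrix(mu, 1L, dimnames = list(NULL, object$target_cols))
    sg <- matrix(sg, 1L, dimnames = list(NULL, object$target_cols))
  }
  list(mean = mu, sd = sg)
}

#' Fit the amyloid-status classifier
#'
#' Boosted logistic classifier returning P(amyloid positive).
#' @param features covariate data.frame (imputed internally).
#' @param abeta_labels binary 0/1 vector.
#' @param nrounds boosting rounds.
#' @return an `abeta_model`.
#' @export
fit_abeta <- function(features, abeta_labels, nrounds = 150L) {
  if (length(unique(abeta_labels[!is.na(abeta_labels)])) < 2L) {
    stop("amyloid labels contain a single class")
  }
  des <- build_design(knn_impute(features))
  dm <- xgboost::xgb.DMatrix(des$Z, label = abeta_labels)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = 3, eta = 0.1,
                  seed = 0, nthread = 1),
    data = dm, nrounds = nrounds, verbose = 0)
  structure(list(fit = fit, schema = des$schema), class = "abeta_model")
}

#' @export
predict.abeta_model <- function(object, newdata, ...) {
  des <- build_design(knn_impute(newdata), object$schema)
  p <- stats::predict(object$fit, xgboost::xgb.DMatrix(des$Z))
  list(prob = p, status = as.integer(p >= 0.5))
}

#' Fit the KNN MMSE regressor
#'
#' Nearest-neighbour mean regressor with the same neighbourhood rule as
#' imputation (`k = round(sqrt(p))`).
#' @param features covariate data.frame (imputed internally).
#' @param mmse numeric vector in [0, 30].
#' @return an `mmse_model`.
#' @export
fit_mmse <- function(features, mmse) {
  stopifnot(all(mmse >= 0 & mmse <= 30))
  des <- build_design(knn_impute(features))
  structure(list(Z = des$Z, y = mmse, schema = des$schema,
                 k = knn_k(ncol(des$Z))),
            class = "mmse_model")
}

#' @export
predict.mmse_model <- function(object, newdata, ...) {
  des <- build_design(knn_impute(newdata), object$schema)
  Ztr <- object$Z
  k <- min(object$k, length(object$y))
  vapply(seq_len(nrow(des$Z)), function(i) {
    d2 <- colSums((t(Ztr) - des$Z[i, ])^2)
    mean(object$y[order(d2)[seq_len(k)]])
  }, 0)
}

#' Fit the full auxiliary model bundle
#'
#' Convenience wrapper fitting the regional tau models, the amyloid
#' classifier and the MMSE regressor on one training split, recording the
#' training subject ids for the out-of-sample guard used in
#' cross-validation.
#'
#' @param features covariate data.frame for the training split.
#' @param targets regional tau target columns (plus `meta_temp_tau`).
#' @param abeta_labels binary amyloid labels.
#' @param mmse MMSE scores.
#' @param atlas optional `coma_atlas`; required for
#'   `meta_mode = "from_regional"`.
#' @param subject_ids training subject identifiers (for the leakage guard).
#' @param meta_mode `"direct"` (MetaTempTau has its own model, mirroring the
#'   estimator design) or `"from_regional"` (derived as the voxel-weighted
#'   combination of the regional predictions).
#' @param cv_guard if TRUE, predicting on any training subject id fails.
#' @param nrounds boosting rounds.
#' @param min_rows minimum training rows for the boosted models.
#' @return a `coma_aux` bundle.
#' @export
fit_auxiliary <- function(features, targets, abeta_labels, mmse,
                          atlas = NULL, subject_ids = NULL,
                          meta_mode = c("direct", "from_regional"),
                          cv_guard = FALSE, nrounds = 150L,
                          min_rows = 20L) {
  meta_mode <- match.arg(meta_mode)
  targets <- as.data.frame(targets)
  if (meta_mode == "from_regional" && is.null(atlas)) {
    stop("meta_mode = 'from_regional' requires the atlas")
  }
  reg <- fit_regional_tau(features, targets, nrounds = nrounds,
                          min_rows = min_rows)
  ab <- fit_abeta(features, abeta_labels, nrounds = nrounds)
  mm <- fit_mmse(features, mmse)
  roi_cols <- grep("^tau_", names(targets), value = TRUE)
  structure(list(regional = reg, abeta = ab, mmse = mm,
                 roi_cols = roi_cols,
                 roi_ids = as.integer(sub("^tau_", "", roi_cols)),
                 meta_mode = meta_mode,
                 meta_weights = if (!is.null(atlas)) {
                   stats::setNames(atlas$roi_table$n_voxels,
                                   atlas$roi_table$id)
                 },
                 meta_members = if (!is.null(atlas)) atlas$meta_temp_members,
                 train_ids = subject_ids, cv_guard = cv_guard),
            class = "coma_aux")
}

#' Predict auxiliary estimates for new subjects
#'
#' Applies imputation and all stage-1 models, returning per-subject regional
#' tau means/SDs, the MetaTempTau estimate, amyloid probability/status and
#' predicted MMSE.
#'
#' @param models a `coma_aux` bundle.
#' @param table covariate data.frame (missingness allowed).
#' @param subject_ids identifiers of the rows in `table`; checked against
#'   the training ids when the bundle was fitted with `cv_guard = TRUE`.
#' @return a `coma_aux_estimates` list: `tau_hat` and `sigma_hat`
#'   (n x ROI matrices), `meta_temp_hat`, `abeta_prob`, `abeta_status`,
#'   `mmse_hat`.
#' @export
predict_auxiliary <- function(models, table, subject_ids = NULL) {
  stopifnot(inherits(models, "coma_aux"))
  if (isTRUE(models$cv_guard) && !is.null(subject_ids) &&
      !is.null(models$train_ids)) {
    overlap <- intersect(subject_ids, models$train_ids)
    if (length(overlap)) {
      stop("out-of-sample guard: subject(s) ",
           paste(utils::head(overlap, 5L), collapse = ", "),
           " were in the training split")
    }
  }
  pr <- stats::predict(models$regional, table)
  tau_hat <- pr$mean[, models$roi_cols, drop = FALSE]
  sigma_hat <- pr$sd[, models$roi_cols, drop = FALSE]
  colnames(tau_hat) <- colnames(sigma_hat) <- models$roi_ids
  meta <- if (models$meta_mode == "from_regional") {
    w <- models$meta_weights[as.character(models$meta_members)]
    mh <- tau_hat[, as.character(models$meta_members), drop = FALSE]
    as.vector(mh %*% (w / sum(w)))
  } else if ("meta_temp_tau" %in% colnames(pr$mean)) {
    pr$mean[, "meta_temp_tau"]
  } else {
    stop("no meta_temp_tau target column and meta_mode = 'direct'")
  }
  ab <- stats::predict(models$abeta, table)
  structure(list(tau_hat = tau_hat, sigma_hat = sigma_hat,
                 meta_temp_hat = meta,
                 abeta_prob = ab$prob, abeta_status = ab$status,
                 mmse_hat = pmin(30, pmax(0, stats::predict(models$mmse,
                                                            table)))),
            class = "coma_aux_estimates")
}
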