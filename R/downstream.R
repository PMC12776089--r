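# Downstream clinical-evaluation battery: longitudinal mixed-effects
# coupling of synthetic and true MetaTempTau, diagnostic classification,
# dependent-correlation contrasts with FDR control, proportional-odds
# Braak-stage regression, and tertile-stratified spline trajectories.

#' Longitudinal coupling of synthetic and true MetaTempTau
#'
#' REML fit of the linear mixed-effects model
#' `true_it = b0 + b1 * synth_it + u0_i + u1_i * synth_it + e_it`
#' with correlated random intercepts/slopes per subject, relating the true
#' composite to the synthetic one across repeated visits.  Reports fixed
#' effects with Wald (normal) standard errors and two-sided p-values,
#' random-effect variances and their correlation, the residual variance,
#' and a likelihood-ratio test (ML refits) against the intercept-only
#' model (fixed and random slope dropped).
#'
#' @param true_meta,synth_meta per-observation composite SUVR values.
#' @param subject_ids per-observation subject identifiers.
#' @param random if FALSE the random effects are dropped and the model
#'   reduces to ordinary least squares (for degenerate designs).
#' @param lr_test if TRUE (default) also fit the null model for the LR
#'   test.
#' @return a `coma_lme` object.
#' @export
fit_longitudinal_coupling <- function(true_meta, synth_meta, subject_ids,
                                      random = TRUE, lr_test = TRUE) {
  stopifnot(length(true_meta) == length(synth_meta),
            length(true_meta) == length(subject_ids))
  dat <- data.frame(y = true_meta, x = synth_meta,
                    id = factor(subject_ids))
  n_obs <- nrow(dat)
  n_sub <- nlevels(dat$id)
  if (!random) {
    fit <- stats::lm(y ~ x, data = dat)
    cf <- summary(fit)$coefficients
    return(structure(list(beta0 = cf[1, 1], beta1 = cf[2, 1],
                          se0 = cf[1, 2], se1 = cf[2, 2],
                          p0 = cf[1, 4], p1 = cf[2, 4],
                          re_var = c(intercept = 0, slope = 0),
                          re_cor = NA_real_,
                          resid_var = summary(fit)$sigma^2,
                          n_subjects = n_sub, n_obs = n_obs,
                          singular = FALSE, lrt = NULL, fit = fit),
                     class = "coma_lme"))
  }
  fit <- suppressWarnings(
    lme4::lmer(y ~ x + (1 + x | id), data = dat, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))
  )
  fe <- lme4::fixef(fit)
  se <- tryCatch(suppressWarnings(sqrt(diag(as.matrix(stats::vcov(fit))))),
                 error = function(e) rep(NA_real_, length(fe)))
  cf <- cbind(fe, se)
  z <- cf[, 1] / cf[, 2]
  p <- 2 * stats::pnorm(-abs(z))
  vc <- lme4::VarCorr(fit)$id
  lrt <- NULL
  if (lr_test) {
    full_ml <- suppressWarnings(
      lme4::lmer(y ~ x + (1 + x | id), data = dat, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))
    null_ml <- suppressWarnings(
      lme4::lmer(y ~ 1 + (1 | id), data = dat, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore")))
    an <- stats::anova(null_ml, full_ml)
    dfcol <- if (!is.null(an$npar)) diff(an$npar) else an$Df[2]
    lrt <- list(chisq = an$Chisq[2], df = dfcol,
                p = an$`Pr(>Chisq)`[2])
  }
  structure(list(beta0 = cf[1, 1], beta1 = cf[2, 1],
                 se0 = cf[1, 2], se1 = cf[2, 2],
                 p0 = p[1], p1 = p[2],
                 re_var = c(intercept = vc[1, 1], slope = vc[2, 2]),
                 re_cor = attr(vc, "correlation")[1, 2],
                 resid_var = stats::sigma(fit)^2,
                 n_subjects = n_sub, n_obs = n_obs,
                 singular = lme4::isSingular(fit), lrt = lrt, fit = fit),
            class = "coma_lme")
}

#' @export
print.coma_lme <- function(x, ...) {
  cat("Longitudinal coupling (", x$n_subjects, " subjects, ", x$n_obs,
      " observations)\n", sep = "")
  cat(sprintf("  fixed intercept: %.3f +/- %.3f (p = %.3g)\n",
              x$beta0, x$se0, x$p0))
  cat(sprintf("  fixed slope:     %.3f +/- %.3f (p = %.3g)\n",
              x$beta1, x$se1, x$p1))
  cat(sprintf("  random SDs: intercept %.3f, slope %.3f (cor %.2f); residual SD %.3f\n",
              sqrt(x$re_var[1]), sqrt(x$re_var[2]),
              ifelse(is.na(x$re_cor), NA, x$re_cor), sqrt(x$resid_var)))
  if (!is.null(x$lrt)) {
    cat(sprintf("  LR test vs intercept-only: chisq = %.2f, df = %d, p = %.3g\n",
                x$lrt$chisq, x$lrt$df, x$lrt$p))
  }
  if (x$singular) cat("  note: singular random-effects fit\n")
  invisible(x)
}

#' Univariate diagnostic classification with ROC-AUC
#'
#' Logistic regression of a binary diagnosis on a single tau summary
#' (e.g. MetaTempTau from synthetic volumes), evaluated on a held-out set
#' by the rank-statistic (Mann-Whitney) AUC with midranks for ties.
#'
#' @param values scalar predictor per subject.
#' @param labels binary labels (0/1).
#' @param train_idx,test_idx index vectors; must not overlap.
#' @return list: `model` (glm fit), `auc` (held-out ROC-AUC), `n_test`.
#' @export
classify_diagnosis <- function(values, labels, train_idx, test_idx) {
  stopifnot(!anyNA(values), length(values) == length(labels))
  if (length(intersect(train_idx, test_idx))) {
    stop("train and test indices overlap")
  }
  if (length(unique(labels[train_idx])) < 2L) {
    stop("training set contains a single class")
  }
  if (length(unique(labels[test_idx])) < 2L) {
    stop("AUC undefined: held-out set contains a single class")
  }
  fit <- suppressWarnings(
    stats::glm(y ~ x, family = stats::binomial(),
               data = data.frame(y = labels[train_idx],
                                 x = values[train_idx])))
  scores <- stats::predict(fit, newdata = data.frame(x = values[test_idx]),
                           type = "response")
  list(model = fit, auc = auc_rank(scores, labels[test_idx]),
       n_test = length(test_idx))
}

# Mann-Whitney AUC with midranks
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Steiger's Z for two dependent correlations sharing one variable
#'
#' Tests whether `r(x, y)` differs from `r(z, y)` when all three variables
#' are measured on the same n subjects: Fisher-z transforms of the two
#' correlations, with the covariance correction for their dependence
#' through `r(x, z)` evaluated at the pooled correlation.
#'
#' @param r_xy,r_zy the two correlations sharing variable y.
#' @param r_xz correlation between the two non-shared variables.
#' @param n sample size (> 3).
#' @return list with `z` and two-sided `p`.
#' @export
steiger_z <- function(r_xy, r_zy, r_xz, n) {
  if (n <= 3) stop("n must exceed 3")
  if (any(abs(c(r_xy, r_zy, r_xz)) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)")
  }
  z1 <- atanh(r_xy); z2 <- atanh(r_zy)
  rbar <- (r_xy + r_zy) / 2
  psi <- r_xz * (1 - 2 * rbar^2) - 0.5 * rbar^2 *
    (1 - 2 * rbar^2 - r_xz^2)
  s <- psi / (1 - rbar^2)^2
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg false-discovery-rate control
#'
#' Step-up BH procedure: returns monotone adjusted p-values and the
#' rejection set at level q.
#'
#' @param p_values numeric vector in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list: `adjusted`, `reject` (logical), `n_rejected`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, reject = adj <= q, n_rejected = sum(adj <= q))
}

#' Proportional-odds regression of tau burden on Braak group
#'
#' Cumulative-logit (proportional-odds) model of the ordered Braak group on
#' a scalar SUVR summary, by maximum likelihood; reports the slope with
#' Wald z, 95% CI and p, and the (strictly increasing) thresholds.
#' Complete or quasi-complete separation is reported with a flag rather
#' than an error.
#'
#' @param suvr scalar summary per subject (e.g. medial-temporal SUVR).
#' @param braak_group ordered group labels (factor or numeric codes).
#' @return an `ordinal_fit` object.
#' @export
ordinal_braak <- function(suvr, braak_group) {
  g <- if (is.ordered(braak_group)) braak_group else
    factor(braak_group, ordered = TRUE)
  keep <- !is.na(suvr) & !is.na(g)
  g <- droplevels(g[keep]); x <- suvr[keep]
  if (nlevels(g) < 2L) stop("need at least 2 populated Braak groups")
  if (nlevels(g) == 2L) {
    # two groups: the cumulative-logit model is binary logistic regression
    yb <- as.integer(g == levels(g)[2])
    fit <- stats::glm(yb ~ x, family = stats::binomial(),
                      data = data.frame(yb = yb, x = x))
    beta <- unname(stats::coef(fit)["x"])
    se <- sqrt(stats::vcov(fit)["x", "x"])
    zeta <- -unname(stats::coef(fit)[1])
  } else {
    fit <- suppressWarnings(
      MASS::polr(g ~ x, data = data.frame(g = g, x = x), Hess = TRUE))
    beta <- unname(stats::coef(fit)["x"])
    vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
    se <- if (!is.null(vc)) sqrt(vc["x", "x"]) else NA_real_
    zeta <- fit$zeta
  }
  zv <- beta / se
  separation <- !is.finite(se) || abs(beta) > 20
  structure(list(beta = beta, se = se, z = zv,
                 ci = beta + c(-1, 1) * stats::qnorm(0.975) * se,
                 p = 2 * stats::pnorm(-abs(zv)),
                 thresholds = zeta,
                 levels = levels(g), n = length(x),
                 separation_flag = separation, fit = fit),
            class = "ordinal_fit")
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("Proportional-odds regression of Braak group on tau burden (n = ",
      x$n, ")\n", sep = "")
  cat(sprintf("  beta = %.3f, 95%% CI [%.3f, %.3f], z = %.2f, p = %.3g\n",
              x$beta, x$ci[1], x$ci[2], x$z, x$p))
  if (x$separation_flag) cat("  note: possible separation; estimates unstable\n")
  invisible(x)
}

#' Tertile-stratified longitudinal cognition trajectories
#'
#' Re-stratifies subjects into tertiles of a synthetic tau summary and fits
#' a linear mixed model with a natural-cubic-spline time basis, a
#' tertile-by-spline interaction, and subject random intercepts (REML, per
#' arm when arm labels are given).  Pairwise tertile differences of the
#' fitted trajectories are evaluated at the endpoint time, with Wald
#' (normal) standard errors.
#'
#' Tertiles are cut at the empirical 1/3 and 2/3 quantiles (rank-based, so
#' group sizes differ by at most one).
#'
#' @param meta_hat scalar synthetic tau summary per subject.
#' @param subject_ids per-observation subject identifiers (matching the
#'   names/order of `meta_hat` via `names(meta_hat)` or position).
#' @param scores longitudinal cognition scores (per observation).
#' @param times observation times (years).
#' @param arm_labels optional per-observation treatment-arm labels.
#' @param df_spline spline degrees of freedom (default 3: two interior
#'   knots at the time terciles).
#' @param t_eval contrast evaluation time; default the last observed time.
#' @return a `trajectory_contrast` object with `tertile` assignment and a
#'   `contrasts` data.frame (arm, contrast, estimate, se, t, p).
#' @export
tertile_trajectories <- function(meta_hat, subject_ids, scores, times,
                                 arm_labels = NULL, df_spline = 3L,
                                 t_eval = NULL) {
  stopifnot(length(scores) == length(times),
            length(scores) == length(subject_ids))
  if (length(unique(times)) < 3L) {
    stop("need at least 3 distinct time points")
  }
  subj <- unique(subject_ids)
  mh <- meta_hat
  if (!is.null(names(mh))) mh <- mh[as.character(subj)] else
    stopifnot(length(mh) == length(subj))
  if (is.null(arm_labels)) arm_labels <- rep("all", length(scores))
  if (is.null(t_eval)) t_eval <- max(times)

  dat <- data.frame(id = factor(subject_ids), score = scores, time = times,
                    arm = arm_labels)
  arm_of_subj <- tapply(as.character(dat$arm), dat$id, function(a) a[1])

  out_contrasts <- NULL
  tert_all <- integer(length(subj)); names(tert_all) <- as.character(subj)
  fits <- list()
  for (arm in unique(dat$arm)) {
    sub_ids <- names(arm_of_subj)[arm_of_subj == arm]
    m <- mh[sub_ids]
    # rank-based tertile cut (sizes differ by <= 1)
    tert <- floor((rank(m, ties.method = "first") - 1) * 3 / length(m)) + 1L
    tert_all[sub_ids] <- tert
    d <- dat[dat$arm == arm, ]
    d$tertile <- factor(tert[as.character(d$id)], levels = 1:3,
                        labels = c("T1", "T2", "T3"))
    kn <- stats::quantile(d$time, c(1, 2) / 3)
    bk <- range(d$time)
    B <- splines::ns(d$time, knots = kn, Boundary.knots = bk)
    colnames(B) <- paste0("s", seq_len(ncol(B)))
    d <- cbind(d, B)
    form <- stats::as.formula(paste(
      "score ~ (", paste(colnames(B), collapse = " + "),
      ") * tertile + (1 | id)"))
    fit <- suppressWarnings(lme4::lmer(form, data = d, REML = TRUE))
    fe <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    b_eval <- drop(stats::predict(B, t_eval))
    # fixed-effect design rows at the endpoint for each tertile
    drow <- function(t_lab) {
      x <- stats::setNames(numeric(length(fe)), names(fe))
      x["(Intercept)"] <- 1
      x[paste0("s", seq_along(b_eval))] <- b_eval
      if (t_lab != "T1") {
        x[paste0("tertile", t_lab)] <- 1
        x[paste0("s", seq_along(b_eval), ":tertile", t_lab)] <- b_eval
      }
      x
    }
    for (ctr in list(c("T3", "T1"), c("T3", "T2"), c("T2", "T1"))) {
      L <- drow(ctr[1]) - drow(ctr[2])
      est <- sum(L * fe)
      se <- sqrt(drop(t(L) %*% V %*% L))
      out_contrasts <- rbind(out_contrasts, data.frame(
        arm = arm, contrast = paste(ctr, collapse = "-"),
        estimate = est, se = se, t = est / se,
        p = 2 * stats::pnorm(-abs(est / se)), t_eval = t_eval))
    }
    fits[[arm]] <- fit
  }
  structure(list(tertile = tert_all, contrasts = out_contrasts,
                 fits = fits, t_eval = t_eval),
            class = "trajectory_contrast")
}

#' @export
print.trajectory_contrast <- function(x, ...) {
  cat("Tertile-stratified trajectory contrasts (endpoint t = ", x$t_eval,
      ")\n", sep = "")
  print(x$contrasts, row.names = FALSE, digits = 4)
  invisible(x)
}
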