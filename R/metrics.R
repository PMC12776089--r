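#' Per-ROI Pearson correlation and its average (Corr_AVG)
#'
#' Sample Pearson correlation across subjects between predicted and true
#' regional SUVR, computed per ROI; `corr_avg` is the arithmetic mean over
#' ROIs.  Zero-variance columns yield NA (with a warning) and are excluded
#' from the average.
#'
#' @param pred_suvr,true_suvr numeric matrices (subjects x ROIs) with
#'   matching ROI columns.
#' @return list with `r` (named per-ROI correlations) and `corr_avg`.
#' @export
roi_pearson <- function(pred_suvr, true_suvr) {
  pred_suvr <- as.matrix(pred_suvr); true_suvr <- as.matrix(true_suvr)
  if (!all(dim(pred_suvr) == dim(true_suvr))) {
    stop("pred and true SUVR matrices must have matching dimensions")
  }
  if (nrow(pred_suvr) < 3L) stop("need at least 3 subjects")
  r <- vapply(seq_len(ncol(pred_suvr)), function(j) {
    x <- pred_suvr[, j]; y <- true_suvr[, j]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, 0)
  names(r) <- colnames(pred_suvr)
  if (anyNA(r)) {
    warning(sum(is.na(r)), " ROI(s) with zero variance excluded from Corr_AVG")
  }
  list(r = r, corr_avg = mean(r, na.rm = TRUE))
}

#' Voxel-wise mean absolute percentage error and mean absolute error
#'
#' `MAPE = 100 * mean(|pred - true| / true)` (percent);
#' `MAE = mean(|pred - true|)` (SUVR).  When a mask is given, the mean runs
#' over masked voxels only (the recommended mode: background voxels are near
#' zero and make the percentage error ill-defined).
#'
#' @param pred,true numeric arrays of identical shape.
#' @param mask optional logical array restricting the domain.
#' @return scalar.
#' @export
mape <- function(pred, true, mask = NULL) {
  d <- metric_domain(pred, true, mask)
  bad <- sum(d$t <= 0)
  if (bad > 0L) {
    stop("MAPE undefined: ", bad, " true voxel(s) <= 0 inside the domain")
  }
  100 * mean(abs(d$p - d$t) / d$t)
}

#' @rdname mape
#' @export
mae <- function(pred, true, mask = NULL) {
  d <- metric_domain(pred, true, mask)
  mean(abs(d$p - d$t))
}

metric_domain <- function(pred, true, mask) {
  if (!all(dim(pred) == dim(true))) stop("pred/true shape mismatch")
  if (is.null(mask)) {
    list(p = as.vector(pred), t = as.vector(true))
  } else {
    if (!all(dim(mask) == dim(true))) stop("mask shape mismatch")
    list(p = pred[mask], t = true[mask])
  }
}

#' Structural similarity index for 3D volumes
#'
#' Standard windowed SSIM: within every cubic window fully inside the
#' volume, luminance, contrast and structure terms are combined as
#' \deqn{SSIM = \frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
#'                   {(\mu_x^2+\mu_y^2+C_1)(\sigma_x^2+\sigma_y^2+C_2)}}
#' with \eqn{C_1 = (K_1 L)^2}, \eqn{C_2 = (K_2 L)^2}, L the dynamic range,
#' uniform window weights and sample (n-1) variances; the index is the mean
#' over all window positions.  Returns a value in [-1, 1]; 1 means the
#' volumes are identical.
#'
#' @param pred,true numeric arrays of identical shape.
#' @param window odd cubic window edge length (default 7).
#' @param data_range dynamic range L; default `max(true) - min(true)`.
#' @param K1,K2 stabilizing constants.
#' @return scalar SSIM.
#' @export
ssim <- function(pred, true, window = 7L, data_range = NULL,
                 K1 = 0.01, K2 = 0.03) {
  if (!all(dim(pred) == dim(true))) stop("pred/true shape mismatch")
  if (window %% 2L != 1L) stop("window must be odd")
  if (any(dim(true) < window)) {
    stop("window (", window, ") larger than volume (",
         paste(dim(true), collapse = "x"), ")")
  }
  if (is.null(data_range)) data_range <- diff(range(true))
  if (data_range <= 0) data_range <- 1
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  n <- window^3
  sx <- box_sum(pred, window); sy <- box_sum(true, window)
  sxx <- box_sum(pred * pred, window); syy <- box_sum(true * true, window)
  sxy <- box_sum(pred * true, window)
  mx <- sx / n; my <- sy / n
  # sample (n-1) normalization, matching the canonical implementation
  vx <- (sxx - n * mx * mx) / (n - 1)
  vy <- (syy - n * my * my) / (n - 1)
  cxy <- (sxy - n * mx * my) / (n - 1)
  smap <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
    ((mx * mx + my * my + C1) * (vx + vy + C2))
  mean(smap)
}

# sums over all w^3 windows fully inside the volume, via cumulative sums
box_sum <- function(x, w) {
  for (d in 1:3) {
    x <- apply(x, setdiff(1:3, d), function(v) {
      cs <- cumsum(v)
      cs[w:length(v)] - c(0, cs)[seq_len(length(v) - w + 1L)]
    })
    # apply returns the reduced dim first; rotate back to (d1, d2, d3) order
    x <- aperm(x, order(c(d, setdiff(1:3, d))))
  }
  x
}

#' Voxel-wise Cohen's d effect-size map
#'
#' Per voxel, `(mean_a - mean_b) / s_pooled` with the pooled-variance
#' denominator `n_a + n_b - 2`.  Voxels with zero pooled SD are set to 0;
#' their count is attached as attribute `n_zero_sd`.
#'
#' @param group_a,group_b lists of 3D arrays (>= 2 volumes each).
#' @return 3D array of Cohen's d values.
#' @export
cohens_d_map <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("need at least 2 volumes per group")
  dims <- dim(group_a[[1]])
  A <- vapply(group_a, as.vector, numeric(prod(dims)))
  B <- vapply(group_b, as.vector, numeric(prod(dims)))
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2); vb <- rowSums((B - mb)^2)
  sp <- sqrt((va + vb) / (na + nb - 2))
  d <- ifelse(sp > 0, (ma - mb) / sp, 0)
  nz <- sum(sp == 0)
  dim(d) <- dims
  attr(d, "n_zero_sd") <- nz
  d
}

#' Image-fidelity report for a set of synthetic volumes
#'
#' Compares synthetic and true volumes subject-by-subject: per-ROI Pearson
#' correlation across subjects (and Corr_AVG), per-ROI MAPE/MAE on regional
#' SUVR, global voxel-wise MAPE/MAE (averaged over subjects), and mean SSIM.
#'
#' @param pred_list,true_list lists of 3D arrays on the atlas grid.
#' @param atlas a `coma_atlas`.
#' @param mask_mode `"brain"` (default; voxel-wise metrics restricted to the
#'   ROI union) or `"all"` (entire grid).
#' @param scale_invariant if TRUE, report only correlation-based metrics
#'   (for predicted/true pairs on different intensity scales, e.g. an unseen
#'   radiotracer).
#' @param ssim_window SSIM window edge length.
#' @return a `coma_fidelity` list: `per_roi` data.frame, `corr_avg`,
#'   `mape`, `mae`, `ssim`, `n`.
#' @export
fidelity_report <- function(pred_list, true_list, atlas,
                            mask_mode = c("brain", "all"),
                            scale_invariant = FALSE,
                            ssim_window = 7L) {
  mask_mode <- match.arg(mask_mode)
  stopifnot(length(pred_list) == length(true_list), length(pred_list) >= 3L)
  n <- length(pred_list)
  P <- t(vapply(pred_list, regional_suvr, numeric(nrow(atlas$roi_table)),
                atlas = atlas))
  T_ <- t(vapply(true_list, regional_suvr, numeric(nrow(atlas$roi_table)),
                 atlas = atlas))
  colnames(P) <- colnames(T_) <- atlas$roi_table$name
  rp <- roi_pearson(P, T_)
  per_roi <- data.frame(id = atlas$roi_table$id,
                        name = atlas$roi_table$name,
                        pearson_r = unname(rp$r))
  out <- list(per_roi = per_roi, corr_avg = rp$corr_avg, n = n,
              scale_invariant = scale_invariant)
  if (!scale_invariant) {
    per_roi$mape <- vapply(seq_len(ncol(P)), function(j)
      100 * mean(abs(P[, j] - T_[, j]) / T_[, j]), 0)
    per_roi$mae <- vapply(seq_len(ncol(P)), function(j)
      mean(abs(P[, j] - T_[, j])), 0)
    out$per_roi <- per_roi
    msk <- if (mask_mode == "brain") atlas_mask(atlas) else NULL
    out$mape <- mean(mapply(function(p, t) mape(p, t, msk),
                            pred_list, true_list))
    out$mae <- mean(mapply(function(p, t) mae(p, t, msk),
                           pred_list, true_list))
    out$ssim <- mean(mapply(function(p, t) ssim(p, t, window = ssim_window),
                            pred_list, true_list))
  }
  structure(out, class = "coma_fidelity")
}

#' @export
print.coma_fidelity <- function(x, ...) {
  cat("Synthetic tau PET fidelity (n = ", x$n, " subjects)\n", sep = "")
  cat(sprintf("  Corr_AVG = %.4f\n", x$corr_avg))
  if (!isTRUE(x$scale_invariant)) {
    cat(sprintf("  MAPE     = %.2f%%\n  MAE      = %.4f SUVR\n", x$mape,
                x$mae))
    cat(sprintf("  SSIM     = %.4f\n", x$ssim))
  } else {
    cat("  (scale-invariant mode: correlation metrics only)\n")
  }
  invisible(x)
}
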