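# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

small_atlas <- function() {
  fixture("atlas16", function() build_atlas(c(16L, 16L, 16L), n_rois = 8L,
                                            seed = 1L))
}

small_params <- function() {
  fixture("params16", function() phantom_params(small_atlas()))
}

# cohort without covariate missingness (network-input fixtures must be
# complete so tiny n cannot produce an all-missing plasma column)
small_cohort <- function() {
  fixture("cohort16", function() {
    atl <- small_atlas()
    simulate_cohort(atl, phantom_params(atl, missingness_rates = c(none = 0)),
                    n = 8L, seed = 11L)
  })
}

small_estimates <- function() {
  fixture("estimates16", function() {
    co <- small_cohort()
    aux <- fit_cohort_auxiliary(co, small_atlas(), nrounds = 30L,
                                           min_rows = 2L)
    predict_auxiliary(aux, tausynth:::strip_ids(cohort_covariates(co)))
  })
}

small_net <- function() {
  fixture("net16", function() {
    net <- coma_unet(c(16L, 16L, 16L), encoder_channels = c(6L, 12L, 24L),
                     seed = 2L)
    co <- small_cohort()
    set_cond_stats(net, cohort_covariates(co), small_estimates())
    net
  })
}

random_volume <- function(grid, seed) {
  set.seed(seed)
  array(stats::runif(prod(grid), 0.2, 2), dim = grid)
}

# independent loop oracles --------------------------------------------------

loop_mape <- function(p, t, mask = NULL) {
  pv <- as.vector(p); tv <- as.vector(t)
  if (!is.null(mask)) { pv <- pv[as.vector(mask)]; tv <- tv[as.vector(mask)] }
  s <- 0
  for (i in seq_along(pv)) s <- s + abs(pv[i] - tv[i]) / tv[i]
  100 * s / length(pv)
}

loop_mae <- function(p, t, mask = NULL) {
  pv <- as.vector(p); tv <- as.vector(t)
  if (!is.null(mask)) { pv <- pv[as.vector(mask)]; tv <- tv[as.vector(mask)] }
  s <- 0
  for (i in seq_along(pv)) s <- s + abs(pv[i] - tv[i])
  s / length(pv)
}

loop_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

loop_cohens_d <- function(va, vb) {
  # va, vb: lists of arrays; returns a plain 3D array
  dims <- dim(va[[1]])
  out <- array(0, dims)
  na <- length(va); nb <- length(vb)
  for (v in seq_len(prod(dims))) {
    a <- vapply(va, function(x) x[v], 0)
    b <- vapply(vb, function(x) x[v], 0)
    sp <- sqrt((sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2))
    out[v] <- if (sp > 0) (mean(a) - mean(b)) / sp else 0
  }
  out
}

# windowed SSIM by direct window enumeration (sample covariances, uniform
# window, canonical constants)
loop_ssim <- function(x, y, w = 7L, K1 = 0.01, K2 = 0.03) {
  L <- diff(range(y)); if (L <= 0) L <- 1
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  d <- dim(x); h <- (w - 1L) %/% 2L
  vals <- numeric(0)
  for (i in (1 + h):(d[1] - h)) for (j in (1 + h):(d[2] - h))
    for (k in (1 + h):(d[3] - h)) {
      xs <- as.vector(x[(i - h):(i + h), (j - h):(j + h), (k - h):(k + h)])
      ys <- as.vector(y[(i - h):(i + h), (j - h):(j + h), (k - h):(k + h)])
      mx <- mean(xs); my <- mean(ys)
      vx <- stats::var(xs); vy <- stats::var(ys); cxy <- stats::cov(xs, ys)
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}
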