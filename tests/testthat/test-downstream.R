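test_that("identity coupling gives unit slope and zero intercept", {
  set.seed(10)
  id <- rep(1:40, each = 3)
  x <- rnorm(120, 1.4, 0.3)
  f <- fit_longitudinal_coupling(x, x, id)
  expect_lt(abs(f$beta1 - 1), 1e-6)
  expect_lt(abs(f$beta0), 1e-6)
})

test_that("mixed-effects coupling recovers simulated fixed effects", {
  hits0 <- 0L
  hits1 <- 0L
  for (rep in 1:50) {
    set.seed(400 + rep)
    n <- 100
    id <- rep(seq_len(n), each = 3)
    b0i <- rnorm(n, 0, 0.1); b1i <- rnorm(n, 0, 0.05)
    x <- rnorm(3 * n, 1.4, 0.3)
    y <- 0.5 + 0.47 * x + b0i[id] + b1i[id] * x + rnorm(3 * n, 0, 0.05)
    f <- fit_longitudinal_coupling(y, x, id, lr_test = FALSE)
    hits0 <- hits0 + (abs(f$beta0 - 0.5) <= 2 * f$se0)
    hits1 <- hits1 + (abs(f$beta1 - 0.47) <= 2 * f$se1)
  }
  # each fixed effect within 2 SE of its truth in >= 90% of replicates
  expect_gte(hits0, 45L)
  expect_gte(hits1, 45L)
})

test_that("permuted synthetic values carry no slope", {
  null_ok <- 0L
  for (rep in 1:20) {
    set.seed(700 + rep)
    n <- 60
    id <- rep(seq_len(n), each = 3)
    x <- rnorm(3 * n, 1.4, 0.3)
    y <- 0.5 + 0.47 * x + rnorm(3 * n, 0, 0.1)
    xp <- sample(x)
    f <- fit_longitudinal_coupling(y, xp, id, lr_test = FALSE)
    if (is.na(f$se1) || abs(f$beta1 / f$se1) < qnorm(0.975)) {
      null_ok <- null_ok + 1L
    }
  }
  expect_gte(null_ok, 18L)
})

test_that("random effects constrained away reduce to ordinary least squares", {
  set.seed(11)
  id <- rep(1:30, each = 2)
  x <- rnorm(60); y <- 0.2 + 0.8 * x + rnorm(60, 0, 0.1)
  f <- fit_longitudinal_coupling(y, x, id, random = FALSE)
  ls <- stats::lm(y ~ x)
  expect_lt(abs(f$beta1 - stats::coef(ls)[2]), 1e-8)
  expect_lt(abs(f$beta0 - stats::coef(ls)[1]), 1e-8)
})

test_that("diagnostic AUC equals the concordant-pair count and is
           rank-invariant", {
  set.seed(12)
  v <- c(rnorm(10, 0), rnorm(10, 1.5))
  l <- rep(0:1, each = 10)
  tr <- c(1:5, 11:15); te <- c(6:10, 16:20)
  cd <- classify_diagnosis(v, l, tr, te)
  # brute-force pair counting on the held-out set
  sc <- v[te]; lb <- l[te]
  pos <- sc[lb == 1]; neg <- sc[lb == 0]
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + (p > q) + 0.5 * (p == q)
  }
  expect_equal(cd$auc, conc / (length(pos) * length(neg)))
  # invariance under a strictly monotone transform of the scores
  cd2 <- classify_diagnosis(exp(2 * v), l, tr, te)
  expect_equal(cd2$auc, cd$auc)
  expect_error(classify_diagnosis(v, rep(1, 20), tr, te), "single class")
})

test_that("perfectly separated scores give AUC 1 and null scores ~0.5", {
  v <- c(1:20 / 10, 5 + 1:20 / 10)
  l <- rep(0:1, each = 20)
  tr <- seq(1, 40, 2); te <- seq(2, 40, 2)
  expect_equal(classify_diagnosis(v, l, tr, te)$auc, 1)
  set.seed(13)
  vr <- rnorm(400); lr <- rep(0:1, 200)
  cd <- classify_diagnosis(vr, lr, 1:200, 201:400)
  expect_lt(abs(cd$auc - 0.5), 0.15)
})

test_that("Steiger's Z matches an independently coded formula and is zero
           under equality", {
  eq <- steiger_z(0.5, 0.5, 0.3, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  # independent coding of the published test (pooled-r covariance form)
  oracle <- function(r12, r13, r23, n) {
    z12 <- 0.5 * log((1 + r12) / (1 - r12))
    z13 <- 0.5 * log((1 + r13) / (1 - r13))
    rm2 <- ((r12 + r13) / 2)^2
    f <- (r23 * (1 - 2 * rm2) - 0.5 * rm2 * (1 - 2 * rm2 - r23^2)) /
      (1 - rm2)^2
    (z12 - z13) * sqrt((n - 3) / (2 - 2 * f))
  }
  got <- steiger_z(0.6, 0.3, 0.4, 100)
  expect_lt(abs(got$z - oracle(0.6, 0.3, 0.4, 100)), 1e-10)
  expect_error(steiger_z(1, 0.5, 0.2, 30), "strictly inside")
  expect_error(steiger_z(0.5, 0.5, 0.2, 3), "exceed 3")
})

test_that("Steiger's Z holds its type-I error on trivariate-normal nulls", {
  set.seed(14)
  n <- 200
  # null: r(x, y) = r(z, y) = 0.5 in the population, r(x, z) = 0.4
  S <- matrix(c(1, 0.5, 0.4, 0.5, 1, 0.5, 0.4, 0.5, 1), 3, 3)
  R <- chol(S)
  rej <- 0L
  reps <- 500L
  for (i in seq_len(reps)) {
    X <- matrix(rnorm(n * 3), n, 3) %*% R
    r_xy <- cor(X[, 1], X[, 2]); r_zy <- cor(X[, 3], X[, 2])
    r_xz <- cor(X[, 1], X[, 3])
    if (steiger_z(r_xy, r_zy, r_xz, n)$p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / reps, 0.02)
  expect_lte(rej / reps, 0.08)
})

test_that("BH step-up matches hand execution and its invariants", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27)
  # hand execution of the step-up rule at q = 0.05: largest i with
  # p_(i) <= i q / m is i = 2, so the first two are rejected; adjusted
  # values are the running minima of p_(i) m / i from the top
  res <- bh_fdr(p, 0.05)
  expect_identical(which(res$reject), 1:2)
  expect_equal(res$adjusted, c(0.005, 0.02, 0.05125, 0.05125, 0.27))
  # monotone in the raw-p order, never below raw p
  expect_true(all(diff(res$adjusted[order(p)]) >= 0))
  expect_true(all(res$adjusted >= p))
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)        # single p unchanged
  expect_true(all(bh_fdr(rep(0, 4))$reject))       # all-zero p rejected
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("proportional-odds regression recovers a simulated slope and
           reduces to logistic regression for two groups", {
  hits <- 0L
  for (rep in 1:50) {
    set.seed(500 + rep)
    x <- rnorm(300)
    lat <- 3 * x + rlogis(300)
    g <- findInterval(lat, c(-1.5, 0.5, 2.5))
    f <- ordinal_braak(x, g)
    if (!f$separation_flag && abs(f$beta - 3) <= 2 * f$se) hits <- hits + 1L
  }
  expect_gte(hits, 45L)
  # two groups: slope equals the binary logistic slope
  set.seed(15)
  x <- rnorm(200)
  y <- rbinom(200, 1, plogis(1.2 * x))
  f2 <- ordinal_braak(x, y)
  gl <- stats::glm(y ~ x, family = stats::binomial())
  expect_lt(abs(f2$beta - stats::coef(gl)[2]), 1e-4)
  expect_true(all(diff(f2$thresholds) > 0 | length(f2$thresholds) == 1))
})

test_that("null ordinal fits cover zero", {
  cover <- 0L
  for (rep in 1:30) {
    set.seed(600 + rep)
    x <- rnorm(200)
    g <- sample(0:2, 200, replace = TRUE)
    f <- ordinal_braak(x, g)
    if (f$ci[1] <= 0 && f$ci[2] >= 0) cover <- cover + 1L
  }
  expect_gte(cover, 27L)
})

test_that("tertile trajectories partition subjects evenly and detect an
           injected decline", {
  set.seed(16)
  ns <- 100
  mh <- stats::setNames(runif(ns), seq_len(ns))
  tt <- rep(0:3, times = ns)
  sid <- rep(seq_len(ns), each = 4)
  sc <- rnorm(4 * ns)
  tj <- tertile_trajectories(mh, sid, sc, tt)
  expect_lte(diff(range(table(tj$tertile))), 1)
  expect_identical(sort(unique(tj$contrasts$contrast)),
                   sort(c("T3-T1", "T3-T2", "T2-T1")))
  expect_error(tertile_trajectories(mh, sid, sc, rep(0:1, 2 * ns)),
               "3 distinct time points")
})

test_that("trajectory contrasts have power for a tertile-specific decline
           and hold size under the null", {
  detect <- 0L; null_rej <- 0L
  n_rep <- 25L
  for (rep in seq_len(n_rep)) {
    set.seed(800 + rep)
    ns <- 300
    mh <- stats::setNames(runif(ns), seq_len(ns))
    tert <- floor((rank(mh, ties.method = "first") - 1) * 3 / ns) + 1L
    tt <- rep(0:3, times = ns)
    sid <- rep(seq_len(ns), each = 4)
    ri <- rep(rnorm(ns, 0, 0.5), each = 4)
    # alternative: -2 points at endpoint in the top tertile only
    dec <- ifelse(tert[sid] == 3L, -2 / 3, 0)
    sc1 <- dec * tt + ri + rnorm(4 * ns, 0, 0.8)
    c1 <- tertile_trajectories(mh, sid, sc1, tt)$contrasts
    r1 <- c1[c1$contrast == "T3-T1", ]
    if (r1$p < 0.05 && r1$estimate < 0) detect <- detect + 1L
    # null: no tertile effect
    sc0 <- ri + rnorm(4 * ns, 0, 0.8)
    c0 <- tertile_trajectories(mh, sid, sc0, tt)$contrasts
    if (c0[c0$contrast == "T3-T1", "p"] < 0.05) null_rej <- null_rej + 1L
  }
  expect_gte(detect / n_rep, 0.9)
  expect_lte(null_rej / n_rep, 0.1 + 0.1)  # binomial slack at 25 replicates
})
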