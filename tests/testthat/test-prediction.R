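test_that("ols_fit reproduces exact and brute-force solutions", {
  x <- 1:10
  f <- ols_fit(cbind(x = x), 2 * x)
  expect_equal(unname(f$coefficients["x"]), 2, tolerance = 1e-12)
  expect_equal(f$residuals, rep(0, 10), tolerance = 1e-10)

  # y orthogonal to centered X -> zero slope, intercept = mean(y)
  X <- cbind(a = c(-1, 0, 1, 0, -1, 1))
  y <- c(1, -2, 1, 2, -1, -1)   # sum(a*y) = 0, mean 0
  f2 <- ols_fit(X, y)
  expect_equal(unname(f2$coefficients), 0, tolerance = 1e-12)
  expect_equal(f2$intercept, mean(y), tolerance = 1e-12)

  set.seed(5)
  X3 <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y3 <- rnorm(50)
  f3 <- ols_fit(X3, y3)
  Xd <- cbind(1, X3)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y3)        # normal equations oracle
  expect_equal(unname(c(f3$intercept, f3$coefficients)), unname(drop(beta)),
               tolerance = 1e-10)
  lf <- lm(y3 ~ X3)
  expect_equal(unname(f3$se), unname(coef(summary(lf))[, "Std. Error"]),
               tolerance = 1e-10)
  # residual orthogonality to every design column
  for (j in 1:4)
    expect_lt(abs(sum(f3$residuals * Xd[, j])),
              1e-8 * sqrt(sum(f3$residuals^2)) * sqrt(sum(Xd[, j]^2)) + 1e-12)

  expect_error(ols_fit(cbind(a = X3[, 1], dup = 2 * X3[, 1]), y3), "dup")
  expect_error(ols_fit(X3[1:3, ], y3[1:3]), "more rows")
})

test_that("ridge_fit matches OLS at lambda 0 and closed forms", {
  set.seed(6)
  X <- matrix(rnorm(120), 40, 3)
  y <- rnorm(40)
  r0 <- ridge_fit(X, y, lambda = 0)
  ols <- ols_fit(X, y)
  expect_equal(r0$coefficients, ols$coefficients, tolerance = 1e-8)
  expect_equal(r0$intercept, ols$intercept, tolerance = 1e-8)

  rbig <- ridge_fit(X, y, lambda = 1e9)
  expect_lt(sqrt(sum(rbig$coefficients^2)),
            1e-3 * sqrt(sum(ols$coefficients^2)))

  # single centered feature, lambda 1, no scaling: beta = Sxy / (Sxx + 1)
  x1 <- scale(rnorm(30), scale = FALSE)
  y1 <- rnorm(30)
  r1 <- ridge_fit(cbind(f = drop(x1)), y1, lambda = 1, standardize = FALSE)
  expect_equal(unname(r1$coefficients["f"]),
               sum(x1 * (y1 - mean(y1))) / (sum(x1^2) + 1), tolerance = 1e-12)

  expect_error(ridge_fit(X, y, lambda = -1), ">= 0")
  expect_error(ridge_fit(cbind(k = rep(1, 40)), y, lambda = 1), "constant")
})

test_that("ridge coefficient norm is non-increasing in lambda", {
  set.seed(13)
  X <- matrix(rnorm(200), 40, 5)
  y <- drop(X %*% rnorm(5)) + rnorm(40)
  norms <- sapply(c(0, 1, 10, 100, 1000, 1e4), function(l)
    sqrt(sum(ridge_fit(X, y, lambda = l)$coefficients^2)))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("screen_features drops constants and applies the alpha/m sieve", {
  set.seed(21)
  X <- cbind(const = rep(1, 60), s1 = rnorm(60), s2 = rnorm(60))
  y <- X[, "s1"] + rnorm(60, sd = 0.1)
  kept <- screen_features(X, y, variance_floor = 1e-8, alpha = 60)
  expect_false(1 %in% kept)           # constant always dropped
  expect_true(2 %in% kept)
  # alpha = m makes the sieve p <= 1: keeps every non-constant column
  expect_equal(screen_features(X, y, alpha = 2), c(2L, 3L))
  expect_error(screen_features(X[, 1, drop = FALSE], y), "variance floor")

  # planted-signal oracle: 100 noise columns + 1 copy of y, alpha = 0.05.
  # P(exactly the copy kept) = (1 - 0.05/101)^100 ~ 0.952 per run; over
  # 100 runs a >=89 cutoff is a ~3-sigma lower bound on that rate.
  hits <- 0
  for (s in 1:100) {
    set.seed(1000 + s)
    Xn <- matrix(rnorm(120 * 100), 120, 100)
    yy <- rnorm(120)
    Xp <- cbind(Xn, copy = yy)
    kept <- screen_features(Xp, yy, alpha = 0.05)
    expect_true(101 %in% kept)
    if (identical(kept, 101L)) hits <- hits + 1
  }
  expect_gte(hits, 89)
})

test_that("pca_reduce is train-only and matches the eigendecomposition", {
  set.seed(31)
  X <- matrix(rnorm(300), 30, 10)
  red <- pca_reduce(X, X, variance_fraction = 1)
  recon <- red$train %*% t(red$rotation) +
    matrix(red$center, 30, 10, byrow = TRUE)
  expect_equal(recon, X, tolerance = 1e-8)

  rank1 <- outer(rnorm(20), rnorm(4))
  expect_equal(ncol(pca_reduce(rank1, rank1, 0.5)$train), 1)

  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(red$sdev^2, ev, tolerance = 1e-10)

  # apply projection uses train centering, not its own
  Xa <- matrix(rnorm(50), 5, 10) + 100
  red2 <- pca_reduce(X, Xa, 0.9)
  manual <- sweep(Xa, 2, colMeans(X)) %*% red2$rotation
  expect_equal(red2$apply, manual, tolerance = 1e-10)
})

test_that("fold assignment is deterministic, balanced, and RNG-clean", {
  f1 <- assign_folds(103, 10, seed = 9)
  f2 <- assign_folds(103, 10, seed = 9)
  expect_identical(f1, f2)
  expect_false(identical(f1, assign_folds(103, 10, seed = 10)))
  expect_true(max(tabulate(f1, 10)) - min(tabulate(f1, 10)) <= 1)
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(assign_folds(50, 5, seed = 3)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("crossval_predict recovers noiseless signal and stays null on noise", {
  set.seed(41)
  X <- matrix(rnorm(300 * 2), 300, 2, dimnames = list(NULL, c("a", "b")))
  y <- drop(X %*% c(2, -1)) + 5
  ev <- crossval_predict(X, y, pipeline_config(lambda = 0, seed = 1))
  expect_gt(ev$r, 0.999)
  expect_lt(ev$mae, 1e-6)

  set.seed(42)
  Xn <- matrix(rnorm(200 * 50), 200, 50)
  yn <- rnorm(200)
  evn <- crossval_predict(Xn, yn, pipeline_config(seed = 1))
  expect_lt(abs(evn$r), 0.2)
})

test_that("controls-only crossval recovers the generating correlation", {
  set.seed(43)
  n <- 500
  C <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("u", "v", "w")))
  beta <- c(1, 0.5, -0.5)
  signal <- drop(C %*% beta)
  y <- signal + rnorm(n, sd = sd(signal))   # population R ~ 1/sqrt(2)
  ev <- crossval_predict(NULL, y, pipeline_config(seed = 2), controls = C)
  expect_equal(ev$r, sqrt(0.5), tolerance = 0.08)
  expect_equal(length(unique(ev$fold)), 10)
})

test_that("combined model degrades gracefully when language is pure noise", {
  set.seed(44)
  n <- 500
  C <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("u", "v")))
  y <- drop(C %*% c(1, -1)) + rnorm(n)
  Xn <- matrix(rnorm(n * 30), n, 30)
  ev_c <- crossval_predict(NULL, y, pipeline_config(seed = 3), controls = C)
  ev_b <- crossval_predict(Xn, y, pipeline_config(seed = 3), controls = C)
  expect_lt(abs(ev_b$r - ev_c$r), 0.05)
})

test_that("held-out outcomes cannot leak into their own predictions", {
  set.seed(45)
  n <- 120
  X <- matrix(rnorm(n * 10), n, 10)
  y <- drop(X[, 1]) + rnorm(n)
  cfg <- pipeline_config(seed = 7, folds = 5)
  base <- crossval_predict(X, y, cfg)
  for (f in c(1, 4)) {
    idx <- which(base$fold == f)
    y2 <- y
    y2[idx] <- sample(y2[idx])
    pert <- crossval_predict(X, y2, cfg)
    expect_equal(pert$predictions[idx], base$predictions[idx],
                 tolerance = 1e-12)
  }
})

test_that("evaluate and compare_models match their definitions", {
  set.seed(51)
  obs <- rnorm(40); pred <- obs + rnorm(40, sd = 0.3)
  ev <- evaluate(pred, obs)
  expect_equal(ev$r, oracle_pearson(pred, obs), tolerance = 1e-12)
  expect_equal(ev$mae, mean(abs(pred - obs)), tolerance = 1e-12)
  expect_equal(evaluate(obs, obs), list(r = 1, mae = 0))
  cent <- obs - mean(obs)
  expect_equal(evaluate(-cent, cent)$r, -1, tolerance = 1e-12)
  expect_error(evaluate(rep(1, 5), rnorm(5)), "constant")

  expect_error(compare_models(c(1, 2, 3), c(1, 2, 3)), "zero-variance")
  expect_error(compare_models(c(1, 2, 3), c(2, 3, 4)), "zero-variance")
  a <- rnorm(30); b <- a + rnorm(30)
  cm <- compare_models(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(cm$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(cm$p, tt$p.value, tolerance = 1e-10)

  # power: A systematically worse than B by 0.5 with unit noise, n = 100.
  # Closed form: ncp = 0.5 * sqrt(100) = 5, so per-rep power is
  # P(|t_99| > crit | ncp 5) ~ 0.9986 (> the claimed 99%); failures over
  # 200 reps are ~ Poisson(0.28), so >= 198 is a ~3-sigma empirical bound.
  rejects <- 0
  for (s in 1:200) {
    set.seed(2000 + s)
    eb <- abs(rnorm(100))
    ea <- eb + rnorm(100, mean = 0.5, sd = 1)
    if (compare_models(ea, eb)$p < 0.05) rejects <- rejects + 1
  }
  expect_gte(rejects, 198)
})
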