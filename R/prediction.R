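#' Pipeline configuration for cross-validated prediction
#'
#' Collects the tuning constants of the language-prediction pipeline
#' (screen -> PCA -> ridge under k-fold cross-validation).
#'
#' @param lambda ridge penalty (default 1000)
#' @param variance_floor drop features with sample variance below this
#'   (default `1e-8`, i.e. only numerically constant features)
#' @param alpha family-wise screening level: after the variance screen a
#'   feature is kept iff its correlation p-value with the outcome is
#'   `<= alpha / m`, `m` the number of screened candidates. The default
#'   60 is deliberately permissive: with ~2000 features it only discards
#'   features essentially unrelated to the outcome
#' @param pca_variance fraction of training variance the retained
#'   principal components must explain (default 0.99)
#' @param folds number of cross-validation folds k (default 10)
#' @param seed integer seed controlling the fold permutation (default 42)
#' @return a list of class `pipeline_config`
#' @export
pipeline_config <- function(lambda = 1000, variance_floor = 1e-8,
                            alpha = 60, pca_variance = 0.99,
                            folds = 10, seed = 42) {
  stopifnot(lambda >= 0, variance_floor >= 0, alpha > 0,
            pca_variance > 0, pca_variance <= 1, folds >= 2)
  structure(list(lambda = lambda, variance_floor = variance_floor,
                 alpha = alpha, pca_variance = pca_variance,
                 folds = as.integer(folds), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Univariate feature screen
#'
#' Two-stage screen used before PCA: first drop columns whose sample
#' variance is below `variance_floor`, then keep column j iff the
#' two-sided p-value of its Pearson correlation with `y` satisfies
#' `p <= alpha / m`, where `m` is the number of columns surviving the
#' variance screen (a Bonferroni-style sieve; `alpha` far above 1 makes
#' it permissive by design).
#'
#' @param X units x features matrix
#' @param y outcome vector
#' @param variance_floor non-negative variance cutoff
#' @param alpha family-wise screening level (> 0)
#' @return integer vector of retained column indices (into `X`)
#' @export
screen_features <- function(X, y, variance_floor = 1e-8, alpha = 60) {
  stopifnot(alpha > 0)
  X <- as.matrix(X)
  n <- nrow(X)
  v <- colVars(X)
  cand <- which(v >= variance_floor & v > 0)
  if (length(cand) == 0) stop("screen_features: all features below variance floor")
  m <- length(cand)
  r <- drop(stats::cor(X[, cand, drop = FALSE], y))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  keep <- unname(cand[p <= alpha / m])
  if (length(keep) == 0)
    stop("screen_features: no feature passes the correlation screen")
  keep
}

colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' Train-only principal component reduction
#'
#' Centers with training means, extracts principal components from the
#' training matrix only, keeps the smallest number of components whose
#' cumulative explained variance reaches `variance_fraction` (capped at
#' the matrix rank), and projects the apply matrix with the training
#' rotation and centering.
#'
#' @param X_train training matrix (>= 2 rows)
#' @param X_apply matrix to project with the training rotation (same
#'   columns)
#' @param variance_fraction in (0, 1]
#' @return list with `train`, `apply` (component scores), `rotation`,
#'   `center`, `sdev` (component standard deviations, all components)
#' @export
pca_reduce <- function(X_train, X_apply, variance_fraction = 0.99) {
  stopifnot(variance_fraction > 0, variance_fraction <= 1)
  X_train <- as.matrix(X_train)
  if (nrow(X_train) < 2) stop("pca_reduce: need >= 2 training rows")
  pc <- stats::prcomp(X_train, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev[1], .Machine$double.eps) * 1e-12)
  frac <- cumsum(ev[seq_len(rank)]) / sum(ev)
  ncomp <- which(frac >= variance_fraction - 1e-12)[1]
  if (is.na(ncomp)) ncomp <- rank
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  apply_c <- sweep(as.matrix(X_apply), 2, pc$center)
  list(train = pc$x[, seq_len(ncomp), drop = FALSE],
       apply = apply_c %*% rot,
       rotation = rot, center = pc$center, sdev = pc$sdev)
}

#' Deterministic fold assignment
#'
#' Partitions `n` units into `k` folds of sizes differing by at most
#' one, by a seeded permutation. The assignment is a pure function of
#' `(n, k, seed)` and does not disturb the caller's RNG state.
#'
#' @param n number of units
#' @param k number of folds
#' @param seed integer seed
#' @return integer vector of fold ids in 1..k
#' @export
assign_folds <- function(n, k, seed) {
  stopifnot(n >= k, k >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample(rep(seq_len(k), length.out = n))
}

#' Cross-validated outcome prediction
#'
#' Predicts the county outcome under k-fold cross-validation, with three
#' model shapes depending on which feature blocks are supplied:
#'
#' * language only (`X`): within each training fold, features are
#'   screened ([screen_features()]), standardized with training-fold
#'   statistics, reduced by train-only PCA ([pca_reduce()]) and fit by
#'   ridge regression ([ridge_fit()]);
#' * controls only (`controls`): a plain OLS fit ([ols_fit()]) on the
#'   socio-demographic columns — no screening or PCA;
#' * combined (`X` + `controls`): per training fold, OLS of the outcome
#'   on the controls, then the language pipeline fit on the OLS
#'   *residuals*; the held-out prediction is the sum of the two parts.
#'
#' All statistics (screening, standardization, PCA, both fits) are
#' computed from the training fold only, so held-out outcomes can never
#' influence their own predictions.
#'
#' @param X county x feature matrix of language features, or `NULL`
#' @param y outcome vector
#' @param config a [pipeline_config()]
#' @param controls optional county x covariate matrix
#' @return object of class `model_evaluation`: list with `predictions`,
#'   `fold` (fold id per county), `r` (pooled Pearson r over all
#'   held-out predictions), `r_by_fold`, `mean_fold_r`, `mae`,
#'   `abs_errors`, `n`, `config`
#' @export
crossval_predict <- function(X, y, config = pipeline_config(),
                             controls = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(X) && is.null(controls))
    stop("crossval_predict: need language features and/or controls")
  n <- length(y)
  k <- config$folds
  if (n < 2 * k) stop("crossval_predict: need n >= 2k")
  if (!is.null(X)) { X <- as.matrix(unclass(X)); stopifnot(nrow(X) == n) }
  if (!is.null(controls)) {
    controls <- as.matrix(controls); stopifnot(nrow(controls) == n)
  }
  fold <- assign_folds(n, k, config$seed)
  if (min(tabulate(fold, k)) < 2) stop("crossval_predict: fold with < 2 counties")
  pred <- numeric(n)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    target <- y[tr]
    base_pred <- rep(0, length(te))
    if (!is.null(controls)) {
      cfit <- ols_fit(controls[tr, , drop = FALSE], y[tr])
      base_pred <- predict(cfit, controls[te, , drop = FALSE])
      target <- cfit$residuals
    }
    lang_pred <- rep(0, length(te))
    if (!is.null(X)) {
      sel <- screen_features(X[tr, , drop = FALSE], target,
                             config$variance_floor, config$alpha)
      mu <- colMeans(X[tr, sel, drop = FALSE])
      sdv <- apply(X[tr, sel, drop = FALSE], 2, stats::sd)
      Ztr <- sweep(sweep(X[tr, sel, drop = FALSE], 2, mu), 2, sdv, "/")
      Zte <- sweep(sweep(X[te, sel, drop = FALSE], 2, mu), 2, sdv, "/")
      red <- pca_reduce(Ztr, Zte, config$pca_variance)
      rfit <- ridge_fit(red$train, target, lambda = config$lambda,
                        standardize = FALSE)
      lang_pred <- predict(rfit, red$apply)
    }
    pred[te] <- base_pred + lang_pred
  }
  ev <- evaluate(pred, y)
  r_by_fold <- vapply(seq_len(k), function(f) {
    idx <- fold == f
    if (stats::sd(pred[idx]) == 0 || stats::sd(y[idx]) == 0) NA_real_
    else stats::cor(pred[idx], y[idx])
  }, numeric(1))
  structure(list(predictions = pred, fold = fold, r = ev$r,
                 r_by_fold = r_by_fold,
                 mean_fold_r = mean(r_by_fold, na.rm = TRUE),
                 mae = ev$mae, abs_errors = abs(pred - y), n = n,
                 config = config),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation> n = %d, %d folds\n", x$n, x$config$folds))
  cat(sprintf("  pooled Pearson r = %.3f  (mean per-fold r = %.3f)\n",
              x$r, x$mean_fold_r))
  cat(sprintf("  mean absolute error = %.3f\n", x$mae))
  invisible(x)
}

#' Prediction accuracy: Pearson r and MAE
#'
#' @param predictions predicted values
#' @param observed observed values (same length, >= 3, non-constant)
#' @return list with `r` (Pearson product-moment correlation) and `mae`
#'   (mean absolute error)
#' @export
evaluate <- function(predictions, observed) {
  if (length(predictions) != length(observed) || length(observed) < 3)
    stop("evaluate: need equal lengths >= 3")
  if (stats::sd(predictions) == 0 || stats::sd(observed) == 0)
    stop("evaluate: constant vector, Pearson r undefined")
  list(r = stats::cor(predictions, observed),
       mae = mean(abs(predictions - observed)))
}

#' Paired t-test between two models' errors
#'
#' Tests whether per-county errors differ systematically between two
#' models evaluated on the same counties. By convention the errors are
#' per-county absolute errors, paired by county; a negative t means
#' model A has smaller error.
#'
#' @param errors_a,errors_b equal-length (>= 3) per-county error vectors
#' @return list with `t`, `p` (two-sided, t distribution with n-1 df),
#'   `df`, `mean_diff`
#' @export
compare_models <- function(errors_a, errors_b) {
  if (length(errors_a) != length(errors_b) || length(errors_a) < 3)
    stop("compare_models: need equal lengths >= 3")
  d <- errors_a - errors_b
  sdd <- stats::sd(d)
  if (sdd == 0)
    stop("compare_models: zero-variance error differences; paired t undefined")
  n <- length(d)
  t <- mean(d) / (sdd / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), df = n - 1,
       mean_diff = mean(d))
}
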