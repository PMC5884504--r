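#' Ordinary least squares fit
#'
#' Fits `y = intercept + X beta + e` by QR decomposition. Coefficient
#' standard errors come from `sigma^2 (X'X)^{-1}` with
#' `sigma^2 = RSS / (n - p - 1)`. The design (with intercept) must be of
#' full column rank; rank deficiency is an error naming the offending
#' columns.
#'
#' @param X numeric matrix, units x features (colnames recommended)
#' @param y numeric response vector
#' @return object of class `linear_fit`: list with `coefficients`,
#'   `intercept`, `se` (including `(Intercept)`), `residuals`, `fitted`,
#'   `sigma2`, `df_residual`, `type = "ols"`
#' @export
ols_fit <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("ols_fit: length(y) != nrow(X)")
  if (n <= p + 1) stop("ols_fit: need more rows than features + intercept")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  Xd <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xd)
  if (qx$rank < ncol(Xd)) {
    bad <- colnames(Xd)[qx$pivot[(qx$rank + 1):ncol(Xd)]]
    stop("ols_fit: rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  coef <- qr.coef(qx, y)
  fitted <- drop(Xd %*% coef)
  res <- y - fitted
  df <- n - p - 1
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(sigma2 * diag(xtx_inv))
  names(se) <- colnames(Xd)
  structure(list(coefficients = coef[-1], intercept = unname(coef[1]),
                 se = se, residuals = res, fitted = fitted,
                 sigma2 = sigma2, df_residual = df, type = "ols"),
            class = "linear_fit")
}

#' Ridge regression fit
#'
#' Solves the penalized normal equations
#' `beta = (X'X + lambda I)^{-1} X'y` on (by default) standardized
#' columns, via a linear solve rather than explicit inversion. The
#' intercept is unpenalized: y is centered and the intercept recovered
#' from the training means. Coefficients are reported on the original
#' feature scale.
#'
#' @param X numeric matrix, units x features
#' @param y numeric response
#' @param lambda non-negative ridge penalty (the convention here applies
#'   `lambda` directly to the standardized normal equations; default 1000)
#' @param standardize scale columns to unit sample sd before penalizing
#'   (default `TRUE`; constant columns are an error when `TRUE`)
#' @return a `linear_fit` with `type = "ridge"` and `lambda`; no
#'   standard errors
#' @export
ridge_fit <- function(X, y, lambda = 1000, standardize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (lambda < 0) stop("ridge_fit: lambda must be >= 0")
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("ridge_fit: length(y) != nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (standardize) {
    scl <- apply(X, 2, stats::sd)
    if (any(scl == 0))
      stop("ridge_fit: constant columns cannot be standardized: ",
           paste(colnames(X)[scl == 0], collapse = ", "))
    Xc <- sweep(Xc, 2, scl, "/")
  } else {
    scl <- rep(1, p)
  }
  yc <- y - mean(y)
  A <- crossprod(Xc) + diag(lambda, p)
  b_std <- drop(solve(A, crossprod(Xc, yc)))
  coef <- b_std / scl
  names(coef) <- colnames(X)
  intercept <- mean(y) - sum(coef * ctr)
  fitted <- drop(X %*% coef) + intercept
  structure(list(coefficients = coef, intercept = intercept,
                 se = NULL, residuals = y - fitted, fitted = fitted,
                 lambda = lambda, type = "ridge"),
            class = "linear_fit")
}

#' @export
predict.linear_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients))
    stop("predict.linear_fit: feature count mismatch")
  drop(newdata %*% object$coefficients) + object$intercept
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit:%s> %d features%s\n", x$type,
              length(x$coefficients),
              if (x$type == "ridge") sprintf(", lambda = %g", x$lambda) else ""))
  invisible(x)
}
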