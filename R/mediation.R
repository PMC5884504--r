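#' Sobel test of an indirect effect
#'
#' Normal-theory (delta-method) test of the product `a * b`:
#' `z = a b / sqrt(b^2 se_a^2 + a^2 se_b^2)`, two-sided p from the
#' standard normal. When both paths are exactly zero the statistic is
#' defined as `z = 0` (p = 1).
#'
#' @param a,se_a path a estimate and its standard error (`se_a > 0`)
#' @param b,se_b path b estimate and its standard error (`se_b > 0`)
#' @return list with `z` and `p`
#' @export
sobel <- function(a, se_a, b, se_b) {
  if (se_a <= 0 || se_b <= 0) stop("sobel: standard errors must be > 0")
  denom <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  z <- if (denom == 0) 0 else (a * b) / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Single-mediator three-regression analysis
#'
#' The standard three-step mediation of `x -> m -> y`, on standardized
#' variables so paths are comparable across mediators:
#' \deqn{y = c x + \beta_1 + \epsilon_1}
#' \deqn{m = a x + \beta_2 + \epsilon_2}
#' \deqn{y = c' x + b m + \beta_3 + \epsilon_3}
#' The mediation (indirect) effect is reported as `c - c'`, which for
#' nested OLS with a single mediator equals `a * b` exactly;
#' significance uses the Sobel z ([sobel()]).
#'
#' @param x independent variable (e.g. socioeconomic index)
#' @param m candidate mediator (e.g. one topic's scores)
#' @param y outcome
#' @return one-row data.frame of class `mediation_entry` with columns
#'   `a`, `se_a`, `b`, `se_b`, `c`, `c_prime`, `mediation` (= c - c'),
#'   `sobel_z`, `p`
#' @export
mediate <- function(x, m, y) {
  n <- length(x)
  if (length(m) != n || length(y) != n || n < 4)
    stop("mediate: need equal lengths >= 4")
  xz <- standardize(x)
  mz <- standardize(m)
  yz <- standardize(y)
  if (abs(stats::cor(xz, mz)) > 0.999)
    stop("mediate: mediator collinear with x; path b undefined")
  f1 <- ols_fit(cbind(x = xz), yz)                 # y ~ x       (path c)
  f2 <- ols_fit(cbind(x = xz), mz)                 # m ~ x       (path a)
  f3 <- ols_fit(cbind(x = xz, m = mz), yz)         # y ~ x + m   (c', b)
  a <- unname(f2$coefficients["x"]); se_a <- unname(f2$se["x"])
  b <- unname(f3$coefficients["m"]); se_b <- unname(f3$se["m"])
  cc <- unname(f1$coefficients["x"])
  cp <- unname(f3$coefficients["x"])
  s <- sobel(a, se_a, b, se_b)
  out <- data.frame(a = a, se_a = se_a, b = b, se_b = se_b,
                    c = cc, c_prime = cp, mediation = cc - cp,
                    sobel_z = s$z, p = s$p)
  class(out) <- c("mediation_entry", class(out))
  out
}

#' Mass mediation screen over all topics
#'
#' Treats every topic as a candidate mediator of the `ses -> outcome`
#' relationship, one [mediate()] per topic, then applies
#' Benjamini-Hochberg across all Sobel p-values. Degenerate topics
#' (zero variance, or |r(topic, ses)| > 0.999) are skipped with a
#' warning rather than aborting the screen. Output rows are ordered by
#' descending mediation size within the positive-b group, followed by
#' the negative-b group (the usual two-row figure layout).
#'
#' @param ses independent-variable vector (socioeconomic index)
#' @param scores [topic_scores()] matrix
#' @param outcome outcome vector
#' @param q BH false-discovery rate (default 0.05)
#' @return data.frame of class `mediation_result` with columns `topic`,
#'   `a`, `se_a`, `b`, `se_b`, `c`, `c_prime`, `mediation`, `sobel_z`,
#'   `p`, `p_bh`, `significant`; skipped topics are absent and listed in
#'   attribute `skipped`
#' @export
mass_mediation <- function(ses, scores, outcome, q = 0.05) {
  S <- as.matrix(unclass(scores))
  stopifnot(nrow(S) == length(ses), nrow(S) == length(outcome))
  skipped <- character(0)
  rows <- vector("list", ncol(S))
  for (j in seq_len(ncol(S))) {
    mj <- S[, j]
    if (stats::sd(mj) == 0 ||
        abs(suppressWarnings(stats::cor(ses, mj))) > 0.999) {
      skipped <- c(skipped, colnames(S)[j])
      next
    }
    e <- mediate(ses, mj, outcome)
    e$topic <- colnames(S)[j]
    rows[[j]] <- e
  }
  if (length(skipped) > 0)
    warning("mass_mediation: skipped degenerate topics: ",
            paste(utils::head(skipped, 5), collapse = ", "),
            if (length(skipped) > 5) " ..." else "")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) stop("mass_mediation: no non-degenerate topics")
  res <- do.call(rbind, rows)
  res <- res[c("topic", "a", "se_a", "b", "se_b", "c", "c_prime",
               "mediation", "sobel_z", "p")]
  adj <- bh_adjust(res$p, q)
  res$p_bh <- adj$p_adj
  res$significant <- adj$reject
  pos <- res[res$b >= 0, , drop = FALSE]
  neg <- res[res$b < 0, , drop = FALSE]
  res <- rbind(pos[order(-pos$mediation), , drop = FALSE],
               neg[order(-neg$mediation), , drop = FALSE])
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  class(res) <- c("mediation_result", class(res))
  res
}
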