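#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: with order statistics `p_(1) <= ... <= p_(m)`,
#' the adjusted value for rank i is `min_{j >= i} (m * p_(j) / j)`,
#' capped at 1; hypothesis i is rejected iff its adjusted p-value is at
#' most `q`. The BH rejection set always contains the Bonferroni
#' (`p <= q/m`) rejection set.
#'
#' @param pvalues numeric vector in \[0, 1\]
#' @param q target false-discovery rate in (0, 1) (default 0.05)
#' @return list with `p_adj` (adjusted p-values, input order) and
#'   `reject` (logical)
#' @export
bh_adjust <- function(pvalues, q = 0.05) {
  stopifnot(q > 0, q < 1)
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("bh_adjust: p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(list(p_adj = numeric(0), reject = logical(0)))
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  p_adj <- numeric(m)
  p_adj[o] <- adj_sorted
  list(p_adj = p_adj, reject = p_adj <= q)
}

#' Differential language analysis
#'
#' Regresses the (standardized) outcome on each (standardized) topic
#' score separately — optionally partialling out covariates such as the
#' socioeconomic index — and adjusts the per-topic p-values by
#' Benjamini-Hochberg across all non-degenerate topics. Without
#' covariates the standardized coefficient equals the Pearson
#' correlation between topic and outcome.
#'
#' Covariate adjustment uses the Frisch-Waugh-Lovell decomposition:
#' outcome and topics are residualized on the covariates (plus
#' intercept), and the per-topic slope and its standard error are
#' computed from the residuals with the full-model degrees of freedom
#' `n - n_covariates - 2`. This is algebraically identical to fitting
#' `outcome ~ topic + covariates` per topic, but vectorizes over
#' thousands of topics.
#'
#' @param scores [topic_scores()] matrix (counties x topics)
#' @param outcome numeric outcome vector
#' @param covariates optional numeric matrix of controls
#' @param q BH false-discovery rate (default 0.05)
#' @return data.frame of class `dla_result` with columns `topic`,
#'   `coef`, `se`, `p`, `p_bh`, `significant`, `degenerate` (constant
#'   topics: estimates `NA`, excluded from the BH family), plus
#'   attributes `n` and `covariate_names`
#' @export
dla_correlate <- function(scores, outcome, covariates = NULL, q = 0.05) {
  S <- as.matrix(unclass(scores))
  n <- nrow(S)
  ncov <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < ncov + 3) stop("dla_correlate: need n >= covariates + 3")
  if (length(outcome) != n) stop("dla_correlate: outcome length mismatch")
  yz <- standardize(outcome)
  sds <- apply(S, 2, stats::sd)
  ok <- sds > 0
  coef <- se <- p <- rep(NA_real_, ncol(S))
  if (any(ok)) {
    Z <- scale(S[, ok, drop = FALSE])  # per-topic z-scores
    if (is.null(covariates)) {
      ry <- yz; rt <- Z
      df <- n - 2
    } else {
      C <- scale(as.matrix(covariates))
      qc <- qr(cbind(1, C))
      ry <- qr.resid(qc, yz)
      rt <- qr.resid(qc, Z)
      df <- n - ncov - 2
    }
    stt <- colSums(rt^2)
    # a topic absorbed by the covariates leaves a ~zero residual: flag it
    usable <- stt > n * 1e-12
    b <- colSums(rt * ry) / stt
    rss <- colSums((ry - sweep(rt, 2, b, "*"))^2)
    serr <- sqrt(rss / df / stt)
    b[!usable] <- NA_real_
    serr[!usable] <- NA_real_
    coef[ok] <- b
    se[ok] <- serr
    p[ok] <- 2 * stats::pt(-abs(b / serr), df = df)
    ok[ok] <- usable
  }
  p_bh <- rep(NA_real_, ncol(S))
  signif <- rep(NA, ncol(S))
  if (any(ok)) {
    adj <- bh_adjust(p[ok], q)
    p_bh[ok] <- adj$p_adj
    signif[ok] <- adj$reject
  }
  res <- data.frame(topic = colnames(S), coef = coef, se = se, p = p,
                    p_bh = p_bh, significant = signif, degenerate = !ok,
                    stringsAsFactors = FALSE)
  attr(res, "n") <- n
  attr(res, "covariate_names") <-
    if (is.null(covariates)) character(0) else colnames(as.matrix(covariates))
  class(res) <- c("dla_result", class(res))
  res
}

#' Ranked report of significant topics with top words
#'
#' Summarizes a [dla_correlate()] result the way word clouds are usually
#' read: BH-significant topics split by coefficient sign, ordered by
#' decreasing |coefficient| within each sign, and each described by its
#' `k_words` highest-weight terms in the lexicon (ties broken by
#' lexicographic term order).
#'
#' @param entries a `dla_result` from [dla_correlate()]
#' @param lexicon the [topic_lexicon()] the scores came from
#' @param k_topics number of topics to keep per sign (default 10)
#' @param k_words number of top words per topic (default 15)
#' @return data.frame with columns `direction` (`"positive"` /
#'   `"negative"`), `rank`, `topic`, `coef`, `p_bh`, `term`, `weight`;
#'   zero rows (with a message) when nothing is significant
#' @export
top_topics <- function(entries, lexicon, k_topics = 10, k_words = 15) {
  stopifnot(inherits(entries, "dla_result"),
            inherits(lexicon, "topic_lexicon"))
  sig <- entries[!entries$degenerate & entries$significant, , drop = FALSE]
  empty <- data.frame(direction = character(0), rank = integer(0),
                      topic = character(0), coef = numeric(0),
                      p_bh = numeric(0), term = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  if (nrow(sig) == 0) {
    message("top_topics: no BH-significant topics")
    return(empty)
  }
  one_side <- function(rows, label) {
    rows <- rows[order(-abs(rows$coef), rows$topic), , drop = FALSE]
    rows <- utils::head(rows, k_topics)
    if (nrow(rows) == 0) return(empty)
    do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      tid <- rows$topic[i]
      if (!tid %in% lexicon$topic_ids)
        stop("top_topics: topic not in lexicon: ", tid)
      w <- lexicon$weights[, tid]
      w <- w[w > 0]
      ord <- order(-w, names(w))
      top <- utils::head(ord, k_words)
      data.frame(direction = label, rank = i, topic = tid,
                 coef = rows$coef[i], p_bh = rows$p_bh[i],
                 term = names(w)[top], weight = unname(w[top]),
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(one_side(sig[sig$coef > 0, , drop = FALSE], "positive"),
        one_side(sig[sig$coef < 0, , drop = FALSE], "negative"))
}
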