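#' County x topic score matrix
#'
#' Holds P(topic | county) values: for each county, its soft usage of
#' every topic in the lexicon. Constructed by [score_topics()].
#'
#' @param matrix numeric county x topic matrix with dimnames
#' @return object of class `topic_scores` (a plain numeric matrix with
#'   county rownames and topic colnames)
#' @export
topic_scores <- function(matrix) {
  m <- as.matrix(matrix)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("scores need county rownames and topic colnames")
  if (any(m < 0)) stop("topic scores must be non-negative")
  class(m) <- c("topic_scores", class(m))
  m
}

#' @export
print.topic_scores <- function(x, ...) {
  cat(sprintf("<topic_scores> %d counties x %d topics\n", nrow(x), ncol(x)))
  invisible(unclass(x))
}

#' Score counties on lexicon topics
#'
#' Computes the county-level topic usage
#' \deqn{P(topic_k \mid county_c) = \sum_{tok} P(topic_k \mid tok)\,
#'       P(tok \mid county_c),}
#' i.e. the lexicon weights averaged under each county's relative token
#' frequencies. Tokens absent from the lexicon contribute zero topic
#' mass; by default rows are *not* renormalized after dropping them, so
#' with a fully normalized lexicon that covers every corpus token each
#' county's scores sum to 1.
#'
#' @param freqs sparse county x token probability matrix from
#'   [relative_frequencies()] (rows sum to 1)
#' @param lexicon a [topic_lexicon()]
#' @param renormalize if `TRUE`, divide each county's scores by the
#'   lexicon-covered probability mass so rows sum to 1 even under partial
#'   coverage (default `FALSE`)
#' @return a [topic_scores()] matrix, counties x topics, topic columns in
#'   lexicon order
#' @export
score_topics <- function(freqs, lexicon, renormalize = FALSE) {
  stopifnot(inherits(lexicon, "topic_lexicon"))
  if (is.null(colnames(freqs)))
    stop("`freqs` must carry token colnames matching lexicon terms")
  common <- intersect(colnames(freqs), lexicon$terms)
  s <- matrix(0, nrow(freqs), length(lexicon$topic_ids),
              dimnames = list(rownames(freqs), lexicon$topic_ids))
  if (length(common) > 0) {
    s[] <- as.matrix(freqs[, common, drop = FALSE] %*%
                       lexicon$weights[common, , drop = FALSE])
  }
  if (renormalize) {
    covered <- Matrix::rowSums(freqs[, common, drop = FALSE])
    pos <- covered > 0
    s[pos, ] <- s[pos, , drop = FALSE] / covered[pos]
  }
  topic_scores(pmax(s, 0))
}

#' Write / read topic scores as CSV
#'
#' Wide CSV with a `county_id` column followed by one column per topic.
#'
#' @param scores a [topic_scores()] matrix
#' @param path file path
#' @return `write_scores`: `path` invisibly; `read_scores`: a
#'   [topic_scores()]
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(county_id = rownames(scores),
                   as.data.frame(unclass(scores)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "county_id") stop("first column must be county_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df$county_id)
  topic_scores(m)
}
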