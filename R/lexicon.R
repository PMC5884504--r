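#' Topic lexicon: term -> P(topic | term) weights
#'
#' A topic lexicon maps every term to a vector of non-negative topic
#' weights with the semantics of a posterior probability P(topic | term),
#' typically obtained from an LDA model fit on a large background corpus.
#' For any term the weights must sum to at most 1; a lexicon in which every
#' term's weights sum to exactly 1 is called *fully normalized*.
#'
#' @param weights sparse or dense numeric matrix, terms in rows and topics
#'   in columns; dimnames required. Values are P(topic | term).
#' @return An object of class `topic_lexicon`: a list with elements
#'   `weights` (a sparse `dgCMatrix`, term x topic), `terms`, `topic_ids`
#'   and `vocab_size`.
#' @examples
#' w <- matrix(c(0.8, 0.4, 0.2, 0.6), 2, 2,
#'             dimnames = list(c("beer", "wine"), c("t1", "t2")))
#' lex <- topic_lexicon(w)
#' lex$vocab_size
#' @export
topic_lexicon <- function(weights) {
  if (is.null(rownames(weights)) || is.null(colnames(weights)))
    stop("`weights` must have term rownames and topic colnames")
  w <- methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  if (any(w@x < 0)) stop("topic weights must be non-negative")
  if (anyDuplicated(rownames(w))) stop("duplicate terms in lexicon")
  if (anyDuplicated(colnames(w))) stop("duplicate topic ids in lexicon")
  rs <- Matrix::rowSums(w)
  if (any(rs > 1 + 1e-9))
    stop("per-term topic weights must sum to <= 1 (P(topic|term) semantics)")
  structure(list(weights = w,
                 terms = rownames(w),
                 topic_ids = colnames(w),
                 vocab_size = nrow(w)),
            class = "topic_lexicon")
}

#' @export
print.topic_lexicon <- function(x, ...) {
  cat(sprintf("<topic_lexicon> %d terms x %d topics (%s normalized)\n",
              x$vocab_size, length(x$topic_ids),
              if (is_normalized(x)) "fully" else "not fully"))
  invisible(x)
}

#' Test whether a lexicon is fully normalized
#'
#' A lexicon is fully normalized when every term's topic weights sum to 1,
#' i.e. the weights form a proper posterior P(topic | term) over the topic
#' set. Topic-mass conservation of the scoring step only holds for fully
#' normalized lexicons.
#'
#' @param lexicon a [topic_lexicon()]
#' @param tol numeric tolerance on the row sums
#' @return logical scalar
#' @export
is_normalized <- function(lexicon, tol = 1e-9) {
  stopifnot(inherits(lexicon, "topic_lexicon"))
  all(abs(Matrix::rowSums(lexicon$weights) - 1) <= tol)
}

#' Read a topic lexicon from CSV
#'
#' The file must have a header with columns `term`, `topic`, `weight`
#' (one row per non-zero term/topic weight). Duplicate (term, topic)
#' pairs, missing columns, non-numeric or negative weights are errors.
#' Topic ordering follows first appearance in the file.
#'
#' @param path path to a CSV file
#' @return a [topic_lexicon()]
#' @seealso [write_lexicon()]
#' @export
load_lexicon <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("term", "topic", "weight")
  if (!all(need %in% names(df)))
    stop("lexicon CSV must have columns term, topic, weight; missing: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  if (!is.numeric(df$weight))
    stop("lexicon column `weight` must be numeric")
  if (any(!is.finite(df$weight)) || any(df$weight < 0))
    stop("lexicon weights must be finite and non-negative")
  key <- paste(df$term, df$topic, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (term, topic) rows in lexicon: ",
         paste(utils::head(df$term[duplicated(key)], 3), collapse = ", "))
  ti <- factor(as.character(df$term), levels = unique(as.character(df$term)))
  ki <- factor(as.character(df$topic), levels = unique(as.character(df$topic)))
  w <- Matrix::sparseMatrix(i = as.integer(ti), j = as.integer(ki),
                            x = df$weight,
                            dims = c(nlevels(ti), nlevels(ki)),
                            dimnames = list(levels(ti), levels(ki)))
  topic_lexicon(w)
}

#' Write a topic lexicon to CSV
#'
#' Writes one `term,topic,weight` row per non-zero weight, at full
#' precision, so that `load_lexicon(write_lexicon(x, f))` round-trips to
#' within 1e-12.
#'
#' @param lexicon a [topic_lexicon()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "topic_lexicon"))
  tw <- Matrix::summary(lexicon$weights)
  df <- data.frame(term = lexicon$terms[tw$i],
                   topic = lexicon$topic_ids[tw$j],
                   weight = tw$x,
                   stringsAsFactors = FALSE)
  # preserve topic appearance order, then term order, on re-read
  df <- df[order(match(df$term, lexicon$terms),
                 match(df$topic, lexicon$topic_ids)), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("term,topic,weight", con)
  writeLines(sprintf("\"%s\",\"%s\",%.17g",
                     gsub("\"", "\"\"", df$term),
                     gsub("\"", "\"\"", df$topic), df$weight), con)
  invisible(path)
}
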