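#' County corpus: sparse per-county token counts
#'
#' Token counts aggregated to the geographic unit ("county"). Storage is
#' a sparse county x token matrix, so memory scales with the number of
#' non-zero (county, token) pairs rather than with counties x vocabulary.
#'
#' @param counts county x token matrix of non-negative integer counts,
#'   with county rownames and token colnames (sparse or dense)
#' @return object of class `county_corpus`: list with `counts` (sparse
#'   `dgCMatrix`) and `total_words` (named integer-valued vector,
#'   `rowSums(counts)`).
#' @export
county_corpus <- function(counts) {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    stop("`counts` must have county rownames and token colnames")
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  dn <- dimnames(m)
  if (is.null(dn)) dn <- list(NULL, NULL)
  if (is.null(dn[[1]]) && nrow(m) == 0) dn[[1]] <- character(0)
  if (is.null(dn[[2]]) && ncol(m) == 0) dn[[2]] <- character(0)
  dimnames(m) <- dn
  if (any(m@x < 0) || any(m@x != round(m@x)))
    stop("counts must be non-negative integers")
  if (anyDuplicated(rownames(m))) stop("duplicate county ids")
  structure(list(counts = m, total_words = Matrix::rowSums(m)),
            class = "county_corpus")
}

#' @export
print.county_corpus <- function(x, ...) {
  cat(sprintf("<county_corpus> %d counties, %d token types, %.0f tokens total\n",
              nrow(x$counts), ncol(x$counts), sum(x$total_words)))
  invisible(x)
}

#' Aggregate raw documents into a county corpus
#'
#' Tokenizes each document with [tokenize()] and sums token frequencies
#' at the county level. The result is independent of document order and
#' of how a county's text is split across documents.
#'
#' @param documents data.frame with columns `county_id` (non-empty
#'   strings) and `text`
#' @return a [county_corpus()]
#' @export
aggregate_counts <- function(documents) {
  stopifnot(is.data.frame(documents),
            all(c("county_id", "text") %in% names(documents)))
  cid <- as.character(documents$county_id)
  if (any(is.na(cid) | cid == "")) stop("county ids must be non-empty strings")
  if (nrow(documents) == 0)
    return(county_corpus(Matrix::sparseMatrix(
      i = integer(0), j = integer(0), x = numeric(0), dims = c(0, 0),
      dimnames = list(character(0), character(0)))))
  toks <- tokenize(documents$text)
  ci <- factor(rep(cid, lengths(toks)), levels = unique(cid))
  tk <- unlist(toks, use.names = FALSE)
  if (length(tk) == 0) {
    m <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(length(unique(cid)), 0),
                              dimnames = list(unique(cid), character(0)))
    return(county_corpus(m))
  }
  tf <- factor(tk)
  m <- Matrix::sparseMatrix(i = as.integer(ci), j = as.integer(tf), x = 1,
                            dims = c(nlevels(ci), nlevels(tf)),
                            dimnames = list(levels(ci), levels(tf)))
  county_corpus(m)
}

#' Drop counties with too little text
#'
#' Retains exactly the counties whose total token count is at least
#' `threshold`. Language estimates from small samples are unstable, so
#' studies of county language impose a minimum-words filter (40,000 words
#' by default) before any scoring.
#'
#' @param corpus a [county_corpus()]
#' @param threshold minimum total words, inclusive (default 40000)
#' @return the filtered [county_corpus()] (possibly with zero counties)
#' @export
filter_min_words <- function(corpus, threshold = 40000) {
  stopifnot(inherits(corpus, "county_corpus"), threshold >= 0)
  keep <- corpus$total_words >= threshold
  out <- county_corpus(corpus$counts[keep, , drop = FALSE])
  message(sprintf("filter_min_words: %d of %d counties retained (>= %s words)",
                  sum(keep), length(keep), format(threshold, big.mark = ",")))
  out
}

#' Per-county relative token frequencies
#'
#' Converts counts to the maximum-likelihood estimate of
#' P(token | county): each county's counts divided by its total words.
#' Counties with zero words are an error (they should have been removed
#' by [filter_min_words()]).
#'
#' @param corpus a [county_corpus()]
#' @return sparse county x token matrix of probabilities; rows sum to 1
#' @export
relative_frequencies <- function(corpus) {
  stopifnot(inherits(corpus, "county_corpus"))
  if (any(corpus$total_words == 0))
    stop("county with zero words: ",
         paste(utils::head(names(which(corpus$total_words == 0)), 3),
               collapse = ", "),
         " (apply filter_min_words first)")
  corpus$counts / corpus$total_words
}

#' Read a county corpus from disk
#'
#' Two plain-text formats are supported: a counts CSV with header
#' `county_id,term,count` (one row per non-zero count), or raw text lines
#' `county_id<TAB>text` which are tokenized and aggregated.
#'
#' @param path input file
#' @param format `"counts"` (CSV) or `"text"` (tab-separated lines)
#' @return a [county_corpus()]
#' @export
read_corpus <- function(path, format = c("counts", "text")) {
  format <- match.arg(format)
  if (format == "counts") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("county_id", "term", "count")
    if (!all(need %in% names(df)))
      stop("corpus CSV must have columns county_id, term, count")
    if (any(df$count < 0) || any(df$count != round(df$count)))
      stop("counts must be non-negative integers")
    ci <- factor(as.character(df$county_id),
                 levels = unique(as.character(df$county_id)))
    ti <- factor(as.character(df$term))
    m <- Matrix::sparseMatrix(i = as.integer(ci), j = as.integer(ti),
                              x = df$count, dims = c(nlevels(ci), nlevels(ti)),
                              dimnames = list(levels(ci), levels(ti)))
    county_corpus(m)
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(lines)]
    tab <- regexpr("\t", lines, fixed = TRUE)
    if (any(tab < 0)) stop("text lines must be county_id<TAB>text")
    aggregate_counts(data.frame(
      county_id = substr(lines, 1, tab - 1),
      text = substring(lines, tab + 1),
      stringsAsFactors = FALSE))
  }
}

#' Write a county corpus as a counts CSV
#'
#' @param corpus a [county_corpus()]
#' @param path output path (`county_id,term,count` rows)
#' @return `path`, invisibly
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "county_corpus"))
  s <- Matrix::summary(corpus$counts)
  df <- data.frame(county_id = rownames(corpus$counts)[s$i],
                   term = colnames(corpus$counts)[s$j],
                   count = as.integer(s$x), stringsAsFactors = FALSE)
  df <- df[order(match(df$county_id, rownames(corpus$counts)), df$term), ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
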