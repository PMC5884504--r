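#' Emoticons recognized by the tokenizer
#'
#' The frozen emoticon inventory. Each entry is matched verbatim, before
#' any punctuation splitting, and survives tokenization unchanged (no
#' lowercasing). The list is intentionally small and fixed for
#' reproducibility; extend it only by editing this table.
#'
#' @format character vector of emoticon strings
#' @export
EMOTICONS <- c(
  "<333", "<33", "<3",
  ":-)", ":-(", ":-D", ":-P", ":-p", ";-)",
  ":)", ":(", ":D", ":P", ":p", ";)", ":/", ":'(", ":|", ":o", ":O",
  "=)", "=(", "=D",
  "xD", "XD", "D:",
  "^_^", "-_-"
)

regex_escape <- function(x) gsub("([^A-Za-z0-9_])", "\\\\\\1", x)

# alternation order matters with perl = TRUE (first listed wins):
# URLs, then emoticons (longest first, frozen above), then @-mentions,
# hashtags, words, and finally runs of other punctuation.
tokenizer_pattern <- function() {
  emo <- paste(regex_escape(EMOTICONS), collapse = "|")
  paste0(
    "https?://[^\\s]+",        # URLs kept whole
    "|www\\.[^\\s]+",
    "|", emo,                  # emoticons, verbatim
    "|@[A-Za-z0-9_]+",         # @-mentions
    "|#[A-Za-z0-9_]+",         # hashtags
    "|[A-Za-z0-9_]+(?:'[A-Za-z]+)*",  # words (apostrophe contractions)
    "|[^\\sA-Za-z0-9_]+"       # residual punctuation runs
  )
}

#' Tokenize social-media text
#'
#' A self-contained, rule-based tokenizer for short social-media
#' messages. It splits on whitespace and punctuation but keeps as single
#' tokens the constructs that carry meaning in this register: URLs,
#' @-mentions, #hashtags and a fixed inventory of emoticons
#' ([EMOTICONS]). All tokens are lowercased except emoticon glyphs
#' (hashtag and mention bodies are lowercased too); punctuation runs are
#' retained as tokens.
#'
#' @param text character vector of raw texts (arbitrary Unicode; `NA`
#'   treated as empty)
#' @return a list with one character vector of tokens per input element
#' @examples
#' tokenize("I <3 #Weed :)")[[1]]   # "i" "<3" "#weed" ":)"
#' tokenize("Drinking beer, BEER!")[[1]]
#' @export
tokenize <- function(text) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  m <- gregexpr(tokenizer_pattern(), text, perl = TRUE)
  toks <- regmatches(text, m)
  lapply(toks, function(tt) {
    if (length(tt) == 0) return(character(0))
    keep <- tt %in% EMOTICONS
    tt[!keep] <- tolower(tt[!keep])
    tt
  })
}
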