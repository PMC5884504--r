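# Small fixtures and independent oracles shared across test files.
# Oracles deliberately use naive formulations (double loops, literal
# definitions) so they stay independent of the implementation they check.

tiny_lexicon <- function() {
  w <- matrix(c(0.8, 0.4, 0.1,
                0.2, 0.6, 0.9), nrow = 3,
              dimnames = list(c("beer", "wine", "church"), c("t1", "t2")))
  topic_lexicon(w)
}

tiny_corpus <- function() {
  m <- matrix(c(2, 2, 0,
                1, 0, 3), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("beer", "wine", "church")))
  county_corpus(m)
}

random_corpus <- function(n_counties, n_tokens, seed, max_count = 9) {
  set.seed(seed)
  m <- matrix(rpois(n_counties * n_tokens, 3) %% (max_count + 1),
              n_counties, n_tokens,
              dimnames = list(sprintf("c%02d", seq_len(n_counties)),
                              sprintf("tok%02d", seq_len(n_tokens))))
  m[rowSums(m) == 0, 1] <- 1
  county_corpus(m)
}

random_normalized_lexicon <- function(terms, n_topics, seed) {
  set.seed(seed)
  w <- matrix(rgamma(length(terms) * n_topics, 1), length(terms), n_topics,
              dimnames = list(terms, sprintf("t%d", seq_len(n_topics))))
  topic_lexicon(w / rowSums(w))
}

# literal Eq-1 double loop over (county, topic, token)
oracle_scores <- function(corpus, lexicon) {
  freqs <- as.matrix(corpus$counts / corpus$total_words)
  out <- matrix(0, nrow(freqs), length(lexicon$topic_ids),
                dimnames = list(rownames(freqs), lexicon$topic_ids))
  W <- as.matrix(lexicon$weights)
  for (ci in seq_len(nrow(freqs))) {
    for (k in seq_along(lexicon$topic_ids)) {
      acc <- 0
      for (tok in colnames(freqs)) {
        if (tok %in% rownames(W)) acc <- acc + W[tok, k] * freqs[ci, tok]
      }
      out[ci, k] <- acc
    }
  }
  out
}

# literal BH step-up: adjusted p_i = min over ranks j >= rank(i) of m p_(j)/j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(o == i)
    adj[i] <- min(1, min(p[o][rank_i:m] * m / (rank_i:m)))
  }
  adj
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# standard small synthetic world reused by several files
small_world <- function(seed = 11, n = 120, ...) {
  args <- utils::modifyList(
    list(n_counties = n, n_topics = 20, vocab_size = 400,
         words_per_county = 2000, direct_topics = 1:2,
         direct_effects = c(0.4, 0.4), mediator_topics = 3:4,
         mediator_a = c(0.6, 0.5), mediator_b = c(0.5, 0.4), seed = seed),
    list(...))
  cfg <- do.call(sim_config, args)
  lex <- generate_lexicon(cfg)
  w <- generate_counties(cfg, lex)
  sc <- quiet(score_topics(relative_frequencies(
    filter_min_words(w$corpus, cfg$min_words)), lex))
  list(cfg = cfg, lex = lex, world = w, scores = sc,
       y = w$outcome$outcome,
       ses = ses_index(w$covariates$log_income, w$covariates$hs_grad))
}
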