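#' Simulation configuration
#'
#' Describes a synthetic county-language world with known planted
#' structure: an LDA-like topic-word model, county topic mixtures tied
#' to a latent socioeconomic index, and an outcome assembled from
#' covariate effects, direct topic effects and mediated topic effects.
#' Defaults give a desk-scale world (200 counties, 50 topics, 2000-word
#' vocabulary, 5000 words per county) that exercises every pipeline
#' stage in seconds; [sim_config_paper_scale()] gives the full-scale
#' variant (1384 counties, 2000 topics, 40000 words per county).
#'
#' @param n_counties number of counties N (default 200)
#' @param n_topics number of topics K (default 50)
#' @param vocab_size vocabulary size V (default 2000)
#' @param words_per_county tokens drawn per county (default 5000)
#' @param min_words word filter threshold the generated corpus is meant
#'   to pass (default `words_per_county`)
#' @param topic_word_conc Dirichlet concentration of topic-word
#'   distributions (default 0.1: sparse, LDA-like topics)
#' @param county_topic_conc per-topic Gamma shape of county topic
#'   mixtures (default 1: broad county mixtures, as expected for large
#'   aggregates of short messages)
#' @param direct_topics integer indices of topics with a direct outcome
#'   effect
#' @param direct_effects standardized outcome coefficients of
#'   `direct_topics` (default 0.3 each)
#' @param mediator_topics integer indices of true mediator topics
#' @param mediator_a per-mediator path a (SES -> topic mixture shift)
#' @param mediator_b per-mediator standardized path b (topic -> outcome)
#' @param ses_effect direct standardized effect of the latent
#'   socioeconomic index on the outcome (default 0.5)
#' @param noise_sd standard deviation of the latent outcome noise
#'   (default 1)
#' @param outcome_mean,outcome_sd affine map of the standardized latent
#'   outcome onto a prevalence-like percent scale (defaults 25 and 5)
#' @param seed integer seed; mandatory source of all randomness
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_counties = 200, n_topics = 50, vocab_size = 2000,
                       words_per_county = 5000, min_words = words_per_county,
                       topic_word_conc = 0.1, county_topic_conc = 1,
                       direct_topics = 1:5,
                       direct_effects = rep(0.3, length(direct_topics)),
                       mediator_topics = 6:7,
                       mediator_a = c(0.6, 0.5)[seq_along(mediator_topics)],
                       mediator_b = c(0.5, 0.4)[seq_along(mediator_topics)],
                       ses_effect = 0.5, noise_sd = 1,
                       outcome_mean = 25, outcome_sd = 5, seed = 42) {
  stopifnot(n_topics >= 2, vocab_size >= 2, n_counties >= 4,
            words_per_county > 0, topic_word_conc > 0,
            county_topic_conc > 0, noise_sd >= 0,
            length(direct_effects) == length(direct_topics),
            length(mediator_a) == length(mediator_topics),
            length(mediator_b) == length(mediator_topics))
  eff <- c(direct_topics, mediator_topics)
  if (length(eff) > 0 && (anyDuplicated(eff) || any(eff < 1) ||
                          any(eff > n_topics)))
    stop("sim_config: effect topic indices must be distinct and within 1..K")
  if (is.null(seed)) stop("sim_config: seed is mandatory")
  structure(list(n_counties = n_counties, n_topics = n_topics,
                 vocab_size = vocab_size,
                 words_per_county = words_per_county, min_words = min_words,
                 topic_word_conc = topic_word_conc,
                 county_topic_conc = county_topic_conc,
                 direct_topics = as.integer(direct_topics),
                 direct_effects = direct_effects,
                 mediator_topics = as.integer(mediator_topics),
                 mediator_a = mediator_a, mediator_b = mediator_b,
                 ses_effect = ses_effect, noise_sd = noise_sd,
                 outcome_mean = outcome_mean, outcome_sd = outcome_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @param ... overrides passed to [sim_config()]
#' @export
sim_config_paper_scale <- function(...) {
  sim_config(n_counties = 1384, n_topics = 2000, vocab_size = 20000,
             words_per_county = 40000, ...)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              n, k, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic topic lexicon
#'
#' Draws K topic-word distributions phi_k ~ Dirichlet(`topic_word_conc`)
#' over a V-word vocabulary and converts them to a fully normalized
#' P(topic | word) lexicon by normalizing across topics under a uniform
#' topic prior. The word-generating phi matrix is attached as attribute
#' `"phi"` (K x V) so [generate_counties()] can draw tokens from the
#' same model; real lexicons do not carry it.
#'
#' @param config a [sim_config()]
#' @return a [topic_lexicon()], fully normalized, deterministic given
#'   `config$seed`
#' @export
generate_lexicon <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    K <- config$n_topics; V <- config$vocab_size
    phi <- matrix(stats::rgamma(K * V, shape = config$topic_word_conc), K, V)
    phi <- phi / rowSums(phi)             # P(word | topic)
    ptw <- t(phi) / colSums(phi)          # P(topic | word), uniform prior
    dimnames(ptw) <- list(sprintf("w%05d", seq_len(V)),
                          sprintf("t%04d", seq_len(K)))
    dimnames(phi) <- rev(dimnames(ptw))
    lex <- topic_lexicon(ptw)
    attr(lex, "phi") <- phi
    lex
  })
}

#' Generate synthetic counties: corpus, covariates, outcome, truth
#'
#' Simulates the full data world downstream code consumes:
#'
#' 1. latent socioeconomic score `ses ~ N(0,1)` per county;
#' 2. county topic mixtures theta from per-topic Gamma weights, with
#'    each mediator topic's weight multiplied by `exp(a_k * ses)` (so
#'    mediator usage rises or falls with SES);
#' 3. `words_per_county` tokens drawn multinomially from
#'    `theta %*% phi`;
#' 4. named covariates on census-like scales, log income and
#'    high-school graduation loading strongly on the latent SES;
#' 5. latent outcome = `ses_effect * ses` + direct topic effects +
#'    mediator `b` effects (both on z-scored realized topic usage) +
#'    `N(0, noise_sd)`, mapped affinely to mean `outcome_mean`, sd
#'    `outcome_sd` percent and clipped to \[0, 100\].
#'
#' @param config a [sim_config()]
#' @param lexicon the matching [generate_lexicon()] result (must carry
#'   the `"phi"` attribute)
#' @return list with `corpus` ([county_corpus()]), `covariates`
#'   (data.frame incl. `county_id`), `outcome` (data.frame `county_id`,
#'   `outcome`), and `truth` (list: `ses`, `theta`, `topic_effects`,
#'   `mediator_a`, `mediator_b`, `ses_effect`, `latent`)
#' @export
generate_counties <- function(config, lexicon) {
  stopifnot(inherits(config, "sim_config"), inherits(lexicon, "topic_lexicon"))
  phi <- attr(lexicon, "phi")
  if (is.null(phi))
    stop("generate_counties: lexicon lacks the synthetic phi attribute; ",
         "use generate_lexicon() with the same config")
  with_seed(config$seed + 1L, {
    N <- config$n_counties; K <- config$n_topics
    ids <- sprintf("c%04d", seq_len(N))
    ses <- stats::rnorm(N)

    g <- matrix(stats::rgamma(N * K, shape = config$county_topic_conc),
                N, K)
    for (i in seq_along(config$mediator_topics)) {
      k <- config$mediator_topics[i]
      g[, k] <- g[, k] * exp(config$mediator_a[i] * ses)
    }
    theta <- g / rowSums(g)
    colnames(theta) <- lexicon$topic_ids
    rownames(theta) <- ids

    pword <- theta %*% phi               # N x V token probabilities
    counts <- t(vapply(seq_len(N), function(i) {
      drop(stats::rmultinom(1, config$words_per_county, pword[i, ]))
    }, numeric(ncol(pword))))
    dimnames(counts) <- list(ids, colnames(phi))
    corpus <- county_corpus(Matrix::drop0(Matrix::Matrix(counts, sparse = TRUE)))

    # covariates: log income / HS graduation load on latent SES
    mix <- function(load, scale_, center_) {
      z <- load * ses + sqrt(max(0, 1 - load^2)) * stats::rnorm(N)
      center_ + scale_ * z
    }
    clip <- function(v, lo = 0, hi = 100) pmin(hi, pmax(lo, v))
    age <- rdirichlet(N, c(18, 20, 40, 22)) * 100
    covariates <- data.frame(
      county_id = ids,
      percent_female = clip(mix(0.0, 2, 51)),
      percent_afam = clip(mix(-0.30, 8, 12)),
      percent_hispanic = clip(mix(-0.10, 7, 10)),
      percent_foreign_born = clip(mix(0.15, 4, 6)),
      percent_married = clip(mix(0.30, 5, 55)),
      log_income = mix(0.90, 0.25, 10.6),
      unemployment = clip(mix(-0.50, 2, 7)),
      hs_grad = clip(mix(0.90, 6, 85)),
      college_grad = clip(mix(0.70, 8, 28)),
      age_1_14 = age[, 1], age_15_29 = age[, 2],
      age_30_60 = age[, 3], age_60_up = age[, 4],
      stringsAsFactors = FALSE)

    topic_effects <- numeric(K)
    topic_effects[config$direct_topics] <- config$direct_effects
    b_effects <- numeric(K)
    b_effects[config$mediator_topics] <- config$mediator_b
    zt <- scale(theta)
    zt[, apply(theta, 2, stats::sd) == 0] <- 0
    latent <- config$ses_effect * ses +
      drop(zt %*% topic_effects) + drop(zt %*% b_effects) +
      stats::rnorm(N, sd = config$noise_sd)
    outcome_pct <- clip(config$outcome_mean +
                          config$outcome_sd * standardize(latent))
    outcome <- data.frame(county_id = ids, outcome = outcome_pct,
                          stringsAsFactors = FALSE)

    list(corpus = corpus, covariates = covariates, outcome = outcome,
         truth = list(ses = stats::setNames(ses, ids), theta = theta,
                      topic_effects = topic_effects,
                      mediator_a = stats::setNames(config$mediator_a,
                                                   lexicon$topic_ids[config$mediator_topics]),
                      mediator_b = stats::setNames(config$mediator_b,
                                                   lexicon$topic_ids[config$mediator_topics]),
                      ses_effect = config$ses_effect, latent = latent))
  })
}

#' Names of the socio-demographic control columns
#'
#' The covariate columns used as "controls" in the prediction models:
#' demographic percentages, age-bin percentages, and the socioeconomic
#' variables. Age bins are compositional (they sum to 100), so the
#' youngest bin is left out as the reference category to keep an
#' intercepted OLS design full rank.
#'
#' @param which `"demographics"`, `"socioeconomics"` or `"all"`
#' @return character vector of column names
#' @export
control_columns <- function(which = c("all", "demographics",
                                      "socioeconomics")) {
  which <- match.arg(which)
  demo <- c("percent_female", "percent_afam", "percent_hispanic",
            "percent_foreign_born", "percent_married",
            "age_15_29", "age_30_60", "age_60_up")
  socio <- c("log_income", "unemployment", "hs_grad", "college_grad")
  switch(which, demographics = demo, socioeconomics = socio,
         all = c(demo, socio))
}
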