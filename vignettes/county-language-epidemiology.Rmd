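---
title: "County-level language epidemiology with countylang"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{County-level language epidemiology with countylang}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countylang)
```

## The problem

Population health surveys measure outcomes such as excessive-drinking
prevalence at the county level, but they are slow and expensive.
Aggregate social-media language offers a cheap, continuously updated
signal: the words posted from a county correlate with, predict, and can
help *explain* county health outcomes. `countylang` implements that
analytical pipeline as reusable, tested components: topic scoring of
county corpora, cross-validated outcome prediction with and without
socio-demographic controls, differential language analysis (DLA), and a
mass mediation screen of every topic as a carrier of the
socioeconomics–outcome relationship.

Because the raw data behind such studies (geolocated tweets, survey
prevalences, census tables) cannot be redistributed, the package ships a
synthetic-world generator with planted, known effects. Every pipeline
guarantee is tested against that world or against closed-form oracles.

## The model

### Topic scoring

A *topic* is a probability distribution over words, typically estimated
by Latent Dirichlet Allocation on a large background corpus and consumed
here as a lexicon of posterior weights $P(k \mid w)$ for topic $k$ and
word $w$. Given a county's relative token frequencies
$P(w \mid c) = n_{cw} / n_{c\cdot}$, the county's usage of topic $k$ is

$$P(k \mid c) \;=\; \sum_{w} P(k \mid w)\, P(w \mid c).$$

Two conventions matter and are frozen as defaults:

* **Out-of-lexicon tokens contribute zero mass** — the sum runs over
  lexicon words only. Rows are *not* renormalized afterwards
  (`renormalize = FALSE`), so the scores follow the formula literally;
  with a fully normalized lexicon covering every corpus token each row
  sums to 1 (topic-mass conservation, asserted in the tests). An
  explicit `renormalize = TRUE` option restores unit rows under partial
  coverage.
* **Counting**: counties with fewer than 40,000 total tokens (an
  inclusive `>=` threshold, configurable) are removed before scoring;
  all tokens, including mentions, URLs and punctuation, count toward
  the total. Language estimates below this scale are too noisy to use.

The tokenizer is a self-contained rule-based approximation of the
social-media tokenizers used in this field: it preserves URLs,
@-mentions, #hashtags and a frozen emoticon inventory (`EMOTICONS`) as
single tokens, lowercases everything except emoticon glyphs, and keeps
punctuation runs as tokens. Freezing the emoticon table in one exported
constant keeps tokenization reproducible.

### Prediction

Three model shapes are cross-validated with `crossval_predict()`:

1. **Language only**: per training fold, features pass a variance floor,
   then a Bonferroni-style correlation sieve (keep if
   $p \le \alpha/m$ with a deliberately permissive default
   $\alpha = 60$), then train-only PCA retaining 99% of variance, then
   ridge regression $\beta = (X^\top X + \lambda I)^{-1} X^\top y$ with
   $\lambda = 1000$. The permissive sieve and PCA exist to control
   overfitting when features outnumber counties; $\lambda$ is exposed
   but not auto-tuned.
2. **Controls only**: plain OLS on the socio-demographic columns (no
   screening or PCA — a handful of features needs none).
3. **Combined**: OLS of the outcome on the controls per training fold,
   then the language pipeline fit on the OLS *residuals*; held-out
   predictions are the sum of both parts. The residualization keeps the
   small control block from being swamped by thousands of language
   features. The control OLS is refit inside each fold to avoid
   leakage.

Held-out predictions are scored by pooled Pearson *r* across all folds
(primary — it directly compares predictions with observed rates) and by
mean per-fold *r* (secondary), plus mean absolute error. Models are
compared by a paired t-test on per-county absolute errors.

All fold-level statistics — screening, standardization, PCA rotations,
both fits — are computed from the training fold only. The test suite
asserts the resulting guarantee directly: permuting the held-out
outcomes never changes their predictions.

### Differential language analysis

Each topic is regressed against the outcome separately, on standardized
variables, optionally with covariates (typically the socioeconomic
index) partialled out; the standardized topic coefficient is reported,
which without covariates equals the Pearson correlation. With ~2000
topics per outcome, p-values are adjusted by the Benjamini–Hochberg
step-up across all non-degenerate topics; two-sided p-values are used
since both positive and negative correlates are of interest. The
covariate-adjusted fits use the Frisch–Waugh–Lovell residualization,
which is algebraically identical to the per-topic multiple regression
but vectorizes over thousands of topics.

Word-cloud figures are replaced by `top_topics()`: a ranked table of
BH-significant topics (by |coefficient| within each sign) with each
topic's top-15 words by lexicon weight, ties broken lexicographically.
The weights and ranks are the testable content of a word cloud; imagery
is cosmetic.

### Mediation

For each topic $m$, with socioeconomic index $x$ and outcome $y$, all
standardized:

$$y = c\,x + \beta_1 + \epsilon_1, \qquad
  m = a\,x + \beta_2 + \epsilon_2, \qquad
  y = c'\,x + b\,m + \beta_3 + \epsilon_3.$$

The mediation size is $c - c'$, which for nested OLS with one mediator
equals the indirect effect $a\,b$ exactly — the identity is asserted to
1e-8 across every screen the tests run. Significance uses the classical
Sobel statistic $z = a b / \sqrt{b^2\,\mathrm{se}_a^2 +
a^2\,\mathrm{se}_b^2}$ with a normal reference, and BH correction across
all topics. Standardizing all three variables makes paths comparable
across topics and makes $c$ equal the Pearson correlation of index and
outcome. Degenerate topics (zero variance or |r(topic, x)| > 0.999) are
skipped with a warning so one bad column cannot kill a 2000-topic
screen. A bootstrap CI for $a b$ was considered and deliberately left
out: the Sobel test is the convention this pipeline mirrors, and its
conservativeness under the null is verified empirically in the
acceptance suite.

## The synthetic world

`sim_config()` describes a world; `generate_lexicon()` and
`generate_counties()` realize it deterministically from a seed:

* **Topics**: $K$ topic–word Dirichlet draws with concentration 0.1
  (sparse, LDA-like); $P(k \mid w)$ obtained by normalizing across
  topics under a uniform topic prior. The word-generating $\phi$ matrix
  travels with the synthetic lexicon as an attribute — real lexicons do
  not have it, and `generate_counties()` refuses lexicons without it.
* **Counties**: a latent standard-normal socioeconomic score per
  county; topic mixtures from per-topic Gamma(1) weights, with each
  planted mediator topic's weight multiplied by $e^{a_k \cdot ses}$;
  token counts drawn multinomially from the mixture composed with
  $\phi$.
* **Covariates** on census-like scales; log income and high-school
  graduation load 0.9 on the latent score, so the computed
  `ses_index()` recovers it almost perfectly. Age-bin percentages are
  compositional, so the default control set (`control_columns()`)
  drops the youngest bin as the reference category — keeping all four
  would make an intercepted OLS design exactly singular.
* **Outcome**: `ses_effect` (default 0.5) times the latent score, plus
  direct topic effects (default five topics at 0.3) and mediator *b*
  paths (defaults 0.5, 0.4; *a* paths 0.6, 0.5) applied to z-scored
  realized topic usage, plus unit-variance noise; the latent sum is
  mapped affinely to mean 25, sd 5 percent and clipped to [0, 100], so
  error magnitudes resemble prevalence units.

Default scale is 200 counties × 50 topics × 2000-word vocabulary ×
5000 words per county — enough for Eq-1 scores to correlate > 0.9 with
the true mixtures while the full suite stays desk-fast.
`sim_config_paper_scale()` switches to 1384 counties × 2000 topics ×
40,000 words for slow runs.

What a green test does and does not establish: the generator plants
linear, homoscedastic effects on independent counties with a single
latent socioeconomic dimension. It emulates none of the things that
make real county language hard — spatial autocorrelation, platform
demographics, topic correlation structure from a real LDA fit, survey
measurement error. Green tests establish that the machinery is correct
and calibrated, not that any particular real-world effect size is
recoverable.

## Numerical choices

* Sample (n−1) standard deviations throughout; standardization of a
  constant vector is an error rather than a silent NaN.
* Ridge solves a linear system (`solve(A, b)`) instead of forming the
  inverse; the intercept is unpenalized via centering; columns are
  standardized before penalization by default (the pipeline passes
  already-centered PCA scores with `standardize = FALSE`).
* OLS uses QR with an explicit rank check that names the collinear
  columns; standard errors come from $\hat\sigma^2 (X^\top X)^{-1}$.
* PCA component count: smallest count reaching the variance fraction,
  capped at matrix rank — a design choice of this package, since the
  studies this pipeline mirrors leave the count unstated.
* BH: step-up adjusted $p_{(i)} = \min_{j \ge i} m\,p_{(j)}/j$ capped
  at 1; the family is all non-degenerate topics for a given covariate
  configuration.
* Fold assignment is a seeded permutation, a pure function of
  `(n, k, seed)` that restores the caller's RNG state; seeds are
  mandatory in both `pipeline_config()` and `sim_config()`.
* Tie-breaks: `top_topics()` orders equal-weight words
  lexicographically; equal-|coefficient| topics by topic id.

## Known limitations

* The tokenizer is a rule-based approximation; it does not reproduce
  any specific external tokenizer token-for-token (emoji beyond the
  frozen emoticon list fall through to punctuation runs).
* Counts CSV I/O drops all-zero token columns (they carry no
  information, but exact column sets may differ after a round trip).
* The mediation screen is a screening device over marginal
  single-mediator models; it makes no joint-model or causal
  identification claims.
* λ = 1000 is a convention carried over from county-scale studies with
  ~2000 topics; at much smaller feature counts it over-shrinks and a
  smaller penalty predicts slightly better (the acceptance experiments
  use the default regardless).
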