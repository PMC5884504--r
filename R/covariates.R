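#' Standardize a numeric vector to z-scores
#'
#' Centers to mean 0 and scales to sample (n-1) standard deviation 1.
#' A constant vector has no z-scores and is an error.
#'
#' @param values numeric vector with at least 2 distinct finite values
#' @return numeric vector of z-scores
#' @export
standardize <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("standardize: non-finite values")
  s <- stats::sd(values)
  if (length(values) < 2 || s == 0)
    stop("standardize: constant input (zero variance)")
  (values - mean(values)) / s
}

#' Composite socioeconomic index
#'
#' Income and education are highly collinear at the county level, so a
#' single composite often predicts better than either alone. The index
#' is the elementwise mean of standardized log income and standardized
#' high-school graduation rate; it inherits invariance to affine
#' rescaling of either raw input.
#'
#' @param log_income numeric vector (log of median household income)
#' @param hs_grad numeric vector (high-school graduation rate, percent)
#' @return numeric vector, `(z(log_income) + z(hs_grad)) / 2`
#' @export
ses_index <- function(log_income, hs_grad) {
  if (length(log_income) != length(hs_grad))
    stop("ses_index: input lengths differ")
  (standardize(log_income) + standardize(hs_grad)) / 2
}

#' Census age-bin collapse
#'
#' Collapses fine census age-percentage bins to the four modeling bins
#' 1-14, 15-29, 30-60 and 60+ by summation. The default mapping covers
#' the 19-column census layout (5-year bins with 15-17/18-19 split and
#' an 85+ terminal bin); pass `mapping` for other layouts.
#'
#' @param covariates data.frame containing the age-bin columns
#' @param mapping named list: target column name -> character vector of
#'   source columns to sum
#' @return `covariates` with source bins removed and the four collapsed
#'   percentage columns appended
#' @export
collapse_age_bins <- function(covariates, mapping = default_age_mapping()) {
  src <- unlist(mapping, use.names = FALSE)
  missing <- setdiff(src, names(covariates))
  if (length(missing) > 0)
    stop("collapse_age_bins: missing source bins: ",
         paste(missing, collapse = ", "))
  for (target in names(mapping)) {
    covariates[[target]] <-
      rowSums(covariates[, mapping[[target]], drop = FALSE])
  }
  covariates[setdiff(names(covariates), src)]
}

#' @rdname collapse_age_bins
#' @export
default_age_mapping <- function() {
  list(
    age_1_14  = c("age_0_4", "age_5_9", "age_10_14"),
    age_15_29 = c("age_15_17", "age_18_19", "age_20_24", "age_25_29"),
    age_30_60 = c("age_30_34", "age_35_39", "age_40_44", "age_45_49",
                  "age_50_54", "age_55_59"),
    age_60_up = c("age_60_64", "age_65_69", "age_70_74", "age_75_79",
                  "age_80_84", "age_85_up")
  )
}

#' Pearson cross-correlation matrix with BH-corrected p-values
#'
#' Computes all pairwise Pearson correlations among the supplied
#' columns, two-sided p-values from the t distribution of r with n-2
#' degrees of freedom, and Benjamini-Hochberg adjusted p-values across
#' the strict upper triangle (each pair tested once).
#'
#' @param table data.frame or matrix of numeric columns over the same
#'   counties (>= 3 rows, no constant columns)
#' @return object of class `cross_correlations`: list with matrices `r`
#'   (symmetric, unit diagonal), `p`, `p_bh` (diagonal `NA`), and `n`
#' @export
cross_correlations <- function(table) {
  x <- as.matrix(table)
  if (!is.numeric(x)) stop("cross_correlations: non-numeric columns")
  n <- nrow(x)
  if (n < 3) stop("cross_correlations: need >= 3 counties")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("cross_correlations: constant column: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- stats::cor(x)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  diag(p) <- NA_real_
  up <- upper.tri(p)
  adj <- bh_adjust(p[up])$p_adj
  p_bh <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  p_bh[up] <- adj
  p_bh[lower.tri(p_bh)] <- t(p_bh)[lower.tri(p_bh)]
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  structure(list(r = r, p = p, p_bh = p_bh, n = n),
            class = "cross_correlations")
}

#' @export
print.cross_correlations <- function(x, digits = 2, ...) {
  cat(sprintf("<cross_correlations> %d variables, n = %d counties\n",
              ncol(x$r), x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' Align counties across corpus features, covariates and outcome
#'
#' County-level analyses use only counties present in every table. This
#' helper intersects county id sets in order (scores, covariates,
#' outcome), logging the count after each restriction, and returns all
#' three inputs subset to the common ids in score order.
#'
#' @param scores [topic_scores()] matrix (or any matrix with county
#'   rownames)
#' @param covariates data.frame with a `county_id` column
#' @param outcome data.frame with columns `county_id`, `outcome`
#' @return list with aligned `scores`, `covariates`, `outcome` and the
#'   common `county_ids`
#' @export
align_counties <- function(scores, covariates, outcome) {
  ids <- rownames(scores)
  message(sprintf("align_counties: %d counties with language", length(ids)))
  ids <- ids[ids %in% as.character(covariates$county_id)]
  message(sprintf("align_counties: %d after requiring covariates", length(ids)))
  ids <- ids[ids %in% as.character(outcome$county_id)]
  message(sprintf("align_counties: %d after requiring outcome", length(ids)))
  if (length(ids) == 0) stop("align_counties: no counties in common")
  cov <- covariates[match(ids, as.character(covariates$county_id)), ,
                    drop = FALSE]
  out <- outcome[match(ids, as.character(outcome$county_id)), , drop = FALSE]
  if (any(out$outcome < 0 | out$outcome > 100))
    stop("outcome prevalences must lie in [0, 100]")
  num <- vapply(cov, is.numeric, logical(1))
  if (any(vapply(cov[num], function(v) any(!is.finite(v)), logical(1))))
    stop("align_counties: missing covariate values in retained counties")
  list(scores = scores[ids, , drop = FALSE],
       covariates = cov, outcome = out, county_ids = ids)
}

#' Read covariate / outcome tables
#'
#' Thin CSV readers enforcing the `county_id` key column.
#'
#' @param path CSV path
#' @return data.frame with `county_id` as character
#' @export
read_covariates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"county_id" %in% names(df)) stop("covariates CSV needs county_id")
  df$county_id <- as.character(df$county_id)
  df
}

#' @rdname read_covariates
#' @export
read_outcome <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("county_id", "outcome") %in% names(df)))
    stop("outcome CSV needs columns county_id, outcome")
  df$county_id <- as.character(df$county_id)
  df
}
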