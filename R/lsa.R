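#' Configuration for local similarity analysis
#'
#' @param max_delay maximal index offset D between the two aligned series
#'   (default 1).
#' @param normalization series transform before scoring: `"normal_scores"`
#'   (rank-based normal quantiles, the default), `"zscore"`, or `"none"`.
#' @param n_perm Monte-Carlo permutations for the p-value (default 1000).
#' @param exact_below series length at or below which the p-value is
#'   computed by full n! enumeration instead (default 6).
#' @param alpha significance level for edge calls (default 0.05).
#' @param seed integer seed; each OTU pair gets its own stream derived
#'   from (seed, otu_a, otu_b) so results do not depend on evaluation
#'   order.
#' @return an `lsa_config` list.
#' @export
lsa_config <- function(max_delay = 1, normalization = c("normal_scores", "zscore", "none"),
                       n_perm = 1000, exact_below = 6, alpha = 0.05, seed = 1) {
  normalization <- match.arg(normalization)
  if (max_delay < 0) abort("max_delay must be >= 0")
  if (n_perm < 99) abort("n_perm must be >= 99")
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  structure(list(max_delay = as.integer(max_delay), normalization = normalization,
                 n_perm = as.integer(n_perm), exact_below = as.integer(exact_below),
                 alpha = alpha, seed = as.integer(seed)),
            class = "lsa_config")
}

#' Normalize a series before local similarity scoring
#'
#' `normal_scores` maps the value at rank r of n to the standard normal
#' quantile at r/(n+1), with ties receiving averaged ranks (an all-tied
#' series maps to all zeros); `zscore` centers and scales by the
#' population SD; `none` is the identity.
#'
#' @param x numeric vector, length >= 3.
#' @param method `"normal_scores"`, `"zscore"` or `"none"`.
#' @return numeric vector of the same length.
#' @examples
#' normalize_series(c(5, 1, 3))          # qnorm(c(3, 1, 2) / 4)
#' normalize_series(1:3, "zscore")       # population SD
#' @export
normalize_series <- function(x, method = c("normal_scores", "zscore", "none")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 3) abort("series must have length >= 3")
  switch(method,
    normal_scores = qnorm(rank(x, ties.method = "average") / (n + 1)),
    zscore = {
      s <- sqrt(mean((x - mean(x))^2))
      if (s == 0) {
        abort("constant series has zero SD; use normal_scores (ties map to 0)")
      }
      (x - mean(x)) / s
    },
    none = x
  )
}

#' Local similarity score with bounded time delay
#'
#' Dynamic program over aligned index pairs (i, j) with |i - j| <= D:
#' positive runs accumulate \eqn{x_i y_j}, negative runs accumulate
#' \eqn{-x_i y_j}, both resetting at zero (local alignment).  The score is
#' the best run sum over both tables divided by the series length; the
#' sign says which table attained it (ties go to +) and the delay is
#' j - i along the maximising run (ties broken toward the smallest
#' absolute delay, then the positive one).
#'
#' @param x,y equal-length numeric vectors (already normalized).
#' @param max_delay D, with 0 <= D < length(x).
#' @return list with `ls_score` (>= 0), `sign` (`"+"` or `"-"`), and
#'   `best_delay` (integer in \[-D, D\]).
#' @examples
#' local_similarity(c(1, -1, 1, -1), c(1, -1, 1, -1), max_delay = 0)
#' @export
local_similarity <- function(x, y, max_delay = 1) {
  if (length(x) != length(y)) abort("series lengths differ")
  r <- ls_dp_cpp(as.numeric(x), as.numeric(y), as.integer(max_delay))
  list(ls_score = r$ls_score, sign = if (r$sign > 0) "+" else "-",
       best_delay = as.integer(r$best_delay))
}

#' Permutation p-value for a local similarity score
#'
#' The p-value is the probability that a random permutation of one series
#' attains a local similarity at least as large as the observed one.  For
#' series of length at most `exact_below` every permutation is enumerated
#' (identity included, p = count / n!); otherwise `n_perm` Monte-Carlo
#' permutations are drawn and p = (count + 1)/(n_perm + 1).  The optional
#' upper bound is the conservative Bonferroni-style correction
#' min(1, p * (2D + 1)) across the delay offsets (a stand-in, not the
#' asymptotic bound of the original method).
#'
#' @param x,y equal-length normalized series.
#' @param max_delay D used for the observed score.
#' @param n_perm Monte-Carlo permutation count (>= 99).
#' @param exact_below enumeration cutoff (default 6).
#' @param seed integer seed for the Monte-Carlo draws.
#' @param upper_bound also return `p_upper` (default TRUE).
#' @return list with `p_value`, `p_upper` (or NULL), `exact` (logical),
#'   `n_perm` (permutations actually used).
#' @export
permutation_pvalue <- function(x, y, max_delay = 1, n_perm = 1000,
                               exact_below = 6, seed = 1, upper_bound = TRUE) {
  if (length(x) != length(y)) abort("series lengths differ")
  r <- ls_perm_pvalue_cpp(as.numeric(x), as.numeric(y), as.integer(max_delay),
                          as.integer(n_perm), as.integer(exact_below),
                          as.integer(seed))
  p_upper <- if (upper_bound) min(1, r$p_value * (2 * max_delay + 1)) else NULL
  list(p_value = r$p_value, p_upper = p_upper, exact = r$exact,
       n_perm = r$n_perm)
}

#' Local similarity analysis over every OTU pair of a series set
#'
#' Normalizes each OTU trajectory, scores every unordered OTU pair with
#' [local_similarity()], and attaches permutation p-values.  Results are
#' deterministic for a fixed `config$seed` and independent of pair
#' evaluation order.  A failing pair is dropped with a warning naming it;
#' it does not abort the run.
#'
#' @param series a `series_set` from [build_series()].
#' @param config an [lsa_config()].
#' @return tibble with one row per pair: `otu_a`, `otu_b`, `ls_score`,
#'   `sign`, `best_delay`, `p_value`, `p_upper`; sorted by (otu_a, otu_b);
#'   carries the treatment label as an attribute.
#' @export
all_pairs_lsa <- function(series, config = lsa_config()) {
  stopifnot(inherits(series, "series_set"), inherits(config, "lsa_config"))
  m <- series_matrix(series)
  otus <- colnames(m)
  if (anyDuplicated(otus)) {
    abort(paste0("duplicate OTU id in series set: ",
                 otus[duplicated(otus)][1]))
  }
  if (length(otus) < 2) abort("need at least 2 OTUs")
  n <- nrow(m)
  if (config$max_delay >= n) abort("max_delay must be smaller than the series length")
  otus <- sort(otus)
  norm <- vapply(otus, function(o) normalize_series(m[, o], config$normalization),
                 numeric(n))

  pairs <- utils::combn(otus, 2)
  np <- ncol(pairs)
  ls_score <- p_value <- p_upper <- numeric(np)
  sign <- character(np)
  best_delay <- integer(np)
  ok <- logical(np)
  for (k in seq_len(np)) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tryCatch({
      ls <- ls_dp_cpp(norm[, a], norm[, b], config$max_delay)
      pv <- ls_perm_pvalue_cpp(norm[, a], norm[, b], config$max_delay,
                               config$n_perm, config$exact_below,
                               pair_seed(config$seed, a, b))
      ls_score[k] <- ls$ls_score
      sign[k] <- if (ls$sign > 0) "+" else "-"
      best_delay[k] <- as.integer(ls$best_delay)
      p_value[k] <- pv$p_value
      p_upper[k] <- min(1, pv$p_value * (2 * config$max_delay + 1))
      ok[k] <- TRUE
    }, error = function(e) {
      warn(sprintf("pair (%s, %s) failed and was omitted: %s", a, b,
                   conditionMessage(e)))
    })
  }
  failed <- sum(!ok)
  out <- tibble::tibble(otu_a = pairs[1, ], otu_b = pairs[2, ],
                        ls_score = ls_score, sign = sign,
                        best_delay = best_delay, p_value = p_value,
                        p_upper = p_upper)[ok, ]
  out <- dplyr::arrange(out, .data$otu_a, .data$otu_b)
  attr(out, "treatment") <- attr(series, "treatment", exact = TRUE)
  attr(out, "n_failed") <- failed
  out
}
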