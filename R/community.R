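#' Rarefy every sample to a common depth
#'
#' Each sample's reads are subsampled without replacement to exactly
#' `depth`, equalizing sequencing effort; one draw per sample.  Samples
#' with fewer than `depth` reads are a hard error (rarefy to the observed
#' minimum to keep every sample).
#'
#' @param table abundance tibble in counts units.
#' @param depth target reads per sample; default is the observed minimum
#'   sample total.
#' @param seed integer seed for the subsampling.
#' @return rarefied count tibble; every row sums to `depth`.
#' @export
rarefy <- function(table, depth = NULL, seed = 1) {
  assert_abundance(table)
  assert_units(table, "counts", "rarefy")
  m <- otu_matrix(table)
  totals <- rowSums(m)
  if (is.null(depth)) depth <- min(totals)
  shallow <- table$sample_id[totals < depth]
  if (length(shallow) > 0) {
    abort(paste0("sample(s) below rarefaction depth ", depth, ": ",
                 paste(shallow, collapse = ", ")))
  }
  if (any(m != round(m))) abort("rarefy requires integer counts")
  # rrarefy's "observed counts" heuristic warning is redundant after the
  # integer/units validation above
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(m, depth)))
  table[otu_names(table)] <- out
  set_units(table, "counts")
}

#' Shannon diversity of one composition
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over the positive entries of the
#' normalized vector (natural log).
#'
#' @param x nonnegative vector of counts or proportions with at least one
#'   positive entry.
#' @return Shannon index (nonnegative scalar).
#' @examples
#' shannon(c(10, 10, 10, 10))  # log(4)
#' @export
shannon <- function(x) {
  if (any(x < 0) || all(x == 0)) abort("x must be nonnegative with a positive entry")
  p <- x[x > 0] / sum(x)
  -sum(p * log(p))
}

#' Per-sample Shannon diversity
#'
#' @param table abundance tibble (counts or relative).
#' @return tibble with the metadata columns and a `shannon` column.
#' @export
sample_diversity <- function(table) {
  assert_abundance(table)
  m <- otu_matrix(table)
  out <- table[meta_cols()]
  out$shannon <- apply(m, 1, shannon)
  out
}

#' Pairwise treatment comparison of Shannon diversity
#'
#' Welch two-sample t tests on the per-sample indices for every treatment
#' pair, with the percent difference of group means.
#'
#' @param table abundance tibble.
#' @return tibble: `treatment_a`, `treatment_b`, `mean_a`, `mean_b`,
#'   `pct_diff` (how much larger a's mean is than b's, in percent),
#'   `statistic`, `p.value`.
#' @export
diversity_comparison <- function(table) {
  div <- sample_diversity(table)
  trts <- unique(div$treatment)
  if (length(trts) < 2) abort("need at least two treatments")
  pairs <- utils::combn(trts, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    a <- div$shannon[div$treatment == p[1]]
    b <- div$shannon[div$treatment == p[2]]
    tt <- stats::t.test(a, b)
    tibble::tibble(treatment_a = p[1], treatment_b = p[2],
                   mean_a = mean(a), mean_b = mean(b),
                   pct_diff = 100 * (mean(a) - mean(b)) / mean(b),
                   statistic = unname(tt$statistic), p.value = tt$p.value)
  })
}

#' Bray-Curtis distance matrix between samples
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; entries lie in
#' \[0, 1\] on the simplex.
#'
#' @param table abundance tibble (relative, or consistently scaled).
#' @return a `dist_matrix`: symmetric matrix with sample ids as dimnames.
#' @export
bray_curtis <- function(table) {
  assert_abundance(table)
  m <- otu_matrix(table)
  zero <- rowSums(m) == 0
  if (sum(zero) >= 2) {
    abort(paste0("Bray-Curtis undefined for a pair of all-zero samples: ",
                 paste(table$sample_id[zero], collapse = ", ")))
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  dimnames(d) <- list(table$sample_id, table$sample_id)
  structure(d, class = c("dist_matrix", class(d)))
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers \eqn{-\tfrac12 D^2}, eigendecomposes, and places samples
#' at eigenvector times the square root of each positive eigenvalue.
#' Negative eigenvalues are dropped; percent variance explained uses
#' positive eigenvalues only.
#'
#' @param d a `dist_matrix` (or anything `as.dist` accepts) over n >= 3
#'   samples.
#' @return a `pcoa_ord` with `points` (tibble: `sample_id`, `Axis1` ...),
#'   `eigenvalues`, and `var_explained` (percent per retained axis).
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3) abort("PCoA requires at least 3 samples")
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # nonpositive ones are dropped below, so the warning is redundant here
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE))
  eig <- cs$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  pts <- cs$points[, pos, drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_along(pos))
  ids <- rownames(dm)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(
    points = dplyr::bind_cols(tibble::tibble(sample_id = ids),
                              tibble::as_tibble(pts)),
    eigenvalues = eig[pos],
    var_explained = 100 * eig[pos] / sum(eig[pos])
  ), class = "pcoa_ord")
}

#' Distance-based permutational multivariate ANOVA
#'
#' Sequential (Type I) sums-of-squares partition of a distance matrix for
#' the crossed two-factor model `~ generation * treatment` (or any terms
#' supplied), with pseudo-F per term and p-values from free permutation of
#' the sample labels: \eqn{p = (\#\{F_{perm} \ge F_{obs}\} + 1)/(n_{perm} + 1)}.
#' Computation is delegated to `vegan::adonis2`.
#'
#' @param d a `dist_matrix`, with dimnames matching `metadata$sample_id`.
#' @param metadata tibble with `sample_id` and the factor columns.
#' @param terms model terms in order, e.g. `c("generation", "treatment",
#'   "generation:treatment")`.
#' @param n_perm number of permutations (>= 99; default 999).
#' @param seed integer seed for the permutations.
#' @return a `permanova_fit`; see [tidy.permanova_fit()].
#' @export
permanova <- function(d, metadata,
                      terms = c("generation", "treatment", "generation:treatment"),
                      n_perm = 999, seed = 1) {
  if (n_perm < 99) abort("n_perm must be >= 99")
  dm <- as.matrix(d)
  ids <- rownames(dm)
  if (!is.null(ids)) {
    idx <- match(ids, metadata$sample_id)
    if (anyNA(idx)) abort("metadata does not cover every sample in the distance matrix")
    metadata <- metadata[idx, ]
  }
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in vars) {
    if (!v %in% names(metadata)) abort(paste0("metadata lacks factor column: ", v))
    if (length(unique(metadata[[v]])) < 2) {
      abort(paste0("factor '", v, "' has a single level"))
    }
    metadata[[v]] <- factor(metadata[[v]])
  }
  dd <- stats::as.dist(dm)
  form <- stats::as.formula(paste("dd ~", paste(terms, collapse = " + ")))
  fit <- with_seed(seed, vegan::adonis2(form, data = as.data.frame(metadata),
                                        permutations = n_perm, by = "terms"))
  structure(list(table = fit, n_perm = n_perm, terms = terms),
            class = "permanova_fit")
}

#' Aggregate OTUs to family level and keep the most abundant families
#'
#' OTU columns are summed by family, families are ranked by grand-mean
#' relative abundance, the `top_k` most abundant are kept and the rest are
#' pooled as `"Other"`.  OTUs absent from the taxonomy are recorded as
#' `"unclassified"`.
#'
#' @param table abundance tibble in relative units.
#' @param taxonomy tibble with columns `otu`, `family`.
#' @param top_k number of named families to keep (default 7).
#' @return tibble with metadata columns and one column per retained family
#'   (plus `Other` when pooling occurred).
#' @export
aggregate_families <- function(table, taxonomy, top_k = 7) {
  assert_abundance(table)
  assert_units(table, "relative", "aggregate_families")
  if (top_k < 1) abort("top_k must be >= 1")
  otus <- otu_names(table)
  fams <- taxon_of(otus, taxonomy, "family")
  m <- otu_matrix(table)
  agg <- t(rowsum(t(m), group = fams))
  means <- colMeans(agg)
  ranked <- names(sort(means, decreasing = TRUE))
  keep <- utils::head(ranked, top_k)
  out <- table[meta_cols()]
  for (f in keep) out[[f]] <- unname(agg[, f])
  rest <- setdiff(ranked, keep)
  if (length(rest) > 0) {
    out[["Other"]] <- unname(rowSums(agg[, rest, drop = FALSE]))
  }
  set_units(out, "relative")
}

#' Drop OTUs whose peak relative abundance is below a display threshold
#'
#' Keeps OTUs whose maximum abundance across all samples is at least
#' `max_threshold` (default 7.5%), the filter used before drawing
#' abundance heatmaps.  An OTU peaking exactly at the threshold is kept.
#'
#' @param table abundance tibble in relative units.
#' @param max_threshold fraction in (0, 1); default 0.075.
#' @return filtered abundance tibble.
#' @export
heatmap_filter <- function(table, max_threshold = 0.075) {
  filter_by_max(table, max_threshold, "heatmap_filter")
}
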