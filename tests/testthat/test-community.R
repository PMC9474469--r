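test_that("rarefaction keeps totals exact and is deterministic", {
  set.seed(4)
  tbl <- make_table(matrix(rpois(40, 60) + 10, 4, 10))
  rr <- rarefy(tbl, depth = 200, seed = 5)
  m <- as.matrix(rr[otu_names(rr)])
  expect_true(all(rowSums(m) == 200))
  expect_identical(rarefy(tbl, depth = 200, seed = 5), rr)
  # a sample already at the target depth is unchanged
  exact <- make_table(matrix(c(150, 50), 1, 2))
  expect_identical(as.matrix(rarefy(exact, 200, seed = 1)[c("OTU001", "OTU002")]),
                   as.matrix(exact[c("OTU001", "OTU002")]))
  expect_error(rarefy(tbl, depth = 10000), "below rarefaction depth")
})

test_that("rarefaction matches the hypergeometric expectation", {
  tbl <- make_table(matrix(c(900, 100), 1, 2))
  draws <- vapply(1:1000, function(s) {
    as.matrix(rarefy(tbl, 100, seed = s)[c("OTU001", "OTU002")])[1]
  }, numeric(1))
  se <- sqrt(100 * 0.9 * 0.1 * (1000 - 100) / (1000 - 1)) / sqrt(1000)
  expect_lt(abs(mean(draws) - 90), 3 * se)
})

test_that("Shannon diversity evaluates the entropy formula in nats", {
  expect_equal(shannon(c(10, 10, 10, 10)), log(4))
  expect_equal(shannon(100), 0)
  expect_equal(shannon(c(1, 2, 3, 4)), 1.2799, tolerance = 1e-4)
  # maximal at uniform, zero iff a single taxon
  set.seed(2)
  for (i in 1:10) {
    x <- runif(6)
    expect_lte(shannon(x), log(6) + 1e-12)
  }
  expect_error(shannon(c(0, 0)), "positive")
  # cross-check against the standard vegan routine
  x <- c(5, 1, 9, 3)
  expect_equal(shannon(x), unname(vegan::diversity(x)))
})

test_that("Bray-Curtis distances match the hand formula and its bounds", {
  tbl <- make_table(rbind(c(6, 2), c(2, 2), c(6, 2), c(0, 4)) / 8)
  d <- bray_curtis(tbl)
  expect_equal(unname(d["s01", "s02"]), 1 / 3)
  expect_equal(unname(d["s01", "s03"]), 0)       # identical samples
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_equal(d, t(d), ignore_attr = TRUE)
  disj <- make_table(rbind(c(1, 0), c(0, 1)))
  expect_equal(unname(bray_curtis(disj)["s01", "s02"]), 1)
  zz <- make_table(rbind(c(0, 0), c(0, 0), c(1, 1)))
  expect_error(bray_curtis(zz), "all-zero")
})

test_that("PCoA reproduces Euclidean geometry", {
  # three collinear points at 0, 1, 2: one positive eigenvalue
  dm <- as.matrix(dist(c(0, 1, 2)))
  rownames(dm) <- colnames(dm) <- c("a", "b", "c")
  ord <- pcoa(dm)
  expect_equal(length(ord$eigenvalues), 1)
  expect_equal(ord$var_explained[1], 100)
  got <- as.matrix(dist(ord$points$Axis1))
  expect_equal(unname(got), unname(dm), tolerance = 1e-9)

  # equidistant points: all positive eigenvalues equal
  dm2 <- matrix(1, 4, 4); diag(dm2) <- 0
  ord2 <- pcoa(dm2)
  expect_equal(ord2$eigenvalues, rep(ord2$eigenvalues[1], length(ord2$eigenvalues)))

  # distances from random points in R^3 are reproduced to 1e-9
  set.seed(9)
  pts <- matrix(rnorm(30), 10, 3)
  dm3 <- as.matrix(dist(pts))
  ord3 <- pcoa(dm3)
  coords <- as.matrix(ord3$points[-1])
  expect_equal(unname(as.matrix(dist(coords))), unname(dm3), tolerance = 1e-9)
  expect_error(pcoa(dm3[1:2, 1:2]), "at least 3")
})

test_that("PCoA eigenvalues are invariant to sample order", {
  set.seed(10)
  pts <- matrix(rnorm(16), 8, 2)
  dm <- as.matrix(dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:8)
  perm <- sample(8)
  a <- pcoa(dm); b <- pcoa(dm[perm, perm])
  expect_equal(a$eigenvalues, b$eigenvalues, tolerance = 1e-9)
})

test_that("PERMANOVA matches exhaustive enumeration on a tiny design", {
  set.seed(12)
  pts <- matrix(rnorm(8), 4, 2)
  dm <- as.matrix(dist(pts))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:4)
  meta <- tibble::tibble(sample_id = paste0("s", 1:4),
                         grp = c("a", "a", "b", "b"))
  exact <- permanova_p_oracle(dm, meta$grp)
  fit <- permanova(dm, meta, terms = "grp", n_perm = 2000, seed = 3)
  td <- tidy(fit)
  p_mc <- td$p.value[td$term == "grp"]
  half <- 2.58 * sqrt(exact * (1 - exact) / 2000) + 1 / 2000
  expect_lt(abs(p_mc - exact), half + 1e-9)
  # pseudo-F itself agrees with the oracle
  expect_equal(td$statistic[td$term == "grp"],
               permanova_f_oracle(dm, meta$grp), tolerance = 1e-9)
})

test_that("PERMANOVA attains the minimal p on perfectly separated duplicate groups", {
  base <- rbind(matrix(0, 6, 2), matrix(5, 6, 2))
  dm <- as.matrix(dist(base))
  rownames(dm) <- colnames(dm) <- paste0("s", 1:12)
  meta <- tibble::tibble(sample_id = paste0("s", 1:12),
                         grp = rep(c("a", "b"), each = 6))
  fit <- permanova(dm, meta, terms = "grp", n_perm = 999, seed = 1)
  td <- tidy(fit)
  # only the ~2/choose(12,6) relabelings preserving the split tie the
  # observed separation, so p sits at (or within noise of) the floor
  expect_lte(td$p.value[td$term == "grp"], 0.02)
  expect_gte(td$p.value[td$term == "grp"], 1 / 1000)
  meta_one <- dplyr::mutate(meta, grp = "a")
  expect_error(permanova(dm, meta_one, terms = "grp"), "single level")
})

test_that("PERMANOVA dfs partition n - 1 for the crossed design", {
  sim <- simulate_dataset(small_sim_config(seed = 13))
  rel <- to_relative(sim$table)
  d <- bray_curtis(rel)
  fit <- permanova(d, rel[c("sample_id", "treatment", "generation",
                            "replicate")], n_perm = 99, seed = 1)
  td <- tidy(fit)
  expect_equal(sum(td$df[td$term != "Total"]), nrow(rel) - 1)
  expect_true(all(td$p.value >= 1 / 100, na.rm = TRUE))
})

test_that("family aggregation ranks by grand mean and pools the rest", {
  m <- matrix(c(0.5, 0.3, 0.1, 0.06, 0.04,
                0.4, 0.4, 0.1, 0.05, 0.05), 2, 5, byrow = TRUE)
  tbl <- make_table(m)
  tax <- tibble::tibble(otu = sprintf("OTU%03d", 1:4),
                        family = c("F1", "F1", "F2", "F3"))
  agg <- aggregate_families(tbl, tax, top_k = 2)
  fams <- setdiff(names(agg), c("sample_id", "treatment", "generation",
                                "replicate"))
  # F1 (mean .80) and unclassified OTU005 (.045) vs F2 (.10), F3 (.055):
  # ranking is F1 > F2 > F3 > unclassified
  expect_identical(fams, c("F1", "F2", "Other"))
  expect_equal(agg$F1, c(0.8, 0.8))
  expect_equal(agg$Other, c(0.2, 0.2) - agg$F2)
  # top_k covering every family leaves no pool
  agg_all <- aggregate_families(tbl, tax, top_k = 10)
  expect_false("Other" %in% names(agg_all))
  one <- aggregate_families(tbl, tibble::tibble(
    otu = sprintf("OTU%03d", 1:5), family = "F"), top_k = 3)
  expect_equal(one$F, rowSums(m))
  expect_error(aggregate_families(tbl, tax, top_k = 0), "top_k")
})

test_that("the heatmap filter drops peaks strictly below the threshold", {
  m <- rbind(c(0.074, 0.075, 0.851), c(0.05, 0.07, 0.88))
  tbl <- make_table(m)
  kept <- heatmap_filter(tbl, 0.075)
  expect_identical(otu_names(kept), c("OTU002", "OTU003"))
  all_kept <- heatmap_filter(tbl, 1e-6)
  expect_equal(length(otu_names(all_kept)), 3)
})
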