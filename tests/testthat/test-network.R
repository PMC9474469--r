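test_that("edges are called by the p <= alpha rule with isolated nodes retained", {
  nodes <- sprintf("OTU%03d", 1:6)
  res <- fake_results(c(0.001, 0.02, 0.2), otus = nodes)
  g <- build_network(res, nodes, alpha = 0.05)
  expect_equal(igraph::vcount(g), 6)
  expect_equal(igraph::ecount(g), 2)
  # alpha below every p: edgeless but fully populated node set
  g0 <- build_network(res, nodes, alpha = 1e-6)
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 6)
  # alpha = 1: every evaluated pair becomes an edge
  g1 <- build_network(res, nodes, alpha = 1)
  expect_equal(igraph::ecount(g1), 3)
  expect_error(build_network(res, nodes[1:2], alpha = 0.05), "outside the node set")
})

test_that("the literal inverted edge rule is available but not default", {
  nodes <- sprintf("OTU%03d", 1:4)
  res <- fake_results(c(0.001, 0.4), otus = nodes)
  g <- build_network(res, nodes, alpha = 0.5, rule = "inverted")
  # p_upper = 3 * p: edges where 3p > 0.5 -> only the 0.4 pair
  expect_equal(igraph::ecount(g), 1)
})

test_that("the alpha scan is monotone in alpha and sorted", {
  nodes <- sprintf("OTU%03d", 1:10)
  set.seed(6)
  res <- list(high = fake_results(runif(30), otus = nodes),
              control = fake_results(runif(30), otus = nodes))
  scan <- alpha_scan(res, nodes, c(0.2, 0.01, 0.05))
  expect_equal(scan$alpha, rep(c(0.01, 0.05, 0.2), each = 2))
  for (trt in names(res)) {
    dd <- scan$density[scan$treatment == trt]
    expect_true(all(diff(dd) >= 0))
  }
  one <- alpha_scan(res["high"], nodes, c(0.01, 0.1))
  expect_equal(nrow(one), 2)
  expect_error(alpha_scan(res, nodes, numeric(0)), "empty")
})

test_that("degree histograms count every node including isolated ones", {
  nodes <- letters[1:5]
  cg <- fake_results(rep(0.001, 10), otus = nodes)
  g <- build_network(cg, nodes, alpha = 0.05)
  h <- degree_histogram(g)
  expect_equal(h$n_nodes[h$degree == 4], 5)
  g0 <- build_network(cg, nodes, alpha = 1e-9)
  h0 <- degree_histogram(g0)
  expect_equal(h0, tibble::tibble(degree = 0L, n_nodes = 5L))
  # star on 6 nodes
  star <- tibble::tibble(otu_a = "hub", otu_b = paste0("leaf", 1:5),
                         ls_score = 1, sign = "+", best_delay = 0L,
                         p_value = 0.001, p_upper = 0.003)
  gs <- build_network(star, c("hub", paste0("leaf", 1:5)), alpha = 0.05)
  hs <- degree_histogram(gs)
  expect_equal(hs$n_nodes[hs$degree == 5], 1)
  expect_equal(hs$n_nodes[hs$degree == 1], 5)
  expect_equal(degree_tail_count(gs, 4), 1)
  expect_equal(degree_tail_count(gs, 12), 0)
})

test_that("module detection recovers disjoint triangles with Q = 0.5", {
  g <- two_triangles()
  part <- detect_modules(g)
  expect_equal(part$modularity, 0.5, tolerance = 1e-12)
  mem <- part$membership
  expect_equal(length(unique(mem$module)), 2)
  expect_equal(length(unique(mem$module[mem$otu %in% c("a", "b", "c")])), 1)
  # the returned Q beats the all-in-one partition (Q = 0)
  gg <- g; class(gg) <- "igraph"
  expect_gte(part$modularity,
             igraph::modularity(gg, rep(1, 6)))
})

test_that("a complete graph has no community structure", {
  nodes <- letters[1:5]
  g <- build_network(fake_results(rep(0.001, 10), otus = nodes), nodes, 0.05)
  part <- detect_modules(g)
  gg <- g; class(gg) <- "igraph"
  expect_equal(igraph::modularity(gg, rep(1, 5)), 0)
  expect_lte(abs(part$modularity), 0.1)
  g0 <- build_network(fake_results(0.9, otus = nodes), nodes, 0.05)
  expect_error(detect_modules(g0), "edgeless")
})

test_that("largest modules are selected by size with annotations", {
  g <- two_triangles()
  part <- detect_modules(g)
  top <- largest_modules(part, g, k = 2)
  expect_equal(nrow(top), 2)
  expect_setequal(unlist(top$otus), letters[1:6])
  expect_equal(top$within_edges, c(3, 3))
  one <- largest_modules(part, g, k = 1)
  expect_equal(one$size, 3)
  expect_error(largest_modules(part, g, k = 5), "exceeds")
})

test_that("global properties reproduce closed-form values", {
  nodes <- letters[1:5]
  cg <- build_network(fake_results(rep(0.001, 10), otus = nodes), nodes, 0.05)
  gp <- global_properties(cg)
  expect_equal(gp$density, 1)
  expect_equal(gp$avg_path_length, 1)
  expect_equal(gp$n_excluded_pairs, 0L)

  # path graph a-b-c-d: distances 1,2,3,1,2,1
  ed <- tibble::tibble(otu_a = c("a", "b", "c"), otu_b = c("b", "c", "d"),
                       ls_score = 1, sign = "+", best_delay = 0L,
                       p_value = 0.001, p_upper = 0.003)
  p4 <- build_network(ed, letters[1:4], alpha = 0.05)
  gp4 <- global_properties(p4)
  expect_equal(gp4$density, 0.5)
  expect_equal(gp4$avg_path_length, 10 / 6)

  gt <- global_properties(two_triangles())
  expect_equal(gt$density, 6 / 15)
  expect_equal(gt$avg_path_length, 1)
  expect_equal(gt$n_excluded_pairs, 9L)
})

test_that("graph metrics agree with an independent BFS implementation", {
  set.seed(14)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    npair <- choose(n, 2)
    p <- ifelse(runif(npair) < 0.15, 0.001, 0.9)
    res <- fake_results(p, otus = nodes)
    g <- build_network(res, nodes, alpha = 0.05)
    gp <- global_properties(g)
    el <- tidy(g)
    oracle <- graph_metrics_oracle(nodes, el[c("otu_a", "otu_b")])
    expect_equal(gp$density, oracle$density, tolerance = 1e-12)
    expect_equal(gp$n_edges, oracle$n_edges)
    expect_equal(gp$n_excluded_pairs, as.integer(oracle$n_excluded_pairs))
    if (!is.na(oracle$avg_path_length)) {
      expect_equal(gp$avg_path_length, oracle$avg_path_length,
                   tolerance = 1e-12)
    }
  }
})

test_that("exclusive edge counts partition each network's edge set", {
  nodes <- letters[1:4]
  mk <- function(pairs) {
    ed <- tibble::tibble(otu_a = substr(pairs, 1, 1),
                         otu_b = substr(pairs, 2, 2),
                         ls_score = 1, sign = "+", best_delay = 0L,
                         p_value = 0.001, p_upper = 0.003)
    build_network(ed, nodes, alpha = 0.05)
  }
  a <- mk(c("ab", "bc"))
  b <- mk(c("bc", "cd"))
  expect_equal(exclusive_edges(a, b), 1)
  expect_equal(exclusive_edges(a, a), 0)
  empty <- mk(character(0))
  expect_equal(exclusive_edges(a, empty), 2)
  cmp <- compare_networks(list(a = a, b = b))
  ex <- cmp$exclusive
  expect_equal(ex$exclusive_edges[ex$from == "a" & ex$to == "b"] +
                 ex$shared_edges[ex$from == "a" & ex$to == "b"],
               igraph::ecount(a))
  other <- build_network(fake_results(0.001, otus = c("x", "y")),
                         c("x", "y"), 0.05)
  expect_error(exclusive_edges(a, other), "node set")
})

test_that("networks round-trip through GraphML and edge-list exports", {
  td <- withr::local_tempdir()
  g <- two_triangles()
  gml <- file.path(td, "g.graphml"); el <- file.path(td, "g.tsv")
  write_network(g, gml, el)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(back), 6)
  expect_equal(igraph::ecount(back), 6)
  tsv <- readr::read_tsv(el, show_col_types = FALSE)
  expect_equal(nrow(tsv), 6)
  expect_true(all(c("otu_a", "otu_b", "p_value") %in% names(tsv)))
})
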