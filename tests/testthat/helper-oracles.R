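# Independent oracles used to check the fast implementations.

# Brute-force local similarity: enumerate every pair of equal-length
# contiguous runs at a fixed offset |d| <= D and score both orientations.
ls_oracle <- function(x, y, D) {
  n <- length(x)
  best <- 0
  for (d in -D:D) {
    for (i in seq_len(n)) {
      j <- i + d
      if (j < 1 || j > n) next
      s <- 0
      len <- n - max(i, j) + 1
      for (k in 0:(len - 1)) {
        s <- s + x[i + k] * y[j + k]
        best <- max(best, s, -s)
      }
    }
  }
  best / n
}

# all permutations of 1..n (no dependency on external packages)
perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perms(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    out <- rbind(out, cbind(i, ifelse(sub >= i, sub + 1L, sub)))
  }
  unname(out)
}

# exact permutation p-value by full enumeration (identity included)
ls_perm_oracle <- function(x, y, D) {
  obs <- ls_oracle(x, y, D)
  pm <- perms(length(y))
  hits <- sum(apply(pm, 1, function(ix) ls_oracle(x, y[ix], D) >= obs - 1e-9))
  hits / nrow(pm)
}

# one-factor PERMANOVA pseudo-F from a distance matrix (for the
# enumeration oracle); groups is a factor vector
permanova_f_oracle <- function(dm, groups) {
  n <- nrow(dm)
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_among <- ss_total - ss_within
  a <- length(unique(groups))
  (ss_among / (a - 1)) / (ss_within / (n - a))
}

# exact one-factor PERMANOVA p-value by enumerating all relabelings
permanova_p_oracle <- function(dm, groups) {
  f_obs <- permanova_f_oracle(dm, groups)
  pm <- perms(length(groups))
  fs <- apply(pm, 1, function(ix) permanova_f_oracle(dm, groups[ix]))
  mean(fs >= f_obs - 1e-12)
}

# hand-rolled graph metrics (independent of igraph) from an edge list on a
# fixed node set: density, average path length over connected pairs (BFS)
graph_metrics_oracle <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[[1]][k]; b <- edges[[2]][k]
      adj[a, b] <- adj[b, a] <- TRUE
    }
  }
  m <- sum(adj) / 2
  dens <- if (n < 2) NA_real_ else 2 * m / (n * (n - 1))
  tot <- 0; cnt <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & is.na(dist))
      dist[nb] <- dist[v] + 1L
      queue <- c(queue, nb)
    }
    reach <- which(!is.na(dist) & dist > 0)
    tot <- tot + sum(dist[reach]); cnt <- cnt + length(reach)
  }
  apl <- if (cnt > 0) tot / cnt else NA_real_
  list(density = dens, avg_path_length = apl, n_edges = m,
       n_excluded_pairs = choose(n, 2) - cnt / 2)
}

# small abundance tibble from a count matrix (one treatment unless given)
make_table <- function(counts, treatment = "high",
                       generation = NULL, replicate = NULL) {
  n <- nrow(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("OTU%03d", seq_len(ncol(counts)))
  }
  tbl <- dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      treatment = rep_len(treatment, n),
      generation = if (is.null(generation)) rep(1L, n) else as.integer(generation),
      replicate = if (is.null(replicate)) seq_len(n) else as.integer(replicate)
    ),
    tibble::as_tibble(counts)
  )
  attr(tbl, "units") <- if (all(abs(rowSums(counts) - 1) < 1e-9)) "relative" else "counts"
  tbl
}

# tiny deterministic config for pipeline tests
small_sim_config <- function(seed = 1, ...) {
  sim_config(
    n_otus = 24, n_generations = 5, n_replicates = 3, depth = 400,
    planted_pairs = tibble::tibble(
      otu_a = c("OTU001", "OTU003"), otu_b = c("OTU002", "OTU004"),
      rho = c(0.95, -0.95), lag = c(0L, 1L)),
    planted_modules = list(list(otus = sprintf("OTU%03d", 5:9), rho = 0.9)),
    seed = seed, ...
  )
}

# shared graph fixtures built in code
fake_results <- function(p_values, otus = NULL) {
  n_pairs <- length(p_values)
  if (is.null(otus)) {
    # enough OTUs for the requested number of pairs
    k <- ceiling((1 + sqrt(1 + 8 * n_pairs)) / 2)
    otus <- sprintf("OTU%03d", seq_len(k))
  }
  pairs <- utils::combn(otus, 2)[, seq_len(n_pairs), drop = FALSE]
  tibble::tibble(otu_a = pairs[1, ], otu_b = pairs[2, ],
                 ls_score = 0.5, sign = "+", best_delay = 0L,
                 p_value = p_values,
                 p_upper = pmin(1, p_values * 3))
}

two_triangles <- function() {
  ed <- tibble::tibble(otu_a = c("a", "a", "b", "d", "d", "e"),
                       otu_b = c("b", "c", "c", "e", "f", "f"),
                       ls_score = 1, sign = "+", best_delay = 0L,
                       p_value = 0.001, p_upper = 0.003)
  build_network(ed, letters[1:6], alpha = 0.05)
}

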