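#' Build a co-occurrence network from pairwise LSA results
#'
#' Nodes are the shared filtered OTU set (isolated nodes retained, so
#' densities are comparable across treatments); an edge joins a pair when
#' its permutation p-value passes the significance level.  The default
#' rule is edge iff p <= alpha.  `rule = "inverted"` instead draws an edge
#' when the p-value upper bound exceeds alpha — a literal reading of the
#' source protocol kept behind a flag, never default.
#'
#' @param results LSA result tibble ([all_pairs_lsa()]).
#' @param nodes character vector: the shared node set.
#' @param alpha significance level.
#' @param treatment optional treatment label stored on the graph (defaults
#'   to the label carried by `results`).
#' @param taxonomy optional taxonomy tibble; adds a `taxon` node attribute.
#' @param rule `"standard"` (p <= alpha) or `"inverted"` (p_upper > alpha).
#' @return a `co_network` (an igraph with `treatment` and `alpha` graph
#'   attributes; edges carry `ls_score`, `sign`, `delay`, `p_value`).
#' @export
build_network <- function(results, nodes, alpha = 0.05, treatment = NULL,
                          taxonomy = NULL, rule = c("standard", "inverted")) {
  rule <- match.arg(rule)
  stray <- setdiff(unique(c(results$otu_a, results$otu_b)), nodes)
  if (length(stray) > 0) {
    abort(paste0("result references OTU(s) outside the node set: ",
                 paste(stray, collapse = ", ")))
  }
  keep <- if (rule == "standard") results$p_value <= alpha
          else results$p_upper > alpha
  ed <- results[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = ed$otu_a, to = ed$otu_b,
                   ls_score = ed$ls_score, sign = ed$sign,
                   delay = ed$best_delay, p_value = ed$p_value),
    directed = FALSE,
    vertices = data.frame(name = sort(nodes))
  )
  if (!is.null(taxonomy)) {
    igraph::V(g)$taxon <- taxon_of(igraph::V(g)$name, taxonomy)
  }
  if (is.null(treatment)) treatment <- attr(results, "treatment", exact = TRUE)
  g <- igraph::set_graph_attr(g, "treatment", treatment %||% NA_character_)
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  class(g) <- c("co_network", class(g))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Network density across a range of significance levels
#'
#' Rebuilds each treatment's network at every alpha and tabulates edge
#' count and density — the robustness scan showing whether the density
#' ordering of the treatments is stable in the threshold.
#'
#' @param results_by_treatment named list of LSA result tibbles.
#' @param nodes shared node set.
#' @param alphas numeric vector of significance levels (>= 2 for a scan).
#' @return `alpha_scan` tibble: `treatment`, `alpha`, `n_edges`,
#'   `density`, sorted by alpha.
#' @export
alpha_scan <- function(results_by_treatment, nodes, alphas) {
  if (length(alphas) < 1) abort("empty alpha list")
  stopifnot(!is.null(names(results_by_treatment)))
  out <- purrr::map_dfr(names(results_by_treatment), function(trt) {
    res <- results_by_treatment[[trt]]
    purrr::map_dfr(alphas, function(a) {
      g <- build_network(res, nodes, alpha = a, treatment = trt)
      tibble::tibble(treatment = trt, alpha = a,
                     n_edges = igraph::ecount(g),
                     density = igraph::edge_density(g))
    })
  })
  out <- dplyr::arrange(out, .data$alpha, .data$treatment)
  class(out) <- c("alpha_scan", class(out))
  out
}

#' Degree histogram of a network
#'
#' Exact node-degree counts, including degree-0 nodes.
#'
#' @param g a `co_network`.
#' @return tibble `degree`, `n_nodes` covering every degree from 0 to the
#'   maximum observed.
#' @export
degree_histogram <- function(g) {
  deg <- igraph::degree(g)
  tab <- table(factor(deg, levels = 0:max(deg, 0)))
  tibble::tibble(degree = as.integer(names(tab)), n_nodes = as.integer(tab))
}

#' Number of nodes with degree above a cutoff
#'
#' @param g a `co_network`.
#' @param k degree cutoff; nodes with degree > k are counted.
#' @return integer count.
#' @export
degree_tail_count <- function(g, k) {
  sum(igraph::degree(g) > k)
}

#' Detect modules by modularity maximization
#'
#' Partitions the nodes to (heuristically) maximize Newman-Girvan
#' modularity \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)}.  `"greedy"` is
#' fast-greedy agglomeration (deterministic); `"louvain"` is multilevel
#' optimization (seeded).  Isolated nodes become singleton modules.
#'
#' @param g a `co_network` with at least one edge.
#' @param method `"greedy"` (default) or `"louvain"`.
#' @param seed integer seed (used by louvain).
#' @return a `module_partition`: list with `membership` tibble (`otu`,
#'   `module`), `modularity` (Q of the returned partition), `sizes`,
#'   `method`.
#' @export
detect_modules <- function(g, method = c("greedy", "louvain"), seed = 1) {
  method <- match.arg(method)
  if (igraph::ecount(g) == 0) {
    abort("modularity Q is undefined on an edgeless graph (no edges to partition)")
  }
  gg <- g
  class(gg) <- "igraph"
  comm <- with_seed(seed, switch(method,
    greedy = igraph::cluster_fast_greedy(gg),
    louvain = igraph::cluster_louvain(gg)
  ))
  mem <- igraph::membership(comm)
  q <- igraph::modularity(gg, mem)
  structure(list(
    membership = tibble::tibble(otu = names(mem), module = as.integer(mem)),
    modularity = q,
    sizes = sort(table(as.integer(mem)), decreasing = TRUE),
    method = method,
    treatment = igraph::graph_attr(g, "treatment")
  ), class = "module_partition")
}

#' The k largest modules with their taxon composition
#'
#' @param partition a `module_partition` over `g`'s nodes.
#' @param g the `co_network` the partition was computed on.
#' @param k number of modules to return (ties in size broken by module id).
#' @return tibble with one row per module: `module`, `size`,
#'   `within_edges`, plus list-columns `otus` and `taxa`.
#' @export
largest_modules <- function(partition, g, k = 2) {
  mem <- partition$membership
  sizes <- dplyr::count(mem, .data$module, name = "size")
  if (k > nrow(sizes)) {
    abort(sprintf("k = %d exceeds the number of modules (%d)", k, nrow(sizes)))
  }
  sizes <- dplyr::arrange(sizes, dplyr::desc(.data$size), .data$module)
  top <- utils::head(sizes, k)
  has_taxon <- "taxon" %in% igraph::vertex_attr_names(g)
  purrr::map_dfr(seq_len(nrow(top)), function(i) {
    mod <- top$module[i]
    members <- mem$otu[mem$module == mod]
    sub <- igraph::induced_subgraph(g, members)
    tibble::tibble(
      module = mod, size = top$size[i],
      within_edges = igraph::ecount(sub),
      otus = list(members),
      taxa = list(if (has_taxon) igraph::V(sub)$taxon
                  else rep("unclassified", length(members)))
    )
  })
}

#' Global properties of one network
#'
#' Density is \eqn{2|E| / (|V|(|V|-1))} over the full node set (isolated
#' nodes included).  Average path length is the mean shortest-path length
#' over connected, distinct node pairs; unreachable pairs are excluded and
#' their count reported.
#'
#' @param g a `co_network` with at least 2 nodes.
#' @return one-row tibble: `treatment`, `n_nodes`, `n_edges`, `density`,
#'   `avg_path_length`, `n_excluded_pairs`.
#' @export
global_properties <- function(g) {
  nv <- igraph::vcount(g)
  if (nv < 2) abort("network must have at least 2 nodes")
  comp <- igraph::components(g)
  connected_pairs <- sum(choose(comp$csize, 2))
  total_pairs <- choose(nv, 2)
  apl <- if (connected_pairs > 0) {
    igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  } else NA_real_
  tibble::tibble(
    treatment = igraph::graph_attr(g, "treatment") %||% NA_character_,
    n_nodes = nv,
    n_edges = igraph::ecount(g),
    density = igraph::edge_density(g),
    avg_path_length = apl,
    n_excluded_pairs = as.integer(total_pairs - connected_pairs)
  )
}

# canonical edge keys of a network (presence only; sign/score ignored)
edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g)
  pair_key(el[, 1], el[, 2])
}

#' Edges exclusive to one network
#'
#' Counts edges present in `a` but absent from `b`; both networks must
#' share the node set.  Edge identity is by endpoint pair only.
#'
#' @param a,b `co_network`s on the same node set.
#' @return integer count.
#' @export
exclusive_edges <- function(a, b) {
  if (!setequal(igraph::V(a)$name, igraph::V(b)$name)) {
    abort("networks must share the same node set")
  }
  length(setdiff(edge_keys(a), edge_keys(b)))
}

#' Compare global properties across treatment networks
#'
#' Tabulates density, average path length and total edges per network,
#' and the exclusive-edge count for every ordered network pair.
#'
#' @param networks named list of `co_network`s on a shared node set.
#' @return a `network_comparison`: list of two tibbles, `properties`
#'   (per network) and `exclusive` (`from`, `to`, `exclusive_edges`,
#'   `shared_edges`).
#' @export
compare_networks <- function(networks) {
  stopifnot(length(networks) >= 2, !is.null(names(networks)))
  props <- purrr::map_dfr(names(networks), function(nm) {
    dplyr::mutate(global_properties(networks[[nm]]), treatment = nm)
  })
  combs <- expand.grid(from = names(networks), to = names(networks),
                       stringsAsFactors = FALSE)
  combs <- combs[combs$from != combs$to, ]
  excl <- purrr::map_dfr(seq_len(nrow(combs)), function(i) {
    a <- networks[[combs$from[i]]]; b <- networks[[combs$to[i]]]
    ka <- edge_keys(a); kb <- edge_keys(b)
    tibble::tibble(from = combs$from[i], to = combs$to[i],
                   exclusive_edges = length(setdiff(ka, kb)),
                   shared_edges = length(intersect(ka, kb)))
  })
  structure(list(properties = props, exclusive = excl),
            class = "network_comparison")
}

#' Write a network as GraphML and as an edge-list TSV
#'
#' @param g a `co_network`.
#' @param graphml_path,edgelist_path output paths (either may be NULL to
#'   skip).
#' @return `g`, invisibly.
#' @export
write_network <- function(g, graphml_path = NULL, edgelist_path = NULL) {
  gg <- g
  class(gg) <- "igraph"
  if (!is.null(graphml_path)) {
    igraph::write_graph(gg, graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    el <- igraph::as_data_frame(gg, what = "edges")
    names(el)[1:2] <- c("otu_a", "otu_b")
    readr::write_tsv(tibble::as_tibble(el), edgelist_path)
  }
  invisible(g)
}
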