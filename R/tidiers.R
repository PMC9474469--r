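#' Tidy a PCoA ordination
#'
#' @param x a `pcoa_ord`.
#' @param ... unused.
#' @return tibble of sample coordinates (`sample_id`, `Axis1`, ...).
#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) x$points

#' One-row summary of a PCoA ordination
#'
#' @param x a `pcoa_ord`.
#' @param ... unused.
#' @return tibble with `n_axes`, `var_axis1`, `var_axis2` (percent),
#'   `var_first_two`.
#' @method glance pcoa_ord
#' @export
glance.pcoa_ord <- function(x, ...) {
  ve <- x$var_explained
  tibble::tibble(n_axes = length(ve),
                 var_axis1 = ve[1],
                 var_axis2 = if (length(ve) >= 2) ve[2] else NA_real_,
                 var_first_two = sum(ve[seq_len(min(2, length(ve)))]))
}

#' Tidy a PERMANOVA fit
#'
#' @param x a `permanova_fit`.
#' @param ... unused.
#' @return broom-style tibble: `term`, `df`, `sum_of_squares`, `r_squared`,
#'   `statistic` (pseudo-F), `p.value`.
#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) {
  tab <- as.data.frame(x$table)
  tibble::tibble(term = rownames(tab), df = tab$Df,
                 sum_of_squares = tab$SumOfSqs, r_squared = tab$R2,
                 statistic = tab$F, p.value = tab$`Pr(>F)`)
}

#' One-row summary of a PERMANOVA fit
#'
#' @param x a `permanova_fit`.
#' @param ... unused.
#' @return tibble with `n_terms`, `n_perm`, `min_p`.
#' @method glance permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  td <- tidy(x)
  td <- td[!td$term %in% c("Residual", "Total"), ]
  tibble::tibble(n_terms = nrow(td), n_perm = x$n_perm,
                 min_p = min(td$p.value, na.rm = TRUE))
}

#' Tidy a module partition
#'
#' @param x a `module_partition`.
#' @param ... unused.
#' @return membership tibble (`otu`, `module`).
#' @method tidy module_partition
#' @export
tidy.module_partition <- function(x, ...) x$membership

#' One-row summary of a module partition
#'
#' @param x a `module_partition`.
#' @param ... unused.
#' @return tibble with `modularity`, `n_modules`, `largest_module`,
#'   `method`.
#' @method glance module_partition
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(modularity = x$modularity, n_modules = length(x$sizes),
                 largest_module = as.integer(x$sizes[1]), method = x$method)
}

#' Tidy a co-occurrence network into its edge list
#'
#' @param x a `co_network`.
#' @param ... unused.
#' @return tibble: `otu_a`, `otu_b`, `ls_score`, `sign`, `delay`,
#'   `p_value`.
#' @method tidy co_network
#' @export
tidy.co_network <- function(x, ...) {
  gg <- x
  class(gg) <- "igraph"
  el <- igraph::as_data_frame(gg, what = "edges")
  if (nrow(el) == 0) {
    return(tibble::tibble(otu_a = character(), otu_b = character(),
                          ls_score = numeric(), sign = character(),
                          delay = integer(), p_value = numeric()))
  }
  names(el)[1:2] <- c("otu_a", "otu_b")
  tibble::as_tibble(el)
}

#' One-row summary of a co-occurrence network
#'
#' @param x a `co_network`.
#' @param ... unused.
#' @return the [global_properties()] tibble.
#' @method glance co_network
#' @export
glance.co_network <- function(x, ...) global_properties(x)

#' Tidy a network comparison
#'
#' @param x a `network_comparison`.
#' @param which `"properties"` (default) or `"exclusive"`.
#' @param ... unused.
#' @return the requested tibble.
#' @method tidy network_comparison
#' @export
tidy.network_comparison <- function(x, which = c("properties", "exclusive"), ...) {
  x[[match.arg(which)]]
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("PCoA over %d samples; %d positive axes; first two explain %.1f%%\n",
              nrow(x$points), length(x$eigenvalues),
              sum(x$var_explained[seq_len(min(2, length(x$var_explained)))])))
  invisible(x)
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA (%d permutations)\n", x$n_perm))
  print(as.data.frame(x$table))
  invisible(x)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("%s modularity partition: Q = %.3f, %d modules (largest %d)\n",
              x$method, x$modularity, length(x$sizes), as.integer(x$sizes[1])))
  invisible(x)
}

#' @export
print.network_comparison <- function(x, ...) {
  cat("Network comparison\n")
  print(x$properties)
  cat("\nExclusive edges (ordered pairs)\n")
  print(x$exclusive)
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("sim_config: %d OTUs, %d treatments x %d generations x %d replicates, depth %d\n",
              x$n_otus, length(x$treatments), x$n_generations,
              x$n_replicates, x$depth))
  cat(sprintf("  planted: %d pairs, %d modules; seed %d\n",
              nrow(x$planted_pairs), length(x$planted_modules), x$seed))
  invisible(x)
}

#' Plot a PCoA ordination
#'
#' @param object a `pcoa_ord`.
#' @param metadata optional tibble with `sample_id` plus grouping columns;
#'   when given, points are coloured by `colour` and shaped by `shape`.
#' @param colour,shape metadata column names (defaults `"generation"` and
#'   `"treatment"`).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pcoa_ord
#' @export
autoplot.pcoa_ord <- function(object, metadata = NULL, colour = "generation",
                              shape = "treatment", ...) {
  pts <- object$points
  ve <- object$var_explained
  p <- if (!is.null(metadata)) {
    pts <- dplyr::left_join(pts, metadata, by = "sample_id")
    ggplot2::ggplot(pts, ggplot2::aes(.data$Axis1, .data$Axis2,
                                      colour = .data[[colour]],
                                      shape = factor(.data[[shape]])))
  } else {
    ggplot2::ggplot(pts, ggplot2::aes(.data$Axis1, .data$Axis2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = sprintf("Axis 1 (%.1f%%)", ve[1]),
                  y = sprintf("Axis 2 (%.1f%%)", ve[2]),
                  shape = shape) +
    ggplot2::theme_minimal()
}

#' Plot an alpha-robustness scan
#'
#' Density per treatment against the significance threshold, on a log-x
#' scale.
#'
#' @param object an `alpha_scan` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot alpha_scan
#' @export
autoplot.alpha_scan <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$alpha, .data$density,
                                       colour = .data$treatment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "significance level", y = "network density") +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network
#'
#' Fruchterman-Reingold layout with node size proportional to degree and
#' edge colour by association sign.
#'
#' @param object a `co_network`.
#' @param seed layout seed.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot co_network
#' @export
autoplot.co_network <- function(object, seed = 1, ...) {
  gg <- object
  class(gg) <- "igraph"
  lay <- with_seed(seed, igraph::layout_with_fr(gg))
  nodes <- tibble::tibble(otu = igraph::V(gg)$name,
                          x = lay[, 1], y = lay[, 2],
                          degree = igraph::degree(gg))
  el <- tidy.co_network(object)
  p <- ggplot2::ggplot()
  if (nrow(el) > 0) {
    idx_a <- match(el$otu_a, nodes$otu)
    idx_b <- match(el$otu_b, nodes$otu)
    seg <- tibble::tibble(x = nodes$x[idx_a], y = nodes$y[idx_a],
                          xend = nodes$x[idx_b], yend = nodes$y[idx_b],
                          sign = el$sign)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign),
      alpha = 0.5)
  }
  p + ggplot2::geom_point(
        data = nodes,
        ggplot2::aes(x = .data$x, y = .data$y, size = .data$degree)) +
    ggplot2::scale_size_continuous(range = c(0.5, 4)) +
    ggplot2::theme_void() +
    ggplot2::labs(title = igraph::graph_attr(gg, "treatment"))
}

#' Plot a network comparison
#'
#' Bar panels of density, average path length and total edges per
#' treatment network.
#'
#' @param object a `network_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot network_comparison
#' @export
autoplot.network_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$properties[c("treatment", "density", "avg_path_length", "n_edges")],
    cols = -"treatment", names_to = "property", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$treatment, .data$value,
                                     fill = .data$treatment)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~property, scales = "free_y") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}
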