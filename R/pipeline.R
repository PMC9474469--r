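#' Configuration for a full pipeline run
#'
#' Exactly one of `table` (an abundance tibble already in memory, counts
#' units, or a path pair via `table_path`/`metadata_path`) and `sim`
#' (a [sim_config()] for a synthetic run) must be supplied.
#'
#' @param sim optional [sim_config()] for a synthetic run.
#' @param table optional abundance tibble (counts units).
#' @param table_path,metadata_path optional TSV paths read with
#'   [read_abundance()].
#' @param taxonomy optional taxonomy tibble.
#' @param lsa an [lsa_config()]; its `alpha` is the edge-call level.
#' @param alphas significance levels for the robustness scan
#'   (default 0.005, 0.01, 0.05).
#' @param rarefy_depth rarefaction depth; NULL (default) uses the observed
#'   minimum sample total.
#' @param node_filter max-abundance threshold defining the shared node set
#'   (default 0.01).
#' @param heatmap_threshold max-abundance threshold of the display filter
#'   (default 0.075).
#' @param seed integer seed for every stage of the run.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = NULL, table = NULL, table_path = NULL,
                       metadata_path = NULL, taxonomy = NULL,
                       lsa = lsa_config(), alphas = c(0.005, 0.01, 0.05),
                       rarefy_depth = NULL, node_filter = 0.01,
                       heatmap_threshold = 0.075, seed = 1) {
  has_table <- !is.null(table) || !is.null(table_path)
  if (has_table == !is.null(sim)) {
    abort("supply exactly one of: an input table, or a sim_config")
  }
  if (!is.null(table_path) && is.null(metadata_path)) {
    abort("metadata_path is required with table_path")
  }
  if (node_filter <= 0 || node_filter >= 1 ||
      heatmap_threshold <= 0 || heatmap_threshold >= 1) {
    abort("filter thresholds must lie in (0, 1)")
  }
  structure(list(sim = sim, table = table, table_path = table_path,
                 metadata_path = metadata_path, taxonomy = taxonomy,
                 lsa = lsa, alphas = alphas, rarefy_depth = rarefy_depth,
                 node_filter = node_filter,
                 heatmap_threshold = heatmap_threshold,
                 seed = as.integer(seed)),
            class = "run_config")
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full co-occurrence pipeline
#'
#' Executes simulate (or read) -> rarefy -> relative abundances -> shared
#' node filter -> per-treatment series -> all-pairs LSA -> networks at the
#' configured alpha -> module detection -> network comparison -> alpha
#' scan -> diversity, Bray-Curtis, PCoA and PERMANOVA, writing every
#' intermediate and final table under `out_dir` and returning a manifest
#' of output checksums.  Identical config and seed give identical
#' checksums.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage log lines (default FALSE).
#' @return (invisibly) a list: `manifest` tibble (`file`, `md5`),
#'   `networks`, `lsa_results`, `comparison`, `recovery` (NULL for
#'   non-synthetic runs), `node_set`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(out_dir, ...)
  failed_marker <- pth("FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 failed_marker)
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  truth <- NULL
  table <- run_stage("input", {
    if (!is.null(config$sim)) {
      sim <- simulate_dataset(config$sim)
      truth <- sim$truth
      readr::write_tsv(truth$true_edges, pth("truth_edges.tsv"))
      readr::write_tsv(truth$true_modules, pth("truth_modules.tsv"))
      sim$table
    } else if (!is.null(config$table)) {
      config$table
    } else {
      read_abundance(config$table_path, config$metadata_path)
    }
  })
  stage_log(quiet, "input: %d samples x %d OTUs", nrow(table),
            length(otu_names(table)))
  write_abundance(table, pth("otu_table.tsv"), pth("metadata.tsv"))

  rare <- run_stage("rarefy",
                    rarefy(table, depth = config$rarefy_depth,
                           seed = config$seed))
  rel <- run_stage("relative", to_relative(rare))

  filtered <- run_stage("node_filter",
                        filter_prevalent_otus(rel, config$node_filter))
  nodes <- otu_names(filtered)
  stage_log(quiet, "node filter at %.3g: %d of %d OTUs retained",
            config$node_filter, length(nodes), length(otu_names(table)))

  treatments <- unique(table$treatment)
  lsa_results <- list()
  networks <- list()
  for (trt in treatments) {
    res <- run_stage(paste0("lsa:", trt), {
      ss <- build_series(filtered, trt)
      all_pairs_lsa(ss, config$lsa)
    })
    readr::write_tsv(res, pth(sprintf("lsa_%s.tsv", trt)))
    g <- run_stage(paste0("network:", trt),
                   build_network(res, nodes, alpha = config$lsa$alpha,
                                 treatment = trt, taxonomy = config$taxonomy))
    write_network(g, pth(sprintf("network_%s.graphml", trt)),
                  pth(sprintf("edges_%s.tsv", trt)))
    stage_log(quiet, "%s: %d pairs scored, %d edges at alpha = %g",
              trt, nrow(res), igraph::ecount(g), config$lsa$alpha)
    lsa_results[[trt]] <- res
    networks[[trt]] <- g
  }

  partitions <- run_stage("modules", purrr::map(networks, function(g) {
    if (igraph::ecount(g) == 0) NULL
    else detect_modules(g, seed = config$seed)
  }))
  mod_tbl <- purrr::map_dfr(names(partitions), function(trt) {
    p <- partitions[[trt]]
    if (is.null(p)) return(tibble::tibble())
    tibble::tibble(treatment = trt, modularity = p$modularity,
                   n_modules = length(p$sizes),
                   largest = as.integer(p$sizes[1]))
  })
  readr::write_tsv(mod_tbl, pth("modularity.tsv"))

  comparison <- run_stage("comparison", compare_networks(networks))
  readr::write_tsv(comparison$properties, pth("network_properties.tsv"))
  readr::write_tsv(comparison$exclusive, pth("exclusive_edges.tsv"))

  scan <- run_stage("alpha_scan", alpha_scan(lsa_results, nodes, config$alphas))
  readr::write_tsv(scan, pth("alpha_scan.tsv"))

  div <- run_stage("diversity", sample_diversity(rel))
  readr::write_tsv(div, pth("diversity.tsv"))
  if (length(treatments) >= 2) {
    readr::write_tsv(diversity_comparison(rel), pth("diversity_comparison.tsv"))
  }

  d <- run_stage("bray_curtis", bray_curtis(rel))
  ord <- run_stage("pcoa", pcoa(d))
  readr::write_tsv(tidy(ord), pth("pcoa_coordinates.tsv"))
  readr::write_tsv(glance(ord), pth("pcoa_summary.tsv"))
  perm <- run_stage("permanova",
                    permanova(d, rel[meta_cols()], n_perm = 999,
                              seed = config$seed))
  readr::write_tsv(tidy(perm), pth("permanova.tsv"))

  recovery <- NULL
  if (!is.null(truth)) {
    recovery <- run_stage("recovery",
                          recovery_report(lsa_results, truth,
                                          alpha = config$lsa$alpha))
    readr::write_tsv(recovery, pth("recovery.tsv"))
  }

  files <- sort(list.files(out_dir, full.names = TRUE, recursive = TRUE))
  files <- files[!basename(files) %in% "manifest.tsv"]
  manifest <- tibble::tibble(file = basename(files),
                             md5 = unname(tools::md5sum(files)))
  manifest <- dplyr::bind_rows(manifest, tibble::tibble(
    file = "<config>", md5 = unname(config_hash(config))))
  readr::write_tsv(manifest, pth("manifest.tsv"))
  stage_log(quiet, "wrote %d output files to %s", nrow(manifest) - 1, out_dir)

  invisible(list(manifest = manifest, networks = networks,
                 lsa_results = lsa_results, comparison = comparison,
                 modularity = mod_tbl, scan = scan,
                 recovery = recovery, node_set = nodes))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(config, digits.d = 15)), tmp)
  tools::md5sum(tmp)
}

#' Score detected edges against planted ground truth
#'
#' For each treatment's LSA result table, compares the edges called at
#' `alpha` with the generator's planted pairs: recall (detected planted /
#' planted), precision (detected planted / all detected) and sign accuracy
#' on the recovered planted edges.  An empty truth gives recall NA; no
#' calls give precision NA.
#'
#' @param results_by_treatment named list of LSA result tibbles.
#' @param truth a `ground_truth` from [simulate_dataset()].
#' @param alpha significance level for edge calls.
#' @return tibble: `treatment`, `n_planted`, `n_called`, `n_recovered`,
#'   `recall`, `precision`, `sign_accuracy`.
#' @export
recovery_report <- function(results_by_treatment, truth, alpha = 0.05) {
  stopifnot(inherits(truth, "ground_truth"), !is.null(names(results_by_treatment)))
  te <- truth$true_edges
  true_keys <- if (nrow(te) > 0) pair_key(te$otu_a, te$otu_b) else character(0)
  true_sign <- stats::setNames(te$sign, true_keys)
  purrr::map_dfr(names(results_by_treatment), function(trt) {
    res <- results_by_treatment[[trt]]
    res_otus <- unique(c(res$otu_a, res$otu_b))
    truth_otus <- unique(c(te$otu_a, te$otu_b))
    missing_ids <- setdiff(truth_otus, res_otus)
    if (length(missing_ids) > 0) {
      warn(paste0("planted OTU(s) absent from '", trt, "' results (counted as misses): ",
                  paste(missing_ids, collapse = ", ")))
    }
    called <- res[res$p_value <= alpha, , drop = FALSE]
    called_keys <- pair_key(called$otu_a, called$otu_b)
    hits <- intersect(called_keys, true_keys)
    n_called <- nrow(called)
    recall <- if (length(true_keys) == 0) NA_real_
              else length(hits) / length(true_keys)
    precision <- if (n_called == 0) NA_real_ else length(hits) / n_called
    sign_acc <- if (length(hits) == 0) NA_real_ else {
      got <- stats::setNames(called$sign, called_keys)[hits]
      mean(got == true_sign[hits])
    }
    tibble::tibble(treatment = trt, n_planted = length(true_keys),
                   n_called = n_called, n_recovered = length(hits),
                   recall = recall, precision = precision,
                   sign_accuracy = sign_acc)
  })
}
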