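#' Read an abundance table and its sample metadata
#'
#' The table TSV has one row per sample (first column `sample_id`, one
#' numeric column per OTU); set `otus_in_rows = TRUE` to transpose a table
#' stored with OTUs in rows.  The metadata TSV must have columns
#' `sample_id`, `treatment`, `generation`, `replicate` covering every
#' sample.  Row and column order are preserved from the table file.
#'
#' @param table_path path to the abundance TSV.
#' @param metadata_path path to the metadata TSV.
#' @param otus_in_rows transpose the table on load (default FALSE).
#' @param units `"counts"` (default) or `"relative"`.
#' @return abundance tibble (metadata columns then OTU columns).
#' @export
read_abundance <- function(table_path, metadata_path, otus_in_rows = FALSE,
                           units = c("counts", "relative")) {
  units <- match.arg(units)
  raw <- readr::read_tsv(table_path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (otus_in_rows) {
    otu_id <- raw[[1]]
    vals <- raw[-1]
    raw <- tibble::as_tibble(cbind(
      tibble::tibble(sample_id = names(vals)),
      stats::setNames(as.data.frame(t(as.matrix(vals))), otu_id)
    ))
  }
  names(raw)[1] <- "sample_id"
  otus <- setdiff(names(raw), "sample_id")
  # strict numeric parse with coordinates on failure
  for (oc in otus) {
    v <- suppressWarnings(as.numeric(raw[[oc]]))
    bad <- which(is.na(v) & !is.na(raw[[oc]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric cell at sample '%s', OTU '%s': '%s'",
                    raw$sample_id[bad[1]], oc, raw[[oc]][bad[1]]))
    }
    if (anyNA(v)) {
      abort(sprintf("missing abundance at sample '%s', OTU '%s'",
                    raw$sample_id[which(is.na(v))[1]], oc))
    }
    raw[[oc]] <- v
  }
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE)
  need <- meta_cols()
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  orphans <- setdiff(raw$sample_id, meta$sample_id)
  if (length(orphans) > 0) {
    abort(paste0("metadata has no row for sample(s): ",
                 paste(orphans, collapse = ", ")))
  }
  out <- dplyr::left_join(raw, meta[need], by = "sample_id")
  out <- dplyr::relocate(out, dplyr::all_of(need))
  out$generation <- as.integer(out$generation)
  out$replicate <- as.integer(out$replicate)
  out <- set_units(out, units)
  assert_abundance(out)
  out
}

#' Write an abundance table and metadata as TSV
#'
#' Inverse of [read_abundance()]: the abundance matrix (with `sample_id`)
#' goes to `table_path` and the four metadata columns to `metadata_path`.
#'
#' @param table abundance tibble.
#' @param table_path,metadata_path output paths.
#' @return `table`, invisibly.
#' @export
write_abundance <- function(table, table_path, metadata_path) {
  assert_abundance(table)
  readr::write_tsv(table[c("sample_id", otu_names(table))], table_path)
  readr::write_tsv(table[meta_cols()], metadata_path)
  invisible(table)
}

#' Convert counts to relative abundances
#'
#' Divides each sample's counts by its total so rows sum to one.
#'
#' @param table abundance tibble in counts units.
#' @return abundance tibble in relative units.
#' @export
to_relative <- function(table) {
  assert_abundance(table)
  assert_units(table, "counts", "to_relative")
  m <- otu_matrix(table)
  rs <- rowSums(m)
  if (any(rs <= 0)) {
    abort(paste0("zero-sum sample(s): ",
                 paste(table$sample_id[rs <= 0], collapse = ", ")))
  }
  table[otu_names(table)] <- m / rs
  set_units(table, "relative")
}

#' Keep OTUs whose maximum relative abundance reaches a threshold
#'
#' The co-occurrence analysis restricts the node set to OTUs that reach at
#' least `threshold` relative abundance in at least one sample — across
#' *all* samples of all treatments jointly, so every treatment's network is
#' built on one shared node set.  An OTU at exactly the threshold is kept.
#'
#' @param table abundance tibble in relative units.
#' @param threshold fraction in (0, 1); default 0.01.
#' @return filtered abundance tibble (same samples, fewer OTU columns).
#' @export
filter_prevalent_otus <- function(table, threshold = 0.01) {
  filter_by_max(table, threshold, "filter_prevalent_otus")
}

filter_by_max <- function(table, threshold, caller) {
  assert_abundance(table)
  assert_units(table, "relative", caller)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    abort(paste0(caller, "(): threshold must lie strictly inside (0, 1)"))
  }
  m <- otu_matrix(table)
  keep <- otu_names(table)[apply(m, 2, max) >= threshold]
  out <- table[c(meta_cols(), keep)]
  set_units(out, "relative")
}

#' Summarize a treatment's replicated series into per-OTU trajectories
#'
#' For one treatment, collapses the replicates at each generation to their
#' mean, giving one trajectory per OTU over the generations present
#' (ascending).  This replicate summarization is what extends plain local
#' similarity analysis to replicated designs.
#'
#' @param table abundance tibble in relative units.
#' @param treatment treatment label to extract.
#' @param summarizer only `"mean"` is supported.
#' @return a `series_set`: long tibble with columns `otu`, `generation`,
#'   `value`, `n_replicates`, carrying the treatment label as an attribute.
#' @export
build_series <- function(table, treatment, summarizer = "mean") {
  assert_abundance(table)
  assert_units(table, "relative", "build_series")
  summarizer <- match.arg(summarizer, "mean")
  if (!treatment %in% unique(table$treatment)) {
    abort(paste0("unknown treatment label: ", treatment))
  }
  all_gens <- sort(unique(table$generation))
  sub <- dplyr::filter(table, .data$treatment == !!treatment)
  have <- sort(unique(sub$generation))
  missing_gens <- setdiff(all_gens, have)
  if (length(missing_gens) > 0) {
    abort(paste0("unbalanced panel: generation(s) ",
                 paste(missing_gens, collapse = ", "),
                 " absent for treatment '", treatment, "'"))
  }
  if (length(have) < 2) abort("at least 2 generations required")
  long <- tidyr::pivot_longer(sub, cols = dplyr::all_of(otu_names(table)),
                              names_to = "otu", values_to = "abundance")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$otu, .data$generation),
    value = mean(.data$abundance),
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$otu, .data$generation)
  structure(out, class = c("series_set", class(out)),
            treatment = treatment, generations = have)
}

# series_set -> generations x OTU matrix
series_matrix <- function(series) {
  wide <- tidyr::pivot_wider(series[c("otu", "generation", "value")],
                             names_from = "otu", values_from = "value")
  wide <- dplyr::arrange(wide, .data$generation)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$generation
  m
}

#' Read an OTU-to-taxon map
#'
#' TSV with columns `otu` and at least one rank column (e.g. `family`,
#' `phylum`).  OTUs missing from the file are later reported as
#' `"unclassified"` rather than raising an error.
#'
#' @param path taxonomy TSV path.
#' @return taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  tax <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"otu" %in% names(tax)) abort("taxonomy file must have an 'otu' column")
  tax
}

# family (or other rank) lookup with "unclassified" fallback
taxon_of <- function(otus, taxonomy, rank = "family") {
  if (is.null(taxonomy) || !rank %in% names(taxonomy)) {
    return(rep("unclassified", length(otus)))
  }
  idx <- match(otus, taxonomy$otu)
  out <- taxonomy[[rank]][idx]
  out[is.na(out)] <- "unclassified"
  out
}
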