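# End-to-end orchestration: per-stratum filtering, correlation, FDR,
# threshold optimization, network construction, metrics, modules, keystones
# and exports, with a manifest recording every stage.

#' Pipeline configuration
#'
#' @param min_reads per-sample depth filter (default 10,000).
#' @param min_mean_rel_abund per-taxon mean relative-abundance filter,
#'   applied separately within each stratum (default 0.001).
#' @param alpha adjusted-p significance gate for edges (default 0.01).
#' @param positive_only keep only positive correlations (default TRUE).
#' @param grid threshold-scan grid (default 0.50-0.90 by 0.01).
#' @param fallback threshold used when the scan does not converge (0.70).
#' @param keystone [keystone_criteria()] for the combined networks.
#' @param min_samples minimum samples per stratum (default 4).
#' @param top_k_phyla chord-matrix size (default 10).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_reads = 10000, min_mean_rel_abund = 0.001,
                            alpha = 0.01, positive_only = TRUE,
                            grid = seq(0.50, 0.90, by = 0.01),
                            fallback = 0.70,
                            keystone = keystone_criteria(),
                            min_samples = 4L, top_k_phyla = 10L) {
  structure(list(min_reads = min_reads,
                 min_mean_rel_abund = min_mean_rel_abund,
                 alpha = alpha, positive_only = positive_only, grid = grid,
                 fallback = fallback, keystone = keystone,
                 min_samples = min_samples, top_k_phyla = top_k_phyla),
            class = "pipeline_config")
}

#' Default strata: combined per fertilization plus group x fertilization
#'
#' Two combined strata (all samples per fertilization level; these are the
#' ones keystone-filtered) and six domestication-group strata.
#'
#' @return list of stratum descriptors (`label`, `fertilization`,
#'   `domestication` (NA for combined), `combined`).
#' @export
default_strata <- function() {
  out <- list(
    list(label = "unfertilized_all", fertilization = "unfertilized",
         domestication = NA_character_, combined = TRUE),
    list(label = "fertilized_all", fertilization = "fertilized",
         domestication = NA_character_, combined = TRUE))
  for (f in c("unfertilized", "fertilized"))
    for (d in c("wild", "traditional", "modern"))
      out[[length(out) + 1L]] <-
        list(label = paste(f, d, sep = "_"), fertilization = f,
             domestication = d, combined = FALSE)
  out
}

#' Run the full co-occurrence pipeline
#'
#' For every stratum: subset samples, apply depth and abundance filters,
#' compute all-pairs Spearman correlations with BH adjustment, select the
#' correlation threshold by the RMT scan, build the network (both gates:
#' `|rho| >= threshold` and `p_adj < alpha`), compute node metrics, detect
#' modules, summarize, and tabulate phylum shares. Combined strata are
#' additionally keystone-filtered (and functionally classified when a
#' gene-presence table is supplied). Strata that fall below `min_samples`
#' after filtering are skipped with a warning.
#'
#' @param abundance an `abundance_table` covering all samples.
#' @param taxonomy taxonomy data frame (see [read_taxonomy()]).
#' @param metadata sample metadata (see [sample_metadata()]).
#' @param gene_presence optional taxon x EC matrix for functional
#'   classification of keystones.
#' @param config a [pipeline_config()].
#' @param strata stratum descriptors; defaults to [default_strata()].
#' @param out_dir optional directory; when given, all per-stratum tables,
#'   GEXF files and a manifest JSON are written there.
#' @return a `pipeline_result`: list with `strata` (per-stratum results),
#'   `manifest` (data frame of per-stage counts) and `config`.
#' @export
run_pipeline <- function(abundance, taxonomy, metadata, gene_presence = NULL,
                         config = pipeline_config(), strata = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(abundance, "abundance_table"))
  metadata <- sample_metadata(metadata)
  if (is.null(strata)) strata <- default_strata()
  results <- list()
  manifest <- list()
  for (st in strata) {
    res <- tryCatch(
      run_stratum(abundance, taxonomy, metadata, gene_presence, config, st),
      error = function(e) {
        warning(sprintf("stratum '%s' skipped: %s", st$label,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(res)) next
    results[[st$label]] <- res
    manifest[[st$label]] <- res$manifest
  }
  manifest_df <- do.call(rbind, lapply(manifest, as.data.frame))
  rownames(manifest_df) <- NULL
  out <- structure(list(strata = results, manifest = manifest_df,
                        config = config), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

run_stratum <- function(abundance, taxonomy, metadata, gene_presence,
                        config, st) {
  ids <- metadata$sample_id[as.character(metadata$fertilization) == st$fertilization]
  if (!is.na(st$domestication))
    ids <- intersect(ids, metadata$sample_id[
      as.character(metadata$domestication) == st$domestication])
  ids <- intersect(rownames(abundance), ids)
  if (length(ids) < config$min_samples)
    stop(sprintf("only %d samples (< %d)", length(ids), config$min_samples))
  sub <- abundance_table(unclass(abundance)[ids, , drop = FALSE])
  n_samples_raw <- nrow(sub); n_taxa_raw <- ncol(sub)
  sub <- filter_samples(sub, config$min_reads)
  if (nrow(sub) < config$min_samples)
    stop(sprintf("only %d samples pass the depth filter", nrow(sub)))
  sub <- filter_taxa(sub, config$min_mean_rel_abund)
  rel_means <- colMeans(to_relative(sub))
  cs <- adjust_fdr(spearman_all_pairs(sub))
  scan <- optimize_threshold(cs, grid = config$grid, fallback = config$fallback)
  g <- build_network(cs, threshold = scan$selected, alpha = config$alpha,
                     positive_only = config$positive_only,
                     taxonomy = taxonomy, mean_rel_abund = rel_means)
  partition <- fast_greedy_modules(g)
  metrics <- node_metrics(g, partition)
  summary <- summarize_network(g, partition)
  shares <- phylum_shares(g)
  chord <- chord_matrix(g, top_k = config$top_k_phyla)
  keystones <- NULL; functions <- NULL; abund_by_group <- NULL
  if (isTRUE(st$combined)) {
    keystones <- identify_keystones(metrics, config$keystone)
    if (!is.null(gene_presence) && nrow(keystones))
      functions <- classify_functions(keystones$taxon, gene_presence)
    if (nrow(keystones)) {
      abund_by_group <- tryCatch(
        keystone_abundance_by_group(sub, metadata, keystones$taxon),
        error = function(e) NULL)
    }
  }
  list(label = st$label, stratum = st, abundance = sub,
       correlations = cs, scan = scan, network = g, partition = partition,
       metrics = metrics, summary = summary, phylum_shares = shares,
       chord = chord, keystones = keystones, functions = functions,
       keystone_abundance = abund_by_group,
       manifest = list(
         label = st$label, n_samples_raw = n_samples_raw,
         n_samples = nrow(sub), n_taxa_raw = n_taxa_raw, n_taxa = ncol(sub),
         n_pairs = nrow(cs),
         n_significant = sum(cs$p_adj < config$alpha),
         threshold = scan$selected, threshold_converged = scan$converged,
         n_nodes = summary$n_nodes, n_edges = summary$n_edges,
         average_weighted_degree = summary$average_weighted_degree,
         clustering_coefficient = summary$clustering_coefficient,
         modularity = summary$modularity, n_modules = summary$n_modules,
         n_keystones = if (isTRUE(st$combined)) {
           if (is.null(keystones)) 0L else nrow(keystones)
         } else NA_integer_))
}

#' Write all pipeline outputs to a directory
#'
#' Per stratum: node metrics, partition, threshold scan, correlation table,
#' chord matrix (TSV), summary (JSON), network (GEXF) and, for combined
#' strata, the keystone report; plus a run manifest JSON.
#'
#' @param result a `pipeline_result`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (res in result$strata) {
    pre <- file.path(out_dir, res$label)
    write_tsv(res$metrics, paste0(pre, "_metrics.tsv"))
    write_partition(res$partition, paste0(pre, "_modules.tsv"))
    write_threshold_scan(res$scan, paste0(pre, "_threshold_scan.tsv"))
    write_correlations(res$correlations, paste0(pre, "_correlations.tsv.gz"))
    write_phylum_matrix(res$chord, paste0(pre, "_chord.tsv"))
    jsonlite::write_json(unclass(res$summary), paste0(pre, "_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    export_gexf(res$network, paste0(pre, ".gexf"), res$partition)
    if (!is.null(res$keystones)) {
      ks <- as.data.frame(res$keystones)
      if (!is.null(res$functions))
        ks$categories <- vapply(res$functions[ks$taxon], paste,
                                character(1), collapse = ";")
      write_tsv(ks, paste0(pre, "_keystones.tsv"))
    }
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d strata\n", length(x$strata)))
  if (!is.null(x$manifest))
    print(x$manifest[, c("label", "n_samples", "n_taxa", "threshold",
                         "n_nodes", "n_edges", "modularity")])
  invisible(x)
}
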