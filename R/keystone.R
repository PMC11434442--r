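# Keystone taxon identification and functional-category classification.
#
# Keystones follow the five-criterion centrality filter of Qiu et al.:
# high degree, weighted degree, closeness and clustering with low
# betweenness marks taxa that are disproportionately influential.

#' Keystone selection criteria
#'
#' All five comparisons are strict, in the directions listed; a node whose
#' metric sits exactly on a threshold is not a keystone.
#'
#' @param min_degree degree must exceed this (default 6).
#' @param min_weighted_degree weighted degree must exceed this (default 6).
#' @param min_closeness closeness centrality must exceed this (default 0.14).
#' @param min_clustering local clustering must exceed this (default 0.09).
#' @param max_betweenness betweenness must be below this (default 0.05).
#' @return a `keystone_criteria` list.
#' @export
keystone_criteria <- function(min_degree = 6, min_weighted_degree = 6,
                              min_closeness = 0.14, min_clustering = 0.09,
                              max_betweenness = 0.05) {
  vals <- c(min_degree, min_weighted_degree, min_closeness, min_clustering,
            max_betweenness)
  stopifnot(all(is.finite(vals)))
  structure(list(min_degree = min_degree,
                 min_weighted_degree = min_weighted_degree,
                 min_closeness = min_closeness,
                 min_clustering = min_clustering,
                 max_betweenness = max_betweenness),
            class = "keystone_criteria")
}

#' Identify keystone taxa from node metrics
#'
#' @param metrics data frame from [node_metrics()] with columns `taxon`,
#'   `degree`, `weighted_degree`, `closeness`, `betweenness`, `clustering`.
#' @param criteria a [keystone_criteria()].
#' @return the rows of `metrics` whose nodes satisfy all five strict
#'   inequalities, with a `keystone` report class.
#' @export
identify_keystones <- function(metrics, criteria = keystone_criteria()) {
  stopifnot(is.data.frame(metrics), inherits(criteria, "keystone_criteria"))
  need <- c("taxon", "degree", "weighted_degree", "closeness", "betweenness",
            "clustering")
  miss <- setdiff(need, names(metrics))
  if (length(miss)) stop("missing metric column(s): ", paste(miss, collapse = ", "))
  for (col in need[-1L]) {
    if (anyNA(metrics[[col]]))
      stop(sprintf("missing %s for node(s): %s", col,
                   paste(metrics$taxon[is.na(metrics[[col]])], collapse = ", ")))
  }
  pass <- metrics$degree > criteria$min_degree &
    metrics$weighted_degree > criteria$min_weighted_degree &
    metrics$closeness > criteria$min_closeness &
    metrics$clustering > criteria$min_clustering &
    metrics$betweenness < criteria$max_betweenness
  out <- metrics[pass, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("keystone_report", "data.frame"))
}

#' Default functional-category catalog
#'
#' Nine soil-function categories, each defined by one or more marker enzymes
#' (EC numbers). A taxon belongs to a category if it carries at least one of
#' the category's enzymes. The C/N-cycling marker
#' (N-acetyl-beta-glucosaminidase) has no universally fixed EC in some
#' listings; EC 3.2.1.52 is used here and can be overridden by supplying a
#' custom catalog.
#'
#' @return data frame with columns `category`, `enzyme`, `ec`.
#' @export
default_function_catalog <- function() {
  data.frame(
    category = c("stress", "siderophore", "P decomposition",
                 "N decomposition", "N decomposition", "N decomposition",
                 "dissimilatory nitrate reduction", "C/N cycling",
                 "C decomposition", "C decomposition", "biocontrol",
                 "assimilatory nitrate reduction"),
    enzyme = c("indolepyruvate decarboxylase", "isochorismate synthase",
               "alkaline phosphatase", "leucyl aminopeptidase", "urease",
               "amidase", "nitrite reductase",
               "N-acetyl-beta-glucosaminidase", "alpha-glucosidase",
               "beta-glucosidase", "S,S-butanediol dehydrogenase",
               "ferredoxin-nitrite reductase"),
    ec = c("4.1.1.74", "5.4.4.2", "3.1.3.1", "3.4.11.1", "3.5.1.5",
           "3.5.1.4", "1.7.2.2", "3.2.1.52", "3.2.1.20", "3.2.1.21",
           "1.1.1.76", "1.7.7.1"),
    stringsAsFactors = FALSE)
}

#' Classify taxa into functional categories
#'
#' A taxon gets a category when it carries at least one of that category's
#' EC numbers in the gene-presence table (copy numbers are binarized at
#' >= 1). Taxa may belong to several categories; taxa absent from the table
#' get an empty set with a warning.
#'
#' @param taxa character vector of taxon ids to classify.
#' @param gene_presence numeric matrix, taxa x EC numbers (column names are
#'   ECs), e.g. from [read_gene_presence()].
#' @param catalog catalog data frame (`category`, `enzyme`, `ec`); defaults
#'   to [default_function_catalog()].
#' @return named list mapping each taxon to a character vector of categories.
#' @export
classify_functions <- function(taxa, gene_presence,
                               catalog = default_function_catalog()) {
  stopifnot(is.matrix(gene_presence), is.data.frame(catalog),
            all(c("category", "ec") %in% names(catalog)))
  unknown <- setdiff(catalog$ec, colnames(gene_presence))
  if (length(unknown))
    stop("catalog EC number(s) absent from gene-presence table: ",
         paste(unknown, collapse = ", "))
  absent <- setdiff(taxa, rownames(gene_presence))
  if (length(absent))
    warning("taxa absent from gene-presence table get no categories: ",
            paste(absent, collapse = ", "))
  out <- stats::setNames(vector("list", length(taxa)), taxa)
  for (t in taxa) {
    if (t %in% absent) { out[[t]] <- character(0); next }
    carried <- colnames(gene_presence)[gene_presence[t, ] >= 1]
    out[[t]] <- sort(unique(catalog$category[catalog$ec %in% carried]))
  }
  out
}

#' Summed keystone relative abundance per sample and group
#'
#' For every sample, sums the relative abundances of the keystone taxa; then
#' summarizes per domestication group as mean +/- SE (SE = sd / sqrt(n)).
#'
#' @param x an `abundance_table` containing the samples to summarize.
#' @param meta metadata (see [sample_metadata()]) covering those samples.
#' @param keystones character vector of keystone taxon ids (subset of the
#'   table's taxa; a `keystone_report` is also accepted).
#' @param group_col metadata column defining the groups (default
#'   `"domestication"`).
#' @return list with `per_sample` (sample_id, group, value) and `summary`
#'   (group, n, mean, se).
#' @export
keystone_abundance_by_group <- function(x, meta, keystones,
                                        group_col = "domestication") {
  stopifnot(inherits(x, "abundance_table"))
  if (inherits(keystones, "keystone_report")) keystones <- keystones$taxon
  bad <- setdiff(keystones, colnames(x))
  if (length(bad))
    stop("keystone taxa not in abundance table: ", paste(bad, collapse = ", "))
  rel <- to_relative(x)
  value <- rowSums(rel[, keystones, drop = FALSE])
  idx <- match(rownames(x), meta$sample_id)
  if (anyNA(idx))
    stop("samples without metadata: ",
         paste(rownames(x)[is.na(idx)], collapse = ", "))
  grp <- as.character(meta[[group_col]][idx])
  per_sample <- data.frame(sample_id = rownames(x), group = grp,
                           value = unname(value), stringsAsFactors = FALSE)
  sizes <- table(grp)
  if (any(sizes < 2L))
    stop("group(s) with < 2 samples, SE undefined: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  agg <- do.call(rbind, lapply(split(per_sample$value, grp), function(v)
    data.frame(n = length(v), mean = mean(v),
               se = stats::sd(v) / sqrt(length(v)))))
  summary <- data.frame(group = rownames(agg), agg, row.names = NULL,
                        stringsAsFactors = FALSE)
  list(per_sample = per_sample, summary = summary)
}
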