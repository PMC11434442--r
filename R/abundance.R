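# Core tables: abundance counts, taxonomy, sample metadata, filter settings.

#' Construct an abundance table
#'
#' An `abundance_table` is an integer count matrix in canonical
#' samples x taxa orientation. Row names are sample ids, column names are
#' taxon ids; both must be unique and counts must be non-negative.
#'
#' @param counts numeric matrix of non-negative counts, samples in rows and
#'   taxa in columns, with unique dimnames.
#' @return an object of class `abundance_table` (a validated matrix).
#' @examples
#' m <- matrix(c(10, 0, 5, 5, 0, 20), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("s", 1:3), c("tA", "tB")))
#' at <- abundance_table(m)
#' read_depth(at)
#' @export
abundance_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("abundance_table requires sample (row) and taxon (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  if (!is.numeric(counts) || anyNA(counts))
    stop("counts must be numeric with no missing values")
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "double"
  structure(counts, class = c("abundance_table", "matrix", "array"))
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d samples x %d taxa, total reads %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Per-sample read depth (row sums)
#' @param x an `abundance_table`.
#' @return named numeric vector of per-sample total counts.
#' @export
read_depth <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  rowSums(unclass(x))
}

#' Filter settings for samples and taxa
#'
#' Defaults mirror the study pipeline: samples with fewer than 10,000 reads
#' are removed, and taxa with mean relative abundance below 0.001 across the
#' retained samples are removed. Both boundaries are inclusive for retention.
#'
#' @param min_reads minimum per-sample read depth (retain depth >= min_reads).
#' @param min_mean_rel_abund minimum mean relative abundance across retained
#'   samples (retain mean >= threshold); a fraction in `[0, 1)`.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_reads = 10000, min_mean_rel_abund = 0.001) {
  stopifnot(length(min_reads) == 1L, min_reads >= 0,
            length(min_mean_rel_abund) == 1L,
            min_mean_rel_abund >= 0, min_mean_rel_abund < 1)
  structure(list(min_reads = min_reads,
                 min_mean_rel_abund = min_mean_rel_abund),
            class = "filter_config")
}

#' Remove low-depth samples
#'
#' Retains exactly the samples with read depth `>= min_reads` (inclusive
#' boundary: the pipeline removes samples with *fewer* reads than the cutoff).
#' Sample order is preserved.
#'
#' @param x an `abundance_table`.
#' @param min_reads depth cutoff; may also be a `filter_config`.
#' @return filtered `abundance_table`.
#' @export
filter_samples <- function(x, min_reads = 10000) {
  stopifnot(inherits(x, "abundance_table"))
  if (inherits(min_reads, "filter_config")) min_reads <- min_reads$min_reads
  keep <- read_depth(x) >= min_reads
  if (!any(keep))
    stop(sprintf("all %d samples removed by min_reads = %s (max depth %s)",
                 nrow(x), format(min_reads), format(max(read_depth(x)))))
  abundance_table(unclass(x)[keep, , drop = FALSE])
}

#' Remove rare taxa
#'
#' Retains taxa whose mean relative abundance across the (already
#' sample-filtered) table is `>= min_mean_rel_abund`. Relative abundances are
#' computed per sample before any taxon is dropped, so removing taxa does not
#' renormalize the remaining ones.
#'
#' @param x an `abundance_table` (sample-filtered; all depths > 0).
#' @param min_mean_rel_abund abundance cutoff; may also be a `filter_config`.
#' @return filtered `abundance_table`.
#' @export
filter_taxa <- function(x, min_mean_rel_abund = 0.001) {
  stopifnot(inherits(x, "abundance_table"))
  if (inherits(min_mean_rel_abund, "filter_config"))
    min_mean_rel_abund <- min_mean_rel_abund$min_mean_rel_abund
  if (nrow(x) == 0L || ncol(x) == 0L) stop("empty abundance table")
  rel <- to_relative(x)
  keep <- colMeans(rel) >= min_mean_rel_abund
  if (!any(keep))
    stop(sprintf("all %d taxa removed by min_mean_rel_abund = %s",
                 ncol(x), format(min_mean_rel_abund)))
  abundance_table(unclass(x)[, keep, drop = FALSE])
}

#' Relative abundances
#'
#' Divides each sample's counts by its read depth; every row of the result
#' sums to 1. Zero-depth samples are an error (filter them out first).
#'
#' @param x an `abundance_table`.
#' @return numeric matrix of fractions, same dimnames as `x`.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  depth <- read_depth(x)
  if (any(depth == 0))
    stop("zero read depth in sample(s): ",
         paste(names(depth)[depth == 0], collapse = ", "))
  unclass(x) / depth
}

#' Look up phylum labels for taxa
#'
#' @param taxa character vector of taxon ids.
#' @param taxonomy a taxonomy data frame (see [read_taxonomy()]) with columns
#'   `taxon_id` and `phylum`.
#' @return character vector of phylum labels; taxa without a phylum (or
#'   absent from the table) get `"Unclassified"`.
#' @export
phylum_of <- function(taxa, taxonomy) {
  stopifnot(is.data.frame(taxonomy),
            all(c("taxon_id", "phylum") %in% names(taxonomy)))
  ph <- taxonomy$phylum[match(taxa, taxonomy$taxon_id)]
  ph[is.na(ph) | !nzchar(ph)] <- "Unclassified"
  ph
}

#' Validate sample metadata
#'
#' Metadata maps each sample to a domestication group (wild, traditional or
#' modern tomato) and a fertilization level, mirroring the 3 x 2 factorial
#' design of the study the pipeline models.
#'
#' @param meta data frame with columns `sample_id`, `domestication`,
#'   `fertilization` and optionally `replicate`.
#' @return the validated data frame with factor columns.
#' @export
sample_metadata <- function(meta) {
  stopifnot(is.data.frame(meta),
            all(c("sample_id", "domestication", "fertilization") %in% names(meta)))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample ids in metadata")
  dlev <- c("wild", "traditional", "modern")
  flev <- c("unfertilized", "fertilized")
  bad_d <- setdiff(unique(as.character(meta$domestication)), dlev)
  if (length(bad_d))
    stop("unknown domestication level(s): ", paste(bad_d, collapse = ", "))
  bad_f <- setdiff(unique(as.character(meta$fertilization)), flev)
  if (length(bad_f))
    stop("unknown fertilization level(s): ", paste(bad_f, collapse = ", "))
  meta$domestication <- factor(meta$domestication, levels = dlev)
  meta$fertilization <- factor(meta$fertilization, levels = flev)
  meta
}
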