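# Delimited-file I/O. All tables are TSV (UTF-8, header row + id column);
# gzip is handled transparently by R's connections.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one data column: ", path)
  df
}

#' Read an abundance table from TSV
#'
#' The file has a header row and an id column (first column). Either
#' orientation is accepted; the result is always canonical samples x taxa.
#'
#' @param path TSV file (optionally gzipped): first column ids, remaining
#'   columns numeric counts.
#' @param orientation `"samples-as-rows"` (default) or `"taxa-as-rows"`.
#' @return an `abundance_table`.
#' @export
read_abundance <- function(path,
                           orientation = c("samples-as-rows", "taxa-as-rows")) {
  orientation <- match.arg(orientation)
  df <- read_tsv_checked(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(names(df)[-1L]))
    stop("duplicate column ids in ", path, ": ",
         paste(unique(names(df)[-1L][duplicated(names(df)[-1L])]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    v <- body[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (anyNA(vn)) {
        i <- which(is.na(vn))[1L]
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                     v[i], ids[i], names(body)[j], path))
      }
      body[[j]] <- vn
    }
  }
  m <- as.matrix(body)
  rownames(m) <- ids
  if (orientation == "taxa-as-rows") m <- t(m)
  at <- abundance_table(m)
  message(sprintf("read_abundance: %d samples x %d taxa from %s",
                  nrow(at), ncol(at), path))
  at
}

#' Write an abundance table to TSV
#' @param x an `abundance_table`.
#' @param path output file; `.gz` suffix writes gzipped.
#' @param id_column name for the leading id column.
#' @export
write_abundance <- function(x, path, id_column = "sample_id") {
  stopifnot(inherits(x, "abundance_table"))
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write_tsv(df, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a taxonomy table from TSV
#'
#' Expects columns `taxon_id` and `phylum`; further ranks (e.g. `species`)
#' are carried along. Empty phylum entries become `"Unclassified"`.
#'
#' @param path TSV file.
#' @return data frame with at least `taxon_id` and `phylum`.
#' @export
read_taxonomy <- function(path) {
  df <- read_tsv_checked(path)
  if (!"taxon_id" %in% names(df)) names(df)[1L] <- "taxon_id"
  if (!"phylum" %in% names(df))
    stop("taxonomy table must have a 'phylum' column: ", path)
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon ids in taxonomy: ", path)
  df$phylum[is.na(df$phylum) | !nzchar(df$phylum)] <- "Unclassified"
  df
}

#' Read sample metadata from TSV
#' @param path TSV file with columns `sample_id`, `domestication`,
#'   `fertilization` (and optionally `replicate`).
#' @return validated metadata data frame (see [sample_metadata()]).
#' @export
read_metadata <- function(path) {
  sample_metadata(read_tsv_checked(path))
}

#' Read a gene-presence table (taxon x EC) from TSV
#'
#' Stand-in for predicted gene content (e.g. PICRUSt2 output): rows are taxa,
#' columns are EC numbers, entries are predicted copy numbers (binarized at
#' >= 1 downstream).
#'
#' @param path TSV file; first column taxon ids.
#' @return numeric matrix, taxa in rows, EC numbers in columns.
#' @export
read_gene_presence <- function(path) {
  df <- read_tsv_checked(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate taxon ids in gene-presence table")
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("gene-presence body must be numeric: ", path)
  rownames(m) <- ids
  m
}
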