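# Phylum-level "influence": how a network's connections distribute over
# phyla, and the symmetric inter-phylum edge-count matrix behind chord
# diagrams.

#' Phylum connection shares and inter-phylum edge counts
#'
#' A phylum's share of network connections is its fraction of edge
#' *endpoints*: each edge contributes two endpoints, so shares sum to 1. The
#' matrix entry (P, Q) counts edges joining a P-labelled node to a Q-labelled
#' node (diagonal: within-phylum edges).
#'
#' @param g a co-occurrence network; vertices need a `phylum` attribute
#'   unless `taxonomy` is supplied.
#' @param taxonomy optional taxonomy data frame used to (re)label vertices.
#' @return a `phylum_share_table`: list with `shares` (named fractions,
#'   descending) and `matrix` (symmetric phylum x phylum edge counts).
#' @export
phylum_shares <- function(g, taxonomy = NULL) {
  stopifnot(igraph::is_igraph(g))
  if (!is.null(taxonomy)) {
    ph <- phylum_of(igraph::V(g)$name, taxonomy)
  } else {
    ph <- igraph::V(g)$phylum
    if (is.null(ph)) stop("vertices have no phylum attribute; supply taxonomy")
  }
  if (igraph::vcount(g) == 0L || igraph::ecount(g) == 0L) {
    return(structure(list(shares = stats::setNames(numeric(0), character(0)),
                          matrix = matrix(0, 0, 0)),
                     class = "phylum_share_table"))
  }
  names(ph) <- igraph::V(g)$name
  el <- igraph::as_edgelist(g, names = TRUE)
  pi_ <- ph[el[, 1L]]; pj <- ph[el[, 2L]]
  lev <- sort(unique(ph))
  mat <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (k in seq_len(nrow(el))) {
    mat[pi_[k], pj[k]] <- mat[pi_[k], pj[k]] + 1
    if (pi_[k] != pj[k]) mat[pj[k], pi_[k]] <- mat[pj[k], pi_[k]] + 1
  }
  ends <- table(factor(c(pi_, pj), levels = lev))
  shares <- as.numeric(ends) / (2 * nrow(el))
  names(shares) <- lev
  shares <- sort(shares, decreasing = TRUE)
  structure(list(shares = shares, matrix = mat),
            class = "phylum_share_table")
}

#' Chord-diagram matrix for the top-k most influential phyla
#'
#' Phyla are ranked by connection share (descending, alphabetical on ties);
#' phyla beyond `top_k` are aggregated into `"Other"`. The total edge count
#' is conserved.
#'
#' @param g a co-occurrence network (see [phylum_shares()]).
#' @param taxonomy optional taxonomy for labelling.
#' @param top_k number of phyla to keep (default 10).
#' @return a `phylum_share_table` restricted to the top phyla (+ "Other").
#' @export
chord_matrix <- function(g, taxonomy = NULL, top_k = 10L) {
  ps <- phylum_shares(g, taxonomy)
  if (length(ps$shares) <= top_k) return(ps)
  ranked <- names(sort(ps$shares, decreasing = TRUE))
  # stable tie-break: descending share then alphabetical
  ranked <- ranked[order(-ps$shares[ranked], ranked)]
  top <- ranked[seq_len(top_k)]
  rest <- setdiff(rownames(ps$matrix), top)
  orig <- rownames(ps$matrix)
  grp <- stats::setNames(ifelse(orig %in% top, orig, "Other"), orig)
  lev <- c(sort(top), "Other")
  mat <- matrix(0, length(lev), length(lev), dimnames = list(lev, lev))
  for (a in seq_along(orig)) for (b in a:length(orig)) {
    cnt <- ps$matrix[a, b] # edges between original phyla a and b
    if (cnt == 0) next
    gi <- grp[orig[a]]; gj <- grp[orig[b]]
    if (gi == gj) mat[gi, gi] <- mat[gi, gi] + cnt
    else { mat[gi, gj] <- mat[gi, gj] + cnt; mat[gj, gi] <- mat[gj, gi] + cnt }
  }
  shares <- c(ps$shares[top], Other = sum(ps$shares[rest]))
  structure(list(shares = sort(shares, decreasing = TRUE), matrix = mat),
            class = "phylum_share_table")
}

#' Total edge count implied by a phylum matrix
#' @param ps a `phylum_share_table`.
#' @return number of edges (diagonal counted once, off-diagonal halved).
#' @export
phylum_matrix_total <- function(ps) {
  stopifnot(inherits(ps, "phylum_share_table"))
  if (!length(ps$matrix)) return(0)
  sum(diag(ps$matrix)) + sum(ps$matrix[upper.tri(ps$matrix)])
}

#' Write a phylum matrix as TSV
#' @param ps a `phylum_share_table`.
#' @param path output file.
#' @export
write_phylum_matrix <- function(ps, path) {
  stopifnot(inherits(ps, "phylum_share_table"))
  df <- data.frame(phylum = rownames(ps$matrix), ps$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}
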