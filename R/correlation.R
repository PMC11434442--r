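# All-pairs Spearman correlation with FDR control: the statistical core
# feeding network construction.

#' All-pairs Spearman correlation among taxa
#'
#' Computes Spearman's rho for every unordered pair of taxa on the table's
#' relative abundances. Rho is the Pearson correlation of mid-ranks (average
#' ranks for ties); two-sided p-values use the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' which matches common implementations at the study's sample sizes (exact
#' permutation tests differ below roughly n = 10). Taxa with constant
#' abundance across samples have undefined rho; their pairs are dropped and
#' the count is reported via `message()`.
#'
#' @param x an `abundance_table` with at least 4 samples and 2 taxa.
#' @return a `correlation_set`: data frame with columns `taxon_i`, `taxon_j`
#'   (i before j in table order), `rho`, `p_raw`, `p_adj` (NA until
#'   [adjust_fdr()] is applied) and `n`.
#' @export
spearman_all_pairs <- function(x) {
  stopifnot(inherits(x, "abundance_table"))
  if (nrow(x) < 4L)
    stop(sprintf("need >= 4 samples for correlation, got %d", nrow(x)))
  if (ncol(x) < 2L) stop("need >= 2 taxa")
  rel <- to_relative(x)
  n <- nrow(rel)
  constant <- apply(rel, 2L, function(v) max(v) == min(v))
  if (any(constant)) {
    k <- sum(constant)
    message(sprintf(
      "spearman_all_pairs: dropping %d constant taxa (%d pairs excluded)",
      k, k * ncol(rel) - choose(k, 2L) - k))
    rel <- rel[, !constant, drop = FALSE]
  }
  if (ncol(rel) < 2L) stop("fewer than 2 non-constant taxa")
  ranks <- apply(rel, 2L, rank) # mid-ranks (ties.method = "average")
  rho <- stats::cor(ranks)      # Pearson on ranks == Spearman
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  r <- rho[idx]
  r <- pmin(1, pmax(-1, r))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(r) == 1] <- 0
  out <- data.frame(
    taxon_i = colnames(rel)[idx[, 1L]],
    taxon_j = colnames(rel)[idx[, 2L]],
    rho = r, p_raw = p, p_adj = NA_real_, n = n,
    stringsAsFactors = FALSE)
  structure(out, class = c("correlation_set", "data.frame"))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Fills `p_adj` with BH step-up values: with p-values sorted ascending,
#' `q_(k) = min over j >= k of p_(j) * m / j`, clipped at 1. Row order is
#' preserved.
#'
#' @param cs a `correlation_set` with `p_raw` populated.
#' @return the same `correlation_set` with `p_adj` filled.
#' @export
adjust_fdr <- function(cs) {
  stopifnot(inherits(cs, "correlation_set"))
  cs$p_adj <- bh_adjust(cs$p_raw)
  cs
}

#' BH step-up adjusted p-values
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  stopifnot(all(p >= 0 & p <= 1))
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))   # step-up: running min from the largest p down
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Write a correlation set to long-format TSV
#' @param cs a `correlation_set`.
#' @param path output file.
#' @export
write_correlations <- function(cs, path) {
  stopifnot(inherits(cs, "correlation_set"))
  write_tsv(as.data.frame(cs), path)
  invisible(path)
}
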