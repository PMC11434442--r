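# Group-comparison statistics: fixed-effects ANOVA from explicit sums of
# squares (the design is balanced, so Type I = Type III), Tukey HSD via the
# studentized-range distribution, and a compact letter display.

#' ANOVA with Tukey HSD pairwise comparisons
#'
#' Two-way (domestication x fertilization) or one-way fixed-effects ANOVA
#' computed from explicit sums of squares. An unbalanced two-way design
#' (unequal or empty cells) degrades gracefully: separate one-way ANOVAs are
#' run per factor with a warning, rather than silently committing to a
#' contested sum-of-squares type. Tukey HSD p-values use the
#' studentized-range distribution with the Tukey-Kramer standard error, and
#' group letters come from the insert-and-absorb compact letter display.
#'
#' @param values numeric response, one value per sample.
#' @param meta data frame with the factor columns, rows aligned with
#'   `values`.
#' @param design `"two-way"` (factors `domestication`, `fertilization`) or
#'   `"one-way"`.
#' @param factor_col for one-way: the grouping column; for two-way: the
#'   factor whose levels are compared by Tukey HSD (default
#'   `"domestication"`).
#' @param alpha significance level for the letter display.
#' @return a `group_test_result`: list with `design`, `anova` (term, df, ss,
#'   ms, F, p), `tukey` (pairwise table) and `letters` (named vector), or —
#'   for the unbalanced fallback — a list of per-factor one-way results.
#' @export
anova_tukey <- function(values, meta, design = c("two-way", "one-way"),
                        factor_col = "domestication", alpha = 0.05) {
  design <- match.arg(design)
  stopifnot(is.numeric(values), nrow(meta) == length(values))
  if (design == "one-way")
    return(one_way_anova_tukey(values, as.character(meta[[factor_col]]), alpha))
  A <- as.character(meta$domestication)
  B <- as.character(meta$fertilization)
  cells <- table(A, B)
  if (any(cells == 0L) || length(unique(as.vector(cells))) != 1L) {
    warning("unbalanced two-way design; falling back to one-way ANOVAs per factor")
    return(structure(list(
      design = "one-way-fallback",
      domestication = one_way_anova_tukey(values, A, alpha),
      fertilization = one_way_anova_tukey(values, B, alpha)),
      class = "group_test_result"))
  }
  N <- length(values)
  gm <- mean(values)
  ybar_a <- tapply(values, A, mean); n_a <- table(A)
  ybar_b <- tapply(values, B, mean); n_b <- table(B)
  cell_mean <- tapply(values, list(A, B), mean)
  ss_a <- sum(n_a * (ybar_a - gm)^2)
  ss_b <- sum(n_b * (ybar_b - gm)^2)
  ss_cells <- sum(cells * (cell_mean - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  fitted <- cell_mean[cbind(A, B)]
  ss_e <- sum((values - fitted)^2)
  df_a <- nlevels(factor(A)) - 1L
  df_b <- nlevels(factor(B)) - 1L
  df_ab <- df_a * df_b
  df_e <- N - nlevels(factor(A)) * nlevels(factor(B))
  ms <- c(ss_a / df_a, ss_b / df_b, ss_ab / df_ab, ss_e / df_e)
  Fv <- c(ms[1:3] / ms[4], NA)
  pv <- c(stats::pf(Fv[1:3], c(df_a, df_b, df_ab), df_e, lower.tail = FALSE), NA)
  tab <- data.frame(
    term = c("domestication", "fertilization", "interaction", "residuals"),
    df = c(df_a, df_b, df_ab, df_e),
    ss = c(ss_a, ss_b, ss_ab, ss_e), ms = ms, F = Fv, p = pv,
    stringsAsFactors = FALSE)
  fac <- if (factor_col == "fertilization") B else A
  tk <- tukey_hsd(values, fac, mse = ms[4], dfe = df_e)
  structure(list(design = "two-way", anova = tab, tukey = tk,
                 letters = cld_letters(tk, alpha = alpha)),
            class = "group_test_result")
}

one_way_anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need >= 2 groups")
  if (any(sizes < 2L)) stop("need >= 2 replicates per group")
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ss_b <- sum(sizes * (means - gm)^2)
  ss_w <- sum((values - means[groups])^2)
  df_b <- length(sizes) - 1L
  df_w <- length(values) - length(sizes)
  ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
  Fv <- ms_b / ms_w
  tab <- data.frame(
    term = c("group", "residuals"), df = c(df_b, df_w), ss = c(ss_b, ss_w),
    ms = c(ms_b, ms_w), F = c(Fv, NA),
    p = c(stats::pf(Fv, df_b, df_w, lower.tail = FALSE), NA),
    stringsAsFactors = FALSE)
  tk <- tukey_hsd(values, groups, mse = ms_w, dfe = df_w)
  structure(list(design = "one-way", anova = tab, tukey = tk,
                 letters = cld_letters(tk, alpha = alpha)),
            class = "group_test_result")
}

#' Tukey HSD pairwise comparisons
#'
#' Tukey-Kramer form: for groups i, j the statistic is
#' `q = |mean_i - mean_j| / sqrt(mse * (1/n_i + 1/n_j) / 2)` referred to the
#' studentized-range distribution with `k` means and `dfe` degrees of
#' freedom.
#'
#' @param values numeric response.
#' @param groups group label per value.
#' @param mse residual mean square of the fitted ANOVA.
#' @param dfe residual degrees of freedom.
#' @return data frame: group_i, group_j, diff, se, q, p_adj.
#' @export
tukey_hsd <- function(values, groups, mse, dfe) {
  groups <- as.character(groups)
  means <- tapply(values, groups, mean)
  sizes <- table(groups)
  lev <- names(means)
  k <- length(lev)
  pairs <- utils::combn(lev, 2L)
  diff <- means[pairs[2L, ]] - means[pairs[1L, ]]
  ni <- as.numeric(sizes[pairs[1L, ]]); nj <- as.numeric(sizes[pairs[2L, ]])
  se <- sqrt(mse * (1 / ni + 1 / nj) / 2)
  q <- abs(diff) / se
  p <- stats::ptukey(q, nmeans = k, df = dfe, lower.tail = FALSE)
  data.frame(group_i = pairs[1L, ], group_j = pairs[2L, ],
             diff = unname(diff), se = unname(se), q = unname(q),
             p_adj = unname(p), row.names = NULL, stringsAsFactors = FALSE)
}

#' Compact letter display (insert-and-absorb)
#'
#' Two groups share a letter iff their Tukey-adjusted p-value is >= alpha.
#'
#' @param tukey pairwise table from [tukey_hsd()].
#' @param alpha significance level.
#' @return named character vector of letter strings, one per group.
#' @export
cld_letters <- function(tukey, alpha = 0.05) {
  groups <- sort(unique(c(tukey$group_i, tukey$group_j)))
  cols <- list(groups) # each column = set of groups sharing one letter
  sig <- tukey[tukey$p_adj < alpha, , drop = FALSE]
  if (nrow(sig)) {
    for (r in seq_len(nrow(sig))) {
      gi <- sig$group_i[r]; gj <- sig$group_j[r]
      newcols <- list()
      for (col in cols) {
        if (gi %in% col && gj %in% col) { # insert: split the offending column
          newcols <- c(newcols, list(setdiff(col, gi)), list(setdiff(col, gj)))
        } else newcols <- c(newcols, list(col))
      }
      # absorb columns that are subsets of another
      keep <- rep(TRUE, length(newcols))
      for (i in seq_along(newcols)) for (j in seq_along(newcols)) {
        if (i != j && keep[i] && keep[j] &&
            all(newcols[[i]] %in% newcols[[j]]) &&
            (length(newcols[[i]]) < length(newcols[[j]]) || i > j))
          keep[i] <- FALSE
      }
      cols <- unique(newcols[keep])
    }
  }
  cols <- cols[order(vapply(cols, function(cl) match(cl[1L], groups), 1L))]
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(cols))
    out[cols[[i]]] <- paste0(out[cols[[i]]], letters[i])
  out
}
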