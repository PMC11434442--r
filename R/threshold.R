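# Correlation-threshold selection by random-matrix theory (RMT).
#
# Rationale: below the "right" threshold a correlation matrix behaves like a
# dense random matrix and its unfolded eigenvalue nearest-neighbour spacings
# follow the Wigner-Dyson (GOE) distribution; once genuine modular structure
# dominates, the thresholded matrix fragments and spacings follow the Poisson
# (exponential) law. We scan a threshold grid and pick the first threshold
# where the spacing distribution fits Poisson better than GOE, stably.

#' Reconstruct a symmetric correlation matrix from a correlation set
#' @param cs a `correlation_set`.
#' @return symmetric matrix of rho values with unit diagonal; pairs absent
#'   from `cs` are zero.
#' @export
rho_matrix <- function(cs) {
  stopifnot(inherits(cs, "correlation_set"))
  taxa <- sort(unique(c(cs$taxon_i, cs$taxon_j)))
  m <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  i <- match(cs$taxon_i, taxa); j <- match(cs$taxon_j, taxa)
  m[cbind(i, j)] <- cs$rho
  m[cbind(j, i)] <- cs$rho
  diag(m) <- 1
  m
}

# Nearest-neighbour spacing distribution of a symmetric matrix's eigenvalues,
# unfolded through a smoothed empirical spectral CDF so the mean spacing is 1.
nn_spacings <- function(mat) {
  ev <- sort(eigen(mat, symmetric = TRUE, only.values = TRUE)$values)
  n <- length(ev)
  nu <- length(unique(round(ev, 10)))
  if (nu < 5L) return(NULL) # spectrum degenerate
  fit <- tryCatch(
    suppressWarnings(
      stats::smooth.spline(ev, seq_len(n) / n, df = min(15, nu - 1))),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  u <- n * stats::predict(fit, ev)$y
  s <- diff(sort(u))
  s <- s[s >= 0]
  if (length(s) < 10L || mean(s) <= 0) return(NULL)
  s / mean(s)
}

# Chi-square distance between the spacing histogram (30 bins on [0, 3]) and a
# model density evaluated at bin centres.
spacing_distance <- function(s, density_fun, bins = 30L, smax = 3) {
  breaks <- seq(0, smax, length.out = bins + 1L)
  width <- smax / bins
  centers <- breaks[-1L] - width / 2
  counts <- tabulate(findInterval(s[s < smax], breaks,
                                  rightmost.closed = TRUE), nbins = bins)
  obs <- counts / (length(s) * width)
  mod <- density_fun(centers)
  sum((obs - mod)^2 / mod)
}

poisson_spacing_density <- function(s) exp(-s)
goe_spacing_density <- function(s) (pi * s / 2) * exp(-pi * s^2 / 4)

#' Select the correlation threshold by eigenvalue-spacing statistics
#'
#' For each candidate threshold `s`, entries of the correlation matrix with
#' `|rho| < s` are zeroed (diagonal kept at 1), the eigenvalue spectrum is
#' unfolded by a smoothed empirical CDF, and the nearest-neighbour spacing
#' histogram is compared (chi-square distance, 30 bins on `[0, 3]`) against
#' the Poisson (exponential) and Wigner-Dyson (GOE) spacing densities. The
#' selected threshold is the smallest grid value whose spacings fit Poisson
#' better than GOE with the fit remaining Poisson-better at the next two grid
#' points. If no threshold qualifies, `fallback` is returned with a warning.
#'
#' @param cs a `correlation_set` (at least ~30 taxa for meaningful
#'   eigenvalue statistics; fewer triggers the fallback with a warning).
#' @param grid strictly increasing candidate thresholds.
#' @param fallback threshold used when the scan does not converge.
#' @return a `threshold_scan`: list with `grid`, `d_poisson`, `d_goe`,
#'   `score` (= d_poisson - d_goe; negative means Poisson fits better),
#'   `selected`, and `converged`.
#' @export
optimize_threshold <- function(cs, grid = seq(0.50, 0.90, by = 0.01),
                               fallback = 0.70) {
  stopifnot(inherits(cs, "correlation_set"))
  if (any(diff(grid) <= 0)) stop("threshold grid must be strictly increasing")
  if (length(grid) == 1L) {
    return(structure(list(grid = grid, d_poisson = NA_real_, d_goe = NA_real_,
                          score = NA_real_, selected = grid, converged = TRUE),
                     class = "threshold_scan"))
  }
  m <- rho_matrix(cs)
  if (nrow(m) < 30L) {
    warning(sprintf(
      "only %d taxa; eigenvalue statistics unreliable, using fallback %.2f",
      nrow(m), fallback))
    return(structure(list(grid = grid, d_poisson = rep(NA_real_, length(grid)),
                          d_goe = rep(NA_real_, length(grid)),
                          score = rep(NA_real_, length(grid)),
                          selected = fallback, converged = FALSE),
                     class = "threshold_scan"))
  }
  d_pois <- d_goe <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    mk <- m * (abs(m) >= grid[k])
    diag(mk) <- 1
    s <- nn_spacings(mk)
    if (is.null(s)) {
      # spectrum too degenerate to unfold: the matrix is fully fragmented,
      # which is the Poisson limit
      d_pois[k] <- 0; d_goe[k] <- Inf
    } else {
      d_pois[k] <- spacing_distance(s, poisson_spacing_density)
      d_goe[k] <- spacing_distance(s, goe_spacing_density)
    }
  }
  score <- d_pois - d_goe
  selected <- NA_real_
  for (k in seq_len(length(grid) - 2L)) {
    if (all(score[k:(k + 2L)] < 0)) { selected <- grid[k]; break }
  }
  converged <- !is.na(selected)
  if (!converged) {
    warning(sprintf("threshold scan did not converge; using fallback %.2f",
                    fallback))
    selected <- fallback
  }
  structure(list(grid = grid, d_poisson = d_pois, d_goe = d_goe,
                 score = score, selected = selected, converged = converged),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("<threshold_scan> %d candidates in [%.2f, %.2f]; selected %.2f%s\n",
              length(x$grid), min(x$grid), max(x$grid), x$selected,
              if (x$converged) "" else " (fallback)"))
  invisible(x)
}

#' Export a threshold scan as TSV
#' @param scan a `threshold_scan`.
#' @param path output file.
#' @export
write_threshold_scan <- function(scan, path) {
  stopifnot(inherits(scan, "threshold_scan"))
  write_tsv(data.frame(threshold = scan$grid, d_poisson = scan$d_poisson,
                       d_goe = scan$d_goe, score = scan$score), path)
  invisible(path)
}
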