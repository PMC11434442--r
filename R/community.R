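# Module detection: Clauset-Newman-Moore greedy modularity maximization
# ("fast greedy" hierarchical agglomeration), implemented directly so that
# tie-breaking is deterministic and the merge path is inspectable.

#' Fast-greedy module detection (Clauset-Newman-Moore)
#'
#' Starts from singleton communities and repeatedly merges the connected pair
#' of communities with the largest modularity gain
#' `dQ = 2 * (e_ij - a_i * a_j)`, returning the partition with maximal Q along
#' the merge path. Ties in dQ are broken deterministically by the lowest
#' (min-id, max-id) community pair, so repeated runs agree. Modularity is
#' unweighted by default (edge presence only); set `weighted = TRUE` to use
#' `|rho|` edge weights for sensitivity analysis.
#'
#' @param g an undirected igraph graph without multi-edges.
#' @param weighted use edge weights in the modularity being maximized.
#' @return a `module_partition`: list with `membership` (named integer vector,
#'   module ids dense from 0), `n_modules`, and `modularity`.
#' @export
fast_greedy_modules <- function(g, weighted = FALSE) {
  stopifnot(igraph::is_igraph(g), !igraph::is_directed(g))
  if (igraph::any_multiple(g)) stop("multi-edges are not supported")
  n <- igraph::vcount(g)
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(n))
  if (n == 0L)
    return(structure(list(membership = stats::setNames(integer(0), character(0)),
                          n_modules = 0L, modularity = 0),
                     class = "module_partition"))
  w <- if (weighted) igraph::E(g)$weight else rep(1, igraph::ecount(g))
  if (igraph::ecount(g) == 0L || sum(w) == 0) {
    memb <- stats::setNames(seq_len(n) - 1L, vnames)
    return(structure(list(membership = memb, n_modules = n, modularity = 0),
                     class = "module_partition"))
  }
  m2 <- 2 * sum(w)
  el <- igraph::as_edgelist(g, names = FALSE)
  # E[i, j]: fraction of edge ends joining communities i and j (diagonal
  # counts both ends of within-community edges); a_i = row sums.
  E <- matrix(0, n, n)
  for (k in seq_len(nrow(el))) {
    i <- el[k, 1L]; j <- el[k, 2L]
    E[i, j] <- E[i, j] + w[k] / m2
    E[j, i] <- E[j, i] + w[k] / m2
  }
  a <- rowSums(E)
  active <- rep(TRUE, n)
  comm <- seq_len(n)            # vertex -> community id
  Q <- -sum(a^2)                # singleton partition
  best_Q <- Q
  best_comm <- comm
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    sub <- E[act, act, drop = FALSE]
    cand <- which(upper.tri(sub) & sub > 0, arr.ind = TRUE)
    if (nrow(cand) == 0L) break # only disconnected communities remain
    dq <- 2 * (sub[cand] - a[act[cand[, 1L]]] * a[act[cand[, 2L]]])
    top <- which(dq == max(dq))
    if (length(top) > 1L) { # lowest (min-id, max-id) pair wins
      ii <- act[cand[top, 1L]]; jj <- act[cand[top, 2L]]
      top <- top[order(ii, jj)][1L]
    }
    i <- act[cand[top, 1L]]; j <- act[cand[top, 2L]]
    Q <- Q + dq[top]
    E[i, ] <- E[i, ] + E[j, ]
    E[, i] <- E[, i] + E[, j]
    E[j, ] <- 0; E[, j] <- 0
    a[i] <- a[i] + a[j]; a[j] <- 0
    active[j] <- FALSE
    comm[comm == j] <- i
    if (Q > best_Q + 1e-12) { best_Q <- Q; best_comm <- comm }
  }
  memb <- stats::setNames(match(best_comm, unique(best_comm)) - 1L, vnames)
  structure(list(membership = memb,
                 n_modules = length(unique(memb)),
                 modularity = best_Q),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("<module_partition> %d modules, Q = %.4f\n",
              x$n_modules, x$modularity))
  invisible(x)
}

#' Modularity of a partition
#'
#' `Q = sum over communities c of (e_cc - a_c^2)` where `e_cc` is the
#' fraction of edge ends inside c and `a_c` the fraction of edge ends
#' attached to c. Unweighted by default.
#'
#' @param g an undirected igraph graph.
#' @param membership named vector (vertex name -> module id) covering every
#'   vertex of `g`, or a `module_partition`.
#' @param weighted use edge weights.
#' @return modularity Q in `[-0.5, 1]`; 0 for an edgeless graph.
#' @export
modularity_q <- function(g, membership, weighted = FALSE) {
  stopifnot(igraph::is_igraph(g))
  if (inherits(membership, "module_partition"))
    membership <- membership$membership
  vnames <- igraph::V(g)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(g)))
  miss <- setdiff(vnames, names(membership))
  if (length(miss))
    stop("vertices missing from partition: ", paste(miss, collapse = ", "))
  if (igraph::ecount(g) == 0L) return(0)
  w <- if (weighted) igraph::E(g)$weight else rep(1, igraph::ecount(g))
  m <- sum(w)
  el <- igraph::as_edgelist(g, names = TRUE)
  ci <- membership[el[, 1L]]; cj <- membership[el[, 2L]]
  within <- tapply(w[ci == cj], ci[ci == cj], sum)
  deg <- tapply(c(w, w), membership[c(el[, 1L], el[, 2L])], sum)
  e_cc <- stats::setNames(rep(0, length(deg)), names(deg))
  e_cc[names(within)] <- within / m
  a_c <- deg / (2 * m)
  sum(e_cc - a_c^2)
}

#' Write a partition as TSV (taxon, module_id)
#' @param partition a `module_partition`.
#' @param path output file.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "module_partition"))
  write_tsv(data.frame(taxon = names(partition$membership),
                       module_id = unname(partition$membership)), path)
  invisible(path)
}
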