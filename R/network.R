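# Co-occurrence graph construction and the node-/network-level metrics the
# keystone filter and network summaries rely on. Graphs are igraph objects;
# centralities follow fixed normalizations so the keystone thresholds are
# meaningful on any network size.

#' Build a co-occurrence network from a correlation set
#'
#' An edge joins taxa i and j iff `p_adj < alpha` and `|rho| >= threshold`
#' (and `rho > 0` when `positive_only`, the default: the networks modelled
#' here keep significant positive correlations only). Edge weight is `|rho|`;
#' the sign is kept as an edge attribute. Taxa with no retained edge are
#' excluded from the node set by default, so node counts are edge-defined.
#'
#' @param cs a `correlation_set` with `p_adj` filled (see [adjust_fdr()]).
#' @param threshold correlation-magnitude cutoff in (0, 1).
#' @param alpha significance level for the adjusted p-value, in (0, 1).
#' @param positive_only keep only positive correlations (default TRUE).
#' @param taxonomy optional taxonomy data frame; adds a `phylum` vertex
#'   attribute (missing taxa labelled "Unclassified").
#' @param mean_rel_abund optional named vector of mean relative abundances;
#'   added as a vertex attribute.
#' @param include_isolates if TRUE, all taxa in `cs` become vertices even
#'   without edges.
#' @return an undirected igraph graph with vertex attribute `name` (taxon id)
#'   and edge attributes `weight` (= |rho|), `rho`, `sign`.
#' @export
build_network <- function(cs, threshold, alpha = 0.01, positive_only = TRUE,
                          taxonomy = NULL, mean_rel_abund = NULL,
                          include_isolates = FALSE) {
  stopifnot(inherits(cs, "correlation_set"),
            threshold > 0, threshold < 1, alpha > 0, alpha < 1)
  if (anyNA(cs$p_adj)) stop("p_adj not populated; run adjust_fdr() first")
  keep <- cs$p_adj < alpha & abs(cs$rho) >= threshold
  if (positive_only) keep <- keep & cs$rho > 0
  ed <- cs[keep, , drop = FALSE]
  if (nrow(ed) == 0L) warning("no edges pass both gates; returning empty network")
  vnames <- if (include_isolates) sort(unique(c(cs$taxon_i, cs$taxon_j)))
            else sort(unique(c(ed$taxon_i, ed$taxon_j)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed$taxon_i, to = ed$taxon_j,
               weight = abs(ed$rho), rho = ed$rho,
               sign = ifelse(ed$rho >= 0, 1L, -1L)),
    directed = FALSE,
    vertices = data.frame(name = vnames))
  if (!is.null(taxonomy))
    igraph::V(g)$phylum <- phylum_of(igraph::V(g)$name, taxonomy)
  if (!is.null(mean_rel_abund))
    igraph::V(g)$mean_rel_abund <-
      unname(mean_rel_abund[igraph::V(g)$name])
  g
}

#' Component-scaled closeness centrality
#'
#' Unweighted shortest-path closeness with Wasserman-Faust scaling, defined
#' per vertex v in a component of size r within a graph of n vertices as
#' `((r - 1) / (n - 1)) * ((r - 1) / sum of distances from v within its
#' component)`. Isolated vertices score 0. Values lie in `[0, 1]` and remain
#' comparable across disconnected graphs.
#'
#' @param g an igraph graph.
#' @return named numeric vector.
#' @export
closeness_wf <- function(g) {
  n <- igraph::vcount(g)
  out <- stats::setNames(numeric(n), igraph::V(g)$name)
  if (n <= 1L) return(out)
  d <- igraph::distances(g, weights = NA)
  for (v in seq_len(n)) {
    dv <- d[v, -v]
    reach <- dv[is.finite(dv)]
    r <- length(reach) + 1L
    if (r >= 2L)
      out[v] <- ((r - 1) / (n - 1)) * ((r - 1) / sum(reach))
  }
  out
}

#' Normalized betweenness centrality
#'
#' Unweighted shortest-path betweenness (Brandes), normalized by
#' `2 / ((n - 1)(n - 2))` for undirected graphs so values lie in `[0, 1]`.
#' Graphs with fewer than 3 vertices return all zeros.
#'
#' @param g an igraph graph.
#' @return named numeric vector.
#' @export
betweenness_norm <- function(g) {
  n <- igraph::vcount(g)
  if (n < 3L) return(stats::setNames(numeric(n), igraph::V(g)$name))
  igraph::betweenness(g, weights = NA, normalized = TRUE)
}

#' Local clustering coefficients
#'
#' `cc(v) = 2 * triangles(v) / (k(v) * (k(v) - 1))`, zero for degree < 2.
#'
#' @param g an igraph graph.
#' @return named numeric vector.
#' @export
local_clustering <- function(g) {
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  stats::setNames(cc, igraph::V(g)$name)
}

#' Per-node metrics table
#'
#' Degree, weighted degree (strength: sum of incident `|rho|` weights),
#' component-scaled closeness, normalized betweenness, local clustering
#' coefficient and, when a partition is supplied, the module id.
#'
#' @param g a co-occurrence network from [build_network()].
#' @param partition optional partition from [fast_greedy_modules()] (or a
#'   named membership vector).
#' @return data frame, one row per vertex.
#' @export
node_metrics <- function(g, partition = NULL) {
  nm <- data.frame(
    taxon = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    weighted_degree = igraph::strength(g),
    closeness = closeness_wf(g),
    betweenness = betweenness_norm(g),
    clustering = local_clustering(g),
    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(partition)) {
    memb <- if (inherits(partition, "module_partition")) partition$membership
            else partition
    nm$module <- unname(memb[nm$taxon])
  }
  if (!is.null(igraph::V(g)$phylum)) nm$phylum <- igraph::V(g)$phylum
  if (!is.null(igraph::V(g)$mean_rel_abund))
    nm$mean_rel_abund <- igraph::V(g)$mean_rel_abund
  nm
}

#' Network-level summary
#'
#' Reports node and edge counts, the average weighted degree (mean over nodes
#' of the sum of incident `|rho|` weights, equal to `2 * sum(weights) / n`),
#' the network clustering coefficient (mean of local clustering over all
#' nodes; global transitivity is also reported for reference) and, when a
#' partition is supplied, its modularity Q.
#'
#' @param g a co-occurrence network.
#' @param partition optional partition (see [node_metrics()]).
#' @return a `network_summary` list.
#' @export
summarize_network <- function(g, partition = NULL) {
  n <- igraph::vcount(g)
  out <- list(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    average_weighted_degree = if (n) mean(igraph::strength(g)) else 0,
    clustering_coefficient = if (n) mean(local_clustering(g)) else 0,
    transitivity = if (n) igraph::transitivity(g, type = "global") else NA_real_,
    modularity = NA_real_,
    n_modules = NA_integer_)
  if (!is.null(partition)) {
    memb <- if (inherits(partition, "module_partition")) partition$membership
            else partition
    out$modularity <- modularity_q(g, memb)
    out$n_modules <- length(unique(memb))
  }
  structure(out, class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("<network_summary> %d nodes, %d edges, ",
                     "avg weighted degree %.3f, clustering %.3f"),
              x$n_nodes, x$n_edges, x$average_weighted_degree,
              x$clustering_coefficient))
  if (!is.na(x$modularity))
    cat(sprintf(", modularity %.3f (%d modules)", x$modularity, x$n_modules))
  cat("\n")
  invisible(x)
}
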