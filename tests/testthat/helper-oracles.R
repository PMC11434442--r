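# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and igraph) wherever the quantity can
# be computed from first principles on small inputs.

# textbook Spearman for tie-free data: 1 - 6*sum(d^2)/(n(n^2-1))
oracle_spearman_tiefree <- function(x, y) {
  stopifnot(!anyDuplicated(x), !anyDuplicated(y))
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# random symmetric 0/1 adjacency with optional weights
rand_adj <- function(n, p, weights = FALSE) {
  a <- matrix(0, n, n)
  up <- which(upper.tri(a))
  a[up] <- as.numeric(stats::runif(length(up)) < p)
  if (weights) a[up] <- a[up] * stats::runif(length(up), 0.5, 1)
  a <- a + t(a)
  dimnames(a) <- list(paste0("v", seq_len(n)), paste0("v", seq_len(n)))
  a
}

adj_to_graph <- function(a) {
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE)
  g
}

# all-pairs shortest-path distances, Floyd-Warshall on the unweighted graph
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_closeness_wf <- function(a) {
  n <- nrow(a)
  d <- oracle_distances(a)
  vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    reach <- dv[is.finite(dv)]
    if (!length(reach)) return(0)
    r <- length(reach) + 1
    ((r - 1) / (n - 1)) * ((r - 1) / sum(reach))
  }, numeric(1))
}

# geodesic counts via matrix powers: the number of walks of minimal length
# equals the number of shortest paths
oracle_betweenness <- function(a) {
  n <- nrow(a)
  if (n < 3) return(numeric(n))
  b <- matrix(as.numeric(a > 0), n, n)
  d <- oracle_distances(a)
  maxd <- max(d[is.finite(d)])
  pows <- list(diag(n), b)
  for (k in seq_len(max(0, maxd - 1))) pows[[k + 2]] <- pows[[k + 1]] %*% b
  sigma <- function(i, j) if (is.finite(d[i, j])) pows[[d[i, j] + 1]][i, j] else 0
  bc <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(d[s, t])) next
    st <- sigma(s, t)
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
          d[s, v] + d[v, t] == d[s, t])
        bc[v] <- bc[v] + sigma(s, v) * sigma(v, t) / st
    }
  }
  bc * 2 / ((n - 1) * (n - 2))
}

oracle_local_cc <- function(a) {
  n <- nrow(a)
  b <- (a > 0) * 1
  vapply(seq_len(n), function(v) {
    nb <- which(b[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- sum(b[nb, nb]) / 2
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# modularity via the pairwise formula (1/2m) sum_ij (A_ij - k_i k_j / 2m) d(ci,cj)
oracle_modularity_pairwise <- function(a, memb, weighted = FALSE) {
  b <- if (weighted) a else (a > 0) * 1
  m2 <- sum(b)
  if (m2 == 0) return(0)
  k <- rowSums(b)
  q <- 0
  n <- nrow(b)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (memb[i] == memb[j]) q <- q + b[i, j] - k[i] * k[j] / m2
  unname(q) / m2
}

# all set partitions of 1..n via restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (id in seq_len(maxid + 1L)) rec(c(prefix, id), max(maxid, id))
  }
  rec(integer(0), 0L)
  out
}

oracle_best_modularity <- function(a) {
  parts <- all_partitions(nrow(a))
  best <- -Inf
  for (p in parts) {
    q <- oracle_modularity_pairwise(a, p)
    if (q > best) best <- q
  }
  best
}

# brute-force two-way balanced ANOVA via R's own fitter (Type I = Type III
# here because the design is balanced)
oracle_anova_two_way <- function(values, A, B) {
  df <- data.frame(y = values, A = factor(A), B = factor(B))
  as.data.frame(stats::anova(stats::aov(y ~ A * B, data = df)))
}

# adjacency of two k-cliques joined by a single bridge edge
two_cliques_bridge <- function(k = 4) {
  n <- 2 * k
  a <- matrix(0, n, n)
  a[1:k, 1:k] <- 1
  a[(k + 1):n, (k + 1):n] <- 1
  diag(a) <- 0
  a[k, k + 1] <- a[k + 1, k] <- 1
  dimnames(a) <- list(paste0("v", 1:n), paste0("v", 1:n))
  a
}

# correlation_set built directly from a data frame (bypasses spearman code)
fake_cs <- function(df) {
  df$p_adj <- if (is.null(df$p_adj)) NA_real_ else df$p_adj
  df$n <- if (is.null(df$n)) 40L else df$n
  structure(df, class = c("correlation_set", "data.frame"))
}
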