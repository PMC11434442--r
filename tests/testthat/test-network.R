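# Network construction and node-/network-level metrics, checked against
# brute-force oracles.

test_that("build_network applies both gates plus the positivity gate", {
  cs <- fake_cs(data.frame(
    taxon_i = c("a", "a", "b"), taxon_j = c("b", "c", "c"),
    rho = c(0.9, 0.5, 0.95), p_raw = NA_real_,
    p_adj = c(0.001, 0.001, 0.5)))
  g <- build_network(cs, threshold = 0.7, alpha = 0.01)
  expect_equal(igraph::ecount(g), 1L)
  el <- igraph::as_edgelist(g)
  expect_setequal(el[1, ], c("a", "b"))

  neg <- fake_cs(data.frame(taxon_i = "a", taxon_j = "b", rho = -0.99,
                            p_raw = NA_real_, p_adj = 1e-6))
  expect_warning(g0 <- build_network(neg, threshold = 0.7), "no edges")
  expect_equal(igraph::ecount(g0), 0L)
  gneg <- build_network(neg, threshold = 0.7, positive_only = FALSE)
  expect_equal(igraph::ecount(gneg), 1L)
  expect_equal(igraph::E(gneg)$weight, 0.99)
})

test_that("edges at any threshold are a subset of edges near threshold zero", {
  set.seed(71)
  pairs <- t(combn(paste0("t", 1:12), 2))
  cs <- fake_cs(data.frame(taxon_i = pairs[, 1], taxon_j = pairs[, 2],
                           rho = runif(nrow(pairs), -1, 1), p_raw = NA_real_,
                           p_adj = runif(nrow(pairs))))
  all_g <- suppressWarnings(build_network(cs, threshold = 1e-9, alpha = 0.5))
  g <- suppressWarnings(build_network(cs, threshold = 0.6, alpha = 0.5))
  eid <- function(gr) apply(igraph::as_edgelist(gr), 1,
                            function(r) paste(sort(r), collapse = "|"))
  expect_true(all(eid(g) %in% eid(all_g)))
})

test_that("degree and weighted degree match hand values and oracles", {
  cs <- fake_cs(data.frame(taxon_i = c("a", "a", "b"),
                           taxon_j = c("b", "c", "c"),
                           rho = c(0.8, 0.9, 0.7), p_raw = NA_real_,
                           p_adj = c(0, 0, 0)))
  g <- build_network(cs, threshold = 0.5)
  nm <- node_metrics(g)
  a <- nm[nm$taxon == "a", ]
  expect_equal(a$degree, 2L)
  expect_equal(a$weighted_degree, 1.7)
  set.seed(72)
  adj <- rand_adj(10, 0.4, weights = TRUE)
  g2 <- adj_to_graph(adj)
  nm2 <- node_metrics(g2)
  expect_equal(nm2$degree, unname(rowSums(adj > 0)[nm2$taxon]))
  expect_equal(nm2$weighted_degree, unname(rowSums(adj)[nm2$taxon]),
               tolerance = 1e-12)
})

test_that("closeness follows Wasserman-Faust component scaling", {
  path3 <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  path3["a", "b"] <- path3["b", "a"] <- 1
  path3["b", "c"] <- path3["c", "b"] <- 1
  cl <- closeness_wf(adj_to_graph(path3))
  expect_equal(cl[["b"]], 1)
  expect_equal(cl[["a"]], 2 / 3)
  star <- matrix(0, 5, 5, dimnames = rep(list(paste0("v", 1:5)), 2))
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(closeness_wf(adj_to_graph(star))[["v1"]], 1)
  # isolated vertex scores zero
  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("x", "y")
  expect_equal(unname(closeness_wf(iso)), c(0, 0))
})

test_that("betweenness matches hand values and the path-count oracle", {
  path3 <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  path3["a", "b"] <- path3["b", "a"] <- 1
  path3["b", "c"] <- path3["c", "b"] <- 1
  expect_equal(betweenness_norm(adj_to_graph(path3))[["b"]], 1)
  k4 <- matrix(1, 4, 4, dimnames = rep(list(paste0("v", 1:4)), 2)); diag(k4) <- 0
  expect_equal(unname(betweenness_norm(adj_to_graph(k4))), rep(0, 4))
  set.seed(73)
  adj <- rand_adj(8, 0.5)
  got <- betweenness_norm(adj_to_graph(adj))
  expect_equal(unname(got[rownames(adj)]), oracle_betweenness(adj),
               tolerance = 1e-9)
})

test_that("local clustering matches triangle counting", {
  tri <- matrix(1, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2)); diag(tri) <- 0
  expect_equal(unname(local_clustering(adj_to_graph(tri))), rep(1, 3))
  star <- matrix(0, 5, 5, dimnames = rep(list(paste0("v", 1:5)), 2))
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(unname(local_clustering(adj_to_graph(star))), rep(0, 5))
  set.seed(74)
  adj <- rand_adj(10, 0.5)
  got <- local_clustering(adj_to_graph(adj))
  expect_equal(unname(got[rownames(adj)]), oracle_local_cc(adj),
               tolerance = 1e-12)
})

test_that("summarize_network reports the five fields with the handshake identity", {
  tri <- fake_cs(data.frame(taxon_i = c("a", "a", "b"),
                            taxon_j = c("b", "c", "c"),
                            rho = c(1, 1, 1) * 0.999, p_raw = NA_real_,
                            p_adj = c(0, 0, 0)))
  g <- build_network(tri, threshold = 0.5)
  igraph::E(g)$weight <- 1
  s <- summarize_network(g)
  expect_equal(s$n_nodes, 3L); expect_equal(s$n_edges, 3L)
  expect_equal(s$average_weighted_degree, 2)
  two <- fake_cs(data.frame(taxon_i = c("a", "c"), taxon_j = c("b", "d"),
                            rho = c(0.8, 0.6), p_raw = NA_real_, p_adj = c(0, 0)))
  g2 <- build_network(two, threshold = 0.5)
  expect_equal(summarize_network(g2)$average_weighted_degree, 0.7)
  set.seed(75)
  adj <- rand_adj(9, 0.4, weights = TRUE)
  g3 <- adj_to_graph(adj)
  s3 <- summarize_network(g3)
  expect_equal(s3$average_weighted_degree * s3$n_nodes,
               2 * sum(igraph::E(g3)$weight), tolerance = 1e-9)
})

test_that("metrics are invariant under node relabeling", {
  set.seed(76)
  adj <- rand_adj(8, 0.45)
  g <- adj_to_graph(adj)
  perm <- sample(rownames(adj))
  adj2 <- adj[perm, perm]
  g2 <- adj_to_graph(adj2)
  for (f in list(closeness_wf, betweenness_norm, local_clustering)) {
    m1 <- f(g); m2 <- f(g2)
    expect_equal(m1[sort(names(m1))], m2[sort(names(m2))], tolerance = 1e-12)
  }
})

test_that("removing an edge never increases degree, strength or triangles", {
  set.seed(77)
  adj <- rand_adj(10, 0.5, weights = TRUE)
  g <- adj_to_graph(adj)
  for (rep in 1:5) {
    e <- sample(igraph::ecount(g), 1)
    g2 <- igraph::delete_edges(g, e)
    expect_true(all(igraph::degree(g2) <= igraph::degree(g)))
    expect_true(all(igraph::strength(g2) <= igraph::strength(g) + 1e-12))
    expect_true(all(igraph::count_triangles(g2) <= igraph::count_triangles(g)))
  }
})
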