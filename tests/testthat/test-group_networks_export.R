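# Phylum shares, chord matrices, GEXF round trips and the orchestrated
# pipeline.

labeled_graph <- function(adj, phyla) {
  g <- adj_to_graph(adj)
  igraph::V(g)$phylum <- phyla[igraph::V(g)$name]
  g
}

test_that("phylum shares follow the endpoint-fraction definition", {
  tri <- matrix(1, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2)); diag(tri) <- 0
  ps <- phylum_shares(labeled_graph(tri, c(a = "P", b = "P", c = "P")))
  expect_equal(unname(ps$shares), 1)
  expect_equal(ps$matrix["P", "P"], 3)

  one <- matrix(0, 2, 2, dimnames = rep(list(c("a", "b")), 2))
  one["a", "b"] <- one["b", "a"] <- 1
  ps2 <- phylum_shares(labeled_graph(one, c(a = "P", b = "Q")))
  expect_equal(unname(ps2$shares[c("P", "Q")]), c(0.5, 0.5))
  expect_equal(ps2$matrix["P", "Q"], 1)
})

test_that("shares match a brute-force endpoint tally and sum to 1", {
  set.seed(101)
  adj <- rand_adj(12, 0.4)
  phyla <- setNames(sample(paste0("P", 1:4), 12, TRUE), rownames(adj))
  ps <- phylum_shares(labeled_graph(adj, phyla))
  expect_equal(sum(ps$shares), 1, tolerance = 1e-9)
  tally <- setNames(rep(0, 4), paste0("P", 1:4))
  m <- 0
  for (i in 1:11) for (j in (i + 1):12) if (adj[i, j] > 0) {
    tally[phyla[rownames(adj)[i]]] <- tally[phyla[rownames(adj)[i]]] + 1
    tally[phyla[rownames(adj)[j]]] <- tally[phyla[rownames(adj)[j]]] + 1
    m <- m + 1
  }
  tally <- tally / (2 * m)
  expect_equal(ps$shares[order(names(ps$shares))],
               tally[order(names(tally))][names(tally[order(names(tally))]) %in%
                                            names(ps$shares)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(phylum_matrix_total(ps), m)
})

test_that("chord matrices keep top-k phyla, aggregate the rest, conserve totals", {
  set.seed(102)
  n <- 40
  adj <- rand_adj(n, 0.3)
  phyla <- setNames(sample(paste0("P", sprintf("%02d", 1:12)), n, TRUE),
                    rownames(adj))
  g <- labeled_graph(adj, phyla)
  ps <- phylum_shares(g)
  ch <- chord_matrix(g, top_k = 10)
  expect_true("Other" %in% rownames(ch$matrix))
  expect_equal(phylum_matrix_total(ch), phylum_matrix_total(ps))
  expect_equal(sum(ch$shares), 1, tolerance = 1e-9)
  # ranking consistent with descending shares
  topk <- setdiff(rownames(ch$matrix), "Other")
  expect_setequal(topk, names(sort(ps$shares, decreasing = TRUE))[1:10])
  # few phyla: no aggregation
  small <- chord_matrix(labeled_graph(adj, setNames(rep(c("A", "B", "C"),
                                                        length.out = n),
                                                    rownames(adj))),
                        top_k = 10)
  expect_false("Other" %in% rownames(small$matrix))
})

test_that("GEXF export round-trips structure and attributes", {
  set.seed(103)
  adj <- rand_adj(7, 0.5, weights = TRUE)
  g <- adj_to_graph(adj)
  igraph::V(g)$phylum <- sample(c("P1", "P2"), 7, TRUE)
  p <- fast_greedy_modules(g)
  f <- withr::local_tempfile(fileext = ".gexf")
  export_gexf(g, f, p)
  back <- read_gexf(f)
  expect_equal(nrow(back$nodes), igraph::vcount(g))
  expect_equal(nrow(back$edges), igraph::ecount(g))
  nm <- node_metrics(g, p)
  ord <- match(nm$taxon, back$nodes$id)
  expect_equal(back$nodes$degree[ord], as.numeric(nm$degree))
  for (col in c("weighted_degree", "closeness", "betweenness", "clustering"))
    expect_equal(back$nodes[[col]][ord], nm[[col]],
                 tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(back$nodes$phylum[ord], igraph::V(g)$phylum)
  # empty graph still produces valid GEXF
  g0 <- igraph::make_empty_graph(0, directed = FALSE)
  f0 <- withr::local_tempfile(fileext = ".gexf")
  export_gexf(g0, f0)
  back0 <- read_gexf(f0)
  expect_equal(nrow(back0$nodes), 0L)
  expect_equal(nrow(back0$edges), 0L)
})

test_that("the pipeline runs one stratum when restricted, deterministically", {
  d <- generate_synthetic(preset_paper_like(seed = 5, samples_per_stratum = 20))
  one <- list(list(label = "unfertilized_wild", fertilization = "unfertilized",
                   domestication = "wild", combined = FALSE))
  res <- suppressMessages(suppressWarnings(
    run_pipeline(d$abundance, d$taxonomy, d$metadata, strata = one)))
  expect_equal(names(res$strata), "unfertilized_wild")
  expect_equal(nrow(res$manifest), 1L)

  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  res1 <- suppressMessages(suppressWarnings(
    run_pipeline(d$abundance, d$taxonomy, d$metadata, strata = one,
                 out_dir = dir1)))
  res2 <- suppressMessages(suppressWarnings(
    run_pipeline(d$abundance, d$taxonomy, d$metadata, strata = one,
                 out_dir = dir2)))
  j1 <- file.path(dir1, "unfertilized_wild_summary.json")
  j2 <- file.path(dir2, "unfertilized_wild_summary.json")
  expect_identical(readLines(j1), readLines(j2)) # byte-identical rerun
  expect_true(file.exists(file.path(dir1, "unfertilized_wild.gexf")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
})

test_that("stage counts are monotone through the pipeline", {
  d <- generate_synthetic(preset_paper_like(seed = 6, samples_per_stratum = 20))
  res <- suppressMessages(suppressWarnings(
    run_pipeline(d$abundance, d$taxonomy, d$metadata)))
  mf <- res$manifest
  expect_true(all(mf$n_taxa <= mf$n_taxa_raw))
  expect_true(all(mf$n_samples <= mf$n_samples_raw))
  expect_true(all(mf$n_edges <= mf$n_significant))
  expect_true(all(mf$n_nodes <= mf$n_taxa))
})

test_that("undersized strata are skipped with a warning", {
  d <- generate_synthetic(synth_spec(n_taxa = 40, samples_per_stratum = 5,
                                     seed = 9))
  wild_unf <- d$metadata$sample_id[d$metadata$domestication == "wild" &
                                     d$metadata$fertilization == "unfertilized"]
  sub <- abundance_table(unclass(d$abundance)[
    setdiff(rownames(d$abundance), wild_unf[1:3]), ]) # leaves only 2 samples
  one <- list(list(label = "unfertilized_wild", fertilization = "unfertilized",
                   domestication = "wild", combined = FALSE))
  expect_warning(
    res <- suppressMessages(run_pipeline(sub, d$taxonomy, d$metadata,
                                         strata = one)),
    "skipped")
  expect_equal(length(res$strata), 0L)
})
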