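# Keystone filter, functional classification, and the group statistics.

metric_row <- function(taxon = "t1", degree = 7, wdeg = 6.5, clo = 0.2,
                       bet = 0.01, cc = 0.1) {
  data.frame(taxon = taxon, degree = degree, weighted_degree = wdeg,
             closeness = clo, betweenness = bet, clustering = cc,
             stringsAsFactors = FALSE)
}

test_that("the five-criterion filter is strict in all directions", {
  expect_equal(nrow(identify_keystones(metric_row())), 1L)
  expect_equal(nrow(identify_keystones(metric_row(degree = 6))), 0L)
  expect_equal(nrow(identify_keystones(metric_row(wdeg = 6))), 0L)
  expect_equal(nrow(identify_keystones(metric_row(clo = 0.14))), 0L)
  expect_equal(nrow(identify_keystones(metric_row(cc = 0.09))), 0L)
  expect_equal(nrow(identify_keystones(metric_row(bet = 0.05))), 0L)
  expect_error(identify_keystones(metric_row(bet = NA)), "missing betweenness.*t1")
})

test_that("keystone selection equals the brute-force filter and is monotone", {
  set.seed(91)
  m <- data.frame(taxon = paste0("t", 1:100),
                  degree = sample(0:15, 100, TRUE),
                  weighted_degree = runif(100, 0, 12),
                  closeness = runif(100), betweenness = runif(100, 0, 0.2),
                  clustering = runif(100), stringsAsFactors = FALSE)
  k <- keystone_criteria()
  got <- identify_keystones(m, k)$taxon
  expected <- character(0)
  for (i in seq_len(nrow(m))) {
    if (m$degree[i] > 6 && m$weighted_degree[i] > 6 && m$closeness[i] > 0.14 &&
        m$clustering[i] > 0.09 && m$betweenness[i] < 0.05)
      expected <- c(expected, m$taxon[i])
  }
  expect_equal(got, expected)
  # relaxing any threshold never removes a keystone
  relaxed <- identify_keystones(m, keystone_criteria(min_degree = 3,
                                                     max_betweenness = 0.1))$taxon
  expect_true(all(got %in% relaxed))
})

test_that("functional classification follows the EC catalog", {
  cat9 <- default_function_catalog()
  expect_equal(length(unique(cat9$category)), 9L)
  ecs <- unique(cat9$ec)
  gp <- matrix(0, 3, length(ecs),
               dimnames = list(c("tA", "tB", "tC"), ecs))
  gp["tA", "3.1.3.1"] <- 2
  gp["tB", c("3.2.1.20", "3.5.1.5")] <- 1
  got <- classify_functions(c("tA", "tB", "tC"), gp)
  expect_equal(got$tA, "P decomposition")
  expect_setequal(got$tB, c("C decomposition", "N decomposition"))
  expect_equal(got$tC, character(0))
  expect_warning(out <- classify_functions("tZ", gp), "absent")
  expect_equal(out$tZ, character(0))
  bad <- data.frame(category = "x", enzyme = "y", ec = "9.9.9.9")
  expect_error(classify_functions("tA", gp, bad), "absent from gene-presence")
})

test_that("keystone abundance summaries match hand arithmetic", {
  counts <- matrix(c(10, 90, 30, 70, 20, 80, 50, 50), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), c("k1", "other")))
  at <- abundance_table(counts)
  meta <- sample_metadata(data.frame(
    sample_id = paste0("s", 1:4),
    domestication = c("wild", "wild", "modern", "modern"),
    fertilization = "unfertilized"))
  res <- keystone_abundance_by_group(at, meta, "k1")
  wild <- res$summary[res$summary$group == "wild", ]
  expect_equal(wild$mean, 0.2)
  expect_equal(wild$se, 0.1)
  # no keystones -> zeros; all taxa -> closure at 1
  none <- keystone_abundance_by_group(at, meta, character(0))
  expect_equal(none$per_sample$value, rep(0, 4))
  all_tx <- keystone_abundance_by_group(at, meta, c("k1", "other"))
  expect_equal(all_tx$per_sample$value, rep(1, 4))
  expect_true(all(res$per_sample$value >= 0 & res$per_sample$value <= 1))
  # group of one sample has no SE
  meta1 <- meta; meta1$domestication <- factor(
    c("wild", "modern", "modern", "modern"),
    levels = levels(meta$domestication))
  expect_error(keystone_abundance_by_group(at, meta1, "k1"), "SE undefined")
})

test_that("identical groups share a letter; separated groups do not", {
  meta <- data.frame(domestication = rep(c("wild", "modern"), each = 3))
  r1 <- anova_tukey(c(1, 2, 3, 1, 2, 3), meta, design = "one-way")
  expect_lt(r1$anova$F[1], 1e-10)
  expect_gt(r1$anova$p[1], 0.999)
  expect_equal(r1$letters[["wild"]], r1$letters[["modern"]])
  set.seed(92)
  y <- c(rnorm(3, 0, 1e-3), rnorm(3, 10, 1e-3))
  r2 <- anova_tukey(y, meta, design = "one-way")
  expect_lt(r2$tukey$p_adj[1], 1e-6)
  expect_false(r2$letters[["wild"]] == r2$letters[["modern"]])
})

test_that("two-way F statistics match the reference decomposition on balanced data", {
  set.seed(93)
  meta <- expand.grid(domestication = c("wild", "traditional", "modern"),
                      fertilization = c("unfertilized", "fertilized"),
                      rep = 1:5, stringsAsFactors = FALSE)
  y <- 0.1 * as.numeric(factor(meta$domestication)) +
    0.3 * (meta$fertilization == "fertilized") + rnorm(nrow(meta), sd = 0.2)
  got <- anova_tukey(y, meta, design = "two-way")
  ref <- oracle_anova_two_way(y, meta$domestication, meta$fertilization)
  expect_equal(got$anova$F[1:3], ref[["F value"]][1:3], tolerance = 1e-9)
  expect_equal(got$anova$p[1:3], ref[["Pr(>F)"]][1:3], tolerance = 1e-9)
  expect_equal(got$anova$ss, ref[["Sum Sq"]], tolerance = 1e-9)
  # Tukey p-values agree with R's TukeyHSD on the one-way layout
  r1 <- anova_tukey(y, meta, design = "one-way")
  fit <- stats::aov(y ~ g, data = data.frame(y = y, g = factor(meta$domestication)))
  ref_tk <- as.data.frame(stats::TukeyHSD(fit)$g)
  key <- paste(r1$tukey$group_j, r1$tukey$group_i, sep = "-")
  expect_equal(r1$tukey$p_adj, ref_tk[key, "p adj"], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("unbalanced two-way designs fall back to one-way per factor", {
  meta <- data.frame(domestication = c("wild", "wild", "wild", "modern", "modern"),
                     fertilization = c("unfertilized", "unfertilized",
                                       "fertilized", "fertilized", "fertilized"))
  expect_warning(r <- anova_tukey(rnorm(5), meta), "unbalanced")
  expect_equal(r$design, "one-way-fallback")
  expect_equal(r$domestication$design, "one-way")
})

test_that("letter display agrees with pairwise significance", {
  set.seed(94)
  for (rep in 1:10) {
    k <- sample(3:5, 1)
    tk <- data.frame(t(combn(paste0("g", 1:k), 2)), stringsAsFactors = FALSE)
    names(tk) <- c("group_i", "group_j")
    tk$p_adj <- runif(nrow(tk))
    lt <- cld_letters(tk)
    for (r in seq_len(nrow(tk))) {
      shared <- any(strsplit(lt[[tk$group_i[r]]], "")[[1]] %in%
                      strsplit(lt[[tk$group_j[r]]], "")[[1]])
      expect_equal(shared, tk$p_adj[r] >= 0.05)
    }
  }
})
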