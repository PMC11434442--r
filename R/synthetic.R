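# Synthetic community generator: a latent-factor lognormal-multinomial model
# emulating species-level long-read profiles from a 3 (domestication) x 2
# (fertilization) factorial rhizosphere study. Planted modules give direct
# control of the pairwise rank correlations the Spearman pipeline should
# detect; hub taxa loading on module factors become planted keystones.

#' Stratum labels of the factorial design
#' @return character vector of the six fertilization x domestication labels.
#' @export
synth_strata <- function() {
  as.vector(outer(c("unfertilized", "fertilized"),
                  c("wild", "traditional", "modern"), paste, sep = "_"))
}

#' Specification for the synthetic generator
#'
#' Describes a community of `n_taxa` species spread over `n_phyla` phyla
#' (Dirichlet-distributed phylum sizes), sampled in six strata (3
#' domestication groups x 2 fertilization levels) with
#' `samples_per_stratum` samples each. Per sample, taxon log-abundances are
#' `baseline + loading * module_factor + sqrt(1 - loading^2) * noise`; reads
#' are drawn multinomially given a lognormal library size (median
#' `exp(library_meanlog)`, floored at `library_floor` to mirror the 10,000
#' read depth filter regime).
#'
#' @param n_taxa number of taxa (default 200).
#' @param n_phyla number of phyla (default 12).
#' @param samples_per_stratum samples per stratum (default 40, mirroring 4
#'   accessions x 10 replicates treated as one group).
#' @param library_meanlog,library_sdlog lognormal library-size parameters
#'   (median 30,000 by default).
#' @param library_floor minimum library size (default 10,000).
#' @param baseline_meanlog,baseline_sdlog lognormal baseline abundance
#'   spread across taxa.
#' @param member_baseline_boost added to the log-baseline of module members
#'   and hubs so planted taxa survive the 0.001 abundance filter.
#' @param modules list of module designs: each
#'   `list(size =, loading =, strata =, taxa = NULL)` with loading in (0, 1]
#'   and `strata` a subset of [synth_strata()]; `taxa` (integer indices) is
#'   normally auto-assigned.
#' @param hubs list of hub designs: each
#'   `list(attach_module =, loading =, strata =)`; the hub loads on the
#'   named module's factor, correlating with every member.
#' @param seed RNG seed.
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_taxa = 200L, n_phyla = 12L,
                       samples_per_stratum = 40L,
                       library_meanlog = log(30000), library_sdlog = 0.35,
                       library_floor = 10000L,
                       baseline_meanlog = 0, baseline_sdlog = 0.8,
                       member_baseline_boost = 1.5,
                       modules = list(), hubs = list(), seed = 1L) {
  for (m in modules) {
    stopifnot(m$loading > 0, m$loading <= 1, m$size >= 2,
              all(m$strata %in% synth_strata()))
  }
  for (h in hubs) {
    stopifnot(h$loading > 0, h$loading <= 1,
              h$attach_module >= 1, h$attach_module <= length(modules),
              all(h$strata %in% synth_strata()))
  }
  structure(list(n_taxa = n_taxa, n_phyla = n_phyla,
                 samples_per_stratum = samples_per_stratum,
                 library_meanlog = library_meanlog,
                 library_sdlog = library_sdlog,
                 library_floor = library_floor,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 member_baseline_boost = member_baseline_boost,
                 modules = modules, hubs = hubs, seed = seed),
            class = "synth_spec")
}

#' Paper-like preset: shared structure plus a planted density gradient
#'
#' Two "core" modules (20 taxa each, loading 0.95) and four hub taxa
#' (loading 0.9 on a core factor) are active in every stratum, so the
#' combined per-fertilization networks have stable structure and planted
#' keystones. Stratum-specific 10-taxon modules create the qualitative
#' density orderings the pipeline should recover: in unfertilized soil
#' wild < traditional < modern edge counts, in fertilized soil the wild
#' group is maximal (wild > modern > traditional).
#'
#' @param seed RNG seed (default 42).
#' @param samples_per_stratum samples per stratum (default 40).
#' @return a `synth_spec`.
#' @export
preset_paper_like <- function(seed = 42L, samples_per_stratum = 40L) {
  all6 <- synth_strata()
  extra <- function(stratum) list(size = 10L, loading = 0.95, strata = stratum)
  modules <- c(
    list(list(size = 20L, loading = 0.95, strata = all6),
         list(size = 20L, loading = 0.95, strata = all6)),
    replicate(1, extra("unfertilized_wild"), simplify = FALSE),
    replicate(2, extra("unfertilized_traditional"), simplify = FALSE),
    replicate(3, extra("unfertilized_modern"), simplify = FALSE),
    replicate(3, extra("fertilized_wild"), simplify = FALSE),
    replicate(1, extra("fertilized_traditional"), simplify = FALSE),
    replicate(2, extra("fertilized_modern"), simplify = FALSE))
  hubs <- list(
    list(attach_module = 1L, loading = 0.9, strata = all6),
    list(attach_module = 1L, loading = 0.9, strata = all6),
    list(attach_module = 2L, loading = 0.9, strata = all6),
    list(attach_module = 2L, loading = 0.9, strata = all6))
  synth_spec(modules = modules, hubs = hubs, seed = seed,
             samples_per_stratum = samples_per_stratum)
}

#' Generate a synthetic dataset
#'
#' @param spec a [synth_spec()].
#' @return list with `abundance` (an `abundance_table`, all strata),
#'   `taxonomy`, `metadata`, `gene_presence` (taxon x EC copy numbers) and
#'   `truth` (planted structure: module membership, hub taxa, per-stratum
#'   planted pairs and the implied density ordering).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_taxa
  taxa <- sprintf("t%03d", seq_len(n))

  # --- module / hub taxon assignment (disjoint) ---
  assigned <- integer(0)
  modules <- spec$modules
  cursor <- 1L
  for (k in seq_along(modules)) {
    if (is.null(modules[[k]]$taxa)) {
      modules[[k]]$taxa <- seq.int(cursor, cursor + modules[[k]]$size - 1L)
      cursor <- cursor + modules[[k]]$size
    }
    if (any(modules[[k]]$taxa %in% assigned))
      stop("module designs overlap: module ", k)
    assigned <- c(assigned, modules[[k]]$taxa)
  }
  hubs <- spec$hubs
  for (k in seq_along(hubs)) {
    hubs[[k]]$taxon <- cursor; cursor <- cursor + 1L
    if (hubs[[k]]$taxon %in% assigned) stop("hub overlaps a module")
    assigned <- c(assigned, hubs[[k]]$taxon)
  }
  if (cursor - 1L > n)
    stop(sprintf("design needs %d taxa but n_taxa = %d", cursor - 1L, n))

  # --- taxonomy: Dirichlet phylum sizes, shuffled assignment ---
  w <- stats::rgamma(spec$n_phyla, 1)
  sizes <- as.vector(stats::rmultinom(1, n - spec$n_phyla, w / sum(w))) + 1L
  phyla <- sample(rep(sprintf("Phylum%02d", seq_len(spec$n_phyla)), sizes))
  taxonomy <- data.frame(taxon_id = taxa, phylum = phyla,
                         species = paste0("sp_", taxa),
                         stringsAsFactors = FALSE)

  # --- metadata ---
  labels <- synth_strata()
  ns <- spec$samples_per_stratum
  meta <- do.call(rbind, lapply(labels, function(lab) {
    parts <- strsplit(lab, "_", fixed = TRUE)[[1]]
    data.frame(fertilization = parts[1], domestication = parts[2],
               replicate = seq_len(ns), stringsAsFactors = FALSE)
  }))
  meta$sample_id <- sprintf("s%03d", seq_len(nrow(meta)))
  meta <- sample_metadata(meta[, c("sample_id", "domestication",
                                   "fertilization", "replicate")])

  # --- baselines; planted taxa are drawn from the abundant half of the
  # community (truncated at the median) so the 0.001 abundance filter cannot
  # silently delete planted structure ---
  b <- stats::rnorm(n, spec$baseline_meanlog, spec$baseline_sdlog)
  b[assigned] <- pmax(b[assigned], spec$baseline_meanlog) +
    spec$member_baseline_boost

  # --- latent log-abundances, stratum by stratum ---
  z <- matrix(0, nrow(meta), n, dimnames = list(meta$sample_id, taxa))
  stratum_of <- paste(meta$fertilization, meta$domestication, sep = "_")
  for (lab in labels) {
    rows <- which(stratum_of == lab)
    eps <- matrix(stats::rnorm(length(rows) * n), length(rows), n)
    zb <- sweep(eps, 2L, b, `+`)
    factors <- list()
    for (k in seq_along(modules)) {
      f <- stats::rnorm(length(rows)) # drawn always, for RNG-stream stability
      factors[[k]] <- f
      if (!(lab %in% modules[[k]]$strata)) next
      lam <- modules[[k]]$loading
      mem <- modules[[k]]$taxa
      zb[, mem] <- matrix(b[mem], length(rows), length(mem), byrow = TRUE) +
        lam * f + sqrt(1 - lam^2) * eps[, mem, drop = FALSE]
    }
    for (k in seq_along(hubs)) {
      hk <- hubs[[k]]
      if (!(lab %in% hk$strata)) next
      if (!(lab %in% modules[[hk$attach_module]]$strata)) next
      lam <- hk$loading
      zb[, hk$taxon] <- b[hk$taxon] + lam * factors[[hk$attach_module]] +
        sqrt(1 - lam^2) * eps[, hk$taxon]
    }
    z[rows, ] <- zb
  }

  # --- multinomial counts ---
  lib <- pmax(spec$library_floor,
              round(stats::rlnorm(nrow(meta), spec$library_meanlog,
                                  spec$library_sdlog)))
  counts <- matrix(0, nrow(meta), n, dimnames = list(meta$sample_id, taxa))
  for (i in seq_len(nrow(meta))) {
    p <- exp(z[i, ] - max(z[i, ]))
    counts[i, ] <- stats::rmultinom(1, lib[i], p / sum(p))
  }
  abundance <- abundance_table(counts)

  # --- gene presence: every functional category gets >= 3 carriers ---
  catalog <- default_function_catalog()
  ecs <- unique(catalog$ec)
  gp <- matrix(stats::rbinom(n * length(ecs), 1, 0.2) *
                 (1L + stats::rpois(n * length(ecs), 1)),
               n, length(ecs), dimnames = list(taxa, ecs))
  for (cat in unique(catalog$category)) {
    cat_ecs <- catalog$ec[catalog$category == cat]
    carriers <- rowSums(gp[, cat_ecs, drop = FALSE] >= 1) > 0
    need <- 3L - sum(carriers)
    if (need > 0L)
      gp[which(!carriers)[seq_len(need)], cat_ecs[1L]] <- 1L
  }

  # --- ground truth ---
  membership <- integer(0)
  planted <- list()
  for (k in seq_along(modules)) {
    mem <- taxa[modules[[k]]$taxa]
    membership[mem] <- k
    prs <- utils::combn(mem, 2L)
    for (lab in modules[[k]]$strata)
      planted[[length(planted) + 1L]] <-
        data.frame(stratum = lab, taxon_i = prs[1L, ], taxon_j = prs[2L, ],
                   stringsAsFactors = FALSE)
  }
  planted_pairs <- if (length(planted)) do.call(rbind, planted)
                   else data.frame(stratum = character(0),
                                   taxon_i = character(0),
                                   taxon_j = character(0))
  pair_counts <- table(factor(planted_pairs$stratum, levels = labels))
  density_order <- lapply(c(unfertilized = "unfertilized",
                            fertilized = "fertilized"), function(f) {
    labs <- grep(paste0("^", f, "_"), labels, value = TRUE)
    sub("^[a-z]+_", "", labs[order(pair_counts[labs])])
  })
  truth <- list(
    module_membership = membership,
    modules = lapply(seq_along(modules), function(k)
      list(id = k, taxa = taxa[modules[[k]]$taxa],
           loading = modules[[k]]$loading, strata = modules[[k]]$strata)),
    hubs = lapply(hubs, function(h)
      list(taxon = taxa[h$taxon], attach_module = h$attach_module,
           loading = h$loading, strata = h$strata)),
    planted_pairs = planted_pairs,
    density_order = density_order,
    seed = spec$seed)

  list(abundance = abundance, taxonomy = taxonomy, metadata = meta,
       gene_presence = gp, truth = truth)
}

#' Write the ground-truth record as JSON
#' @param truth the `truth` element from [generate_synthetic()].
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b label vectors over the same items (names are ignored; align
#'   them before calling).
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  total <- choose(length(a), 2)
  expected <- sum_i * sum_j / total
  maxind <- (sum_i + sum_j) / 2
  if (maxind == expected) return(1)
  (sum_ij - expected) / (maxind - expected)
}
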