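---
title: "Methods: co-occurrence networks, keystone taxa and the synthetic world"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence networks, keystone taxa and the synthetic world}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhizonet)
```

# The model

`rhizonet` infers a co-occurrence network per experimental stratum: nodes
are taxa, edges are statistically credible monotone associations between
their relative abundances across samples. The association measure is
Spearman's ρ, chosen because sequencing-derived abundances are compositional
and heavy-tailed; rank correlation is invariant to the monotone distortions
that normalization introduces. No CLR or other compositional transform is
applied — the pipeline this package models applies none, and the synthetic
world is built so that rank correlations are the signal. Users who need
compositionally-aware inference (SparCC, SPIEC-EASI) should treat these
networks as what they are: filtered rank-correlation graphs.

## Filters

* `min_reads = 10000`: samples below 10,000 reads are removed (inclusive
  retention at the boundary — the rule removes samples with *fewer* reads).
* `min_mean_rel_abund = 0.001`: a taxon is kept when its **mean** relative
  abundance across the stratum's retained samples is ≥ 0.001. Two open
  choices are resolved here: the statistic is the mean (not the maximum),
  matching how microeco-style pipelines apply an abundance cutoff, and the
  filter is applied **per stratum**, so each network sees its own community.
  Relative abundances are computed after sample filtering but before taxon
  filtering; dropping rare taxa therefore does not renormalize the
  remainder, keeping abundance values comparable across networks.

## Correlation and significance

ρ is the Pearson correlation of mid-ranks (average ranks on ties). p-values
use the t approximation `t = ρ√((n−2)/(1−ρ²))` on n−2 df — accurate at the
n = 40 per-stratum sample sizes this design targets; below n ≈ 10 exact
permutation p-values differ, which is documented rather than fixed because
no stratum should be that small (the pipeline refuses n < 4 outright).
Constant taxa have undefined ρ; their pairs are dropped and counted, not
imputed as 0. FDR control is Benjamini–Hochberg step-up (the "FDR
adjustment" of the modelled pipeline's tooling; BY would be more
conservative and is not offered).

## Threshold selection

The |ρ| cutoff composes with the FDR gate (`|ρ| ≥ s` **and** `q < 0.01`).
The cutoff s is chosen by a random-matrix-theory scan over a grid (default
0.50–0.90, step 0.01): for each candidate, sub-threshold entries are zeroed
(unit diagonal kept), the eigenvalue spectrum is unfolded through a smoothed
empirical CDF, and the nearest-neighbour spacing histogram (30 equal bins on
[0, 3]) is compared by chi-square distance to the Poisson density `exp(−s)`
and the Wigner–Dyson (GOE) surmise `(πs/2)exp(−πs²/4)`. Dense random
structure gives GOE spacings; genuine modular structure, once noise edges
are pruned, fragments the matrix and gives Poisson spacings. The selected
threshold is the smallest grid value fitting Poisson better than GOE with
the same verdict at the next two grid points; no qualifying value (or fewer
than 30 taxa, where eigenvalue statistics are meaningless) falls back to
0.70 with a warning.

One numerical choice deserves a note: unfolding "by rank" in the strict
sense (replacing eigenvalues by their ranks) makes every spacing identical
and carries no information. The implementation therefore unfolds through a
`smooth.spline` fit of the empirical spectral CDF (df ≤ 15), the standard
practical variant; when the spectrum is so degenerate the spline cannot be
fit (< 5 distinct eigenvalues), the matrix is already fully fragmented and
is scored as the Poisson limit. On i.i.d. noise at n = 40 the scan's verdict
flips from GOE to Poisson almost exactly at the empirical null 95th
percentile of |ρ| (~0.31), which is the behaviour that justifies the
procedure.

## Networks and metrics

Edges keep only positive correlations by default (the modelled analysis
reports only significant positive co-occurrences); the flag is exposed for
reuse. Isolated taxa are excluded: node membership is edge-defined, which is
why node counts vary across strata drawn from a common taxon pool.

Shortest-path metrics are computed on the **unweighted** graph: correlation
weights are similarities, and turning them into distances would add an
arbitrary transform the method never specifies. The normalizations are fixed
so the keystone thresholds are size-independent:

* closeness: Wasserman–Faust component scaling,
  `C(v) = ((r−1)/(n−1)) · ((r−1)/Σd(v,u))` with r the component size —
  bounded in [0, 1] and meaningful on disconnected graphs (a hub inside a
  small fragment scores low, which is intended);
* betweenness: Brandes' algorithm scaled by `2/((n−1)(n−2))`;
* clustering: `2·triangles/(k(k−1))`, 0 for degree < 2; the network-level
  "clustering coefficient" is the unweighted mean of local values (global
  transitivity is also reported but is not the headline number);
* average weighted degree: mean over nodes of summed incident |ρ|
  (equivalently `2Σw/n`).

## Modules

Community detection is Clauset–Newman–Moore greedy modularity maximization,
implemented in the package rather than delegated so that ties in ΔQ are
broken deterministically (lowest (min-id, max-id) community pair) and the
partition returned is exactly the maximal-Q point of the merge path.
Modularity is unweighted by default — the modelled analysis never states a
weighted Q — with the weighted variant behind a flag for sensitivity
analysis. On every graph small enough to enumerate all partitions the greedy
answer is compared against the exhaustive maximum in the tests; greedy
optimality is not guaranteed in general and the gap, where any, is visible
there.

## Keystones, functions, statistics

Keystone taxa satisfy all five strict inequalities: degree > 6, weighted
degree > 6, closeness > 0.14, clustering > 0.09, betweenness < 0.05. The
thresholds are interpreted against the normalized centralities above —
the criteria's closeness/betweenness scales only make sense normalized.
Keystone filtering runs on the two combined per-fertilization networks;
per-group networks are summarized but not keystone-filtered, mirroring how
the modelled study reports them.

Functional categories come from a taxon × EC gene-presence table (a
PICRUSt2-style prediction binarized at ≥ 1 copy): a taxon belongs to a
category if it carries at least one of the category's marker enzymes.
The C/N-cycling marker (N-acetyl-β-glucosaminidase) has no EC stated in the
source analysis; EC 3.2.1.52 — that enzyme's standard number — is used and
the catalog is replaceable.

Group comparisons are fixed-effects ANOVA from explicit sums of squares
(the target design is balanced, 3 × 2 with equal replicates, where Type I =
Type III; unbalanced input degrades to separate one-way ANOVAs with a
warning rather than silently committing to a contested SS type), Tukey HSD
via the studentized-range distribution in Tukey–Kramer form, and compact
letters by insert-and-absorb, whose invariant — two groups share a letter
iff their adjusted p ≥ α — is property-tested.

# The synthetic world

The generator emulates species-level long-read relative-abundance profiles
from a 3 × 2 factorial with 40 samples per cell (four accessions × ten
replicates treated as one group): ~200 taxa over 12 phyla
(Dirichlet-distributed sizes), lognormal library sizes (median 30,000,
floored at 10,000 to mirror the depth-filter regime), and multinomial
counts. Log-abundance of a module member is
`baseline + λ·f + √(1−λ²)·ε` with a per-sample standard-normal module factor
f, so the latent correlation of two members is λ² and Spearman's ρ detects
it directly — the reason a latent-factor lognormal-multinomial was chosen
over a Dirichlet-multinomial, which offers no such direct handle on pairwise
rank correlation. Hub taxa load on a module's factor (loading 0.9 against
the members' 0.95), acquiring high degree, clique-like neighbourhoods, high
component-scaled closeness and near-zero betweenness: planted keystones.

Fixed world choices, made once: baseline log-abundances N(0, 0.8); planted
(module/hub) taxa take the upper half of that distribution (truncation at
the median) plus a boost of 1.5 log units. The truncation is structural, not
a tuning: in the modelled study, network taxa are by construction those that
passed the abundance filter, so a generator whose planted structure could
randomly fall below the 0.001 filter would be simulating a different
experiment (and would silently delete planted edges for some seeds).

`preset_paper_like()` plants two 20-taxon core modules and four hubs active
in every stratum (giving the combined networks stable structure and
keystones) plus stratum-specific 10-taxon modules whose counts encode the
qualitative finding the end-to-end tests check: unfertilized wild <
traditional < modern network density, fertilized wild maximal.

What the generator does **not** emulate: taxonomic misclassification,
chimeras, read-depth/abundance coupling, negative associations from
exclusion, or compositional closure effects beyond the multinomial. A green
end-to-end test therefore establishes that the pipeline recovers planted
rank-correlation structure through all its gates — not that the method is
robust to the artifacts real nanopore profiles carry.

# Degenerate inputs and numerical conventions

* Filters are inclusive at their boundaries; filtering to an empty table is
  an error naming the counts involved.
* Zero-depth samples make relative abundance undefined → error naming the
  sample; constant taxa are excluded from correlation with a logged count.
* An empty edge set is a valid (warned) network; an edgeless graph has
  singleton modules and Q = 0; graphs with < 3 nodes have zero betweenness.
* All tie-breaks (ΔQ merges, chord-matrix ranking) are deterministic, and
  reruns at a fixed seed are byte-identical, including the summary JSON.
* Per-stratum threshold optimization is independent per network, which is
  why different strata may select different cutoffs.

# Known limitations

* The RMT criterion is one member of a family ("correlation optimization"
  is underdetermined); the per-network selected cutoffs on real data need
  not reproduce any particular published value, and on the synthetic preset
  the scan typically selects the grid minimum 0.50 because the planted
  structure is far stronger than the noise floor at n = 40.
* The t-approximate p-values are anticonservative below n ≈ 10.
* Greedy modularity has a known resolution limit; small planted modules
  attached to large cliques may be absorbed.
* Betweenness/closeness ignore edge weights by design (see above).
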