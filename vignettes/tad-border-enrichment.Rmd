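---
title: "TAD-border enrichment of disease-associated SNPs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TAD-border enrichment of disease-associated SNPs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadrisk)
```

## The scientific question

Topologically associating domains (TADs) partition mammalian chromosomes
into intervals with frequent internal Hi-C contacts and strong insulation
across their limits. The 20-kb regions just *inside* a TAD at each of its
two ends — its **borders**, as distinct from the inter-TAD linker
*boundaries* — concentrate the insulating function whose disruption can
re-wire enhancer–promoter contacts across adjacent domains. `tadrisk` asks,
disease by disease, whether the SNPs that genome-wide association studies
attach to that disease sit inside TAD borders more often than chance
predicts, whether this preferential location is more frequent among cancers
than among non-cancer diseases, and whether it can be explained away by a
few SNPs shared between many diseases.

## TAD calling from the insulation signal

TADs are called per chromosome from a binned contact matrix (10-kb bins by
default) with a sliding-window insulation statistic. For every inter-bin
position $b$ the signal is the mean count over pairs $(i, j)$ with $i$ in
the $k$ bins left of $b$ and $j$ in the $k$ bins right of it; the window
shrinks at chromosome ends, and pairs touching *gap* bins (off-diagonal row
sum zero, or below `gap_zero_fraction` — default 0.05 — times the median
positive row sum) are excluded. Demarcations between TADs are local minima
of this signal: strictly lower than the nearest defined neighbour value on
each side, with plateaus collapsed to their leftmost position so the call
is deterministic.

The window half-size $k$ (in bins) is the caller's one tunable parameter;
small $k$ resolves fine substructure and yields many TADs, large $k$ keeps
only large domains. All downstream analyses therefore scan $k$ over a range
(default 3–20) and either aggregate over $k$ or apply a majority rule.

**Statistical boundary filter.** With `statistical_filter = TRUE` a
candidate demarcation must be supported by the counts themselves: the pairs
inside the two $k \times k$ triangles flanking $b$ must stochastically
dominate the pairs in the $k \times k$ diamond crossing $b$, by a one-sided
Wilcoxon rank-sum test. Two numerical choices matter here and were made
deliberately:

* counts are first divided by the chromosome-wide mean count at their
  genomic distance. Without this normalization the triangle pairs (short
  distances) beat the diamond pairs (distances up to $2k - 1$) under any
  decaying contact profile, and the test is vacuous;
* the candidate p-values are Benjamini–Hochberg corrected across the
  chromosome and demarcations are retained at FDR `filter_alpha`
  (default 0.05). A chromosome of a few hundred bins offers dozens of noise
  minima; a raw per-candidate threshold would admit a constant fraction of
  them, while family-level FDR keeps the spurious-demarcation count near
  zero at no cost in sensitivity (planted demarcations have vanishing
  p-values).

TADs are the maximal intervals between consecutive retained demarcations
and gap-run edges; no TAD spans a gap run. TADs shorter than `min_tad_bins`
(default 2) are merged into the neighbour across their smaller-signal
demarcation. On synthetic single-scale data the filtered caller recovers
the planted partition at essentially every $k$, so TAD counts are flat in
$k$; the monotone more-TADs-at-small-$k$ trend of the raw insulation
landscape is visible with the filter off, which is how the corresponding
test exercises it.

## Borders and the enrichment test

For a TAD $[s, e)$ in bp the borders are $[s, \min(s + 20000, m))$ and
$[\max(e - 20000, m), e)$ with $m = \lfloor (s+e)/2 \rfloor$, so short TADs
are tiled without overlap. Border intervals are merged into a union before
any counting, which keeps the success population of the test well defined.

For disease $d$ with $Q$ associated SNPs of which $q$ fall in the border
union, the enrichment p-value is the hypergeometric upper tail
$$
p_d \;=\; \sum_{x \ge q} \frac{\binom{n}{x}\binom{N-n}{Q-x}}{\binom{N}{Q}},
$$
computed at bp resolution (two SNPs in one border count as two units).
Two null models set $(N, n)$:

* **genome-based** (default, the more conservative): $N$ = genome length in
  bp, $n$ = bp in the border union. Gap regions are included in $N$ — the
  population is literally the genome — though a caller may pass a reduced
  length for sensitivity analysis;
* **SNP-based**: $N$ = distinct disease-associated SNPs in the catalog
  (each counted once), $n$ = how many of them are in borders at that $k$.

$H(q \mid N, n, Q) = H(q \mid N, Q, n)$, so "the disease's SNPs hit borders
unusually often" and "borders contain the disease's SNPs unusually often"
are the same statement. `stats::phyper()` carries the computation and is
stable at $N \sim 3 \times 10^9$; the test suite checks it against an
exhaustive enumeration oracle for every parameter tuple with $N \le 12$.

**Multiple testing.** Benjamini–Hochberg is applied separately for cancers
and non-cancer diseases (the two groups are defined on biological grounds
before any testing) and within each (dataset, $k$, category filter, null
model) stratum. Correcting per $k$ — rather than pooling all $k$ — treats
each window size as its own TAD landscape; both schemes and an uncorrected
variant are exposed. A disease is *majority-enriched* when its adjusted
p-value is $\le 0.05$ for strictly more than half of the $k$ values.

The cancers vs non-cancer comparison is a two-sided Fisher exact test on
the 2×2 table of majority-enrichment by group, with stars at
$p \le 0.05/0.01/0.001/0.0001$ (the 0.001 level is included for
completeness). Tables with a zero margin are flagged degenerate and
reported with $p = 1$. Histograms of $-\log_{10} p_\mathrm{adj}$ use bin
width 0.1 (unspecified upstream; small enough not to dilute the core of
the distribution), truncate the display at 4 and keep the overflow in a
tail count that still participates in the per-group normalization.

## Diseasome networks and coherence

The disease–SNP bipartite graph is projected onto diseases: an edge links
two diseases sharing at least `edge_threshold` (default 1) SNPs of the
prescribed class — majority-rule border SNPs or their complement, each
optionally restricted to intergenic SNPs, giving four network variants.
The *network coherence* of a node subset is the z-score of its induced
edge count against random node subsets of the same size drawn uniformly
(without replacement within a draw, draws independent) from the same
network variant — not from the full disease universe, since the question
is positional within that network. The default is 1000 draws with the
population standard-deviation formula; when $\binom{|V|}{s} \le 10^5$ the
null is enumerated exactly instead. A zero null standard deviation
(edgeless network, subset = all nodes) yields an explicitly flagged
undefined z-score rather than a silent zero.

## What the synthetic generator emulates

Every stage is validated against data with planted ground truth:

* **Contact matrices**: one Poisson draw per unordered bin pair with mean
  $A (1 + |i - j|)^{-\alpha}$, multiplied by $B$ when both bins share a
  planted TAD; symmetric, zero diagonal, gap rows/columns zeroed. Defaults
  $A = 10$, $\alpha = 1$, $B = 4$ give a contrast at which the planted
  partition is recoverable but not trivial. Poisson noise was chosen over
  negative binomial as the simplest count model that exercises the caller;
  overdispersion, ICE/KR normalization and read-level simulation are out
  of scope.
* **TAD partitions**: sizes uniform in `tad_size_range`; a final remainder
  shorter than the minimum is absorbed into the preceding TAD so no
  degenerate domain is planted.
* **Catalog**: each disease draws $Q \sim \max(1, \mathrm{Pois}(47))$ SNPs
  (matching the order of magnitude of real per-disease counts, with
  roughly 18 intergenic under the default gene model); for planted-enriched
  diseases each SNP lands uniformly in the planted border union with
  probability $\rho$, else uniformly in the genome. With probability
  `snp_sharing_prob` a SNP is reused from an earlier disease of the same
  class, planting the within-class assortativity the diseasome analysis
  must detect; the real catalog's sharing topology is not quantitatively
  documented, so this remains a free parameter rather than a calibrated
  one.
* **Gene model**: non-overlapping genes alternating with intergenic gaps
  (targets: 40% intergenic genome, 8.5% of genic bp exonic, mean gene
  23 kb, around the median human gene length), every gene with at least
  one exon; classification precedence is exon > intron > intergenic.

With $B = 1$ and $\rho = 0$ the generator is an exact global null for the
whole pipeline. What passing on synthetic data does *not* show: real Hi-C
matrices carry non-Poisson dispersion, distance profiles that deviate from
a single power law, translocations and coverage artefacts; real catalogs
carry linkage disequilibrium among SNPs, which the generator deliberately
omits. Results on real data therefore still require the usual external
sanity checks (e.g., the border union covering roughly 8–14% of the genome
across $k$).

## Validation problem sizes

The checks shipped with the package use: boundary recovery on 500-bin
chromosomes with TADs of 5–50 bins at $k = 5$ over 20 seeds (pooled
precision and recall $\ge 0.9$ within ±1 bin); type-I error on 100-disease
global-null catalogs over 50 seeds; power/FDR with $\rho = 0.5$, border
fraction $\approx 0.1$ (TADs of 20–60 bins) and 60 planted diseases of 400
over 20 seeds with majority over $k = 3..8$; the cancer-confined Fisher
comparison over 20 seeds with majority over $k = 3..7$. These sizes keep
each property estimable with small Monte-Carlo error while remaining
desk-scale; larger runs only tighten the same estimates.

## Known limitations

* The dense-TSV matrix reader and the synthetic generator are the two
  input paths; `.cool` files must be exported to dense text upstream
  (e.g., with the `cooler` command-line tools).
* EFO ontology traversal is a data-preparation step: the loader consumes
  precomputed id lists for the disease and cancer subtrees
  (EFO_0000408 / EFO_0000311).
* No LD modelling, proxy-SNP expansion, assembly liftover, nested TADs or
  inter-chromosomal contacts.
* Catalog positions are 1-based on input and 0-based half-open internally
  and in all BED output; bin $b$ covers $[b \cdot \mathrm{binsize},
  (b+1) \cdot \mathrm{binsize})$.

## A small end-to-end run

```{r, eval = FALSE}
run <- run_pipeline(list(
  sim = list(n_chromosomes = 2, bins_per_chromosome = 300,
             tad_size_range = c(20, 60), n_cancers = 30, n_noncancers = 90,
             frac_enriched_cancers = 0.4, border_placement_prob = 0.5,
             seed = 1),
  k_range = 3:8, seed = 1))
print(run)
run$comparison$all      # Fisher table, p-value, stars
head(run$coherence)     # network-coherence report
```
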