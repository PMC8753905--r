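# tadrisk

Genome-wide testing of whether disease-associated SNPs (daSNPs) are
preferentially located in the borders of topologically associating domains
(TADs), for statistical geneticists and regulatory genomicists working at
the interface of GWAS catalogs and Hi-C data.

TAD borders — here the 20-kb regions *inside* a TAD at each of its two
limits, as opposed to the inter-TAD linker "boundary" — insulate adjacent
domains; a risk variant weakening a border is a candidate mechanism for
coordinated gene mis-regulation. `tadrisk` implements the full analysis:

1. **TAD calling** from binned Hi-C contact matrices with a sliding-window
   insulation signal; demarcations between TADs are local minima of the
   mean contact count in a window of half-size *k* bins, optionally
   confirmed by a rank-sum test on distance-normalized counts. *k* is
   scanned (default 3–20) because the TAD landscape depends on it.
2. **Border extraction**: 20-kb regions inward from both TAD ends, clipped
   at the TAD midpoint and merged into a union.
3. **Per-disease enrichment**: for a disease with *Q* SNPs of which *q*
   lie in borders, the p-value is the hypergeometric upper tail
   *H(q | N, n, Q)* with *(N, n)* either the genome length and the border
   union in bp (genome-based null) or the distinct catalog SNPs and those
   in borders (SNP-based null). Benjamini–Hochberg correction is applied
   separately for cancers and non-cancer diseases; a disease counts as
   enriched when adjusted *p* ≤ 0.05 for a strict majority of *k* values.
4. **Group comparison**: Fisher's exact test on enrichment by
   cancer/non-cancer, per dataset and aggregated, with category filters
   (all / exonic / intronic / intergenic SNPs).
5. **Diseasome networks**: diseases linked by shared border (or
   non-border) SNPs; subset clustering quantified by the *network
   coherence*, the z-score of the induced edge count against 1000 random
   same-size node subsets (exact enumeration on small networks).

A synthetic-data generator plants TAD partitions, Poisson contact matrices
with distance decay, a toy gene model and a GWAS-catalog-like disease/SNP
table with controllable border enrichment and SNP sharing, so the whole
pipeline is testable against ground truth. See the vignette
(`vignettes/tad-border-enrichment.Rmd`) for the models, parameter
meanings and design choices.

## Worked example

```r
library(tadrisk)

run <- run_pipeline(list(
  sim = list(n_chromosomes = 2, bins_per_chromosome = 500,
             tad_size_range = c(20, 60),
             n_cancers = 40, n_noncancers = 100,
             frac_enriched_cancers = 0.5, border_placement_prob = 0.5,
             snps_per_disease = 47, seed = 1),
  k_range = 3:7, n_draws = 200, seed = 1))
print(run)
```

```
TAD-border enrichment run (synthetic mode, dataset ds1)
  k range 3-7; border 20000 bp; null model genome_based; BH scheme bh_within_group; alpha 0.05
  genome 1e+07 bp; border fraction 0.100-0.104 across k
  140 diseases, 5863 SNPs (980 majority border SNPs)
  [all] majority-enriched: 20/40 cancers, 0/100 non-cancers; Fisher p = 1.666e-13 ****
```

Half of the 40 simulated cancers were planted with border enrichment
(each of their SNPs placed in a planted TAD border with probability 0.5);
the pipeline calls exactly those 20 cancers, no false positives among the
100 untouched non-cancer diseases, and the Fisher comparison flags the
cancer excess at p ≈ 2e-13. The border union covers ~10% of the synthetic
genome, so an average null disease leaves ~10% of its SNPs in borders.

```r
run$comparison$all$table
#>           enriched not_enriched
#> cancer          20           20
#> noncancer        0          100
head(run$coherence[, c("snp_class", "node_type", "n_nodes", "m_obs", "z")])
#>    snp_class              node_type n_nodes m_obs         z
#> 1     border             cancer_all      40    60 13.867735
#> 2     border        cancer_enriched      20    21 13.101885
#> 3     border    cancer_not_enriched      20     4  1.241205
#> 4     border          noncancer_all     100    44 -1.183419
#> 5     border noncancer_not_enriched     100    44 -1.310118
#> 6 non_border             cancer_all      40   107  7.646327
```

The planted within-class SNP sharing shows up as strongly positive
coherence of the cancer subsets, while the non-cancer subsets sit near the
random expectation.

For file-based input, contact matrices are read from dense TSV (one square
matrix per chromosome; `.cool` archives can be exported to this format
with the `cooler` command-line tools) and the catalog from a
GWAS-catalog-like TSV together with plain-text EFO id lists for the
disease (EFO_0000408) and cancer (EFO_0000311) subtrees; see
`?run_pipeline` and `?load_gwas_catalog`. A thin command-line wrapper
lives at `exec/tadrisk` (`tadrisk simulate | call-tads | all`).

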