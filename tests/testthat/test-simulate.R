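# Synthetic-data generator: planted TADs, contact model, gene model,
# catalog.

test_that("plant_tads tiles chromosomes exactly with bounded sizes", {
  # forced partition
  one <- plant_tads(c(chr1 = 10), c(10, 10), seed = 1)
  expect_equal(one$start_bin, 0)
  expect_equal(one$end_bin, 10)

  # remainder < min absorbed into the preceding TAD
  three <- plant_tads(c(chr1 = 10), c(3, 3), seed = 1)
  expect_equal(three$start_bin, c(0, 3, 6))
  expect_equal(three$end_bin, c(3, 6, 10))

  # assert-by-construction on a larger layout
  tads <- plant_tads(c(chr1 = 500), c(5, 50), seed = 42)
  expect_equal(tads$start_bin[1], 0)
  expect_equal(tads$end_bin[nrow(tads)], 500)
  expect_equal(tads$start_bin[-1], tads$end_bin[-nrow(tads)])  # exact tiling
  sizes <- tads$end_bin - tads$start_bin
  expect_true(all(sizes >= 5))
  # absorption can stretch the last TAD past the max by < min
  expect_true(all(sizes <= 50 + 5))

  # deterministic given seed
  expect_identical(tads, plant_tads(c(chr1 = 500), c(5, 50), seed = 42))

  expect_error(plant_tads(c(chr1 = 3), c(5, 10)), "shorter")
})

test_that("simulated contact matrices are symmetric, non-negative, gap-zeroed", {
  cfg <- sim_config(n_chromosomes = 1, bins_per_chromosome = 60,
                    tad_size_range = c(5, 15), seed = 3)
  tads <- plant_tads(c(chr1 = 60), c(5, 15), seed = 3)
  cm <- simulate_contact_matrix(tads, 60, cfg, gap_bins = c(10, 11), seed = 3)
  expect_identical(cm$counts, t(cm$counts))
  expect_true(all(cm$counts >= 0))
  expect_equal(diag(cm$counts), rep(0, 60))
  expect_equal(cm$counts[11, ], rep(0, 60))  # gap bin 10 (0-based)
  expect_equal(cm$counts[, 12], rep(0, 60))

  expect_error(
    simulate_contact_matrix(tads, 60, modifyList(cfg, list(baseline_intensity = 0)),
                            seed = 1),
    "positive")
})

test_that("contact model means match A (1+d)^-alpha with within-TAD factor B", {
  # one 500-bin chromosome, one TAD covering everything vs no TAD structure;
  # with A=8, alpha=1: adjacent within-TAD mean = 8/2*4 = 16, cross = 4
  cfg <- sim_config(n_chromosomes = 1, bins_per_chromosome = 100,
                    tad_size_range = c(50, 50), baseline_intensity = 8,
                    decay_exponent = 1, within_tad_factor = 4, seed = 1)
  tads <- data.frame(chrom = "chr1", start_bin = c(0, 50), end_bin = c(50, 100))
  # pool adjacent-pair counts over many independent matrices: >= 10^4 draws
  within <- c(); cross <- c()
  for (s in 1:110) {
    cm <- simulate_contact_matrix(tads, 100, cfg, seed = 1000 + s)
    sup <- cm$counts[cbind(1:99, 2:100)]
    within <- c(within, sup[-50])   # adjacent pairs inside one TAD
    cross <- c(cross, sup[50])      # the pair straddling the TAD limit
  }
  expect_gt(length(within), 1e4)
  expect_lt(abs(mean(within) - 16), 3 * sd(within) / sqrt(length(within)))
  expect_lt(abs(mean(cross) - 4), 3 * sd(cross) / sqrt(length(cross)))
})

test_that("with B = 1 expected counts depend only on distance", {
  cfg <- sim_config(n_chromosomes = 1, bins_per_chromosome = 200,
                    tad_size_range = c(10, 20), baseline_intensity = 10,
                    decay_exponent = 1, within_tad_factor = 1, seed = 2)
  tads <- plant_tads(c(chr1 = 200), c(10, 20), seed = 2)
  # distance 4: expected 10 * 5^-1 = 2, regardless of TAD membership
  vals <- c()
  for (s in 1:30) {
    cm <- simulate_contact_matrix(tads, 200, cfg, seed = 2000 + s)
    vals <- c(vals, cm$counts[cbind(1:196, 5:200)])
  }
  expect_lt(abs(mean(vals) - 2), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("gene model hits its genic and exonic fractions", {
  gm <- simulate_gene_model(c(chr1 = 1e7), intergenic_fraction = 0.4,
                            exon_fraction = 0.085, seed = 5)
  genic <- sum(gm$genes$end - gm$genes$start)
  exonic <- sum(gm$exons$end - gm$exons$start)
  expect_lt(abs(genic / 1e7 - 0.6), 0.06)
  expect_lt(abs(exonic / genic - 0.085), 0.0085 + 0.01)
  # every gene has at least one exon inside it
  expect_true(all(gm$genes$gene_id %in% gm$exons$gene_id))
  by_gene <- split(gm$exons, gm$exons$gene_id)
  for (g in seq_len(nrow(gm$genes))) {
    ex <- by_gene[[gm$genes$gene_id[g]]]
    expect_true(all(ex$start >= gm$genes$start[g] & ex$end <= gm$genes$end[g]))
  }

  empty <- simulate_gene_model(c(chr1 = 1e6), intergenic_fraction = 1, seed = 1)
  expect_equal(nrow(empty$genes), 0)
  expect_equal(classify_snps(data.frame(chrom = "chr1", pos0 = c(1, 2)), empty),
               c("intergenic", "intergenic"))
})

test_that("catalog generator respects rho and the border-placement expectation", {
  truth <- list(
    layout_bp = c(chr1 = 1e7),
    border_union = data.frame(chrom = "chr1", start = 0, end = 1e6),
    gene_model = simulate_gene_model(c(chr1 = 1e7), intergenic_fraction = 1)
  )
  # rho = 1: every SNP of the (only, enriched) disease is in the border union
  cfg1 <- sim_config(n_chromosomes = 1, bins_per_chromosome = 1000,
                     n_cancers = 1, n_noncancers = 0,
                     frac_enriched_cancers = 1, border_placement_prob = 1,
                     snps_per_disease = 20, snp_sharing_prob = 0, seed = 9)
  cat1 <- simulate_catalog(truth, cfg1, seed = 9)
  expect_true(all(cat1$snps$pos0 < 1e6))

  # rho = 0.5, border fraction 0.1: E[q] = Q * (0.5 + 0.5 * 0.1) = 0.55 Q
  cfg2 <- sim_config(n_chromosomes = 1, bins_per_chromosome = 1000,
                     n_cancers = 1, n_noncancers = 0,
                     frac_enriched_cancers = 1, border_placement_prob = 0.5,
                     snps_per_disease = 40, snp_sharing_prob = 0, seed = 1)
  qs <- vapply(1:1000, function(s) {
    catg <- simulate_catalog(truth, cfg2, seed = s)
    sum(catg$snps$pos0 < 1e6) / nrow(catg$snps) * 40
  }, numeric(1))
  expect_lt(abs(mean(qs) - 22), 3 * sd(qs) / sqrt(length(qs)))

  expect_error(
    simulate_catalog(list(layout_bp = numeric(),
                          border_union = truth$border_union,
                          gene_model = truth$gene_model), cfg1, seed = 1),
    "empty genome")
})

test_that("SNP sharing reuses identifiers within the same disease class", {
  truth <- list(
    layout_bp = c(chr1 = 1e7),
    border_union = data.frame(chrom = "chr1", start = 0, end = 1e6),
    gene_model = simulate_gene_model(c(chr1 = 1e7), intergenic_fraction = 1)
  )
  cfg <- sim_config(n_chromosomes = 1, bins_per_chromosome = 1000,
                    n_cancers = 10, n_noncancers = 10,
                    snps_per_disease = 30, snp_sharing_prob = 0.5, seed = 4)
  catg <- simulate_catalog(truth, cfg, seed = 4)
  shared <- table(catg$assoc$snpId)
  expect_gt(sum(shared > 1), 0)
  # no duplicated association within a disease
  expect_equal(anyDuplicated(catg$assoc[, c("efoId", "snpId")]), 0L)
})

test_that("the whole study generator is bit-reproducible given a seed", {
  cfg <- sim_config(n_chromosomes = 2, bins_per_chromosome = 80,
                    tad_size_range = c(5, 20), n_cancers = 3,
                    n_noncancers = 4, frac_enriched_cancers = 0.5,
                    border_placement_prob = 0.5, seed = 11)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$truth$planted_tads, s2$truth$planted_tads)
  expect_identical(s1$matrices[[1]]$counts, s2$matrices[[1]]$counts)
  expect_identical(s1$catalog, s2$catalog)
})
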