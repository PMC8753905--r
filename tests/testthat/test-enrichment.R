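# Hypergeometric test, null models, BH correction, majority calls,
# histograms and the Fisher group comparison.

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_identical(hypergeom_upper_tail(0, 100, 10, 5), 1)
  expect_equal(hypergeom_upper_tail(2, 10, 3, 4), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(3, 10, 3, 4), 1 / 30, tolerance = 1e-12)

  for (N in c(5, 7, 9)) {
    for (n in 0:N) for (Q in 1:N) for (q in 0:min(n, Q)) {
      expect_equal(hypergeom_upper_tail(q, N, n, Q),
                   hyper_upper_enum(q, N, n, Q), tolerance = 1e-12)
    }
  }

  expect_error(hypergeom_upper_tail(5, 10, 3, 4), "invalid")
  expect_error(hypergeom_upper_tail(1, 10, 11, 4), "invalid")
})

test_that("the hypergeometric tail is symmetric in n and Q at genome scale", {
  set.seed(2)
  for (i in 1:200) {
    N <- sample(1e6:3e9, 1)
    n <- sample(1e3:1e6, 1)
    Q <- sample(10:500, 1)
    q <- sample(0:min(Q, 50), 1)
    a <- hypergeom_upper_tail(q, N, n, Q)
    b <- hypergeom_upper_tail(q, N, Q, n)
    expect_lt(abs(a - b), 1e-9 * max(a, b))
  }
})

test_that("null-model parameters mirror their populations", {
  g <- make_null_params("genome_based", genome_bp = 1e7,
                        border_union_bp = 1e6)
  expect_equal(c(g$N, g$n), c(1e7, 1e6))
  s <- make_null_params("snp_based", n_snps = 1000, n_border_snps = 130)
  expect_equal(c(s$N, s$n), c(1000, 130))
  expect_error(make_null_params("snp_based", n_snps = 10, n_border_snps = 11),
               "exceeds")
})

test_that("per-disease tests count q and Q under the category filter", {
  catg <- toy_catalog()
  tads <- data.frame(chrom = "chr1", start_bin = c(10, 40),
                     end_bin = c(30, 60))
  borders <- list("3" = extract_borders(tads, bin_size = 10000))
  res <- test_all_diseases(catg, borders, genome_bp = 1e6)
  # borders [100000,120000) u [280000,300000) u [400000,420000) u [580000,600000)
  r1 <- res[res$efoId == "EFO_1", ]
  expect_equal(c(r1$q, r1$Q), c(1, 2))  # rs1 in, rs2 at 120000 out
  expect_equal(r1$n, borders[["3"]]$union_bp)
  expect_equal(r1$p_raw,
               hypergeom_upper_tail(1, 1e6, borders[["3"]]$union_bp, 2))
  # all SNPs outside borders -> q = 0, p = 1 (EFO_2: rs2 at 120000, rs3)
  r2 <- res[res$efoId == "EFO_2", ]
  expect_equal(c(r2$q, r2$p_raw), c(0, 1))

  # intergenic filter drops non-intergenic SNPs from q and Q
  res_ig <- test_all_diseases(catg, borders, category_filter = "intergenic",
                              genome_bp = 1e6)
  r1_ig <- res_ig[res_ig$efoId == "EFO_1", ]
  expect_equal(c(r1_ig$q, r1_ig$Q), c(1, 1))  # only rs1 is intergenic
  # EFO_3's only SNP (rs4) is exonic -> skipped under the intergenic filter
  expect_false("EFO_3" %in% res_ig$efoId)

  # SNP-based null: n equals the membership recount
  res_snp <- test_all_diseases(catg, borders, null_model = "snp_based")
  memb <- snp_border_membership(catg$snps, borders)
  expect_equal(unique(res_snp$n), sum(memb[, "3"]))
  expect_equal(unique(res_snp$N), nrow(catg$snps))
})

test_that("BH step-up reproduces hand-computed adjustments", {
  mk <- function(p) data.frame(efoId = paste0("d", seq_along(p)),
                               isCancer = FALSE, dataset = "ds1", k = 3,
                               filter = "all", null_model = "genome_based",
                               q = 1, Q = 1, n = 1, N = 2, p_raw = p)
  out1 <- adjust_pvalues(mk(c(0.01, 0.02, 0.03, 0.04)), scheme = "bh_global")
  expect_equal(out1$p_adj, rep(0.04, 4))
  out2 <- adjust_pvalues(mk(c(0.005, 0.04, 0.05)), scheme = "bh_global")
  expect_equal(out2$p_adj, c(0.015, 0.05, 0.05))
  out3 <- adjust_pvalues(mk(rep(0.02, 5)), scheme = "bh_global")
  expect_equal(out3$p_adj, rep(0.02, 5))
  # scheme none passes raw values through
  expect_equal(adjust_pvalues(mk(c(0.3, 0.01)), scheme = "none")$p_adj,
               c(0.3, 0.01))
})

test_that("within-group BH corrects cancers and non-cancers separately", {
  res <- data.frame(
    efoId = paste0("d", 1:6),
    isCancer = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    dataset = "ds1", k = 3, filter = "all", null_model = "genome_based",
    q = 1, Q = 1, n = 1, N = 2,
    p_raw = c(0.01, 0.02, 0.03, 0.01, 0.02, 0.03))
  out <- adjust_pvalues(res, scheme = "bh_within_group")
  expect_equal(out$p_adj[out$isCancer],
               p.adjust(c(0.01, 0.02, 0.03), "BH"))
  expect_equal(out$p_adj[out$isCancer], out$p_adj[!out$isCancer])
  # and per-k strata are corrected independently
  res2 <- rbind(res, transform(res, k = 4, p_raw = p_raw / 10))
  out2 <- adjust_pvalues(res2, scheme = "bh_within_group")
  expect_equal(out2$p_adj[out2$k == 4], out$p_adj / 10)
})

test_that("majority-over-k enrichment requires a strict majority", {
  mk_flags <- function(efo, n_sig, n_k = 18) {
    data.frame(efoId = efo, isCancer = FALSE, dataset = "ds1",
               k = seq_len(n_k), filter = "all",
               null_model = "genome_based", q = 0, Q = 1, n = 1, N = 2,
               p_raw = 1,
               p_adj = c(rep(0.01, n_sig), rep(0.5, n_k - n_sig)),
               enriched = c(rep(TRUE, n_sig), rep(FALSE, n_k - n_sig)))
  }
  res <- rbind(mk_flags("d10", 10), mk_flags("d9", 9))
  maj <- majority_enriched(res, k_range = 1:18)
  expect_true(maj$majority_enriched[maj$efoId == "d10"])
  expect_false(maj$majority_enriched[maj$efoId == "d9"])

  # brute-force recount on a random flag table
  set.seed(11)
  ks <- 1:7
  efos <- paste0("e", 1:20)
  tab <- expand.grid(efoId = efos, k = ks, stringsAsFactors = FALSE)
  tab$isCancer <- tab$efoId %in% efos[1:5]
  tab$dataset <- "ds1"; tab$filter <- "all"; tab$null_model <- "genome_based"
  tab$q <- 0; tab$Q <- 1; tab$n <- 1; tab$N <- 2; tab$p_raw <- 1
  tab$p_adj <- runif(nrow(tab))
  tab$enriched <- tab$p_adj <= 0.05
  maj <- majority_enriched(tab, k_range = ks)
  brute <- sapply(maj$efoId, function(e) {
    sum(tab$p_adj[tab$efoId == e] <= 0.05) > length(ks) / 2
  })
  expect_equal(maj$majority_enriched, unname(brute))
})

test_that("histogram bins -log10 p-values with a retained tail", {
  res <- data.frame(
    p_adj = c(1, 0.5, 0.05, 0.01, 1e-3, 1e-6),
    isCancer = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  h <- enrichment_histogram(res, truncation = 4, bin_width = 0.1,
                            normalize_by_group = FALSE)
  expect_equal(sum(h$bins$cancer), 3)       # all cancer values <= 4
  expect_equal(sum(h$bins$noncancer), 2)    # 1e-6 beyond truncation
  expect_equal(unname(h$tail["noncancer"]), 1)
  # manual binning: -log10 = 0, 0.301, 1.301 for cancers
  expect_equal(h$bins$cancer[h$bins$lower == 0], 1)
  expect_equal(h$bins$cancer[abs(h$bins$lower - 0.3) < 1e-9], 1)
  expect_equal(h$bins$cancer[abs(h$bins$lower - 1.3) < 1e-9], 1)

  # all p = 1 -> all mass in the first bin
  res1 <- data.frame(p_adj = rep(1, 4), isCancer = rep(TRUE, 4))
  h1 <- enrichment_histogram(res1)
  expect_equal(h1$bins$cancer[1], 1)
  expect_equal(sum(h1$bins$cancer[-1]), 0)
  # empty group: normalization skipped, all-zero histogram
  expect_true(all(h1$bins$noncancer == 0))
})

test_that("Fisher comparison reproduces enumeration oracles and stars", {
  cmp <- fisher_group_comparison(c(rep(TRUE, 3), FALSE),
                                 c(TRUE, rep(FALSE, 3)))
  expect_equal(cmp$fisher_p, 34 / 70, tolerance = 1e-12)
  expect_equal(cmp$stars, "")

  same <- fisher_group_comparison(c(TRUE, TRUE, FALSE),
                                  c(TRUE, TRUE, FALSE))
  expect_equal(same$fisher_p, 1)

  extreme <- fisher_group_comparison(rep(TRUE, 10), rep(FALSE, 10))
  expect_equal(extreme$fisher_p, 2 / choose(20, 10), tolerance = 1e-9)
  expect_equal(extreme$stars, "****")

  degen <- fisher_group_comparison(logical(0), c(TRUE, FALSE))
  expect_true(degen$degenerate)
  expect_equal(degen$fisher_p, 1)
})

test_that("dataset aggregation sums tables before retesting", {
  c1 <- fisher_group_comparison(c(TRUE, TRUE, FALSE), c(FALSE, FALSE, TRUE))
  pooled1 <- aggregate_over_datasets(list(c1))
  expect_equal(pooled1$table, c1$table)
  expect_equal(pooled1$fisher_p, c1$fisher_p)

  pooled2 <- aggregate_over_datasets(list(c1, c1))
  expect_equal(pooled2$table, 2 * c1$table)
  expect_equal(pooled2$fisher_p,
               fisher.test(2 * c1$table)$p.value)

  c2 <- fisher_group_comparison(c(TRUE, FALSE), c(TRUE, TRUE, FALSE))
  pooled3 <- aggregate_over_datasets(list(c1, c1, c2))
  expect_equal(pooled3$table, 2 * c1$table + c2$table)
})
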