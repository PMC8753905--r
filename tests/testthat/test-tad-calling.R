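# Gap detection, insulation signal and the TAD caller.

test_that("detect_gaps flags empty and low-coverage bins", {
  m <- matrix(1, 4, 4); diag(m) <- 0
  expect_equal(detect_gaps(m), rep(FALSE, 4))

  m2 <- m; m2[3, ] <- 0; m2[, 3] <- 0
  expect_equal(detect_gaps(m2), c(FALSE, FALSE, TRUE, FALSE))

  # row sums (100, 100, 3, 100), threshold 0.05 * 100 = 5 -> bin 3 gap
  m3 <- matrix(0, 4, 4)
  m3[1, 2] <- m3[2, 1] <- 50
  m3[1, 4] <- m3[4, 1] <- 50
  m3[2, 4] <- m3[4, 2] <- 50
  m3[3, 2] <- m3[2, 3] <- 0
  m3[3, 1] <- m3[1, 3] <- 0
  m3[3, 4] <- m3[4, 3] <- 3
  # rows: 100, 100, 3, 103
  expect_equal(detect_gaps(m3, 0.05), c(FALSE, FALSE, TRUE, FALSE))

  expect_error(detect_gaps(matrix(0, 3, 3)), "unusable")
})

test_that("gap detection is idempotent after masking and monotone in coverage", {
  set.seed(7)
  m <- matrix(rpois(400, 5), 20, 20)
  m <- m + t(m); diag(m) <- 0
  m[4, ] <- m[, 4] <- 0
  m[9, ] <- m[, 9] <- rpois(20, 0.1); m[9, 9] <- 0
  m <- pmax(m, t(m))  # keep symmetric
  g1 <- detect_gaps(m)
  masked <- m; masked[g1, ] <- 0; masked[, g1] <- 0
  expect_equal(detect_gaps(masked), g1)

  # adding contacts to a gap bin removes its flag without creating others
  m2 <- m
  m2[4, ] <- m2[, 4] <- round(mean(m[m > 0]))
  m2[4, 4] <- 0
  g2 <- detect_gaps(m2)
  expect_false(g2[4])
  expect_true(all(which(g2) %in% which(g1)))
})

test_that("insulation signal equals brute-force window means", {
  # constant matrix
  cmc <- matrix(3, 5, 5); diag(cmc) <- 3  # include diagonal; windows skip it
  expect_equal(insulation_signal(cmc, 2), rep(3, 4))

  # k = 1 reduces to the superdiagonal
  set.seed(1)
  r <- matrix(rpois(36, 4), 6, 6); r <- r + t(r); diag(r) <- 0
  expect_equal(insulation_signal(r, 1), r[cbind(1:5, 2:6)])

  # worked 4-bin example at k = 2, boundary 2: mean(2, 3, 4, 5) = 3.5
  m <- matrix(c(0, 1, 2, 3, 1, 0, 4, 5, 2, 4, 0, 6, 3, 5, 6, 0), 4, 4,
              byrow = TRUE)
  expect_equal(insulation_signal(m, 2)[2], 3.5)

  # brute-force oracle on random matrices, random k
  for (s in 1:5) {
    set.seed(s)
    n <- 12
    mm <- matrix(rpois(n^2, 6), n, n); mm <- mm + t(mm); diag(mm) <- 0
    k <- sample(1:5, 1)
    sig <- insulation_signal(mm, k)
    brute <- sapply(1:(n - 1), function(b) {
      rows <- max(1, b - k + 1):b
      cols <- (b + 1):min(n, b + k)
      mean(mm[rows, cols, drop = FALSE])
    })
    expect_equal(sig, brute)
  }

  expect_error(insulation_signal(m, 4), "k must")
})

test_that("signal excludes pairs touching gap bins", {
  m <- matrix(5, 6, 6); diag(m) <- 0
  gaps <- c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE)
  sig <- insulation_signal(m, 2, gap_mask = gaps)
  expect_equal(sig, rep(5, 5))  # all remaining pairs have value 5
})

test_that("call_tads recovers the two-block demarcation and handles plateaus", {
  cm <- two_block_matrix()
  sig <- insulation_signal(cm, 2, gap_mask = rep(FALSE, 6))
  expect_equal(sig, c(5, 3, 1, 3, 5))
  tads <- call_tads(cm, 2, statistical_filter = FALSE,
                    gap_mask = rep(FALSE, 6))
  expect_equal(tads$start_bin, c(0, 3))
  expect_equal(tads$end_bin, c(3, 6))

  # plateau minimum collapses to its leftmost boundary: superdiagonal
  # (5, 1, 1, 5) at k = 1 -> boundary at position 2 -> TADs [0,2), [2,5)
  p <- matrix(10, 5, 5)
  p[cbind(1:4, 2:5)] <- c(5, 1, 1, 5)
  p[cbind(2:5, 1:4)] <- c(5, 1, 1, 5)
  diag(p) <- 0
  tp <- call_tads(contact_matrix(p), 1, statistical_filter = FALSE,
                  gap_mask = rep(FALSE, 5))
  expect_equal(tp$start_bin, c(0, 2))
  expect_equal(tp$end_bin, c(2, 5))

  # uniform matrix: no local minima, a single TAD
  u <- matrix(4, 8, 8); diag(u) <- 0
  tu <- call_tads(contact_matrix(u), 2, statistical_filter = FALSE,
                  gap_mask = rep(FALSE, 8))
  expect_equal(nrow(tu), 1)
  expect_equal(c(tu$start_bin, tu$end_bin), c(0, 8))
})

test_that("TADs never span gap runs and respect chromosome relabeling", {
  st <- recovery_study(13, bins = 200, size_range = c(5, 30))
  cm <- st$matrices[[1]]
  gm <- rep(FALSE, 200); gm[81:90] <- TRUE  # force a gap run
  cmg <- contact_matrix({
    x <- cm$counts; x[gm, ] <- 0; x[, gm] <- 0; x
  }, chrom = cm$chrom, bin_size = cm$bin_size)
  tads <- call_tads(cmg, 5, gap_mask = gm)
  # no TAD overlaps bins 80..89 (0-based)
  expect_true(all(tads$end_bin <= 80 | tads$start_bin >= 90))

  relabeled <- contact_matrix(cmg$counts, chrom = "chrX",
                              bin_size = cmg$bin_size)
  tads2 <- call_tads(relabeled, 5, gap_mask = gm)
  expect_equal(tads$start_bin, tads2$start_bin)
  expect_equal(tads$end_bin, tads2$end_bin)
})

test_that("multi-k calls are independent, deterministic, and trend with k", {
  st <- recovery_study(21, bins = 300, size_range = c(5, 40))
  cm <- st$matrices[[1]]
  single <- call_tads(cm, 3, gap_mask = rep(FALSE, 300))
  multi <- call_tads_multi_k(cm, k_range = 3, gap_mask = rep(FALSE, 300))
  expect_equal(multi[["3"]], single)

  m1 <- call_tads_multi_k(cm, k_range = c(3, 8), gap_mask = rep(FALSE, 300))
  m2 <- call_tads_multi_k(cm, k_range = c(3, 8), gap_mask = rep(FALSE, 300))
  expect_identical(m1, m2)

  # raw insulation landscape: smaller k yields at least as many TADs in
  # >= 80% of seeds (with the boundary filter off the caller reflects the
  # granularity of the window directly)
  mono <- vapply(1:10, function(s) {
    cmx <- recovery_study(100 + s, bins = 300, size_range = c(5, 40))$matrices[[1]]
    nk <- vapply(call_tads_multi_k(cmx, k_range = c(3, 10, 18),
                                   gap_mask = rep(FALSE, 300),
                                   statistical_filter = FALSE),
                 nrow, integer(1))
    nk[1] >= nk[2] && nk[2] >= nk[3]
  }, logical(1))
  expect_gte(mean(mono), 0.8)
})

test_that("short TADs merge into the neighbour across the weaker demarcation", {
  st <- recovery_study(31, bins = 200, size_range = c(5, 30))
  tads <- call_tads(st$matrices[[1]], 5, min_tad_bins = 4,
                    gap_mask = rep(FALSE, 200))
  expect_true(all(tads$end_bin - tads$start_bin >= 4))
})
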