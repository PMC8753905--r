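# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# Two-block contact matrix: within-block value `hi`, cross-block `lo`,
# zero diagonal. Blocks are bins 1..b and (b+1)..n (1-based).
two_block_matrix <- function(n = 6, b = 3, hi = 5, lo = 1) {
  m <- matrix(lo, n, n)
  m[1:b, 1:b] <- hi
  m[(b + 1):n, (b + 1):n] <- hi
  diag(m) <- 0
  contact_matrix(m, chrom = "chrT", bin_size = 10000)
}

# Minimal gene model: one gene [1000, 5000) with exon [1000, 1500).
toy_gene_model <- function() {
  list(
    genes = data.frame(chrom = "chr1", start = 1000, end = 5000,
                       gene_id = "G1", stringsAsFactors = FALSE),
    exons = data.frame(chrom = "chr1", start = 1000, end = 1500,
                       gene_id = "G1", stringsAsFactors = FALSE)
  )
}

# Small hand-built catalog: 3 diseases (1 cancer), 5 SNPs.
toy_catalog <- function() {
  disease_catalog(
    diseases = data.frame(
      efoId = c("EFO_1", "EFO_2", "EFO_3"),
      label = c("cancer A", "disease B", "disease C"),
      isCancer = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE),
    snps = data.frame(
      snpId = paste0("rs", 1:5), chrom = "chr1",
      pos0 = c(110000, 120000, 250000, 410000, 430000),
      category = c("intergenic", "intronic", "intergenic", "exonic",
                   "intergenic"),
      stringsAsFactors = FALSE),
    assoc = data.frame(
      efoId = c("EFO_1", "EFO_1", "EFO_2", "EFO_2", "EFO_3"),
      snpId = c("rs1", "rs2", "rs2", "rs3", "rs4"),
      stringsAsFactors = FALSE)
  )
}

# Exhaustive-enumeration oracle for the hypergeometric upper tail:
# enumerate all C(N, Q) draws from a labelled population.
hyper_upper_enum <- function(q, N, n, Q) {
  pop <- c(rep(TRUE, n), rep(FALSE, N - n))
  draws <- utils::combn(N, Q)
  hits <- colSums(matrix(pop[draws], nrow = Q))
  mean(hits >= q)
}

# Boundary precision/recall of a TAD call against planted truth, with
# +/- tol bins tolerance. Interior boundaries only.
boundary_agreement <- function(called_tads, truth_tads, n_bins, tol = 1) {
  interior <- function(df) {
    setdiff(unique(c(df$start_bin, df$end_bin)), c(0, n_bins))
  }
  tb <- interior(truth_tads)
  cb <- interior(called_tads)
  list(
    n_true = length(tb), n_called = length(cb),
    true_hit = sum(vapply(tb, function(b) any(abs(cb - b) <= tol), logical(1))),
    called_hit = sum(vapply(cb, function(b) any(abs(tb - b) <= tol), logical(1)))
  )
}

# Random permutation of group labels, seeded independently of the run.
with_shuffled_labels <- function(labels, seed) {
  set.seed(seed + 50000)
  sample(labels)
}

# Standard planted-TAD study for recovery tests.
recovery_study <- function(seed, n_chrom = 1, bins = 500,
                           size_range = c(5, 50)) {
  simulate_study(sim_config(
    n_chromosomes = n_chrom, bins_per_chromosome = bins,
    tad_size_range = size_range, baseline_intensity = 10,
    decay_exponent = 1, within_tad_factor = 4,
    n_cancers = 1, n_noncancers = 1, seed = seed))
}
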