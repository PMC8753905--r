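#' Simulation configuration for synthetic Hi-C and catalog data
#'
#' Bundles every parameter of the synthetic-data generator: the chromosome
#' layout, the planted TAD structure, the Poisson contact model, the gene
#' model, and the disease/SNP catalog. Defaults emulate a 10-kb-resolution
#' Hi-C experiment and a GWAS-catalog-like table in which each disease
#' carries on average 47 SNPs, of which roughly 18 are intergenic.
#'
#' The contact model for bins `i != j` is
#' `lambda = A * (1 + |i - j|)^(-alpha) * (B if i,j share a planted TAD else 1)`
#' with a Poisson count drawn once per unordered pair. `B = 1` together with
#' `border_placement_prob = 0` yields a global null in which no downstream
#' stage should find signal.
#'
#' @param n_chromosomes number of chromosomes.
#' @param bins_per_chromosome bins per chromosome (all equal).
#' @param bin_size bin width in bp (default 10000).
#' @param tad_size_range integer vector `c(min, max)` of planted TAD sizes
#'   in bins.
#' @param baseline_intensity `A`, expected contact count at distance 0.
#' @param decay_exponent `alpha > 0`, power-law distance decay.
#' @param within_tad_factor `B >= 1`, contact boost inside a planted TAD.
#' @param gap_bins list (one integer vector per chromosome) of 0-based bin
#'   indices with no coverage, or `NULL` for none.
#' @param n_cancers,n_noncancers number of cancer / non-cancer diseases.
#' @param frac_enriched_cancers,frac_enriched_noncancers fraction of each
#'   class planted with border enrichment.
#' @param snps_per_disease mean SNP count per disease (Poisson, min 1;
#'   default 47).
#' @param intergenic_fraction target fraction of the genome outside genes
#'   (default 0.4, so uniformly placed SNPs are ~40% intergenic).
#' @param exon_fraction fraction of genic bp lying in exons (default 0.085,
#'   so uniformly placed SNPs are ~5% exonic).
#' @param mean_gene_bp mean simulated gene length in bp (default 23000,
#'   around the median human gene length).
#' @param border_placement_prob `rho`: probability that a SNP of an enriched
#'   disease is placed uniformly inside the planted border union rather than
#'   uniformly in the genome.
#' @param snp_sharing_prob probability that a SNP is reused from an earlier
#'   disease of the same class instead of newly placed.
#' @param border_bp width of planted borders in bp (default 20000).
#' @param seed integer seed making the whole generator reproducible.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_chromosomes = 1, bins_per_chromosome = 100,
#'                   n_cancers = 3, n_noncancers = 5, seed = 1)
#' cfg$bin_size
#' @export
sim_config <- function(n_chromosomes = 2,
                       bins_per_chromosome = 500,
                       bin_size = 10000,
                       tad_size_range = c(5, 50),
                       baseline_intensity = 10,
                       decay_exponent = 1,
                       within_tad_factor = 4,
                       gap_bins = NULL,
                       n_cancers = 10,
                       n_noncancers = 30,
                       frac_enriched_cancers = 0,
                       frac_enriched_noncancers = 0,
                       snps_per_disease = 47,
                       intergenic_fraction = 0.4,
                       exon_fraction = 0.085,
                       mean_gene_bp = 23000,
                       border_placement_prob = 0,
                       snp_sharing_prob = 0.1,
                       border_bp = 20000,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    bins_per_chromosome = as.integer(bins_per_chromosome),
    bin_size = as.integer(bin_size),
    tad_size_range = as.integer(tad_size_range),
    baseline_intensity = baseline_intensity,
    decay_exponent = decay_exponent,
    within_tad_factor = within_tad_factor,
    gap_bins = gap_bins,
    n_cancers = as.integer(n_cancers),
    n_noncancers = as.integer(n_noncancers),
    frac_enriched_cancers = frac_enriched_cancers,
    frac_enriched_noncancers = frac_enriched_noncancers,
    snps_per_disease = snps_per_disease,
    intergenic_fraction = intergenic_fraction,
    exon_fraction = exon_fraction,
    mean_gene_bp = mean_gene_bp,
    border_placement_prob = border_placement_prob,
    snp_sharing_prob = snp_sharing_prob,
    border_bp = as.integer(border_bp),
    seed = as.integer(seed)
  )
  errs <- character()
  chk <- function(ok, msg) if (!ok) errs <<- c(errs, msg)
  chk(cfg$n_chromosomes >= 1, "n_chromosomes must be >= 1")
  chk(cfg$bins_per_chromosome >= 2, "bins_per_chromosome must be >= 2")
  chk(cfg$bin_size >= 1, "bin_size must be >= 1")
  chk(length(cfg$tad_size_range) == 2 &&
        cfg$tad_size_range[1] >= 1 &&
        cfg$tad_size_range[1] <= cfg$tad_size_range[2],
      "tad_size_range must be c(min, max) with 1 <= min <= max")
  chk(cfg$bins_per_chromosome >= 2 * cfg$tad_size_range[1],
      "bins_per_chromosome must be >= 2 * tad_size_range min")
  chk(cfg$baseline_intensity > 0, "baseline_intensity must be > 0")
  chk(cfg$decay_exponent > 0, "decay_exponent must be > 0")
  chk(cfg$within_tad_factor >= 1, "within_tad_factor must be >= 1")
  for (f in c("frac_enriched_cancers", "frac_enriched_noncancers",
              "intergenic_fraction", "exon_fraction",
              "border_placement_prob", "snp_sharing_prob")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] <= 1, paste(f, "must be in [0, 1]"))
  }
  chk(cfg$snps_per_disease > 0, "snps_per_disease must be > 0")
  if (length(errs)) {
    stop_invalid("invalid sim_config:\n  - %s", paste(errs, collapse = "\n  - "))
  }
  structure(cfg, class = "sim_config")
}

#' Plant a TAD partition on a chromosome layout
#'
#' Tiles each chromosome's non-gap extent with disjoint half-open bin
#' intervals whose sizes are drawn uniformly from `size_range`. A final
#' remainder shorter than `size_range[1]` is absorbed into the preceding
#' TAD, so all planted TADs (within a tileable segment) respect the minimum
#' size; a remainder of at least the minimum becomes its own (possibly
#' truncated) TAD.
#'
#' @param layout integer vector of chromosome lengths in bins, named by
#'   chromosome.
#' @param size_range integer `c(min, max)` TAD size in bins.
#' @param seed integer seed.
#' @param gap_bins optional list (per chromosome) of 0-based gap bin indices;
#'   each maximal non-gap run is tiled independently.
#' @return A data.frame with columns `chrom`, `start_bin`, `end_bin`
#'   (0-based, half-open).
#' @examples
#' plant_tads(c(chr1 = 10), c(3, 3), seed = 1)
#' @export
plant_tads <- function(layout, size_range, seed = NULL, gap_bins = NULL) {
  if (is.null(names(layout))) {
    names(layout) <- paste0("chr", seq_along(layout))
  }
  size_range <- as.integer(size_range)
  if (size_range[1] < 1 || size_range[1] > size_range[2]) {
    stop_invalid("size_range must satisfy 1 <= min <= max")
  }
  if (any(layout < size_range[1])) {
    stop_invalid("chromosome shorter than minimum TAD size (%d bins)",
                 size_range[1])
  }
  with_seed(seed, {
    out <- lapply(names(layout), function(ch) {
      n <- layout[[ch]]
      gaps <- sort(unique(as.integer(gap_bins[[ch]] %||% integer())))
      is_gap <- rep(FALSE, n)
      is_gap[gaps + 1] <- TRUE
      runs <- rle(is_gap)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths  # 0-based run starts
      segs <- which(!runs$values)
      pieces <- lapply(segs, function(s) {
        tile_segment(starts[s], ends[s], size_range)
      })
      df <- do.call(rbind, pieces)
      df$chrom <- ch
      df[, c("chrom", "start_bin", "end_bin")]
    })
    do.call(rbind, out)
  })
}

# Tile one half-open bin segment [from, to) with TADs of size in size_range.
tile_segment <- function(from, to, size_range) {
  len <- to - from
  if (len <= size_range[2]) {
    # Short segment (e.g., squeezed between gaps): a single TAD.
    return(data.frame(start_bin = from, end_bin = to))
  }
  starts <- integer()
  pos <- from
  repeat {
    size <- sample.int(size_range[2] - size_range[1] + 1L, 1L) +
      size_range[1] - 1L
    starts <- c(starts, pos)
    pos <- pos + size
    if (pos >= to) break
    if (to - pos < size_range[1]) {
      # remainder too small for its own TAD: absorb into the last one
      break
    }
  }
  data.frame(start_bin = starts, end_bin = c(starts[-1], to))
}

#' Simulate a Hi-C contact matrix with planted TAD structure
#'
#' Draws, once per unordered bin pair `i < j`, a Poisson count with mean
#' `A * (1 + |i - j|)^(-alpha)`, multiplied by `B` when both bins lie in the
#' same planted TAD. The matrix is symmetric by construction, its diagonal
#' is zero (self-contacts carry no insulation information) and gap rows and
#' columns are zeroed.
#'
#' @param tads data.frame of planted TADs for one chromosome (as from
#'   [plant_tads()], single `chrom`).
#' @param n_bins chromosome length in bins.
#' @param config a [sim_config()] (supplies `A`, `alpha`, `B`, `bin_size`).
#' @param gap_bins 0-based gap bin indices for this chromosome.
#' @param seed integer seed.
#' @return A [contact_matrix] object.
#' @export
simulate_contact_matrix <- function(tads, n_bins, config,
                                    gap_bins = NULL, seed = NULL) {
  A <- config$baseline_intensity
  alpha <- config$decay_exponent
  B <- config$within_tad_factor
  if (A <= 0 || alpha <= 0) {
    stop_invalid("baseline_intensity and decay_exponent must be positive")
  }
  chrom <- if (nrow(tads)) as.character(tads$chrom[1]) else "chr1"
  # TAD id per bin (NA outside any TAD)
  tad_of <- rep(NA_integer_, n_bins)
  for (t in seq_len(nrow(tads))) {
    tad_of[(tads$start_bin[t] + 1):tads$end_bin[t]] <- t
  }
  with_seed(seed, {
    idx <- which(upper.tri(matrix(0, n_bins, n_bins)), arr.ind = TRUE)
    d <- idx[, 2] - idx[, 1]
    same <- !is.na(tad_of[idx[, 1]]) & !is.na(tad_of[idx[, 2]]) &
      tad_of[idx[, 1]] == tad_of[idx[, 2]]
    lambda <- A * (1 + d)^(-alpha) * ifelse(same, B, 1)
    counts <- matrix(0, n_bins, n_bins)
    draws <- stats::rpois(nrow(idx), lambda)
    counts[idx] <- draws
    counts <- counts + t(counts)
    gap_mask <- rep(FALSE, n_bins)
    if (length(gap_bins)) {
      gap_mask[gap_bins + 1] <- TRUE
      counts[gap_mask, ] <- 0
      counts[, gap_mask] <- 0
    }
    contact_matrix(counts, chrom = chrom, bin_size = config$bin_size,
                   gap_mask = gap_mask)
  })
}

#' Simulate a toy gene model
#'
#' Lays non-overlapping genes along each chromosome, alternating intergenic
#' gaps and genes so that roughly `1 - intergenic_fraction` of the genome is
#' genic, and carves exons inside each gene so that roughly `exon_fraction`
#' of genic bp is exonic. Every gene has at least one exon strictly inside
#' it. Coordinates are 0-based half-open bp.
#'
#' @param layout named integer vector of chromosome lengths in bp.
#' @param intergenic_fraction target fraction of the genome outside genes.
#' @param exon_fraction target fraction of genic bp inside exons.
#' @param mean_gene_bp mean gene length.
#' @param seed integer seed.
#' @return An object of class `gene_model`: list with data.frames `genes`
#'   (`chrom`, `start`, `end`, `gene_id`) and `exons` (`chrom`, `start`,
#'   `end`, `gene_id`). With `intergenic_fraction = 1` the model is empty.
#' @export
simulate_gene_model <- function(layout,
                                intergenic_fraction = 0.4,
                                exon_fraction = 0.085,
                                mean_gene_bp = 23000,
                                seed = NULL) {
  if (is.null(names(layout))) {
    names(layout) <- paste0("chr", seq_along(layout))
  }
  empty <- function() {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     gene_id = character(), stringsAsFactors = FALSE)
    structure(list(genes = df, exons = df), class = "gene_model")
  }
  if (intergenic_fraction >= 1) return(empty())
  genic_frac <- 1 - intergenic_fraction
  with_seed(seed, {
    genes <- list(); exons <- list(); gid <- 0L
    for (ch in names(layout)) {
      L <- layout[[ch]]
      pos <- 0
      repeat {
        # intergenic gap, then a gene; mean gap chosen to hit genic_frac
        gap <- stats::rexp(1, rate = genic_frac / (mean_gene_bp * intergenic_fraction))
        glen <- max(2000, round(stats::rexp(1, rate = 1 / mean_gene_bp)))
        start <- round(pos + gap)
        end <- start + glen
        if (end >= L) break
        gid <- gid + 1L
        id <- sprintf("G%05d", gid)
        genes[[length(genes) + 1L]] <-
          data.frame(chrom = ch, start = start, end = end, gene_id = id,
                     stringsAsFactors = FALSE)
        exons[[length(exons) + 1L]] <- carve_exons(ch, start, end, id,
                                                   exon_fraction)
        pos <- end
      }
    }
    structure(
      list(genes = do.call(rbind, genes) %||% empty()$genes,
           exons = do.call(rbind, exons) %||% empty()$exons),
      class = "gene_model"
    )
  })
}

# Place exons inside one gene totalling ~frac of its length.
carve_exons <- function(chrom, start, end, gene_id, frac) {
  glen <- end - start
  total <- max(50, round(frac * glen))
  n_ex <- max(1L, stats::rpois(1, 2))
  cuts <- sort(sample.int(total - 1, min(n_ex - 1, total - 1)))
  sizes <- diff(c(0, cuts, total))
  sizes <- sizes[sizes > 0]
  # random non-overlapping placement: distribute the intron slack
  slack <- glen - sum(sizes)
  gaps <- if (slack > 0) {
    w <- stats::runif(length(sizes) + 1)
    round(slack * w / sum(w))
  } else {
    rep(0, length(sizes) + 1)
  }
  starts <- start + cumsum(gaps[seq_along(sizes)]) +
    c(0, cumsum(sizes[-length(sizes)]))
  ends <- pmin(starts + sizes, end)
  keep <- ends > starts
  data.frame(chrom = chrom, start = starts[keep], end = ends[keep],
             gene_id = gene_id, stringsAsFactors = FALSE)
}

#' Simulate a GWAS-catalog-like disease/SNP table
#'
#' Generates `n_cancers + n_noncancers` diseases, each with
#' `Q ~ max(1, Poisson(snps_per_disease))` SNPs. For a planted-enriched
#' disease each newly placed SNP falls uniformly inside the planted border
#' union with probability `border_placement_prob`, otherwise uniformly in
#' the genome; non-enriched diseases place all SNPs uniformly. With
#' probability `snp_sharing_prob` a SNP is instead reused from a previously
#' generated disease of the same class (cancer / non-cancer), which plants
#' the assortative SNP sharing the diseasome analysis should detect.
#' Positions are de-duplicated within a disease and every SNP is classified
#' against the gene model.
#'
#' @param truth a `truth_set` from [simulate_study()] internals, or any list
#'   with elements `layout_bp` (named bp lengths), `border_union`
#'   (data.frame `chrom`,`start`,`end` of planted borders) and `gene_model`.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return A [disease_catalog] with an extra attribute
#'   `enriched_disease_ids` (the planted ground truth).
#' @export
simulate_catalog <- function(truth, config, seed = NULL) {
  layout <- truth$layout_bp
  if (!length(layout) || sum(layout) <= 0) stop_invalid("empty genome")
  borders <- truth$border_union
  any_enriched <- config$frac_enriched_cancers > 0 ||
    config$frac_enriched_noncancers > 0
  if (any_enriched && (is.null(borders) || nrow(borders) == 0)) {
    stop_invalid("planted border union is empty but enriched diseases requested")
  }
  rho <- config$border_placement_prob

  n_dis <- config$n_cancers + config$n_noncancers
  is_cancer <- c(rep(TRUE, config$n_cancers), rep(FALSE, config$n_noncancers))
  efo <- sprintf("EFO_S%04d", seq_len(n_dis))
  label <- ifelse(is_cancer,
                  sprintf("synthetic cancer %d", seq_len(n_dis)),
                  sprintf("synthetic disease %d", seq_len(n_dis)))

  with_seed(seed, {
    enriched <- c(
      sample(which(is_cancer),
             round(config$frac_enriched_cancers * config$n_cancers)),
      sample(which(!is_cancer),
             round(config$frac_enriched_noncancers * config$n_noncancers))
    )
    genome_bp <- sum(layout)
    chr_off <- cumsum(c(0, as.numeric(layout[-length(layout)])))
    names(chr_off) <- names(layout)
    border_w <- if (!is.null(borders) && nrow(borders)) {
      borders$end - borders$start
    } else {
      numeric()
    }

    draw_uniform_genome <- function() {
      g <- stats::runif(1, 0, genome_bp)
      ci <- findInterval(g, c(chr_off, genome_bp), rightmost.closed = TRUE)
      ci <- min(ci, length(layout))
      c(ci, floor(g - chr_off[ci]))
    }
    draw_in_borders <- function() {
      bi <- sample.int(nrow(borders), 1, prob = border_w)
      pos <- borders$start[bi] + floor(stats::runif(1, 0, border_w[bi]))
      c(match(borders$chrom[bi], names(layout)), pos)
    }

    pool <- list(cancer = character(), noncancer = character())
    snp_tab <- new.env(parent = emptyenv())  # key "chrom:pos" -> snpId
    snp_rows <- list()
    assoc <- list()
    next_rs <- 0L

    for (d in seq_len(n_dis)) {
      Q <- max(1L, stats::rpois(1, config$snps_per_disease))
      cls <- if (is_cancer[d]) "cancer" else "noncancer"
      ids <- character(Q)
      for (s in seq_len(Q)) {
        if (length(pool[[cls]]) > 0 &&
            stats::runif(1) < config$snp_sharing_prob) {
          ids[s] <- sample(pool[[cls]], 1)
        } else {
          in_border <- (d %in% enriched) && stats::runif(1) < rho
          cp <- if (in_border) draw_in_borders() else draw_uniform_genome()
          key <- paste0(cp[1], ":", cp[2])
          if (!is.null(snp_tab[[key]])) {
            ids[s] <- snp_tab[[key]]
          } else {
            next_rs <- next_rs + 1L
            rs <- sprintf("rs%07d", next_rs)
            snp_tab[[key]] <- rs
            snp_rows[[next_rs]] <- data.frame(
              snpId = rs, chrom = names(layout)[cp[1]], pos0 = cp[2],
              stringsAsFactors = FALSE
            )
            ids[s] <- rs
          }
        }
      }
      ids <- unique(ids)
      pool[[cls]] <- unique(c(pool[[cls]], ids))
      assoc[[d]] <- data.frame(efoId = efo[d], snpId = ids,
                               stringsAsFactors = FALSE)
    }

    snps <- do.call(rbind, snp_rows)
    snps$category <- classify_snps(snps, truth$gene_model)
    catalog <- disease_catalog(
      diseases = data.frame(efoId = efo, label = label, isCancer = is_cancer,
                            stringsAsFactors = FALSE),
      snps = snps,
      assoc = do.call(rbind, assoc)
    )
    attr(catalog, "enriched_disease_ids") <- efo[sort(enriched)]
    catalog
  })
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running the whole generator: plants TADs on every
#' chromosome, simulates one contact matrix per chromosome, builds the toy
#' gene model and the disease catalog, and returns everything together with
#' the ground truth. Per-stage seeds are derived deterministically from
#' `config$seed` (or the `seed` argument).
#'
#' @param config a [sim_config()].
#' @param seed optional override of `config$seed`.
#' @return A list of class `tadrisk_study` with elements `config`,
#'   `matrices` (list of [contact_matrix]), `catalog` ([disease_catalog]),
#'   and `truth` (list: `layout_bins`, `layout_bp`, `planted_tads`,
#'   `border_union`, `gene_model`, `enriched_disease_ids`).
#' @examples
#' st <- simulate_study(sim_config(n_chromosomes = 1,
#'                                 bins_per_chromosome = 60,
#'                                 tad_size_range = c(5, 15),
#'                                 n_cancers = 2, n_noncancers = 3,
#'                                 seed = 7))
#' names(st$matrices)
#' @export
simulate_study <- function(config, seed = NULL) {
  seed <- seed %||% config$seed
  layout_bins <- setNames(rep(config$bins_per_chromosome, config$n_chromosomes),
                          paste0("chr", seq_len(config$n_chromosomes)))
  layout_bp <- layout_bins * config$bin_size

  tads <- plant_tads(layout_bins, config$tad_size_range,
                     seed = derive_seed(seed, 1),
                     gap_bins = config$gap_bins)
  borders <- extract_borders(tads, bin_size = config$bin_size,
                             border_bp = config$border_bp)
  gene_model <- simulate_gene_model(layout_bp,
                                    intergenic_fraction = config$intergenic_fraction,
                                    exon_fraction = config$exon_fraction,
                                    mean_gene_bp = config$mean_gene_bp,
                                    seed = derive_seed(seed, 2))
  matrices <- lapply(seq_along(layout_bins), function(i) {
    ch <- names(layout_bins)[i]
    simulate_contact_matrix(tads[tads$chrom == ch, , drop = FALSE],
                            n_bins = layout_bins[[i]],
                            config = config,
                            gap_bins = config$gap_bins[[ch]],
                            seed = derive_seed(seed, 100 + i))
  })
  names(matrices) <- names(layout_bins)

  truth <- list(
    layout_bins = layout_bins,
    layout_bp = layout_bp,
    planted_tads = tads,
    border_union = granges_to_intervals(borders$union),
    gene_model = gene_model
  )
  catalog <- simulate_catalog(truth, config, seed = derive_seed(seed, 3))
  truth$enriched_disease_ids <- attr(catalog, "enriched_disease_ids")

  structure(
    list(config = config, matrices = matrices, catalog = catalog,
         truth = truth),
    class = "tadrisk_study"
  )
}

#' Write a synthetic study to plain-text files
#'
#' One dense-TSV contact matrix per chromosome, the catalog as TSV
#' (`snpId`, `chrom`, `pos` 1-based, `efoId`, `diseaseLabel`, `isCancer`,
#' `category`), the planted TADs, borders and gene model as BED, and the
#' planted-enriched disease ids as JSON.
#'
#' @param study a `tadrisk_study` from [simulate_study()].
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(study$matrices)) {
    write_dense_matrix(study$matrices[[ch]],
                       file.path(out_dir, sprintf("matrix_%s.tsv", ch)))
  }
  cat_df <- merge(study$catalog$assoc, study$catalog$snps, by = "snpId")
  cat_df <- merge(cat_df, study$catalog$diseases, by = "efoId")
  out <- data.frame(snpId = cat_df$snpId, chrom = cat_df$chrom,
                    pos = cat_df$pos0 + 1, efoId = cat_df$efoId,
                    diseaseLabel = cat_df$label, isCancer = cat_df$isCancer,
                    category = cat_df$category, stringsAsFactors = FALSE)
  out <- out[order(out$efoId, out$snpId), ]
  utils::write.table(out, file.path(out_dir, "catalog.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tads <- study$truth$planted_tads
  attr(tads, "bin_size") <- study$config$bin_size
  write_bed(tads, file.path(out_dir, "planted_tads.bed"), k = "truth")
  bu <- study$truth$border_union
  gr <- intervals_to_granges(bu$chrom, bu$start, bu$end)
  names(gr) <- sprintf("planted_border_%d", seq_along(gr))
  rtracklayer::export(gr, file.path(out_dir, "planted_borders.bed"),
                      format = "BED")
  gm <- study$truth$gene_model
  if (nrow(gm$genes)) {
    ggr <- intervals_to_granges(gm$genes$chrom, gm$genes$start, gm$genes$end)
    names(ggr) <- gm$genes$gene_id
    rtracklayer::export(ggr, file.path(out_dir, "genes.bed"), format = "BED")
    egr <- intervals_to_granges(gm$exons$chrom, gm$exons$start, gm$exons$end)
    names(egr) <- sprintf("%s_exon%d", gm$exons$gene_id, seq_along(egr))
    rtracklayer::export(egr, file.path(out_dir, "exons.bed"), format = "BED")
  }
  jsonlite::write_json(
    list(enriched_disease_ids = study$truth$enriched_disease_ids),
    file.path(out_dir, "truth.json"), auto_unbox = FALSE
  )
  invisible(out_dir)
}

#' @export
print.tadrisk_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d chromosome(s) x %d bins (%d bp), %d diseases (%d cancers), %d planted-enriched\n",
    x$config$n_chromosomes, x$config$bins_per_chromosome, x$config$bin_size,
    nrow(x$catalog$diseases), sum(x$catalog$diseases$isCancer),
    length(x$truth$enriched_disease_ids)
  ))
  invisible(x)
}
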