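# End-to-end orchestration: simulate or ingest matrices, call TADs across
# k, annotate the catalog, run enrichment and the group comparison, build
# diseasome reports, and write a plain-text results bundle.

#' Validate and normalize a pipeline configuration
#'
#' Fills defaults (`k_range` 3..20, `border_bp` 20000, `alpha` 0.05,
#' `n_draws` 1000, genome-based null, BH within groups) and reports *all*
#' violations together rather than stopping at the first.
#'
#' @param config named list (possibly empty). Recognized fields:
#'   `mode` ("synthetic" or "dense_tsv"), `sim` (a [sim_config()] or list of
#'   its arguments), `matrix_files`/`chroms`/`bin_size` (dense_tsv mode),
#'   `catalog_file`, `efo_disease_ids`, `efo_cancer_ids`, `dataset`,
#'   `k_range`, `border_bp`, `null_model`, `category_filters`, `mt_scheme`,
#'   `alpha`, `statistical_filter`, `min_tad_bins`, `gap_zero_fraction`,
#'   `edge_threshold`, `n_draws`, `out_dir`, `seed`, `write_outputs`.
#' @return Normalized config list (class `pipeline_config`), or an error
#'   listing every violation.
#' @export
validate_config <- function(config = list()) {
  defaults <- list(
    mode = "synthetic", dataset = "ds1", k_range = 3:20, border_bp = 20000,
    null_model = "genome_based", category_filters = "all",
    mt_scheme = "bh_within_group", alpha = 0.05,
    statistical_filter = TRUE, min_tad_bins = 2, gap_zero_fraction = 0.05,
    edge_threshold = 1, n_draws = 1000, out_dir = NULL, seed = 1L,
    write_outputs = FALSE, sim = list()
  )
  cfg <- utils::modifyList(defaults, config)
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$mode %in% c("synthetic", "dense_tsv"),
      "mode must be 'synthetic' or 'dense_tsv'")
  chk(length(cfg$k_range) >= 1 && all(cfg$k_range >= 1),
      "k_range must be a nonempty set of window sizes >= 1")
  if (length(cfg$k_range) >= 1 && is.numeric(cfg$k_range)) {
    chk(min(cfg$k_range) <= max(cfg$k_range), "k_range must be ordered")
  }
  chk(is.numeric(cfg$border_bp) && cfg$border_bp > 0,
      "border_bp must be > 0")
  chk(cfg$null_model %in% c("genome_based", "snp_based"),
      "null_model must be 'genome_based' or 'snp_based'")
  chk(all(cfg$category_filters %in% c("all", "exonic", "intronic",
                                      "intergenic")),
      "category_filters must be among all/exonic/intronic/intergenic")
  chk(cfg$mt_scheme %in% c("bh_within_group", "bh_global", "none"),
      "mt_scheme must be bh_within_group/bh_global/none")
  chk(is.numeric(cfg$alpha) && cfg$alpha > 0 && cfg$alpha < 1,
      "alpha must be in (0, 1)")
  chk(is.numeric(cfg$n_draws) && cfg$n_draws >= 1,
      "n_draws must be >= 1")
  chk(is.numeric(cfg$edge_threshold) && cfg$edge_threshold >= 1,
      "edge_threshold must be >= 1")
  if (cfg$mode == "dense_tsv") {
    chk(!is.null(cfg$matrix_files) && all(file.exists(cfg$matrix_files)),
        "dense_tsv mode requires existing matrix_files")
    chk(!is.null(cfg$catalog_file) && file.exists(cfg$catalog_file %||% ""),
        "dense_tsv mode requires an existing catalog_file")
  }
  if (cfg$mode == "synthetic" && !inherits(cfg$sim, "sim_config")) {
    cfg$sim <- tryCatch(do.call(sim_config, cfg$sim),
                        error = function(e) {
                          errs <<- c(errs, conditionMessage(e))
                          NULL
                        })
  }
  if (length(errs)) {
    stop_invalid("invalid pipeline config:\n  - %s",
                 paste(errs, collapse = "\n  - "))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full TAD-border enrichment pipeline
#'
#' Stages: (1) obtain contact matrices and a disease catalog (synthetic
#' generation, or dense-TSV + catalog files); (2) detect gaps and call TADs
#' at every `k` in `k_range`; (3) extract 20-kb borders and their unions;
#' (4) compute per-k SNP border membership and the majority border-SNP set;
#' (5) per-disease hypergeometric enrichment, BH correction, majority-over-k
#' calls and the p-value histogram; (6) cancer vs non-cancer Fisher
#' comparison; (7) diseasome coherence report. Re-running with the same
#' config and seed reproduces identical outputs.
#'
#' @param config a [validate_config()]-ready list or `pipeline_config`.
#' @return An object of class `tadrisk_run`: list with `config`, `study`
#'   (synthetic mode only), `tads_by_k`, `borders_by_k`,
#'   `border_fractions`, `membership`, `border_snp_ids`, `results`
#'   (per-filter enrichment tables), `majority` (per-filter), `histogram`,
#'   `comparison` (per-filter `group_comparison`), `coherence`, and
#'   `counts` (bookkeeping: diseases tested, SNPs, gap bins).
#' @examples
#' \donttest{
#' cfg <- list(sim = list(n_chromosomes = 1, bins_per_chromosome = 120,
#'                        tad_size_range = c(5, 15), n_cancers = 3,
#'                        n_noncancers = 5, seed = 2),
#'             k_range = 3:5, n_draws = 100, seed = 2)
#' run <- run_pipeline(cfg)
#' print(run)
#' }
#' @export
run_pipeline <- function(config = list()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)

  # --- stage 1: inputs ------------------------------------------------
  if (cfg$mode == "synthetic") {
    study <- simulate_study(cfg$sim, seed = cfg$seed)
    matrices <- study$matrices
    catalog <- study$catalog
    genome_bp <- sum(study$truth$layout_bp)
  } else {
    chroms <- cfg$chroms %||% paste0("chr", seq_along(cfg$matrix_files))
    matrices <- mapply(function(f, ch) {
      read_dense_matrix(f, chrom = ch, bin_size = cfg$bin_size %||% 10000)
    }, cfg$matrix_files, chroms, SIMPLIFY = FALSE)
    names(matrices) <- chroms
    catalog <- load_gwas_catalog(cfg$catalog_file,
                                 cfg$efo_disease_ids, cfg$efo_cancer_ids)
    genome_bp <- sum(vapply(matrices, function(m) {
      n_bins(m) * m$bin_size
    }, numeric(1)))
    study <- NULL
  }

  # --- stage 2: gaps + TAD calling ------------------------------------
  gap_masks <- lapply(matrices, function(m) {
    m$gap_mask %||% detect_gaps(m, cfg$gap_zero_fraction)
  })
  tads_by_k <- lapply(as.character(cfg$k_range), function(kname) {
    k <- as.integer(kname)
    per_chrom <- lapply(names(matrices), function(ch) {
      call_tads(matrices[[ch]], k,
                min_tad_bins = cfg$min_tad_bins,
                statistical_filter = cfg$statistical_filter,
                gap_mask = gap_masks[[ch]])
    })
    out <- do.call(rbind, per_chrom)
    attr(out, "bin_size") <- matrices[[1]]$bin_size
    out
  })
  names(tads_by_k) <- as.character(cfg$k_range)

  # --- stage 3: borders -----------------------------------------------
  borders_by_k <- lapply(tads_by_k, extract_borders,
                         border_bp = cfg$border_bp)
  border_fractions <- vapply(borders_by_k, border_genome_fraction,
                             numeric(1), genome_length_bp = genome_bp)

  # --- stage 4: membership + majority border SNPs ---------------------
  membership <- snp_border_membership(catalog$snps, borders_by_k)
  border_snp_ids <- majority_border_snp_set(membership)

  # --- stage 5: enrichment --------------------------------------------
  results <- list(); majority <- list(); comparison <- list()
  for (filt in cfg$category_filters) {
    res <- test_all_diseases(catalog, borders_by_k,
                             null_model = cfg$null_model,
                             category_filter = filt,
                             genome_bp = genome_bp,
                             dataset = cfg$dataset)
    res <- adjust_pvalues(res, scheme = cfg$mt_scheme, alpha = cfg$alpha)
    maj <- majority_enriched(res, k_range = cfg$k_range, alpha = cfg$alpha)
    results[[filt]] <- res
    majority[[filt]] <- maj
    comparison[[filt]] <- fisher_group_comparison(
      maj$majority_enriched[maj$isCancer],
      maj$majority_enriched[!maj$isCancer]
    )
  }
  histogram <- enrichment_histogram(results[[cfg$category_filters[1]]])

  # --- stage 6: diseasome ----------------------------------------------
  maj1 <- majority[[cfg$category_filters[1]]]
  enriched_ids <- maj1$efoId[maj1$majority_enriched]
  coherence <- if ("category" %in% names(catalog$snps)) {
    coherence_report(catalog, border_snp_ids, enriched_ids,
                     n_draws = cfg$n_draws,
                     seed = derive_seed(cfg$seed, 9000),
                     edge_threshold = cfg$edge_threshold)
  } else {
    NULL
  }

  run <- structure(
    list(config = cfg, study = study, tads_by_k = tads_by_k,
         borders_by_k = borders_by_k, border_fractions = border_fractions,
         membership = membership, border_snp_ids = border_snp_ids,
         results = results, majority = majority, histogram = histogram,
         comparison = comparison, coherence = coherence,
         counts = list(
           diseases_tested = nrow(catalog$diseases),
           snps = nrow(catalog$snps),
           border_snps = length(border_snp_ids),
           gap_bins = sum(vapply(gap_masks, sum, numeric(1)))
         ),
         catalog = catalog, genome_bp = genome_bp),
    class = "tadrisk_run"
  )
  if (isTRUE(cfg$write_outputs)) {
    if (is.null(cfg$out_dir)) stop_invalid("write_outputs requires out_dir")
    write_run_outputs(run, cfg$out_dir)
  }
  run
}

#' @export
print.tadrisk_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("TAD-border enrichment run (%s mode, dataset %s)\n",
              cfg$mode, cfg$dataset))
  cat(sprintf("  k range %s-%s; border %d bp; null model %s; BH scheme %s; alpha %g\n",
              min(cfg$k_range), max(cfg$k_range), cfg$border_bp,
              cfg$null_model, cfg$mt_scheme, cfg$alpha))
  cat(sprintf("  genome %.3g bp; border fraction %.3f-%.3f across k\n",
              x$genome_bp, min(x$border_fractions), max(x$border_fractions)))
  cat(sprintf("  %d diseases, %d SNPs (%d majority border SNPs)\n",
              x$counts$diseases_tested, x$counts$snps, x$counts$border_snps))
  for (filt in names(x$majority)) {
    maj <- x$majority[[filt]]
    cmp <- x$comparison[[filt]]
    cat(sprintf(
      "  [%s] majority-enriched: %d/%d cancers, %d/%d non-cancers; Fisher p = %.4g %s\n",
      filt, sum(maj$majority_enriched & maj$isCancer), sum(maj$isCancer),
      sum(maj$majority_enriched & !maj$isCancer), sum(!maj$isCancer),
      cmp$fisher_p, cmp$stars))
  }
  invisible(x)
}

#' Write the results bundle as plain-text files
#'
#' TADs and borders per k as BED, enrichment and majority tables, the
#' histogram, membership matrix and coherence report as TSV, the group
#' comparison and a provenance record as JSON.
#'
#' @param run a `tadrisk_run`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (kname in names(run$tads_by_k)) {
    write_bed(run$tads_by_k[[kname]],
              file.path(out_dir, sprintf("tads_%s_k%s.bed", cfg$dataset, kname)))
    write_bed(run$borders_by_k[[kname]],
              file.path(out_dir, sprintf("borders_%s_k%s.bed", cfg$dataset, kname)),
              k = kname)
  }
  for (filt in names(run$results)) {
    tsv(run$results[[filt]], sprintf("enrichment_%s_%s.tsv", cfg$dataset, filt))
    tsv(run$majority[[filt]], sprintf("majority_%s_%s.tsv", cfg$dataset, filt))
  }
  memb <- data.frame(snpId = rownames(run$membership), run$membership,
                     check.names = FALSE)
  tsv(memb, sprintf("membership_%s.tsv", cfg$dataset))
  tsv(run$histogram$bins, sprintf("histogram_%s.tsv", cfg$dataset))
  if (!is.null(run$coherence)) {
    tsv(run$coherence, sprintf("coherence_%s.tsv", cfg$dataset))
  }
  comp <- lapply(run$comparison, function(cmp) {
    list(table = as.data.frame(as.table(cmp$table)),
         fisher_p = cmp$fisher_p, stars = cmp$stars,
         degenerate = cmp$degenerate)
  })
  jsonlite::write_json(comp, file.path(out_dir, sprintf("comparison_%s.json",
                                                        cfg$dataset)),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(
    dataset = cfg$dataset, mode = cfg$mode, seed = cfg$seed,
    k_range = cfg$k_range, border_bp = cfg$border_bp,
    null_model = cfg$null_model, mt_scheme = cfg$mt_scheme,
    alpha = cfg$alpha,
    package_version = as.character(utils::packageVersion("tadrisk")),
    r_version = R.version.string
  )
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a flat YAML pipeline configuration
#'
#' @param path YAML file with keys matching [validate_config()] fields
#'   (nested `sim:` block for the generator).
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}
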