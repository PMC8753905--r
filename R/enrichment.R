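# Per-disease hypergeometric TAD-border enrichment, multiple-testing
# correction, majority-over-k calls, histograms and the cancer vs
# non-cancer Fisher comparison.

#' Hypergeometric upper-tail probability
#'
#' Probability of observing at least `q` successes when drawing `Q` elements
#' without replacement from a population of size `N` containing `n`
#' successes: `P = sum_{x >= q} C(n, x) C(N - n, Q - x) / C(N, Q)`.
#' Computed with [stats::phyper()], numerically stable up to genome-scale
#' populations (`N ~ 3e9`). The distribution is symmetric in `n` and `Q`:
#' `H(q | N, n, Q) = H(q | N, Q, n)`.
#'
#' @param q observed number of successes (border SNPs).
#' @param N population size (genome bp, or number of catalog SNPs).
#' @param n successes in the population (border bp, or border SNPs).
#' @param Q number of draws (SNPs of the disease).
#' @return Upper-tail probability in `(0, 1]`; `q = 0` gives exactly 1.
#' @examples
#' hypergeom_upper_tail(2, N = 10, n = 3, Q = 4)  # 1/3
#' @export
hypergeom_upper_tail <- function(q, N, n, Q) {
  if (any(q < 0) || any(n < 0) || any(Q < 0) || any(N <= 0) ||
      any(n > N) || any(Q > N) || any(q > pmin(n, Q))) {
    stop_invalid("invalid hypergeometric parameters: q=%s N=%s n=%s Q=%s",
                 paste(q, collapse = ","), paste(N, collapse = ","),
                 paste(n, collapse = ","), paste(Q, collapse = ","))
  }
  stats::phyper(q - 1, n, N - n, Q, lower.tail = FALSE)
}

#' Null-model parameters for the enrichment test
#'
#' Two null models are supported. In the *genome-based* model chance means
#' drawing the same number of pointwise loci uniformly in the genome: `N` is
#' the genome length in bp and `n` the bp inside the border union. In the
#' *SNP-based* model chance means drawing from the catalog itself: `N` is
#' the number of distinct disease-associated SNPs (each counted once) and
#' `n` how many of them lie in borders at the given `k`.
#'
#' @param model `"genome_based"` or `"snp_based"`.
#' @param genome_bp,border_union_bp genome and border-union sizes in bp
#'   (genome-based model).
#' @param n_snps,n_border_snps distinct catalog SNPs and how many are in
#'   borders (SNP-based model).
#' @return list with `model`, `N`, `n`.
#' @export
make_null_params <- function(model = c("genome_based", "snp_based"),
                             genome_bp = NULL, border_union_bp = NULL,
                             n_snps = NULL, n_border_snps = NULL) {
  model <- match.arg(model)
  if (model == "genome_based") {
    N <- genome_bp; n <- border_union_bp
  } else {
    N <- n_snps; n <- n_border_snps
  }
  if (is.null(N) || is.null(n)) stop_invalid("missing sizes for %s null", model)
  if (n > N) stop_invalid("n (%s) exceeds N (%s)", n, N)
  list(model = model, N = N, n = n)
}

#' Per-disease enrichment tests across window sizes
#'
#' For every disease and every `k`, tests whether the disease's SNPs
#' (optionally restricted to one category) fall inside the TAD-border union
#' at that `k` more often than the null model predicts, using the
#' hypergeometric upper tail with `Q` = number of (filtered) SNPs of the
#' disease and `q` = how many of them are in borders. Diseases with `Q = 0`
#' after filtering are skipped.
#'
#' @param catalog a [disease_catalog]; SNPs need a `category` column when
#'   `category_filter != "all"`.
#' @param borders_by_k named list of [border_set] per `k`.
#' @param null_model `"genome_based"` (default, the more conservative) or
#'   `"snp_based"`.
#' @param category_filter one of `"all"`, `"exonic"`, `"intronic"`,
#'   `"intergenic"`.
#' @param genome_bp genome length in bp (required for the genome-based
#'   null). Gap regions are included in this length by default; pass a
#'   reduced length to exclude them.
#' @param dataset identifier recorded in the output (default "ds1").
#' @return data.frame with one row per (disease, k): `efoId`, `isCancer`,
#'   `dataset`, `k`, `filter`, `null_model`, `q`, `Q`, `n`, `N`, `p_raw`.
#' @export
test_all_diseases <- function(catalog, borders_by_k,
                              null_model = c("genome_based", "snp_based"),
                              category_filter = c("all", "exonic", "intronic",
                                                  "intergenic"),
                              genome_bp = NULL, dataset = "ds1") {
  null_model <- match.arg(null_model)
  category_filter <- match.arg(category_filter)
  snps <- catalog$snps
  if (category_filter != "all") {
    if (!"category" %in% names(snps)) {
      stop_invalid("catalog SNPs carry no category; run classify_snps() first")
    }
    snps <- snps[snps$category == category_filter, , drop = FALSE]
  }
  if (null_model == "genome_based" && is.null(genome_bp)) {
    stop_invalid("genome_bp is required for the genome-based null model")
  }
  memb <- snp_border_membership(snps, borders_by_k)
  assoc <- catalog$assoc[catalog$assoc$snpId %in% snps$snpId, , drop = FALSE]
  snp_sets <- split(assoc$snpId, assoc$efoId)
  is_cancer <- stats::setNames(catalog$diseases$isCancer,
                               catalog$diseases$efoId)

  rows <- list()
  skipped <- setdiff(catalog$diseases$efoId, names(snp_sets))
  if (length(skipped)) {
    message(sprintf("test_all_diseases: %d disease(s) skipped (no %s SNPs)",
                    length(skipped), category_filter))
  }
  for (kname in names(borders_by_k)) {
    np <- if (null_model == "genome_based") {
      make_null_params("genome_based", genome_bp = genome_bp,
                       border_union_bp = borders_by_k[[kname]]$union_bp)
    } else {
      make_null_params("snp_based", n_snps = nrow(snps),
                       n_border_snps = sum(memb[, kname]))
    }
    in_border <- memb[, kname]
    for (efo in names(snp_sets)) {
      ids <- snp_sets[[efo]]
      Q <- length(ids)
      q <- sum(in_border[ids])
      rows[[length(rows) + 1L]] <- data.frame(
        efoId = efo, isCancer = unname(is_cancer[efo]), dataset = dataset,
        k = as.integer(kname), filter = category_filter,
        null_model = null_model, q = q, Q = Q, n = np$n, N = np$N,
        p_raw = hypergeom_upper_tail(q, N = np$N, n = np$n, Q = Q),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiple-testing correction of enrichment p-values
#'
#' Benjamini-Hochberg step-up within strata. The default scheme
#' (`bh_within_group`) corrects cancers and non-cancer diseases separately
#' — the two groups are defined on biological grounds independently of the
#' testing — within each (dataset, k, filter, null model) stratum, so that
#' each TAD landscape is corrected on its own. `bh_global` pools the two
#' groups; `none` passes raw p-values through.
#'
#' @param results data.frame from [test_all_diseases()].
#' @param scheme `"bh_within_group"`, `"bh_global"` or `"none"`.
#' @param alpha significance level used for the `enriched` flag
#'   (default 0.05).
#' @return `results` with columns `p_adj` and `enriched` appended.
#' @export
adjust_pvalues <- function(results,
                           scheme = c("bh_within_group", "bh_global", "none"),
                           alpha = 0.05) {
  scheme <- match.arg(scheme)
  if (nrow(results) == 0) {
    results$p_adj <- numeric(0); results$enriched <- logical(0)
    return(results)
  }
  strata_cols <- intersect(c("dataset", "k", "filter", "null_model"),
                           names(results))
  key <- do.call(paste, c(results[strata_cols], sep = "\r"))
  if (scheme == "bh_within_group") {
    key <- paste(key, results$isCancer, sep = "\r")
  }
  results$p_adj <- results$p_raw
  if (scheme != "none") {
    for (g in unique(key)) {
      sel <- key == g
      results$p_adj[sel] <- stats::p.adjust(results$p_raw[sel], method = "BH")
    }
  }
  results$enriched <- results$p_adj <= alpha
  results
}

#' Majority-over-k enrichment call
#'
#' A disease counts as enriched when its adjusted p-value is at or below
#' `alpha` for strictly more than half of the window sizes in `k_range`.
#' Missing (disease, k) combinations count as not enriched.
#'
#' @param results data.frame from [adjust_pvalues()] (one dataset/filter/null
#'   stratum).
#' @param k_range the window sizes over which the majority is taken
#'   (default: all `k` present).
#' @param alpha significance level (default 0.05).
#' @return data.frame `efoId`, `isCancer`, `n_significant`, `n_k`,
#'   `majority_enriched`.
#' @export
majority_enriched <- function(results, k_range = NULL, alpha = 0.05) {
  k_range <- k_range %||% sort(unique(results$k))
  res <- results[results$k %in% k_range, , drop = FALSE]
  missing_k <- length(setdiff(k_range, unique(res$k)))
  if (missing_k > 0) {
    message(sprintf("majority_enriched: %d k value(s) absent, counted as not enriched",
                    missing_k))
  }
  sig <- res$p_adj <= alpha
  agg <- stats::aggregate(sig, by = list(efoId = res$efoId), FUN = sum)
  names(agg)[2] <- "n_significant"
  is_cancer <- res$isCancer[match(agg$efoId, res$efoId)]
  data.frame(
    efoId = agg$efoId, isCancer = is_cancer,
    n_significant = agg$n_significant, n_k = length(k_range),
    majority_enriched = agg$n_significant > length(k_range) / 2,
    stringsAsFactors = FALSE
  )
}

#' Histogram of corrected enrichment p-values
#'
#' Bins `-log10(p_adj)` with fixed width on `[0, truncation]`, normalized
#' separately for cancers and non-cancer diseases; one entry per
#' (disease, dataset, k) row of `results`. Values beyond the truncation are
#' clamped out of the displayed range but kept in a `tail` count, which
#' participates in the normalization. The cancer minus non-cancer
#' difference histogram highlights the relative predominance of cancers at
#' small p.
#'
#' @param results data.frame with `p_adj` and `isCancer`.
#' @param truncation display limit on `-log10(p)` (default 4).
#' @param bin_width histogram bin width in `-log10` units (default 0.1).
#' @param normalize_by_group scale each group to unit mass?
#' @return list with `bins` (data.frame: `lower`, `upper`, `cancer`,
#'   `noncancer`, `difference`), `tail` (named counts beyond truncation) and
#'   `n` (group sizes).
#' @export
enrichment_histogram <- function(results, truncation = 4, bin_width = 0.1,
                                 normalize_by_group = TRUE) {
  breaks <- seq(0, truncation, by = bin_width)
  v <- -log10(results$p_adj)
  grp <- ifelse(results$isCancer, "cancer", "noncancer")
  nb <- length(breaks) - 1
  count_group <- function(g) {
    x <- v[grp == g]
    tail_n <- sum(x > truncation)
    x <- x[x <= truncation]
    # left-closed, right-open bins; x == truncation folded into the last bin
    idx <- pmin(findInterval(x, breaks), nb)
    list(counts = tabulate(idx, nbins = nb), tail = tail_n, n = sum(grp == g))
  }
  ca <- count_group("cancer"); nc <- count_group("noncancer")
  norm <- function(counts, tail_n, n) {
    if (!normalize_by_group || n == 0) return(counts)
    counts / n
  }
  bins <- data.frame(
    lower = breaks[-length(breaks)], upper = breaks[-1],
    cancer = norm(ca$counts, ca$tail, ca$n),
    noncancer = norm(nc$counts, nc$tail, nc$n)
  )
  bins$difference <- bins$cancer - bins$noncancer
  list(bins = bins,
       tail = c(cancer = ca$tail, noncancer = nc$tail),
       n = c(cancer = ca$n, noncancer = nc$n))
}

#' Cancer vs non-cancer comparison of enrichment fractions
#'
#' Two-sided Fisher's exact test on the 2x2 table of (enriched / not) by
#' (cancer / non-cancer), with significance stars. A table with a zero
#' margin is flagged degenerate and reported with p = 1.
#'
#' @param cancer_flags logical vector: majority-enrichment flags of cancers.
#' @param noncancer_flags logical: flags of non-cancer diseases.
#' @return An object of class `group_comparison`: list with `table` (2x2),
#'   `fractions`, `fisher_p`, `stars`, `degenerate`.
#' @export
fisher_group_comparison <- function(cancer_flags, noncancer_flags) {
  tab <- matrix(c(sum(cancer_flags), sum(!cancer_flags),
                  sum(noncancer_flags), sum(!noncancer_flags)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("cancer", "noncancer"),
                                c("enriched", "not_enriched")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  structure(
    list(table = tab,
         fractions = c(cancer = if (sum(tab[1, ]) > 0) tab[1, 1] / sum(tab[1, ]) else NA,
                       noncancer = if (sum(tab[2, ]) > 0) tab[2, 1] / sum(tab[2, ]) else NA),
         fisher_p = p, stars = p_stars(p), degenerate = degenerate),
    class = "group_comparison"
  )
}

p_stars <- function(p) {
  if (p <= 1e-4) "****" else if (p <= 1e-3) "***" else if (p <= 0.01) "**"
  else if (p <= 0.05) "*" else ""
}

#' @export
print.group_comparison <- function(x, ...) {
  print(x$table)
  cat(sprintf("Fisher exact p = %.4g %s%s\n", x$fisher_p, x$stars,
              if (x$degenerate) " (degenerate table)" else ""))
  invisible(x)
}

#' Pool group comparisons over datasets
#'
#' Sums the per-dataset 2x2 tables (a disease contributes once per dataset)
#' and recomputes the Fisher test on the pooled table.
#'
#' @param comparisons list of `group_comparison` objects, or a list of lists
#'   `list(cancer_flags, noncancer_flags)`.
#' @return A pooled `group_comparison`.
#' @export
aggregate_over_datasets <- function(comparisons) {
  tabs <- lapply(comparisons, function(cmp) {
    if (inherits(cmp, "group_comparison")) cmp$table
    else fisher_group_comparison(cmp[[1]], cmp[[2]])$table
  })
  tab <- Reduce("+", tabs)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(tab)$p.value
  structure(
    list(table = tab,
         fractions = c(cancer = tab[1, 1] / max(1, sum(tab[1, ])),
                       noncancer = tab[2, 1] / max(1, sum(tab[2, ]))),
         fisher_p = p, stars = p_stars(p), degenerate = degenerate),
    class = "group_comparison"
  )
}
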