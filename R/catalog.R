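# Disease--SNP catalog handling: loading, category classification, border
# membership per window size, the majority rule, and the pairwise-distance
# audit.

#' Disease--SNP catalog container
#'
#' @param diseases data.frame `efoId`, `label`, `isCancer`.
#' @param snps data.frame `snpId`, `chrom`, `pos0` (0-based bp) and
#'   optionally `category`.
#' @param assoc data.frame `efoId`, `snpId`: one row per (disease, SNP)
#'   association, already de-duplicated.
#' @return An object of class `disease_catalog`.
#' @export
disease_catalog <- function(diseases, snps, assoc) {
  stopifnot(all(c("efoId", "label", "isCancer") %in% names(diseases)),
            all(c("snpId", "chrom", "pos0") %in% names(snps)),
            all(c("efoId", "snpId") %in% names(assoc)))
  if (anyDuplicated(diseases$efoId)) stop_invalid("duplicate disease ids")
  if (anyDuplicated(snps$snpId)) stop_invalid("duplicate SNP ids")
  if (anyDuplicated(assoc[, c("efoId", "snpId")])) {
    stop_invalid("duplicate (disease, SNP) associations")
  }
  bad <- setdiff(assoc$snpId, snps$snpId)
  if (length(bad)) stop_invalid("associations refer to unknown SNPs (%s...)", bad[1])
  structure(list(diseases = diseases, snps = snps, assoc = assoc),
            class = "disease_catalog")
}

#' @export
print.disease_catalog <- function(x, ...) {
  cat(sprintf(
    "Disease catalog: %d diseases (%d cancers, %d non-cancers), %d distinct SNPs, %d associations\n",
    nrow(x$diseases), sum(x$diseases$isCancer), sum(!x$diseases$isCancer),
    nrow(x$snps), nrow(x$assoc)))
  if ("category" %in% names(x$snps)) {
    tab <- table(factor(x$snps$category,
                        levels = c("exonic", "intronic", "intergenic")))
    cat(sprintf("  categories: %s\n",
                paste(sprintf("%s %.0f%%", names(tab),
                              100 * tab / sum(tab)), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.disease_catalog <- function(object, ...) {
  qs <- table(object$assoc$efoId)
  cat(sprintf("SNPs per disease: mean %.1f, median %.0f, range [%d, %d]\n",
              mean(qs), stats::median(qs), min(qs), max(qs)))
  print(object)
  invisible(object)
}

#' Load a GWAS-catalog-like association table
#'
#' Reads a tab-separated table of SNP--trait associations, keeps only traits
#' whose EFO id appears in the supplied disease list (the analog of the EFO
#' disease subtree, EFO_0000408), flags cancers by membership in the cancer
#' list (EFO_0000311 subtree), drops per-disease duplicate SNP entries
#' (one SNP can be reported by several studies) and rows with missing
#' coordinates. Input positions are 1-based and converted to 0-based
#' internally. Ontology traversal itself is a data-preparation step outside
#' this package: the id lists are consumed as plain text, one id per line.
#'
#' @param path TSV file with the association table.
#' @param efo_disease_ids character vector of EFO ids (or path to a plain
#'   text file, one per line) defining the disease universe.
#' @param efo_cancer_ids same, defining which diseases are cancers.
#' @param col_map named list mapping the internal names `snpId`, `chrom`,
#'   `pos`, `efoId`, `label` to the file's column names.
#' @return A [disease_catalog]. SNP categories are not assigned here; see
#'   [classify_snps()].
#' @export
load_gwas_catalog <- function(path, efo_disease_ids, efo_cancer_ids,
                              col_map = list(snpId = "snpId", chrom = "chrom",
                                             pos = "pos", efoId = "efoId",
                                             label = "diseaseLabel")) {
  read_ids <- function(x) {
    if (length(x) == 1 && file.exists(x)) readLines(x) else x
  }
  efo_disease_ids <- read_ids(efo_disease_ids)
  efo_cancer_ids <- read_ids(efo_cancer_ids)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- unlist(col_map[c("snpId", "chrom", "pos", "efoId")])
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_invalid("missing columns: %s", paste(miss, collapse = ", "))

  df <- data.frame(
    snpId = as.character(tab[[col_map$snpId]]),
    chrom = as.character(tab[[col_map$chrom]]),
    pos = suppressWarnings(as.numeric(tab[[col_map$pos]])),
    efoId = as.character(tab[[col_map$efoId]]),
    label = if (!is.null(col_map$label) && col_map$label %in% names(tab)) {
      as.character(tab[[col_map$label]])
    } else {
      as.character(tab[[col_map$efoId]])
    },
    stringsAsFactors = FALSE
  )
  n0 <- nrow(df)
  df <- df[df$efoId %in% efo_disease_ids, , drop = FALSE]
  dropped_trait <- n0 - nrow(df)
  n1 <- nrow(df)
  df <- df[!is.na(df$pos) & !is.na(df$chrom) & df$chrom != "" &
             !is.na(df$snpId) & df$snpId != "", , drop = FALSE]
  dropped_na <- n1 - nrow(df)
  if (dropped_na > 0) {
    message(sprintf("load_gwas_catalog: dropped %d rows with missing coordinates",
                    dropped_na))
  }
  if (dropped_trait > 0) {
    message(sprintf("load_gwas_catalog: excluded %d rows outside the disease id list",
                    dropped_trait))
  }
  df <- df[!duplicated(df[, c("efoId", "snpId")]), , drop = FALSE]
  if (nrow(df) == 0) stop_invalid("no diseases left after filtering")

  snps <- df[!duplicated(df$snpId), c("snpId", "chrom", "pos")]
  snps$pos0 <- snps$pos - 1
  snps$pos <- NULL
  diseases <- df[!duplicated(df$efoId), c("efoId", "label")]
  diseases$isCancer <- diseases$efoId %in% efo_cancer_ids
  rownames(snps) <- rownames(diseases) <- NULL
  disease_catalog(diseases = diseases, snps = snps,
                  assoc = df[, c("efoId", "snpId")])
}

#' Classify SNPs as exonic, intronic or intergenic
#'
#' Precedence: a position inside any exon is `exonic`; otherwise inside any
#' gene it is `intronic`; otherwise `intergenic`. With an empty gene model
#' every SNP is intergenic.
#'
#' @param snps data.frame with `chrom` and `pos0` (0-based bp).
#' @param gene_model a `gene_model` (see [simulate_gene_model()]) or any
#'   list with data.frames `genes` and `exons` holding `chrom`, `start`,
#'   `end` in 0-based half-open bp.
#' @return Character vector of categories, aligned with `snps` rows.
#' @export
classify_snps <- function(snps, gene_model) {
  cat <- rep("intergenic", nrow(snps))
  if (nrow(snps) == 0) return(cat)
  pts <- points_to_granges(snps$chrom, snps$pos0)
  in_set <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(rep(FALSE, length(pts)))
    GenomicRanges::countOverlaps(
      pts, intervals_to_granges(df$chrom, df$start, df$end)) > 0
  }
  cat[in_set(gene_model$genes)] <- "intronic"
  cat[in_set(gene_model$exons)] <- "exonic"
  cat
}

#' Per-k border membership of SNPs
#'
#' Flags, for every SNP and every window size `k`, whether the SNP position
#' falls inside the border union called at that `k` (half-open test at bp
#' resolution). Two SNPs in the same border count as two units. SNPs on
#' chromosomes absent from the border set are not in a border.
#'
#' @param snps data.frame with `snpId`, `chrom`, `pos0`.
#' @param borders_by_k named list (names = `k`) of [border_set] objects.
#' @return Logical matrix, rows = SNPs (rownames `snpId`), columns = `k`.
#' @export
snp_border_membership <- function(snps, borders_by_k) {
  pts <- points_to_granges(snps$chrom, snps$pos0)
  border_chroms <- unique(unlist(lapply(borders_by_k, function(bs) {
    as.character(GenomicRanges::seqnames(bs$union))
  })))
  off <- setdiff(unique(snps$chrom), border_chroms)
  if (length(off)) {
    warning(sprintf("%d SNP(s) on chromosome(s) absent from the border set (%s): counted as not in a border",
                    sum(snps$chrom %in% off), paste(off, collapse = ", ")),
            call. = FALSE)
  }
  memb <- vapply(borders_by_k, function(bs) {
    suppressWarnings(GenomicRanges::countOverlaps(pts, bs$union) > 0)
  }, logical(nrow(snps)))
  memb <- matrix(memb, nrow = nrow(snps),
                 dimnames = list(snps$snpId, names(borders_by_k)))
  memb
}

#' Majority-rule border SNP set
#'
#' A SNP is a *border SNP* when it lies in a TAD border for strictly more
#' than half of the window sizes `k`.
#'
#' @param membership logical matrix from [snp_border_membership()].
#' @param k_range which columns (k values) to use; default all.
#' @return Character vector of border `snpId`s; the complement within
#'   `rownames(membership)` is the non-border set.
#' @export
majority_border_snp_set <- function(membership, k_range = colnames(membership)) {
  m <- membership[, as.character(k_range), drop = FALSE]
  rownames(m)[rowSums(m) > ncol(m) / 2]
}

#' Pairwise-distance audit of a disease's SNPs
#'
#' Counts, for each distance threshold, the unordered pairs of SNPs of one
#' disease lying on the same chromosome closer than the threshold. Used to
#' audit how often two SNPs could fall into the same bin or border.
#'
#' @param catalog a [disease_catalog].
#' @param thresholds distances in bp (default `10 kb` to `1 Mb`).
#' @param efo_ids diseases to audit (default all).
#' @return data.frame `efoId`, `threshold`, `n_pairs`.
#' @export
pairwise_close_counts <- function(catalog,
                                  thresholds = c(1e4, 1e5, 1e6),
                                  efo_ids = catalog$diseases$efoId) {
  snp_pos <- stats::setNames(catalog$snps$pos0, catalog$snps$snpId)
  snp_chr <- stats::setNames(catalog$snps$chrom, catalog$snps$snpId)
  out <- lapply(efo_ids, function(efo) {
    ids <- catalog$assoc$snpId[catalog$assoc$efoId == efo]
    n <- sapply(thresholds, function(t) {
      total <- 0L
      for (ch in unique(snp_chr[ids])) {
        p <- sort(snp_pos[ids][snp_chr[ids] == ch])
        if (length(p) >= 2) {
          d <- abs(outer(p, p, "-"))
          total <- total + sum(d[upper.tri(d)] < t)
        }
      }
      total
    })
    data.frame(efoId = efo, threshold = thresholds, n_pairs = n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
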