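#' Binned Hi-C contact matrix for one chromosome
#'
#' Light container for a square, symmetric, non-negative contact-count
#' matrix at a fixed bin size, with an optional gap mask marking bins with
#' (near-)zero coverage. Bin `b` (0-based) covers bp
#' `[b * bin_size, (b + 1) * bin_size)`.
#'
#' @param counts square numeric matrix of contact counts.
#' @param chrom chromosome identifier.
#' @param bin_size bin width in bp.
#' @param gap_mask logical per bin, or `NULL` (no gaps known yet).
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom = "chr1", bin_size = 10000,
                           gap_mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) {
    stop_invalid("contact matrix must be square (got %d x %d)",
                 nrow(counts), ncol(counts))
  }
  if (any(counts < 0)) stop_invalid("contact counts must be non-negative")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-8))) {
    stop_invalid("contact matrix must be symmetric")
  }
  if (!is.null(gap_mask) && length(gap_mask) != nrow(counts)) {
    stop_invalid("gap_mask length must equal the number of bins")
  }
  structure(
    list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
         counts = counts, gap_mask = gap_mask),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  n <- nrow(x$counts)
  ngap <- if (is.null(x$gap_mask)) NA_integer_ else sum(x$gap_mask)
  cat(sprintf("Contact matrix %s: %d bins x %d bp (%s gap bins), total counts %.0f\n",
              x$chrom, n, x$bin_size,
              ifelse(is.na(ngap), "?", ngap), sum(x$counts) / 2))
  invisible(x)
}

n_bins <- function(cm) nrow(cm$counts)

#' Write / read a contact matrix as dense TSV
#'
#' Plain-text fixture format: a tab-separated square matrix whose header row
#' holds the 0-based bin indices. `chrom` and `bin_size` travel in the file
#' name or are supplied by the caller on read.
#'
#' @param cm a [contact_matrix].
#' @param path file path.
#' @rdname dense_tsv
#' @export
write_dense_matrix <- function(cm, path) {
  m <- cm$counts
  colnames(m) <- seq_len(ncol(m)) - 1
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @param chrom,bin_size metadata for the matrix being read.
#' @rdname dense_tsv
#' @export
read_dense_matrix <- function(path, chrom = "chr1", bin_size = 10000) {
  m <- as.matrix(utils::read.delim(path, header = TRUE, check.names = FALSE))
  dimnames(m) <- NULL
  contact_matrix(m, chrom = chrom, bin_size = bin_size)
}
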