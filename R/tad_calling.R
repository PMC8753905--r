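# TAD calling from the sliding-window insulation signal.
#
# The caller follows the TopDom idea: count contacts in a window straddling
# each inter-bin position; demarcations between TADs appear as local minima
# of this signal. An optional rank-sum filter keeps only candidates where
# the contacts flanking the position (within prospective TADs) stochastically
# dominate the contacts crossing it.

#' Detect gap bins in a contact matrix
#'
#' A bin is flagged as a gap when its off-diagonal row sum is zero or falls
#' below `gap_zero_fraction` times the median positive row sum. Gap bins are
#' excluded from the insulation signal and split the chromosome into
#' independently segmented runs.
#'
#' @param cm a [contact_matrix] (or plain square matrix).
#' @param gap_zero_fraction relative threshold (default 0.05).
#' @return Logical vector, `TRUE` for gap bins.
#' @examples
#' m <- matrix(1, 4, 4); diag(m) <- 0; m[3, ] <- m[, 3] <- 0
#' detect_gaps(m)
#' @export
detect_gaps <- function(cm, gap_zero_fraction = 0.05) {
  counts <- if (inherits(cm, "contact_matrix")) cm$counts else as.matrix(cm)
  rs <- rowSums(counts) - diag(counts)
  pos <- rs[rs > 0]
  if (!length(pos)) stop_invalid("all bins are gaps: unusable chromosome")
  gap <- rs == 0 | rs < gap_zero_fraction * stats::median(pos)
  if (all(gap)) stop_invalid("all bins are gaps: unusable chromosome")
  gap
}

#' Sliding-window insulation signal
#'
#' For each inter-bin boundary position `b` (0-based, `1 <= b <= n - 1`,
#' separating bins `b - 1` and `b`), the signal is the mean contact count
#' over pairs `(i, j)` with `i` in `[max(0, b - k), b)` and `j` in
#' `[b, min(n, b + k))`, excluding pairs that touch a gap bin. The window
#' shrinks at chromosome edges. Positions whose window holds only gap pairs
#' are `NA`.
#'
#' @param cm a [contact_matrix] or square matrix.
#' @param k window half-size in bins.
#' @param gap_mask optional logical gap mask (defaults to the matrix's own,
#'   else no gaps).
#' @return Numeric vector of length `n - 1`; element `b` is the signal at
#'   boundary position `b`.
#' @export
insulation_signal <- function(cm, k, gap_mask = NULL) {
  counts <- if (inherits(cm, "contact_matrix")) cm$counts else as.matrix(cm)
  if (is.null(gap_mask) && inherits(cm, "contact_matrix")) {
    gap_mask <- cm$gap_mask
  }
  n <- nrow(counts)
  if (k < 1 || k >= n) stop_invalid("k must satisfy 1 <= k < n_bins (k=%d, n=%d)", k, n)
  gap_mask <- gap_mask %||% rep(FALSE, n)
  sig <- rep(NA_real_, n - 1)
  for (b in seq_len(n - 1)) {
    rows <- max(1, b - k + 1):b
    cols <- (b + 1):min(n, b + k)
    rows <- rows[!gap_mask[rows]]
    cols <- cols[!gap_mask[cols]]
    if (length(rows) && length(cols)) {
      sig[b] <- mean(counts[rows, cols, drop = FALSE])
    }
  }
  sig
}

#' Call TADs from one contact matrix at one window size
#'
#' Candidate demarcations are boundary positions where the insulation signal
#' is a local minimum: strictly lower than the nearest *defined* neighbour
#' value on each side, with plateaus collapsed to their leftmost position.
#' With `statistical_filter = TRUE` (default) a candidate at `b` is retained
#' only when the contacts inside the two flanking `k x k` triangles
#' stochastically dominate the contacts in the `k x k` diamond crossing `b`
#' (one-sided Wilcoxon rank-sum test). Counts entering the test are first
#' divided by the chromosome-wide mean count at their genomic distance, so
#' the comparison is not trivially won by the shorter-distance triangle
#' pairs under the global distance decay; the candidate p-values are then
#' Benjamini-Hochberg corrected across the chromosome and demarcations are
#' retained at FDR `filter_alpha`, since a long chromosome offers many noise
#' minima. TADs are the
#' maximal intervals between consecutive retained demarcations and gap-run
#' edges; TADs shorter than `min_tad_bins` are merged into the neighbour
#' across their smaller-signal demarcation. No TAD spans a gap run.
#'
#' @param cm a [contact_matrix].
#' @param k window half-size in bins.
#' @param min_tad_bins minimum TAD size in bins (default 2).
#' @param statistical_filter apply the rank-sum boundary filter?
#' @param filter_alpha significance level of the filter (default 0.05).
#' @param gap_mask optional precomputed gap mask; otherwise [detect_gaps()]
#'   is applied.
#' @param gap_zero_fraction passed to [detect_gaps()].
#' @return data.frame with columns `chrom`, `start_bin`, `end_bin` (0-based
#'   half-open) and `k`; attribute `bin_size` carries the resolution.
#' @examples
#' blocks <- matrix(1, 6, 6)
#' blocks[1:3, 1:3] <- 5; blocks[4:6, 4:6] <- 5; diag(blocks) <- 0
#' cm <- contact_matrix(blocks, bin_size = 10000)
#' call_tads(cm, k = 2, statistical_filter = FALSE)
#' @export
call_tads <- function(cm, k, min_tad_bins = 2, statistical_filter = TRUE,
                      filter_alpha = 0.05, gap_mask = NULL,
                      gap_zero_fraction = 0.05) {
  gap_mask <- gap_mask %||% cm$gap_mask %||% detect_gaps(cm, gap_zero_fraction)
  n <- n_bins(cm)
  sig <- insulation_signal(cm, k, gap_mask)

  scale_d <- if (statistical_filter) {
    distance_scale(cm$counts, gap_mask, max_d = min(2 * k, n - 1))
  } else {
    NULL
  }

  runs <- nongap_runs(gap_mask)
  cand_by_run <- lapply(seq_len(nrow(runs)), function(r) {
    local_minima(sig, runs$start[r], runs$end[r])
  })
  if (statistical_filter) {
    # One rank-sum p-value per candidate, BH-corrected across all candidates
    # of the chromosome; the demarcation family is retained at FDR
    # filter_alpha (a per-candidate threshold would admit ~alpha of the many
    # noise minima of a long chromosome).
    pvals <- unlist(lapply(seq_len(nrow(runs)), function(r) {
      vapply(cand_by_run[[r]], function(b) {
        boundary_filter_p(cm$counts, b, k, gap_mask,
                          runs$start[r], runs$end[r], scale_d)
      }, numeric(1))
    }))
    keep <- stats::p.adjust(pvals, method = "BH") <= filter_alpha
    offs <- cumsum(c(0, lengths(cand_by_run)))
    cand_by_run <- lapply(seq_len(nrow(runs)), function(r) {
      idx <- seq_len(lengths(cand_by_run)[r]) + offs[r]
      cand_by_run[[r]][keep[idx]]
    })
  }
  tads <- list()
  for (r in seq_len(nrow(runs))) {
    r1 <- runs$start[r]; r2 <- runs$end[r]  # 1-based inclusive bin range
    bounds <- sort(unique(cand_by_run[[r]]))
    # bins r1..r2 split at boundaries b (between bins b and b+1, 1-based)
    starts <- c(r1, bounds + 1)
    ends <- c(bounds, r2)
    seg <- merge_short_tads(starts, ends, sig, min_tad_bins)
    tads[[r]] <- data.frame(start_bin = seg$starts - 1, end_bin = seg$ends)
  }
  out <- do.call(rbind, tads)
  out <- data.frame(chrom = cm$chrom, out, k = k, stringsAsFactors = FALSE)
  attr(out, "bin_size") <- cm$bin_size
  out
}

# Maximal runs of non-gap bins, 1-based inclusive.
nongap_runs <- function(gap_mask) {
  r <- rle(!gap_mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Local minima of sig over boundary positions r1..(r2-1), using nearest
# defined neighbours; plateaus report their leftmost position. Returns
# 1-based boundary indices (boundary b separates bins b and b + 1).
local_minima <- function(sig, r1, r2) {
  bs <- seq(r1, r2 - 1)
  bs <- bs[bs >= 1 & bs <= length(sig)]
  def <- bs[!is.na(sig[bs])]
  if (length(def) < 3) return(integer())
  v <- sig[def]
  mins <- integer()
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[j + 1] == v[i]) j <- j + 1
    left_ok <- i > 1 && v[i - 1] > v[i]
    right_ok <- j < length(v) && v[j + 1] > v[i]
    if (left_ok && right_ok) mins <- c(mins, def[i])
    i <- j + 1
  }
  mins
}

# Mean contact count per genomic distance d = 1..max_d over non-gap pairs;
# used to normalize out the power-law distance decay before the rank-sum
# filter (flanking-triangle pairs sit at shorter distances than cross-diamond
# pairs, so raw counts would dominate trivially).
distance_scale <- function(counts, gap_mask, max_d) {
  n <- nrow(counts)
  vapply(seq_len(max_d), function(d) {
    i <- seq_len(n - d)
    keep <- !gap_mask[i] & !gap_mask[i + d]
    v <- counts[cbind(i[keep], i[keep] + d)]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
}

# Rank-sum p-value at candidate boundary b (1-based): distance-normalized
# contacts within the two flanking triangles vs contacts crossing the
# boundary (the k x k diamond). Returns 0 when the test is not computable
# (too few pairs), so such candidates always survive the FDR step.
boundary_filter_p <- function(counts, b, k, gap_mask, r1, r2, scale_d) {
  left <- max(r1, b - k + 1):b
  right <- (b + 1):min(r2, b + k)
  left <- left[!gap_mask[left]]
  right <- right[!gap_mask[right]]
  tri <- function(idx) {
    if (length(idx) < 2) return(NULL)
    pr <- utils::combn(idx, 2)
    cbind(pr[1, ], pr[2, ])
  }
  wpair <- rbind(tri(left), tri(right))
  if (is.null(wpair) || length(left) == 0 || length(right) == 0) return(0)
  cpair <- cbind(rep(left, times = length(right)),
                 rep(right, each = length(left)))
  norm_vals <- function(pr) {
    d <- pr[, 2] - pr[, 1]
    sc <- scale_d[d]
    ok <- !is.na(sc) & sc > 0
    counts[pr[ok, , drop = FALSE]] / sc[ok]
  }
  within <- norm_vals(wpair)
  cross <- norm_vals(cpair)
  if (length(within) < 2 || length(cross) < 2) return(0)
  p <- suppressWarnings(
    stats::wilcox.test(within, cross, alternative = "greater",
                       exact = FALSE)$p.value
  )
  if (!is.finite(p)) 0 else p
}

# Merge segments shorter than min_bins into the neighbour across their
# smaller-signal internal boundary. starts/ends are 1-based inclusive.
merge_short_tads <- function(starts, ends, sig, min_bins) {
  repeat {
    sizes <- ends - starts + 1
    short <- which(sizes < min_bins)
    if (!length(short) || length(starts) == 1) break
    i <- short[which.min(sizes[short])]
    left_sig <- if (i > 1) sig[starts[i] - 1] else NA_real_
    right_sig <- if (i < length(starts)) sig[ends[i]] else NA_real_
    merge_left <- if (is.na(right_sig)) TRUE
      else if (is.na(left_sig)) FALSE
      else left_sig <= right_sig
    if (merge_left && i > 1) {
      ends[i - 1] <- ends[i]
      starts <- starts[-i]; ends <- ends[-i]
    } else if (i < length(starts)) {
      starts[i + 1] <- starts[i]
      starts <- starts[-i]; ends <- ends[-i]
    } else if (i > 1) {
      ends[i - 1] <- ends[i]
      starts <- starts[-i]; ends <- ends[-i]
    } else {
      break
    }
  }
  list(starts = starts, ends = ends)
}

#' Call TADs across a range of window sizes
#'
#' Runs [call_tads()] independently for every `k` in `k_range` (the default
#' scans `k = 3` to `k = 20`). Smaller `k` tends to produce more, smaller
#' TADs; larger `k` keeps only large domains.
#'
#' @inheritParams call_tads
#' @param k_range integer vector of window half-sizes.
#' @param ... passed on to [call_tads()].
#' @return Named list (names = `k`) of TAD data.frames.
#' @export
call_tads_multi_k <- function(cm, k_range = 3:20, gap_mask = NULL,
                              gap_zero_fraction = 0.05, ...) {
  gap_mask <- gap_mask %||% cm$gap_mask %||% detect_gaps(cm, gap_zero_fraction)
  out <- lapply(k_range, function(k) call_tads(cm, k, gap_mask = gap_mask, ...))
  names(out) <- as.character(k_range)
  out
}
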