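#' Copy-number normalization of a Break-seq track
#'
#' Divides each Break-seq bin count by the local relative copy number
#' estimated from the matched DNA-seq track, so that DSB enrichment is not
#' confounded with DNA dosage (a hemizygous deletion halves read depth and
#' would otherwise mask hotspots inside it). The per-bin copy-number ratio
#' is the DNA-seq count smoothed by a running median over `smooth_bins`
#' bins, divided by the genome-wide median DNA-seq count. The ratio is
#' floored to avoid division blow-ups in near-zero-coverage bins. Total
#' counts are deliberately not conserved: the operation rescales.
#'
#' @param break_track Break-seq [coverage_track()].
#' @param dna_track DNA-seq [coverage_track()] with identical binning.
#' @param floor lower bound on the copy-number ratio used as divisor.
#' @param smooth_bins running-median window (odd number of bins).
#' @return a [coverage_track()] with normalized (non-integer) counts.
#' @export
normalize_by_copy_number <- function(break_track, dna_track, floor = 0.25,
                                     smooth_bins = 51L) {
  if (!identical(break_track$chrom, dna_track$chrom) ||
      !identical(break_track$start, dna_track$start) ||
      !identical(break_track$end, dna_track$end)) {
    stop("break and DNA tracks must share identical binning")
  }
  med <- median(dna_track$count)
  if (med <= 0) stop("DNA track has non-positive genome-wide median; cannot normalize")
  smoothed <- numeric(nrow(dna_track))
  for (ch in unique(dna_track$chrom)) {
    on <- dna_track$chrom == ch
    x <- dna_track$count[on]
    k <- min(smooth_bins, if (sum(on) %% 2L == 1L) sum(on) else sum(on) - 1L)
    smoothed[on] <- if (k >= 3) runmed(x, k, endrule = "median") else x
  }
  cn_ratio <- smoothed / med
  out <- break_track
  out$count <- break_track$count / pmax(cn_ratio, floor)
  coverage_track(out, track_bin_size(break_track))
}

#' Call DSB peaks against a Poisson local background
#'
#' A transparent local-lambda Poisson caller: each bin's count is tested
#' against the maximum of the genome-wide mean count and the mean counts in
#' two windows centred on the bin (the bin itself excluded), the per-bin
#' upper-tail Poisson p-values are corrected genome-wide by
#' Benjamini-Hochberg, significant bins are merged across gaps of up to
#' `merge_gap` bp, and merged peaks narrower than `min_width_bins` bins are
#' discarded. The summit is the maximum-count bin.
#'
#' @param track a [coverage_track()] (raw or copy-number normalized).
#' @param q_max BH q-value threshold for significant bins.
#' @param local_windows widths (bp) of the two local background windows.
#' @param min_width_bins minimum peak width in bins.
#' @param merge_gap maximum gap (bp) bridged when merging significant bins.
#' @return data.frame of peaks: `chrom`, `start`, `end` (0-based half-open),
#'   `summit` (bp of summit bin start), `n_bins`, `pvalue`, `qvalue`,
#'   `score` (-log10 q), `signal_mean`, `name`.
#' @export
call_peaks <- function(track, q_max = 0.05, local_windows = c(5000L, 10000L),
                       min_width_bins = 2L, merge_gap = 500L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), n_bins = integer(), pvalue = numeric(),
                      qvalue = numeric(), score = numeric(),
                      signal_mean = numeric(), name = character())
  if (nrow(track) == 0) {
    warning("empty coverage track: no peaks called")
    return(empty)
  }
  chroms <- unique(track$chrom)
  p <- bin_pvalues(track, local_windows)$p
  q <- p.adjust(p, method = "BH")

  peaks <- list()
  for (ch in chroms) {
    on <- which(track$chrom == ch)
    sig <- on[q[on] <= q_max]
    if (!length(sig)) next
    gap_bp <- track$start[sig][-1] - track$end[sig][-length(sig)]
    grp <- cumsum(c(1L, as.integer(gap_bp > merge_gap)))
    for (g in split(sig, grp)) {
      first <- g[1]; last <- g[length(g)]
      if (length(g) < min_width_bins) next
      summit <- g[which.max(track$count[g])]
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = ch, start = track$start[first], end = track$end[last],
        summit = track$start[summit], n_bins = length(g),
        pvalue = min(p[g]), qvalue = min(q[g]),
        score = -log10(pmax(min(q[g]), 1e-300)),
        signal_mean = mean(track$count[g]))
    }
  }
  if (!length(peaks)) return(empty)
  out <- do.call(rbind, peaks)
  out <- out[order(match(out$chrom, chroms), out$start), ]
  out$name <- sprintf("peak_%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Per-bin Poisson upper-tail p-values against the local background
#'
#' The testing core of [call_peaks()]: each bin's count is tested at
#' `lambda = max(genome-wide mean, local window means excluding the bin)`.
#'
#' @inheritParams call_peaks
#' @return list with numeric vectors `p` and `lambda`, one entry per bin.
#' @export
bin_pvalues <- function(track, local_windows = c(5000L, 10000L)) {
  bin_size <- track_bin_size(track)
  gw_mean <- sum(track$count) / nrow(track)
  lambda <- numeric(nrow(track))
  for (ch in unique(track$chrom)) {
    on <- which(track$chrom == ch)
    x <- track$count[on]
    lam <- rep(gw_mean, length(x))
    cs <- cumsum(c(0, x))
    for (w in local_windows) {
      half <- max(1L, floor(w / (2L * bin_size)))
      lo <- pmax(seq_along(x) - half, 1L)
      hi <- pmin(seq_along(x) + half, length(x))
      n_win <- hi - lo  # window size minus the excluded candidate bin
      s_win <- cs[hi + 1L] - cs[lo] - x
      lam <- pmax(lam, ifelse(n_win > 0, s_win / n_win, 0))
    }
    lambda[on] <- lam
  }
  # upper tail P(X >= count); counts may be non-integer after normalization
  p <- ppois(pmax(ceiling(track$count) - 1, 0), lambda, lower.tail = FALSE)
  p[track$count == 0] <- 1
  list(p = p, lambda = lambda)
}

#' Write peaks as 6-column BED plus a statistics TSV
#'
#' BED score is `min(1000, 10 * (-log10 q))`, truncated to integer.
#'
#' @param peaks result of [call_peaks()].
#' @param bed_path,tsv_path output paths (either may be `NULL` to skip).
#' @export
write_peaks <- function(peaks, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = peaks$chrom, start = peaks$start, end = peaks$end,
                      name = peaks$name,
                      score = as.integer(pmin(1000, 10 * peaks$score)))
    write_bed(bed, bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(peaks, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}
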