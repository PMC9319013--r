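#' Log2 normalization of binned read counts
#'
#' `ratio[i] = log2((count[i] + pseudo) / (median(count) + pseudo))`, with an
#' optional GC correction when a per-bin GC fraction is supplied: counts are
#' detrended by a running median of count against GC (a lowess-style fit),
#' rescaled so the overall median is preserved, before the log ratio is
#' taken. Without GC values the correction is skipped with a message.
#'
#' @param counts numeric vector of per-bin read counts (one chromosome or
#'   genome-wide, as the caller prefers).
#' @param pseudo pseudo-count guarding against log of zero.
#' @param gc optional per-bin GC fraction for bias correction.
#' @param gc_window running-median window (odd) used for the GC fit.
#' @return numeric vector of per-bin log2 ratios.
#' @export
bin_and_log2 <- function(counts, pseudo = 0.5, gc = NULL, gc_window = 51L) {
  stopifnot(is.numeric(counts))
  if (!is.null(gc)) {
    stopifnot(length(gc) == length(counts))
    o <- order(gc)
    k <- min(gc_window, if (length(counts) %% 2L) length(counts) else length(counts) - 1L)
    fit <- numeric(length(counts))
    fit[o] <- if (k >= 3) runmed(counts[o], k, endrule = "median") else counts[o]
    fit <- pmax(fit, pseudo)
    counts <- counts * median(fit) / fit
  } else {
    message("no GC values supplied; skipping GC correction")
  }
  log2((counts + pseudo) / (median(counts) + pseudo))
}

# best single split of x by two-sample t; returns c(split, |t|) or NULL
best_split <- function(x, min_seg_bins) {
  n <- length(x)
  if (n < 2L * min_seg_bins) return(NULL)
  ks <- min_seg_bins:(n - min_seg_bins)
  cs <- cumsum(x); css <- cumsum(x^2)
  n1 <- ks; n2 <- n - ks
  s1 <- cs[ks]; s2 <- cs[n] - s1
  m1 <- s1 / n1; m2 <- s2 / n2
  ss1 <- css[ks] - s1^2 / n1
  ss2 <- (css[n] - css[ks]) - s2^2 / n2
  sp2 <- (ss1 + ss2) / (n - 2)
  se <- sqrt(pmax(sp2, 0) * (1 / n1 + 1 / n2))
  tt <- ifelse(se == 0, ifelse(m1 == m2, 0, Inf), abs(m1 - m2) / se)
  k <- ks[which.max(tt)]  # which.max takes the leftmost maximum
  c(k, max(tt))
}

#' Segment per-bin log2 ratios by recursive binary segmentation
#'
#' At each recursion the split maximizing the two-sample t-statistic between
#' the left and right means is accepted iff `|t| >= t_threshold` and both
#' sides hold at least `min_seg_bins` bins; adjacent segments whose means
#' differ by less than `merge_delta` are merged afterwards. Ties break
#' toward the leftmost maximizing split; the procedure is deterministic.
#'
#' @param ratios numeric vector of log2 ratios for one chromosome, or a
#'   data.frame with `chrom` and `ratio` columns for many.
#' @param t_threshold minimum |t| to accept a split.
#' @param min_seg_bins minimum segment length in bins.
#' @param merge_delta post-hoc merge threshold on |delta mean_log2|.
#' @param chrom chromosome name used when `ratios` is a bare vector.
#' @param bin_size bp per bin, used to report bp coordinates.
#' @return data.frame of segments: `chrom`, `start_bin`, `end_bin`
#'   (half-open bin units), `start_bp`, `end_bp`, `n_bins`, `mean_log2`.
#' @export
segment <- function(ratios, t_threshold = 5.0, min_seg_bins = 5L,
                    merge_delta = 0.1, chrom = "chr", bin_size = 15000L) {
  if (is.data.frame(ratios)) {
    out <- lapply(unique(ratios$chrom), function(ch) {
      segment(ratios$ratio[ratios$chrom == ch], t_threshold, min_seg_bins,
              merge_delta, chrom = ch, bin_size = bin_size)
    })
    return(do.call(rbind, out))
  }
  x <- as.numeric(ratios)
  n <- length(x)
  if (n < 2L * min_seg_bins) {
    warning("chromosome ", chrom, " has fewer than 2*min_seg_bins bins; single segment")
    bounds <- c(0L, n)
  } else {
    recurse <- function(lo, hi) {  # half-open bin range [lo, hi)
      bs <- best_split(x[(lo + 1):hi], min_seg_bins)
      if (is.null(bs) || bs[2] < t_threshold) return(c(lo, hi))
      k <- lo + bs[1]
      union(recurse(lo, k), recurse(k, hi))
    }
    bounds <- sort(unique(recurse(0L, n)))
  }
  segs <- data.frame(start_bin = bounds[-length(bounds)], end_bin = bounds[-1])
  segs$mean_log2 <- vapply(seq_len(nrow(segs)), function(i) {
    mean(x[(segs$start_bin[i] + 1):segs$end_bin[i]])
  }, numeric(1))
  # iterative left-to-right merge of near-equal neighbours
  repeat {
    if (nrow(segs) < 2) break
    d <- abs(diff(segs$mean_log2))
    i <- which(d < merge_delta)
    if (!length(i)) break
    i <- i[1]
    merged_n <- (segs$end_bin[i] - segs$start_bin[i]) +
      (segs$end_bin[i + 1] - segs$start_bin[i + 1])
    segs$mean_log2[i] <- mean(x[(segs$start_bin[i] + 1):segs$end_bin[i + 1]])
    segs$end_bin[i] <- segs$end_bin[i + 1]
    segs <- segs[-(i + 1), ]
  }
  data.frame(chrom = chrom, start_bin = segs$start_bin, end_bin = segs$end_bin,
             start_bp = segs$start_bin * bin_size, end_bp = segs$end_bin * bin_size,
             n_bins = segs$end_bin - segs$start_bin, mean_log2 = segs$mean_log2,
             row.names = NULL)
}

#' Gain/loss calls and CNV boundaries
#'
#' Segments with mean log2 ratio at or below `loss_max` are losses, at or
#' above `gain_min` gains, otherwise neutral. A CNV boundary is the bp
#' position between adjacent segments whose calls differ or whose means
#' differ by at least `boundary_delta`.
#'
#' @param segments result of [segment()].
#' @param loss_max,gain_min call thresholds on mean log2 ratio.
#' @return `call_segments` returns the segments with a `call` column.
#' @export
call_segments <- function(segments, loss_max = -0.3, gain_min = 0.3) {
  segments$call <- ifelse(segments$mean_log2 <= loss_max, "loss",
                          ifelse(segments$mean_log2 >= gain_min, "gain", "neutral"))
  segments
}

#' @rdname call_segments
#' @param called result of [call_segments()].
#' @param boundary_delta minimum |delta mean_log2| for a boundary between
#'   same-call neighbours.
#' @return `cnv_boundaries` returns a data.frame `chrom`, `pos` (bp).
#' @export
cnv_boundaries <- function(called, boundary_delta = 0.3) {
  out <- list()
  for (ch in unique(called$chrom)) {
    s <- called[called$chrom == ch, ]
    if (nrow(s) < 2) next
    change <- s$call[-nrow(s)] != s$call[-1] |
      abs(diff(s$mean_log2)) >= boundary_delta
    if (any(change)) {
      out[[ch]] <- data.frame(chrom = ch, pos = s$end_bp[-nrow(s)][change])
    }
  }
  if (!length(out)) return(data.frame(chrom = character(), pos = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Copy-number profile from a binned count track
#'
#' Convenience wrapper: rebins a coverage track to the CNV bin size,
#' computes log2 ratios, segments, and calls.
#'
#' @param track a [coverage_track()] (e.g. a DNA-seq track).
#' @param spec a [genome_spec()] supplying `bin_size_cnv`.
#' @param ... passed to [segment()].
#' @return called segment data.frame (see [call_segments()]).
#' @export
cnv_profile <- function(track, spec, ...) {
  bin <- spec$bin_size_cnv
  fac <- bin / track_bin_size(track)
  if (fac != round(fac)) stop("CNV bin size must be a multiple of the track bin size")
  out <- list()
  for (ch in unique(track$chrom)) {
    on <- track$chrom == ch
    x <- track$count[on]
    w <- track$end[on] - track$start[on]
    grp <- (seq_along(x) - 1L) %/% fac
    cnt <- as.numeric(tapply(x, grp, sum))
    bp <- as.numeric(tapply(w, grp, sum))
    # scale terminal partial bins to full-bin equivalents
    out[[ch]] <- data.frame(chrom = ch, count = cnt * bin / bp)
  }
  binned <- do.call(rbind, out)
  binned$ratio <- bin_and_log2(binned$count)
  segs <- segment(binned[, c("chrom", "ratio")], bin_size = bin, ...)
  call_segments(segs)
}
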