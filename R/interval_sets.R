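peaks_to_ir <- function(df, chrom) {
  b <- df[df$chrom == chrom, , drop = FALSE]
  IRanges::IRanges(b$start + 1L, b$end)
}

interval_df <- function(chrom = character(), start = integer(), end = integer()) {
  data.frame(chrom = chrom, start = start, end = end)
}

#' Replicate consensus of peak sets
#'
#' The consensus of R replicate peak sets is the set of per-base regions
#' covered by a peak in *every* replicate (the intersection of the R
#' indicator functions), merged and filtered to a minimum width. A peak
#' present in only R-1 replicates contributes nothing.
#'
#' @param replicate_peak_sets list (length >= 1) of peak data.frames with
#'   `chrom`, `start`, `end` (sorted, non-overlapping) and optionally `name`.
#' @param min_width minimum consensus interval width in bp.
#' @param line_label optional label carried on the result.
#' @return a `consensus_set`: list with `line_label`, `peaks` (data.frame of
#'   consensus intervals) and `provenance` (per consensus interval, the
#'   contributing replicate peak names, when names are present).
#' @export
consensus <- function(replicate_peak_sets, min_width = 50L, line_label = NA_character_) {
  if (!length(replicate_peak_sets)) stop("need at least one replicate peak set")
  chroms <- unique(unlist(lapply(replicate_peak_sets, function(d) d$chrom)))
  out <- list()
  for (ch in chroms) {
    irs <- lapply(replicate_peak_sets, peaks_to_ir, chrom = ch)
    inter <- Reduce(function(a, b) {
      IRanges::intersect(IRanges::reduce(a), IRanges::reduce(b))
    }, irs)
    inter <- inter[IRanges::width(inter) >= min_width]
    if (length(inter)) {
      out[[ch]] <- interval_df(ch, BiocGenerics::start(inter) - 1L,
                               BiocGenerics::end(inter))
    }
  }
  peaks <- if (length(out)) do.call(rbind, out) else interval_df()
  rownames(peaks) <- NULL
  provenance <- lapply(seq_len(nrow(peaks)), function(i) {
    unlist(lapply(seq_along(replicate_peak_sets), function(r) {
      d <- replicate_peak_sets[[r]]
      hit <- d$chrom == peaks$chrom[i] & d$start < peaks$end[i] & d$end > peaks$start[i]
      if (is.null(d$name)) {
        sprintf("rep%d_peak%d", r, which(hit))
      } else {
        paste0("rep", r, ":", d$name[hit])
      }
    }))
  })
  structure(list(line_label = line_label, peaks = peaks, provenance = provenance),
            class = "consensus_set")
}

consensus_peaks <- function(x) {
  if (inherits(x, "consensus_set")) x$peaks else x
}

#' Common / specific partition of two consensus sets
#'
#' An interval of set A is "common" iff it overlaps at least `min_overlap`
#' bp of any interval of set B, otherwise "A-specific"; symmetrically for B.
#' Commonality is counted from A's side, so
#' `|common| + |a_specific| = |A|` exactly.
#'
#' @param a,b `consensus_set`s (or plain interval data.frames).
#' @param min_overlap minimum overlap in bp for an interval to count as
#'   common.
#' @return a `set_partition`: list with data.frames `common`, `a_specific`,
#'   `b_specific`, `b_common`, and a `counts` list.
#' @export
partition <- function(a, b, min_overlap = 1L) {
  pa <- consensus_peaks(a)
  pb <- consensus_peaks(b)
  a_common <- overlaps_any(pa, pb, min_overlap)
  b_common <- overlaps_any(pb, pa, min_overlap)
  res <- list(common = pa[a_common, , drop = FALSE],
              a_specific = pa[!a_common, , drop = FALSE],
              b_specific = pb[!b_common, , drop = FALSE],
              b_common = pb[b_common, , drop = FALSE])
  res <- lapply(res, function(d) { rownames(d) <- NULL; d })
  res$counts <- list(common = sum(a_common), a_specific = sum(!a_common),
                     b_specific = sum(!b_common), b_common = sum(b_common))
  class(res) <- "set_partition"
  res
}

overlaps_any <- function(query, subject, min_overlap = 1L) {
  hit <- logical(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- peaks_to_ir(subject, ch)
    if (!length(si)) next
    ov <- IRanges::findOverlaps(IRanges::IRanges(query$start[qi] + 1L, query$end[qi]),
                                si, minoverlap = min_overlap)
    hit[qi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit
}

#' Per-chromosome peak density
#'
#' @param peaks interval data.frame (or `consensus_set`).
#' @param genome a [genome_spec()].
#' @return data.frame `chrom`, `count`, `per_mb` (count per Mb, rounded to
#'   2 decimals), one row per genome chromosome.
#' @export
density_per_chromosome <- function(peaks, genome) {
  p <- consensus_peaks(peaks)
  counts <- vapply(genome$chromosomes$name,
                   function(ch) sum(p$chrom == ch), integer(1))
  data.frame(chrom = genome$chromosomes$name,
             count = counts,
             per_mb = round(counts / (genome$chromosomes$length / 1e6), 2),
             row.names = NULL)
}
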