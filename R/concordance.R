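#' Flatten paired breakpoints to per-end records
#'
#' @param breakpoints data.frame with `chrom1, pos1, chrom2, pos2, class`
#'   (and optionally `source_id`).
#' @return data.frame with one row per junction end: `source_id`, `end`
#'   (1 or 2), `chrom`, `pos`, `class`.
#' @export
breakpoint_ends <- function(breakpoints) {
  bp <- breakpoints
  if (!"class" %in% names(bp)) {
    bp$class <- ifelse(bp$chrom1 == bp$chrom2, "intra", "inter")
  }
  if (!nrow(bp)) {
    return(data.frame(source_id = character(), end = integer(),
                      chrom = character(), pos = integer(), class = character()))
  }
  id <- if (is.null(bp$source_id)) sprintf("sv_%03d", seq_len(nrow(bp))) else bp$source_id
  out <- rbind(data.frame(source_id = id, end = 1L, chrom = bp$chrom1,
                          pos = bp$pos1, class = bp$class),
               data.frame(source_id = id, end = 2L, chrom = bp$chrom2,
                          pos = bp$pos2, class = bp$class))
  out[order(out$chrom, out$pos), ]
}

hits_points_in_intervals <- function(dsbs, points, window) {
  out <- list()
  for (ch in unique(dsbs$chrom)) {
    di <- which(dsbs$chrom == ch)
    pi <- which(points$chrom == ch)
    if (!length(pi)) next
    # a point p hits a DSB iff start - window <= p < end + window
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(points$pos[pi] + 1L, points$pos[pi] + 1L),
      IRanges::IRanges(dsbs$start[di] + 1L - window, dsbs$end[di] + window))
    if (!length(ov)) next
    out[[ch]] <- data.frame(dsb_index = di[S4Vectors::subjectHits(ov)],
                            point_index = pi[S4Vectors::queryHits(ov)])
  }
  if (!length(out)) return(data.frame(dsb_index = integer(), point_index = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap DSB intervals with SV junction ends
#'
#' A DSB hits a junction end iff the end's coordinate lies within
#' `[start - window, end + window)` of the DSB. Every (DSB, end) pair is
#' reported; a DSB overlapping both ends of one event appears once per end.
#'
#' @param dsbs interval data.frame (`chrom`, `start`, `end`) or
#'   `consensus_set`.
#' @param breakpoints paired-breakpoint data.frame (see [load_bedpe()]).
#' @param window symmetric extension of each DSB in bp.
#' @return data.frame of hits: DSB coordinates plus `source_id`, `end`,
#'   `pos`, `class` of the junction end hit.
#' @export
dsb_sv_overlap <- function(dsbs, breakpoints, window = 0L) {
  d <- consensus_peaks(dsbs)
  ends <- breakpoint_ends(breakpoints)
  h <- hits_points_in_intervals(d, ends, window)
  out <- cbind(d[h$dsb_index, c("chrom", "start", "end")],
               ends[h$point_index, c("source_id", "end", "pos", "class")])
  names(out)[4:7] <- c("source_id", "bp_end", "pos", "class")
  rownames(out) <- NULL
  out
}

#' Concordance report for one genomic region
#'
#' Counts junction *ends* of each class whose coordinate falls inside the
#' region, and how many of those are hit by a DSB ("k of n intra junctions
#' and j of m inter junctions").
#'
#' @param dsbs interval data.frame or `consensus_set`.
#' @param region list or data.frame row with `chrom`, `start`, `end`.
#' @param breakpoints paired-breakpoint data.frame.
#' @param window DSB extension in bp (as in [dsb_sv_overlap()]).
#' @return list with `intra_total` (n), `intra_hit` (k), `inter_total` (m),
#'   `inter_hit` (j), and a formatted `text`.
#' @export
region_report <- function(dsbs, region, breakpoints, window = 0L) {
  ends <- breakpoint_ends(breakpoints)
  in_region <- ends$chrom == region$chrom & ends$pos >= region$start &
    ends$pos < region$end
  ends_in <- ends[in_region, , drop = FALSE]
  hits <- dsb_sv_overlap(dsbs, breakpoints, window = window)
  hit_keys <- unique(paste(hits$source_id, hits$bp_end))
  is_hit <- paste(ends_in$source_id, ends_in$end) %in% hit_keys
  res <- list(intra_total = sum(ends_in$class == "intra"),
              intra_hit = sum(is_hit & ends_in$class == "intra"),
              inter_total = sum(ends_in$class == "inter"),
              inter_hit = sum(is_hit & ends_in$class == "inter"))
  res$text <- sprintf("%d of %d intra junctions and %d of %d inter junctions",
                      res$intra_hit, res$intra_total,
                      res$inter_hit, res$inter_total)
  res
}

#' Overlap DSB intervals with CNV boundaries
#'
#' Same semantics as [dsb_sv_overlap()]; the default window of one CNV bin
#' reflects that boundary positions are only bin-resolved.
#'
#' @param dsbs interval data.frame or `consensus_set`.
#' @param boundaries data.frame `chrom`, `pos` from [cnv_boundaries()].
#' @param window DSB extension in bp.
#' @return data.frame of hits (DSB coordinates plus boundary `pos`).
#' @export
dsb_cnv_overlap <- function(dsbs, boundaries, window = 15000L) {
  d <- consensus_peaks(dsbs)
  h <- hits_points_in_intervals(d, boundaries, window)
  out <- cbind(d[h$dsb_index, c("chrom", "start", "end")],
               data.frame(pos = boundaries$pos[h$point_index]))
  rownames(out) <- NULL
  out
}

count_hits_fast <- function(starts, ends, pos_by_chrom, chrom, window) {
  total <- 0L
  for (ch in names(pos_by_chrom)) {
    di <- chrom == ch
    if (!any(di)) next
    e <- pos_by_chrom[[ch]]
    total <- total + sum(findInterval(ends[di] + window - 1L, e) -
                           findInterval(starts[di] - window - 1L, e))
  }
  total
}

#' Permutation null for DSB / breakpoint-end concordance
#'
#' The observed statistic is the number of (DSB, junction end) overlap
#' pairs. Each permutation redraws the DSB start positions uniformly within
#' their own chromosome, preserving interval lengths and non-overlap (the
#' free space between intervals is re-partitioned uniformly at random). The
#' empirical p-value uses the add-one rule
#' `(1 + #(null >= observed)) / (n_perm + 1)`, so it is never zero.
#'
#' @param dsbs interval data.frame or `consensus_set`.
#' @param breakpoints paired-breakpoint data.frame.
#' @param genome a [genome_spec()].
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param window DSB extension in bp.
#' @return list with `observed`, `null_mean`, `p`, and the vector
#'   `null_counts`.
#' @export
permutation_null <- function(dsbs, breakpoints, genome, n_perm = 1000L, seed = 1L,
                             window = 0L) {
  d <- consensus_peaks(dsbs)
  ends <- breakpoint_ends(breakpoints)
  pos_by_chrom <- lapply(split(ends$pos, ends$chrom), sort)
  observed <- count_hits_fast(d$start, d$end, pos_by_chrom, d$chrom, window)
  if (!nrow(ends)) {
    return(list(observed = 0L, null_mean = 0, p = 1, null_counts = integer(n_perm)))
  }
  by_chrom <- split(seq_len(nrow(d)), d$chrom)
  lens <- d$end - d$start
  null_counts <- with_substream(seed, "permutation", {
    vapply(seq_len(n_perm), function(i) {
      starts <- integer(nrow(d))
      for (ch in names(by_chrom)) {
        idx <- by_chrom[[ch]]
        L <- lens[idx]
        free <- chrom_length(genome, ch) - sum(L)
        if (free < 0) stop("DSB intervals exceed chromosome length on ", ch)
        gaps <- sort(runif(length(idx), 0, free))
        starts[idx] <- as.integer(round(gaps)) +
          cumsum(c(0L, L[-length(L)]))
      }
      count_hits_fast(starts, starts + lens, pos_by_chrom, d$chrom, window)
    }, integer(1))
  })
  list(observed = observed, null_mean = mean(null_counts),
       p = (1 + sum(null_counts >= observed)) / (n_perm + 1),
       null_counts = null_counts)
}
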