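FEATURE_CLASSES <- c("exon", "five_prime_utr", "three_prime_utr", "promoter",
                     "downstream", "intron", "intergenic")

#' Classify peaks against gene models
#'
#' Each peak receives exactly one feature class, tested in priority order
#' exon > 5'UTR > 3'UTR > promoter > downstream > intron > intergenic; the
#' first class with at least 1 bp of overlap wins. The promoter is the
#' `promoter_bp` window upstream of the TSS and the downstream region the
#' `downstream_bp` window past the TES, both strand-aware. UTRs are used
#' only if the gene model set carries optional `utr5` / `utr3` tables.
#'
#' @param peaks interval data.frame (`chrom`, `start`, `end`) or
#'   `consensus_set`.
#' @param gene_models a `gene_model_set`.
#' @param promoter_bp promoter window upstream of the TSS (bp).
#' @param downstream_bp downstream window past the TES (bp).
#' @return character vector of feature classes, one per peak.
#' @export
classify_peaks <- function(peaks, gene_models, promoter_bp = 2000L,
                           downstream_bp = 2000L) {
  p <- consensus_peaks(peaks)
  g <- gene_models$genes
  plus <- g$strand == "+"
  promoters <- data.frame(chrom = g$chrom,
                          start = ifelse(plus, pmax(0L, g$start - promoter_bp), g$end),
                          end = ifelse(plus, g$start, g$end + promoter_bp))
  downstreams <- data.frame(chrom = g$chrom,
                            start = ifelse(plus, g$end, pmax(0L, g$start - downstream_bp)),
                            end = ifelse(plus, g$end + downstream_bp, g$start))
  layers <- list(
    exon = gene_models$exons,
    five_prime_utr = gene_models$utr5,
    three_prime_utr = gene_models$utr3,
    promoter = promoters,
    downstream = downstreams,
    intron = g)  # gene body; earlier layers already claimed exonic overlap
  cls <- rep("intergenic", nrow(p))
  unset <- rep(TRUE, nrow(p))
  for (nm in names(layers)) {
    ivs <- layers[[nm]]
    if (is.null(ivs) || !nrow(ivs)) next
    hit <- overlaps_any(p, ivs)
    cls[unset & hit] <- nm
    unset <- unset & !hit
  }
  cls
}

#' Feature-class distribution of a peak set
#'
#' @inheritParams classify_peaks
#' @return data.frame `class`, `count`, `fraction` over all seven classes
#'   (fractions sum to 1 for non-empty peak sets, all zero otherwise).
#' @export
feature_distribution <- function(peaks, gene_models, promoter_bp = 2000L,
                                 downstream_bp = 2000L) {
  cls <- classify_peaks(peaks, gene_models, promoter_bp, downstream_bp)
  counts <- vapply(FEATURE_CLASSES, function(k) sum(cls == k), integer(1))
  data.frame(class = FEATURE_CLASSES, count = counts,
             fraction = if (length(cls)) counts / length(cls) else rep(0, length(counts)),
             row.names = NULL)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Implements the minimum-likelihood two-sided definition directly: with
#' all margins fixed, the p-value sums the hypergeometric probabilities of
#' every table whose probability does not exceed that of the observed table
#' (within a relative tolerance of 1e-7 to absorb floating-point ties).
#' Summation is done in log space. A one-sided upper tail is also
#' available.
#'
#' @param a,b,c,d non-negative integer cells, row-wise: `(a b / c d)`.
#' @param alternative `"two.sided"` (minimum likelihood) or `"greater"`
#'   (upper tail of `a`).
#' @return the p-value.
#' @export
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3) # 34/70
fisher_exact_2x2 <- function(a, b, c, d, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("all cells must be non-negative")
  if (any(cells != round(cells))) stop("all cells must be integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || b + d == 0) return(1)
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- dhyper(xs, r1, r2, c1, log = TRUE)
  lobs <- dhyper(a, r1, r2, c1, log = TRUE)
  keep <- if (alternative == "two.sided") {
    logp <= lobs + log(1 + 1e-7)
  } else {
    xs >= a
  }
  lp <- logp[keep]
  m <- max(lp)
  min(1, exp(m) * sum(exp(lp - m)))
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up adjustment (delegates to [stats::p.adjust()]).
#'
#' @param pvalues numeric vector of p-values.
#' @return q-values in `[0, 1]`.
#' @export
bh_fdr <- function(pvalues) {
  p.adjust(pvalues, method = "BH")
}

#' Nearest gene within a maximum distance
#'
#' Distance is 0 when the peak overlaps the gene body, otherwise the gap
#' between the nearest extremities. The signed distance is negative when
#' the peak lies left (lower coordinate) of the gene. Ties break toward the
#' lexicographically smaller gene id; peaks farther than `max_distance`
#' from every gene get `NA`.
#'
#' @param peaks interval data.frame or `consensus_set`.
#' @param gene_models a `gene_model_set`.
#' @param max_distance maximum gap in bp.
#' @return data.frame with one row per peak: peak coordinates, `gene_id`
#'   (`NA` when no gene is close enough), `distance` (signed).
#' @export
nearest_gene <- function(peaks, gene_models, max_distance = 5000L) {
  p <- consensus_peaks(peaks)
  g <- gene_models$genes
  gene_id <- rep(NA_character_, nrow(p))
  distance <- rep(NA_integer_, nrow(p))
  for (i in seq_len(nrow(p))) {
    cand <- which(g$chrom == p$chrom[i])
    if (!length(cand)) next
    gap_left <- g$start[cand] - p$end[i]   # gene right of peak
    gap_right <- p$start[i] - g$end[cand]  # gene left of peak
    dist <- pmax(gap_left, gap_right, 0L)
    ok <- dist <= max_distance
    if (!any(ok)) next
    best <- min(dist[ok])
    tied <- cand[ok][dist[ok] == best]
    pick <- tied[order(g$gene_id[tied])][1]
    gene_id[i] <- g$gene_id[pick]
    d <- max(g$start[pick] - p$end[i], p$start[i] - g$end[pick], 0L)
    distance[i] <- if (p$start[i] >= g$end[pick]) d else if (p$end[i] <= g$start[pick]) -d else 0L
  }
  data.frame(p[, c("chrom", "start", "end")], gene_id = gene_id,
             distance = distance, row.names = NULL)
}
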