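#' Log2 counts-per-million normalization
#'
#' `log2(count / library_size * 1e6 + 1)`: scale invariance across library
#' sizes with a +1 pseudo-count guarding the log at zero.
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric matrix of log2(CPM + 1) values.
#' @export
normalize_counts <- function(counts) {
  libs <- colSums(counts)
  if (any(libs == 0)) stop("zero-total library")
  log2(sweep(counts, 2, libs, `/`) * 1e6 + 1)
}

#' One-way ANOVA differential expression between two groups
#'
#' Per-gene one-way ANOVA F across the group labels on the normalized
#' matrix (for two groups this equals the squared pooled-variance t), with
#' Benjamini-Hochberg q-values and tiered fold-change calls. The log2 fold
#' change is the difference of group means of log2(CPM + 1), line B over
#' line A.
#'
#' @param norm numeric matrix from [normalize_counts()].
#' @param groups character vector of group labels, one per column; exactly
#'   two distinct labels, each with >= 2 samples. The second label sorted
#'   alphabetically is the "B" (numerator) group.
#' @param alpha q-value threshold for calling direction.
#' @param fc_min minimum |log2 fold change| for an up/down call; the tiers
#'   in routine use are 1, 3.5 and 4.
#' @return data.frame: `gene_id`, `mean_a`, `mean_b`, `log2_fc`,
#'   `F_statistic`, `p`, `q`, `direction` in `{up, down, ns}`.
#' @export
anova_de <- function(norm, groups, alpha = 0.05, fc_min = 1) {
  labs <- sort(unique(groups))
  if (length(labs) != 2) stop("exactly two groups required")
  ga <- groups == labs[1]; gb <- groups == labs[2]
  if (sum(ga) < 2 || sum(gb) < 2) stop("need >= 2 samples per group")
  n_a <- sum(ga); n_b <- sum(gb); n <- n_a + n_b
  mean_a <- rowMeans(norm[, ga, drop = FALSE])
  mean_b <- rowMeans(norm[, gb, drop = FALSE])
  gm <- (n_a * mean_a + n_b * mean_b) / n
  ss_between <- n_a * (mean_a - gm)^2 + n_b * (mean_b - gm)^2
  ss_within <- rowSums((norm[, ga, drop = FALSE] - mean_a)^2) +
    rowSums((norm[, gb, drop = FALSE] - mean_b)^2)
  df1 <- 1L; df2 <- n - 2L
  F_statistic <- (ss_between / df1) / (ss_within / df2)
  F_statistic[ss_between == 0] <- 0  # flat genes: F = 0 even at zero variance
  p <- pf(F_statistic, df1, df2, lower.tail = FALSE)
  q <- bh_fdr(p)
  log2_fc <- mean_b - mean_a
  direction <- ifelse(q <= alpha & log2_fc > fc_min, "up",
                      ifelse(q <= alpha & log2_fc < -fc_min, "down", "ns"))
  data.frame(gene_id = rownames(norm), mean_a = mean_a, mean_b = mean_b,
             log2_fc = log2_fc, F_statistic = F_statistic, p = p, q = q,
             direction = direction, row.names = NULL)
}

#' Link differential expression to DSB proximity
#'
#' Inner join of the DE results with a nearest-gene table (genes within the
#' distance cut-off of line-specific DSBs), keeping genes with a
#' significant up or down call.
#'
#' @param de_results data.frame from [anova_de()].
#' @param nearest data.frame from [nearest_gene()] computed on the
#'   line-specific DSB set.
#' @return data.frame of linked genes with DSB coordinates, distance and DE
#'   statistics, plus per-direction counts as attributes `n_up` / `n_down`.
#' @export
link_de_to_dsb <- function(de_results, nearest) {
  near <- nearest[!is.na(nearest$gene_id), , drop = FALSE]
  de_sig <- de_results[de_results$direction != "ns", , drop = FALSE]
  merged <- merge(near, de_sig, by = "gene_id")
  merged <- merged[order(merged$gene_id), ]
  rownames(merged) <- NULL
  attr(merged, "n_up") <- sum(merged$direction == "up")
  attr(merged, "n_down") <- sum(merged$direction == "down")
  merged
}
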