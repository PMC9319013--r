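# Brute-force oracles and tiny fixture builders shared across test files.
# Every oracle is deliberately naive (per-base indicators, quadratic scans,
# full enumeration) and independent of the package's implementation paths.

# per-base indicator intersection of replicate interval sets on one chromosome
oracle_consensus_1chrom <- function(sets, chrom_len, min_width) {
  ind <- rep(TRUE, chrom_len)
  for (s in sets) {
    cov <- rep(FALSE, chrom_len)
    for (i in seq_len(nrow(s))) {
      if (s$end[i] > s$start[i]) cov[(s$start[i] + 1):s$end[i]] <- TRUE
    }
    ind <- ind & cov
  }
  r <- rle(ind)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values & r$lengths >= min_width
  data.frame(start = starts[keep], end = ends[keep])
}

# quadratic (dsb x point) overlap scan
oracle_point_hits <- function(dsbs, points, window) {
  out <- NULL
  for (i in seq_len(nrow(dsbs))) {
    for (j in seq_len(nrow(points))) {
      if (dsbs$chrom[i] == points$chrom[j] &&
          points$pos[j] >= dsbs$start[i] - window &&
          points$pos[j] < dsbs$end[i] + window) {
        out <- rbind(out, data.frame(dsb = i, point = j))
      }
    }
  }
  if (is.null(out)) data.frame(dsb = integer(), point = integer()) else out
}

# full enumeration two-sided Fisher via exact choose() arithmetic
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  p_obs <- choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# sorted non-overlapping random intervals on [0, chrom_len)
random_intervals <- function(n, chrom_len, max_width = 500, chrom = "chr1") {
  w <- sample.int(max_width, n, replace = TRUE)
  free <- chrom_len - sum(w)
  stopifnot(free > 0)
  gaps <- sort(runif(n, 0, free))
  starts <- as.integer(round(gaps)) + cumsum(c(0L, w[-n]))
  data.frame(chrom = chrom, start = starts, end = starts + w)
}

# minimal hand-built gene model set
make_gene_models <- function(genes, exons = NULL) {
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  genes$tes <- ifelse(genes$strand == "+", genes$end, genes$start)
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, end = genes$end)
  }
  structure(list(genes = genes, exons = exons), class = "gene_model_set")
}

# truth set with dense hotspots on a bare one-chromosome genome, used by the
# coverage-mean and peak-recovery checks
dense_hotspot_truth <- function(n_hot = 250, spacing = 4000, width = 400,
                                chrom = "chrT") {
  hs <- data.frame(chrom = chrom,
                   start = spacing * seq_len(n_hot),
                   end = spacing * seq_len(n_hot) + width,
                   line = "B", fold = NA)
  structure(list(hotspots = hs,
                 cnv = data.frame(chrom = character(), start = integer(),
                                  end = integer(), line = character(),
                                  cn = integer()),
                 sv = NULL, de = NULL, survival = NULL, region = NULL),
            class = "truth_set")
}
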