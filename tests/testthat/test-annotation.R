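toy_models <- function() {
  genes <- data.frame(
    gene_id = c("gA", "gB"), chrom = "chr1",
    start = c(10000L, 14000L), end = c(13000L, 20000L),
    strand = c("+", "-"))
  exons <- data.frame(gene_id = c("gA", "gA", "gB", "gB"), chrom = "chr1",
                      start = c(10000L, 12000L, 14000L, 18000L),
                      end = c(10500L, 13000L, 15000L, 20000L))
  make_gene_models(genes, exons)
}

pk <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end)
}

test_that("peak classification follows the priority order", {
  gm <- toy_models()
  # inside an exon of gA that also lies in no-man's land of gB: exon wins
  expect_equal(classify_peaks(pk(10100, 10200), gm), "exon")
  # intron of gA only
  expect_equal(classify_peaks(pk(11000, 11100), gm), "intron")
  # straddling the exon/intron boundary: exon by priority
  expect_equal(classify_peaks(pk(10400, 10700), gm), "exon")
  # promoter of '+' gene gA: 2 kb upstream of start
  expect_equal(classify_peaks(pk(8500, 9000), gm), "promoter")
  # gB is on '-': its promoter is past its end coordinate...
  expect_equal(classify_peaks(pk(20500, 20600), gm), "promoter")
  # ...but 20500 is also 'downstream' of nothing else; shrink the promoter
  # and the same peak becomes downstream of gA? No: gA ends at 13000. With
  # a 100 bp promoter the peak is intergenic.
  expect_equal(classify_peaks(pk(20500, 20600), gm, promoter_bp = 100), "intergenic")
  # downstream of '+' gene gA (past its TES at 13000) -- but that window
  # overlaps gB's body; gB's intron only starts at 15000, and 13000-14000
  # is before gB, so a peak at 13500 is downstream of gA
  expect_equal(classify_peaks(pk(13400, 13600), gm), "downstream")
  # far from everything
  expect_equal(classify_peaks(pk(500000, 500100), gm), "intergenic")
  # UTR layers engage only when provided
  gm$utr5 <- data.frame(chrom = "chr1", start = 11000L, end = 11100L)
  expect_equal(classify_peaks(pk(11000, 11050), gm), "five_prime_utr")
})

test_that("feature distributions sum to one and match hand tallies", {
  gm <- toy_models()
  peaks <- rbind(pk(10100, 10200), pk(11000, 11100), pk(8500, 9000),
                 pk(500000, 500100), pk(600000, 600100))
  fd <- feature_distribution(peaks, gm)
  expect_equal(sum(fd$fraction), 1)
  expect_equal(fd$count[fd$class == "exon"], 1L)
  expect_equal(fd$count[fd$class == "intron"], 1L)
  expect_equal(fd$count[fd$class == "promoter"], 1L)
  expect_equal(fd$count[fd$class == "intergenic"], 2L)
  none <- feature_distribution(data.frame(chrom = character(), start = integer(),
                                          end = integer()), gm)
  expect_true(all(none$count == 0))
})

test_that("fisher_exact_2x2 matches exhaustive enumeration to 12 digits", {
  expect_equal(fisher_exact_2x2(3, 1, 1, 3), 34 / 70, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(0, 10, 0, 10), 1)
  # zero margins force p = 1
  expect_equal(fisher_exact_2x2(0, 0, 5, 7), 1)
  expect_equal(fisher_exact_2x2(5, 0, 7, 0), 1)
  set.seed(55)
  for (i in 1:60) {
    m <- sample.int(13, 4) - 1L  # all cells 0..12, margins <= 24
    p_pkg <- fisher_exact_2x2(m[1], m[2], m[3], m[4])
    p_oracle <- oracle_fisher(m[1], m[2], m[3], m[4])
    expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
    # invariance under simultaneous row and column transposition
    expect_equal(fisher_exact_2x2(m[4], m[3], m[2], m[1]), p_pkg,
                 tolerance = 1e-12)
    # independent cross-check against the reference implementation
    ft <- fisher.test(matrix(m, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, ft, tolerance = 1e-10)
  }
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("BH adjustment passes the worked examples", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
})

test_that("nearest gene respects the distance cut-off and tie rule", {
  gm <- toy_models()
  inside <- nearest_gene(pk(11000, 11100), gm)
  expect_equal(inside$gene_id, "gA")
  expect_equal(inside$distance, 0L)
  # 5001 bp past the last gene end: no gene
  far <- nearest_gene(pk(25001, 25100), gm, max_distance = 5000)
  expect_true(is.na(far$gene_id))
  at5k <- nearest_gene(pk(25000, 25100), gm, max_distance = 5000)
  expect_equal(at5k$gene_id, "gB")
  expect_equal(at5k$distance, 5000L)
  # equidistant between gA (end 13000) and gB (start 14000): lexicographic
  mid <- nearest_gene(pk(13400, 13600), gm)
  expect_equal(mid$gene_id, "gA")
  expect_equal(mid$distance, 400L)

  # brute-force cross-check on a random fixture
  set.seed(21)
  spec <- genome_spec(data.frame(name = "chr1", length = 2e6))
  big <- build_genome(spec, 60, seed = 5, mean_span = 8000)
  peaks <- random_intervals(40, 2e6)
  got <- nearest_gene(peaks, big, max_distance = 5000)
  for (i in seq_len(nrow(peaks))) {
    d <- pmax(big$genes$start - peaks$end[i], peaks$start[i] - big$genes$end, 0)
    if (min(d) > 5000) {
      expect_true(is.na(got$gene_id[i]))
    } else {
      expect_equal(abs(got$distance[i]), min(d))
      expect_equal(got$gene_id[i],
                   sort(big$genes$gene_id[d == min(d)])[1])
    }
  }
})
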