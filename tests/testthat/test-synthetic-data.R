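test_that("build_genome handles empty, deterministic and oversized requests", {
  spec <- genome_spec(data.frame(name = "chr1", length = 1e7))
  empty <- build_genome(spec, 0, seed = 1)
  expect_equal(nrow(empty$genes), 0)

  g1 <- build_genome(spec, 40, seed = 7)
  g2 <- build_genome(spec, 40, seed = 7)
  expect_identical(g1, g2)
  g3 <- build_genome(spec, 40, seed = 8)
  expect_false(identical(g1$genes$start, g3$genes$start))

  small <- genome_spec(data.frame(name = "chr1", length = 1e6))
  expect_error(build_genome(small, 50, seed = 1, mean_span = 30000),
               "genome too small")
})

test_that("generated gene models satisfy their structural invariants", {
  spec <- genome_spec(data.frame(name = c("c1", "c2"), length = c(5e6, 3e6)))
  gm <- build_genome(spec, 200, seed = 11, mean_span = 5000)
  g <- gm$genes
  expect_equal(nrow(g), 200)
  for (ch in unique(g$chrom)) {
    s <- g[g$chrom == ch, ]
    s <- s[order(s$start), ]
    expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  expect_equal(g$tss, ifelse(g$strand == "+", g$start, g$end))
  # exons inside the gene body, sorted, non-overlapping, 1-10 per gene
  ex_by_gene <- split(gm$exons, gm$exons$gene_id)
  expect_true(all(lengths(lapply(ex_by_gene, function(e) e$start)) <= 10))
  for (id in names(ex_by_gene)) {
    e <- ex_by_gene[[id]]
    gene <- g[g$gene_id == id, ]
    expect_true(all(e$start >= gene$start & e$end <= gene$end))
    expect_true(all(diff(e$start) > 0))
    expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
})

test_that("simulated coverage matches its analytic Poisson means", {
  cfg <- sim_config(seed = 5, background_rate = 5, hotspot_fold = 8)
  spec <- default_genome_spec()
  gm <- build_genome(spec, 50, seed = 2, mean_span = 5000)
  truth <- build_truth(spec, gm, cfg)

  # line A carries no CNV: genome-wide mean outside hotspots = background
  trk_a <- simulate_coverage(spec, truth, cfg, "A", 1, assay = "dnaseq")
  m <- mean(trk_a$count)
  se <- sd(trk_a$count) / sqrt(nrow(trk_a))
  expect_lt(abs(m - 5), 3 * se)

  # line B DNA-seq inside the planted hemizygous deletion: mean ~ background/2
  trk_b <- simulate_coverage(spec, truth, cfg, "B", 1, assay = "dnaseq")
  del <- truth$cnv[1, ]
  inside <- trk_b$chrom == del$chrom & trk_b$start >= del$start & trk_b$end <= del$end
  m <- mean(trk_b$count[inside]); se <- sd(trk_b$count[inside]) / sqrt(sum(inside))
  expect_lt(abs(m - 2.5), 3 * se)

  # >= 1000 hotspot bins at fold 8: mean ~ 8 x background
  dense_spec <- genome_spec(data.frame(name = "chrT", length = 1100000))
  dtruth <- dense_hotspot_truth(n_hot = 250)
  trk <- simulate_coverage(dense_spec, dtruth, cfg, "B", 1)
  hot <- rep(FALSE, nrow(trk))
  for (i in seq_len(nrow(dtruth$hotspots))) {
    hot <- hot | (trk$start >= dtruth$hotspots$start[i] &
                    trk$end <= dtruth$hotspots$end[i])
  }
  expect_gte(sum(hot), 1000)
  m <- mean(trk$count[hot]); se <- sd(trk$count[hot]) / sqrt(sum(hot))
  expect_lt(abs(m - 40), 3 * se)

  # hotspot_fold = 1 collapses to the null model
  cfg1 <- sim_config(seed = 5, hotspot_fold = 1)
  trk1 <- simulate_coverage(dense_spec, dtruth, cfg1, "B", 1)
  m <- mean(trk1$count); se <- sd(trk1$count) / sqrt(nrow(trk1))
  expect_lt(abs(m - 5), 3 * se)

  expect_error(simulate_coverage(spec, truth, cfg, "C", 1), "unknown line_label")
  expect_error(simulate_coverage(spec, truth, cfg, "A", 99), "replicate_index")
})

test_that("coverage output is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 33)
  spec <- genome_spec(data.frame(name = "chrT", length = 500000))
  truth <- dense_hotspot_truth(n_hot = 20)
  f1 <- tempfile(fileext = ".bedgraph"); f2 <- tempfile(fileext = ".bedgraph")
  write_bedgraph(simulate_coverage(spec, truth, cfg, "B", 2), f1)
  write_bedgraph(simulate_coverage(spec, truth, cfg, "B", 2), f2)
  expect_identical(readLines(f1), readLines(f2))
  # different replicate index = different substream
  f3 <- tempfile(fileext = ".bedgraph")
  write_bedgraph(simulate_coverage(spec, truth, cfg, "B", 3), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("expression simulation recovers planted fold changes", {
  spec <- genome_spec(data.frame(name = "chrE", length = 2e7))
  gm <- build_genome(spec, 2000, seed = 3, mean_span = 3000)
  cfg <- sim_config(seed = 23, baseline_meanlog = log(500), baseline_sdlog = 0)
  planted <- gm$genes$gene_id[seq_len(20)]
  de_truth <- data.frame(gene_id = planted, log2fc = 4)

  sim1 <- simulate_expression(gm, de_truth, cfg)
  sim2 <- simulate_expression(gm, de_truth, cfg)
  expect_identical(sim1$counts, sim2$counts)

  norm <- normalize_counts(sim1$counts)
  lfc <- rowMeans(norm[, sim1$groups == "B"]) - rowMeans(norm[, sim1$groups == "A"])
  expect_lt(abs(mean(lfc[planted]) - 4), 0.5)
  # delta method: sd(ln count) ~ sqrt(1/mu + phi) = 0.32 at mu = 500,
  # phi = 0.1, so lfc ~ N(0, 0.33) and median |lfc| ~ 0.674 * 0.33 = 0.22
  expect_lt(abs(median(abs(lfc[setdiff(rownames(norm), planted)])) - 0.22), 0.1)

  expect_error(simulate_expression(gm, data.frame(gene_id = "nope", log2fc = 1), cfg),
               "unknown gene_id")
})

test_that("survival simulation is calibrated for type I error and power", {
  truth_null <- list(cutoff = qlnorm(0.6, log(100), 0.8), hazard_ratio = 1,
                     marker_meanlog = log(100), marker_sdlog = 0.8)
  rejections <- vapply(1:200, function(s) {
    cohort <- simulate_survival_cohort(sim_config(seed = s, cohort_size = 150),
                                       truth_null)
    logrank(cohort, truth_null$cutoff)$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / 200))

  truth_alt <- truth_null; truth_alt$hazard_ratio <- 2.5
  hits <- vapply(1:100, function(s) {
    cohort <- simulate_survival_cohort(sim_config(seed = s), truth_alt)
    logrank(cohort, truth_alt$cutoff)$p < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  no_cens <- simulate_survival_cohort(sim_config(seed = 1, censoring_rate = 0),
                                      truth_alt)
  expect_true(all(no_cens$event == 1))
})

test_that("truth manifests round-trip through JSON", {
  cfg <- sim_config(seed = 9)
  spec <- default_genome_spec()
  gm <- build_genome(spec, cfg$n_genes, seed = 1, mean_span = cfg$gene_mean_span)
  truth <- build_truth(spec, gm, cfg)
  path <- tempfile(fileext = ".json")
  write_truth(truth, path)
  back <- read_truth(path)
  expect_equal(back$hotspots, truth$hotspots, ignore_attr = TRUE)
  expect_equal(back$sv, truth$sv, ignore_attr = TRUE)
  expect_equal(back$de, truth$de, ignore_attr = TRUE)
  expect_equal(back$survival$cutoff, truth$survival$cutoff)
  # co-located SV ends really lie inside hotspots
  co <- truth$sv[truth$sv$co_located, ]
  hs <- truth$hotspots
  for (i in seq_len(nrow(co))) {
    expect_true(any(hs$chrom == co$chrom1[i] & hs$start <= co$pos1[i] &
                      hs$end > co$pos1[i]))
  }
})
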