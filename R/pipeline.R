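#' Pipeline configuration
#'
#' Combines the simulation settings with the analysis parameters of every
#' stage. `read_pipeline_config()` loads the same structure from a YAML
#' file with top-level sections `simulation:` and `analysis:`.
#'
#' @param sim a [sim_config()].
#' @param q_max peak-calling q-value threshold.
#' @param consensus_min_width minimum consensus interval width (bp).
#' @param min_overlap cross-line commonality overlap (bp).
#' @param window_sv DSB window for SV-end overlap (bp).
#' @param window_cnv DSB window for CNV-boundary overlap (bp).
#' @param n_perm permutations for the concordance null.
#' @param de_alpha,de_fc_min DE significance and fold-change tier (the
#'   tiers in routine use are 1, 3.5 and 4).
#' @param max_gene_distance DSB-to-gene linking distance (bp).
#' @param quantile_range admissible low-group range for cut-off search.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), q_max = 0.05,
                            consensus_min_width = 50L, min_overlap = 1L,
                            window_sv = 0L, window_cnv = 15000L,
                            n_perm = 200L, de_alpha = 0.05, de_fc_min = 4,
                            max_gene_distance = 5000L,
                            quantile_range = c(0.10, 0.90)) {
  cfg <- list(sim = sim,
              analysis = list(q_max = q_max,
                              consensus_min_width = consensus_min_width,
                              min_overlap = min_overlap, window_sv = window_sv,
                              window_cnv = window_cnv, n_perm = n_perm,
                              de_alpha = de_alpha, de_fc_min = de_fc_min,
                              max_gene_distance = max_gene_distance,
                              quantile_range = quantile_range))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  spec <- default_genome_spec()
  if (spec$bin_size_cnv %% spec$bin_size_cov != 0) {
    stop("contradictory bin sizes: CNV bin must be a multiple of the coverage bin")
  }
  a <- cfg$analysis
  if (a$q_max <= 0 || a$q_max > 1) stop("q_max must be in (0, 1]")
  if (a$n_perm < 1) stop("n_perm must be >= 1")
  if (a$quantile_range[1] >= a$quantile_range[2]) {
    stop("quantile_range must be increasing")
  }
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- do.call(sim_config, y$simulation %||% list())
  do.call(pipeline_config, c(list(sim = sim), y$analysis %||% list()))
}

#' Run the full pipeline on a simulated experiment
#'
#' Simulates the two-cell-line experiment, then runs every analysis stage
#' in dependency order: copy-number-normalized peak calling per replicate,
#' per-line replicate consensus, cross-line partition, per-chromosome
#' density, gene-feature classification with the intronic-enrichment Fisher
#' test, CNV segmentation of the DNA-seq tracks with boundary extraction,
#' structural-variant tallies and the A-to-B delta, DSB/SV and DSB/CNV
#' concordance with a permutation null over the pericentromeric region,
#' differential expression with DSB linkage, and survival cut-off
#' optimization.
#'
#' @param config a [pipeline_config()] (or a YAML path accepted by
#'   [read_pipeline_config()]).
#' @param outdir optional output directory; when given, every stage's
#'   tabular artifacts plus a JSON report are written there.
#' @return the report: a nested list with one element per stage.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  a <- config$analysis
  sim <- simulate_experiment(config$sim)
  lines <- c("A", "B")

  peak_sets <- lapply(setNames(lines, lines), function(ln) {
    lapply(sim$breakseq[[ln]], function(track) {
      call_peaks(normalize_by_copy_number(track, sim$dnaseq[[ln]]),
                 q_max = a$q_max)
    })
  })
  cons <- lapply(setNames(lines, lines), function(ln) {
    consensus(peak_sets[[ln]], min_width = a$consensus_min_width,
              line_label = ln)
  })
  part <- partition(cons$A, cons$B, min_overlap = a$min_overlap)
  dens <- density_per_chromosome(part$b_specific, sim$spec)

  feat <- lapply(cons, feature_distribution, gene_models = sim$gene_models)
  intronic <- vapply(lines, function(ln) {
    feat[[ln]]$count[feat[[ln]]$class == "intron"]
  }, numeric(1))
  totals <- vapply(lines, function(ln) sum(feat[[ln]]$count), numeric(1))
  fisher_p <- fisher_exact_2x2(intronic["B"], totals["B"] - intronic["B"],
                               intronic["A"], totals["A"] - intronic["A"])

  cnv <- lapply(setNames(lines, lines), function(ln) {
    suppressMessages(cnv_profile(sim$dnaseq[[ln]], sim$spec))
  })
  bounds <- lapply(cnv, cnv_boundaries)

  sv_by_line <- split(sim$truth$sv, sim$truth$sv$line)
  tallies <- lapply(sv_by_line, classify_and_tally)
  delta <- sv_delta(tallies$A, tallies$B)

  b_spec <- part$b_specific
  region <- sim$truth$region
  # the SV concordance uses the full line-B consensus (shared breaks count);
  # the CNV-boundary overlap uses the line-B-specific set
  concord <- list(
    sv_hits = dsb_sv_overlap(cons$B, sv_by_line$B, window = a$window_sv),
    region = region_report(cons$B, region, sv_by_line$B, window = a$window_sv),
    cnv_hits = dsb_cnv_overlap(b_spec, bounds$B, window = a$window_cnv),
    null = permutation_null(cons$B, sv_by_line$B, sim$spec,
                            n_perm = a$n_perm,
                            seed = substream_seed(config$sim$seed, "concordance")))

  norm <- normalize_counts(sim$expression$counts)
  de <- anova_de(norm, sim$expression$groups, alpha = a$de_alpha,
                 fc_min = a$de_fc_min)
  near <- nearest_gene(b_spec, sim$gene_models,
                       max_distance = a$max_gene_distance)
  linked <- link_de_to_dsb(de, near)

  surv <- optimize_cutoff(sim$cohort, quantile_range = a$quantile_range)

  report <- list(
    dsb = list(per_replicate = lapply(peak_sets, vapply, nrow, integer(1)),
               consensus = vapply(cons, function(x) nrow(x$peaks), integer(1)),
               partition = part$counts),
    density = dens,
    features = feat,
    fisher_intronic_p = fisher_p,
    cnv = list(segments = cnv, boundaries = bounds),
    sv = list(tallies = tallies, delta = delta),
    concordance = concord,
    de = list(n_up = sum(de$direction == "up"),
              n_down = sum(de$direction == "down"),
              linked = linked),
    survival = list(cutoff = surv$cutoff, p = surv$result$p,
                    hazard_ratio = surv$result$hazard_ratio),
    truth = sim$truth)

  if (!is.null(outdir)) write_report(report, sim, outdir)
  report
}

write_report <- function(report, sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_experiment(sim, file.path(outdir, "inputs"))
  tsv <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(report$density, "density.tsv")
  for (ln in names(report$cnv$segments)) {
    tsv(report$cnv$segments[[ln]], sprintf("cnv_segments_%s.tsv", ln))
  }
  tsv(report$concordance$sv_hits, "concordance_sv_hits.tsv")
  tsv(report$de$linked, "de_near_dsb.tsv")
  summary <- report
  summary$truth <- NULL
  summary$concordance$null$null_counts <- NULL
  summary$concordance$sv_hits <- NULL
  summary$concordance$cnv_hits <- nrow(report$concordance$cnv_hits)
  summary$cnv <- NULL
  summary$de$linked <- report$de$linked$gene_id
  jsonlite::write_json(summary, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns")
  invisible(outdir)
}
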