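#' Simulate a binned coverage track for one library
#'
#' Bin counts are Poisson with mean
#' `background_rate * width_frac * cn_scale * hotspot_scale`, where
#' `cn_scale` is the planted local copy number over the reference ploidy of
#' 2, and `hotspot_scale` interpolates between 1 and `hotspot_fold` with the
#' fraction of the bin covered by a hotspot assigned to this line or shared.
#' DNA-seq tracks see the copy-number signal but no hotspot enrichment
#' (`hotspot_scale` identically 1), which is what makes them usable as the
#' normalization control.
#'
#' @param spec a [genome_spec()].
#' @param truth a `truth_set` from [build_truth()].
#' @param cfg a [sim_config()].
#' @param line_label `"A"` or `"B"`.
#' @param replicate_index 1-based replicate number (`<= cfg$n_replicates`);
#'   ignored for DNA-seq, which has one library per line.
#' @param assay `"breakseq"` or `"dnaseq"`.
#' @return a [coverage_track()].
#' @export
simulate_coverage <- function(spec, truth, cfg, line_label, replicate_index = 1L,
                              assay = c("breakseq", "dnaseq")) {
  assay <- match.arg(assay)
  if (!line_label %in% c("A", "B")) stop("unknown line_label: ", line_label)
  if (assay == "breakseq" && replicate_index > cfg$n_replicates) {
    stop("replicate_index exceeds n_replicates")
  }
  bins <- genome_bins(spec, spec$bin_size_cov)
  width_frac <- (bins$end - bins$start) / spec$bin_size_cov

  cn_scale <- rep(1, nrow(bins))
  cnv <- truth$cnv[truth$cnv$line == line_label, , drop = FALSE]
  if (nrow(cnv)) {
    frac <- overlap_fraction(bins, cnv)
    # planted segments are bin-aligned, so frac is 0/1; interpolate anyway
    for (i in seq_len(nrow(cnv))) {
      cn_scale <- cn_scale * (1 + frac[, i] * (cnv$cn[i] / 2 - 1))
    }
  }

  hs_scale <- rep(1, nrow(bins))
  if (assay == "breakseq") {
    hs <- truth$hotspots[truth$hotspots$line %in% c(line_label, "shared"), , drop = FALSE]
    if (nrow(hs)) {
      frac <- overlap_fraction(bins, hs)
      hs_scale <- 1 + rowSums(frac) * (cfg$hotspot_fold - 1)
    }
  }

  stream <- paste("coverage", assay, line_label,
                  if (assay == "breakseq") replicate_index else 0L, sep = "/")
  counts <- with_substream(cfg$seed, stream, {
    rpois(nrow(bins), cfg$background_rate * width_frac * cn_scale * hs_scale)
  })
  coverage_track(data.frame(chrom = bins$chrom, start = bins$start,
                            end = bins$end, count = counts),
                 spec$bin_size_cov)
}

# fraction of each bin covered by each interval of `ivs` (same chromosome)
overlap_fraction <- function(bins, ivs) {
  out <- matrix(0, nrow(bins), nrow(ivs))
  for (i in seq_len(nrow(ivs))) {
    on <- bins$chrom == ivs$chrom[i]
    ov <- pmin(bins$end[on], ivs$end[i]) - pmax(bins$start[on], ivs$start[i])
    out[on, i] <- pmax(0, ov) / (bins$end[on] - bins$start[on])
  }
  out
}

#' Simulate a gene-level RNA count matrix
#'
#' Per-gene baseline means are log-normal; planted log2 fold changes are
#' applied multiplicatively to the line-B samples; counts are negative
#' binomial with the configured dispersion; per-sample library-size factors
#' are log-normal with sd `libsize_jitter_sdlog`.
#'
#' @param gene_models a `gene_model_set`.
#' @param de_truth data.frame with `gene_id` and `log2fc` (genes not listed
#'   get fold change 0).
#' @param cfg a [sim_config()].
#' @return list with `counts` (integer matrix genes x samples), `groups`
#'   (character vector, `"A"`/`"B"`), and `lib_factors`.
#' @export
simulate_expression <- function(gene_models, de_truth, cfg = sim_config()) {
  ids <- gene_models$genes$gene_id
  if (!all(de_truth$gene_id %in% ids)) {
    stop("de_truth references unknown gene_id: ",
         paste(setdiff(de_truth$gene_id, ids), collapse = ", "))
  }
  n <- cfg$n_replicates
  groups <- rep(c("A", "B"), each = n)
  lfc <- setNames(rep(0, length(ids)), ids)
  lfc[de_truth$gene_id] <- de_truth$log2fc
  with_substream(cfg$seed, "expression", {
    base <- rlnorm(length(ids), cfg$baseline_meanlog, cfg$baseline_sdlog)
    libf <- rlnorm(2L * n, 0, cfg$libsize_jitter_sdlog)
    mu <- base %o% rep(1, 2L * n)
    mu[, groups == "B"] <- mu[, groups == "B"] * 2^lfc
    mu <- sweep(mu, 2, libf, `*`)
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                     nrow = length(ids))
    dimnames(counts) <- list(ids, paste0(rep(c("A", "B"), each = n), seq_len(n)))
    list(counts = counts, groups = groups, lib_factors = libf)
  })
}

#' Simulate a survival cohort with a planted expression threshold
#'
#' Marker expression is log-normal; event times are exponential with the
#' baseline hazard below the planted cut-off and `hazard_ratio` times that
#' above it; censoring times are exponential with hazard
#' `censoring_rate * baseline_hazard`, independent of the event process.
#'
#' @param cfg a [sim_config()].
#' @param survival_truth the `survival` element of a `truth_set` (fields
#'   `cutoff`, `hazard_ratio`, `marker_meanlog`, `marker_sdlog`).
#' @return data.frame with `time`, `event` (1 = event, 0 = censored),
#'   `marker`.
#' @export
simulate_survival_cohort <- function(cfg, survival_truth) {
  n <- cfg$cohort_size
  with_substream(cfg$seed, "survival", {
    marker <- rlnorm(n, survival_truth$marker_meanlog, survival_truth$marker_sdlog)
    hr <- ifelse(marker > survival_truth$cutoff, survival_truth$hazard_ratio, 1)
    t_event <- rexp(n, rate = cfg$baseline_hazard * hr)
    if (cfg$censoring_rate > 0) {
      t_cens <- rexp(n, rate = cfg$censoring_rate * cfg$baseline_hazard)
    } else {
      t_cens <- rep(Inf, n)
    }
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               marker = marker)
  })
}

#' Simulate the full two-cell-line experiment in memory
#'
#' Convenience orchestrator: builds the toy genome and gene models, lays out
#' the planted truth, and simulates every input the pipeline consumes --
#' Break-seq replicate tracks and one DNA-seq track per line, the RNA count
#' matrix, and the survival cohort.
#'
#' @param cfg a [sim_config()].
#' @param spec optional [genome_spec()]; defaults to [default_genome_spec()].
#' @return list with `spec`, `gene_models`, `truth`, `breakseq` (nested list
#'   `[[line]][[replicate]]`), `dnaseq` (`[[line]]`), `expression`, `cohort`.
#' @export
simulate_experiment <- function(cfg = sim_config(), spec = default_genome_spec()) {
  gm <- build_genome(spec, cfg$n_genes, seed = substream_seed(cfg$seed, "genes"),
                     mean_span = cfg$gene_mean_span)
  truth <- build_truth(spec, gm, cfg)
  lines <- c("A", "B")
  breakseq <- lapply(setNames(lines, lines), function(ln) {
    lapply(seq_len(cfg$n_replicates), function(r) {
      simulate_coverage(spec, truth, cfg, ln, r, assay = "breakseq")
    })
  })
  dnaseq <- lapply(setNames(lines, lines), function(ln) {
    simulate_coverage(spec, truth, cfg, ln, assay = "dnaseq")
  })
  expr <- simulate_expression(gm, truth$de, cfg)
  cohort <- simulate_survival_cohort(cfg, truth$survival)
  list(spec = spec, gene_models = gm, truth = truth, breakseq = breakseq,
       dnaseq = dnaseq, expression = expr, cohort = cohort, cfg = cfg)
}

#' Write a simulated experiment to disk in standard formats
#'
#' bedGraph per coverage track, GTF-like gene models, BEDPE truth
#' breakpoints, TSV count matrix and cohort, JSON truth manifest.
#'
#' @param sim result of [simulate_experiment()].
#' @param outdir output directory (created if missing).
#' @return the output directory, invisibly.
#' @export
write_experiment <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)
  for (ln in names(sim$breakseq)) {
    for (r in seq_along(sim$breakseq[[ln]])) {
      write_bedgraph(sim$breakseq[[ln]][[r]],
                     p(sprintf("breakseq_%s_rep%d.bedgraph", ln, r)))
    }
    write_bedgraph(sim$dnaseq[[ln]], p(sprintf("dnaseq_%s.bedgraph", ln)))
    sv <- sim$truth$sv[sim$truth$sv$line == ln, , drop = FALSE]
    write_bedpe(sv, p(sprintf("sv_%s.bedpe", ln)))
  }
  write_gene_models(sim$gene_models, p("genes.gtf"))
  write_count_matrix(sim$expression$counts, sim$expression$groups, p("counts.tsv"))
  write_cohort(sim$cohort, p("cohort.tsv"))
  write_truth(sim$truth, p("truth.json"))
  invisible(outdir)
}
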