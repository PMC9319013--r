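#' Simulation configuration
#'
#' Bundles every knob of the synthetic two-cell-line experiment. The
#' defaults are the study conditions the package is tested under: two cell
#' lines ("A", the non-cancer control analog; "B", the cancer analog) with
#' four Break-seq replicates each, Poisson background of 5 reads per 100 bp
#' coverage bin, 8-fold read enrichment inside DSB hotspots, negative
#' binomial RNA counts with dispersion 0.1, and an 800-patient survival
#' cohort with ~exponential follow-up and exponential censoring.
#'
#' @param seed master integer seed; every downstream stream of randomness is
#'   derived from it via [substream_seed()].
#' @param n_replicates Break-seq (and RNA-seq) replicates per line.
#' @param background_rate mean reads per coverage bin outside hotspots at
#'   copy number 2.
#' @param hotspot_fold fold read enrichment inside a DSB hotspot.
#' @param nb_dispersion negative binomial dispersion of RNA counts
#'   (variance = mu + dispersion * mu^2).
#' @param cohort_size number of patients in the simulated survival cohort.
#' @param censoring_rate censoring hazard expressed as a multiple of the
#'   baseline event hazard (0 = no censoring).
#' @param n_genes number of genes in the toy gene model set.
#' @param gene_mean_span mean gene span in bp (the toy genome is gene-dense
#'   so that composition effects of CPM normalization stay realistic).
#' @param baseline_meanlog,baseline_sdlog log-normal parameters of per-gene
#'   baseline RNA expression means.
#' @param libsize_jitter_sdlog log-normal sd of per-sample RNA library-size
#'   factors (0 = equal libraries).
#' @param stub_bp width of the intact pericentromeric stub on the
#'   deletion-bearing chromosome arm (bp).
#' @param baseline_hazard event hazard of the low-marker survival group.
#' @param marker_meanlog,marker_sdlog log-normal parameters of the biomarker
#'   expression distribution.
#' @param cutoff_quantile quantile of the marker distribution at which the
#'   planted risk threshold sits.
#' @param hazard_ratio hazard ratio of the high-marker group over the
#'   low-marker group.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_replicates = 4L, background_rate = 5,
                       hotspot_fold = 8, nb_dispersion = 0.1,
                       cohort_size = 800L, censoring_rate = 0.4,
                       n_genes = 1500L, gene_mean_span = 3000,
                       baseline_meanlog = log(150),
                       baseline_sdlog = 1, libsize_jitter_sdlog = 0.1,
                       stub_bp = 300000L, baseline_hazard = 0.1,
                       marker_meanlog = log(100), marker_sdlog = 0.8,
                       cutoff_quantile = 0.6, hazard_ratio = 2.5) {
  cfg <- list(seed = as.integer(seed), n_replicates = as.integer(n_replicates),
              background_rate = background_rate, hotspot_fold = hotspot_fold,
              nb_dispersion = nb_dispersion, cohort_size = as.integer(cohort_size),
              censoring_rate = censoring_rate, n_genes = as.integer(n_genes),
              gene_mean_span = gene_mean_span,
              baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
              libsize_jitter_sdlog = libsize_jitter_sdlog,
              stub_bp = as.integer(stub_bp), baseline_hazard = baseline_hazard,
              marker_meanlog = marker_meanlog, marker_sdlog = marker_sdlog,
              cutoff_quantile = cutoff_quantile, hazard_ratio = hazard_ratio)
  rates <- c("background_rate", "hotspot_fold", "nb_dispersion",
             "censoring_rate", "baseline_hazard", "hazard_ratio")
  if (any(unlist(cfg[rates]) < 0)) stop("rates must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Default toy genome for the two-line experiment
#'
#' Two chromosomes: `chr16a`, a 6 Mb analog of chromosome 16 whose q arm
#' starts at 2.01 Mb and carries (in line B only) a mid-arm deletion with an
#' intact pericentromeric stub and intact distal arm; and `chr10a`, a 5 Mb
#' translocation-partner chromosome with no copy-number change.
#'
#' @inheritParams genome_bins
#' @return a [genome_spec()].
#' @export
default_genome_spec <- function() {
  genome_spec(data.frame(name = c("chr16a", "chr10a"),
                         length = c(6000000L, 5000000L)),
              bin_size_cov = 100L, bin_size_cnv = 15000L)
}

# fixed landmarks of the chr16a analog (bp, aligned to 15 kb CNV bins)
CENTROMERE_16A <- 2010000L
DELETION_END_16A <- 4155000L

hotspot_df <- function(chrom, start, line, width = 400L) {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start) + width, line = line)
}

#' Build the planted ground truth of the synthetic experiment
#'
#' Lays out the study conditions on the toy genome: shared and line-specific
#' DSB hotspots concentrated in the pericentromeric stub of `chr16a`; a
#' single-copy mid-arm deletion on `chr16a` in line B with the stub and the
#' distal arm intact; paired structural-variant junctions whose stub-side
#' ends are mostly co-located with hotspots (4 of 5 intra-chromosomal and
#' 5 of 6 inter-chromosomal ends); genes immediately downstream of the stub
#' planted with strong up-regulation in line B; additional up- and
#' down-regulated genes placed within 5 kb of line-B-specific hotspots; and
#' a survival cohort whose hazard doubles-plus above a marker threshold at
#' the 60th percentile.
#'
#' @param spec a [genome_spec()] (landmarks assume [default_genome_spec()]
#'   chromosome names and lengths).
#' @param gene_models a `gene_model_set` from [build_genome()].
#' @param cfg a [sim_config()].
#' @return a `truth_set`: list with data.frames `hotspots`, `cnv`, `sv`,
#'   `de`, list `survival`, and the pericentromeric `region`.
#' @export
build_truth <- function(spec, gene_models, cfg = sim_config()) {
  stopifnot(inherits(spec, "genome_spec"), inherits(gene_models, "gene_model_set"))
  stub <- list(chrom = "chr16a", start = CENTROMERE_16A,
               end = CENTROMERE_16A + cfg$stub_bp)

  hs <- rbind(
    # shared hotspots inside the stub and elsewhere
    hotspot_df("chr16a", c(2020000, 2080000, 2150000, 2220000), "shared"),
    hotspot_df("chr16a", 4700000, "shared"),
    hotspot_df("chr10a", 2600000, "shared"),
    # line-B (cancer analog) hotspots: stub cluster, deleted arm, distal arm
    hotspot_df("chr16a", c(2040000, 2100000, 2130000, 2180000, 2250000, 2290000), "B"),
    hotspot_df("chr16a", c(2500000, 3000000, 3500000, 4000000), "B"),
    hotspot_df("chr16a", c(4500000, 5200000), "B"),
    # line-A hotspots
    hotspot_df("chr16a", 1000000, "A"),
    hotspot_df("chr10a", c(1500000, 3200000), "A"))

  # genes immediately downstream of the stub: the over-expression cluster
  g <- gene_models$genes
  downstream <- g[g$chrom == "chr16a" & g$start >= stub$end, ]
  downstream <- downstream[order(downstream$start), ]
  if (nrow(downstream) < 3) stop("genome too sparse: need >= 3 genes downstream of the stub")
  up_cluster <- downstream$gene_id[1:3]

  # genes clear of their neighbours and of the rearranged chr16a mid-arm,
  # to host DSB-proximal expression changes; the hotspot sits in the gene
  # body so the gene is unambiguously the nearest one (distance 0)
  iso <- isolated_genes(g, min_gap = 200)
  iso <- iso[!(iso$chrom == "chr16a" & iso$start < DELETION_END_16A + 50000) &
               !(iso$gene_id %in% up_cluster), ]
  cand_start <- pmax(iso$start + 100L, (iso$start + iso$end) %/% 2L - 200L)
  clear <- vapply(seq_len(nrow(iso)), function(i) {
    !any(hs$chrom == iso$chrom[i] & hs$start < cand_start[i] + 400L + 5000L &
           hs$end > cand_start[i] - 5000L)
  }, logical(1))
  iso <- iso[clear, , drop = FALSE]
  cand_start <- cand_start[clear]
  if (nrow(iso) < 6) stop("genome too sparse: need 6 isolated genes for DSB-linked DE")
  link <- iso[seq_len(6), ]
  hs <- rbind(hs, hotspot_df(link$chrom, cand_start[seq_len(6)], "B"))
  hs <- hs[order(hs$chrom, hs$start), ]
  rownames(hs) <- NULL
  if (overlaps_within(hs)) stop("internal error: planted hotspots overlap")
  hs$fold <- cfg$hotspot_fold

  cnv <- data.frame(chrom = "chr16a", start = stub$end, end = DELETION_END_16A,
                    line = "B", cn = 1L)

  sv <- build_sv_truth(spec, stub, cfg)

  de <- data.frame(gene_id = c(up_cluster, link$gene_id),
                   log2fc = c(rep(5, 5), rep(-5, 4)),
                   role = c(rep("stub_downstream", 3), rep("dsb_linked", 6)))

  out <- list(hotspots = hs, cnv = cnv, sv = sv, de = de,
              survival = list(cutoff = qlnorm(cfg$cutoff_quantile,
                                              cfg$marker_meanlog, cfg$marker_sdlog),
                              cutoff_quantile = cfg$cutoff_quantile,
                              hazard_ratio = cfg$hazard_ratio,
                              marker_meanlog = cfg$marker_meanlog,
                              marker_sdlog = cfg$marker_sdlog),
              region = stub)
  class(out) <- "truth_set"
  out
}

isolated_genes <- function(genes, min_gap) {
  keep <- logical(nrow(genes))
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    o <- idx[order(genes$start[idx])]
    gap_left <- c(Inf, genes$start[o][-1] - genes$end[o][-length(o)])
    gap_right <- c(gap_left[-1], Inf)
    keep[o] <- gap_left >= min_gap & gap_right >= min_gap
  }
  genes[keep, ]
}

overlaps_within <- function(df) {
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1 && any(b$start[-1] < b$end[-nrow(b)])) return(TRUE)
  }
  FALSE
}

build_sv_truth <- function(spec, stub, cfg) {
  # stub-side junction ends; positions chosen inside planted hotspots except
  # the last of each class (the "miss" mirroring 4-of-5 and 5-of-6)
  intra_stub <- c(2020100, 2040200, 2100100, 2130300, 2070000)
  intra_coloc <- c(TRUE, TRUE, TRUE, TRUE, FALSE)
  inter_stub <- c(2080100, 2150200, 2180100, 2250300, 2290100, 2200000)
  inter_coloc <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)

  pericentric <- rbind(
    data.frame(chrom1 = "chr16a", pos1 = as.integer(intra_stub), strand1 = "+",
               chrom2 = "chr16a",
               pos2 = c(3200000L, 3400000L, 2800000L, 4500000L, 5100000L),
               strand2 = "-", line = "B", co_located = intra_coloc),
    data.frame(chrom1 = "chr16a", pos1 = as.integer(inter_stub), strand1 = "+",
               chrom2 = "chr10a",
               pos2 = c(2050000L, 2120000L, 2310000L, 2440000L, 2590000L, 2700000L),
               strand2 = "+", line = "B", co_located = inter_coloc))

  bg <- with_substream(cfg$seed, "truth/sv", {
    rand_pos <- function(n, chrom) {
      len <- chrom_length(spec, chrom)
      p <- as.integer(runif(n, 0, len - 1))
      # keep background junction ends clear of the pericentromeric stub
      while (any(bad <- chrom == stub$chrom & p >= stub$start - 1000 &
                   p < stub$end + 1000)) {
        p[bad] <- as.integer(runif(sum(bad), 0, len[bad] - 1))
      }
      p
    }
    mk <- function(line, n_intra, n_inter) {
      ch_i <- sample(spec$chromosomes$name, n_intra, replace = TRUE)
      a <- rand_pos(n_intra, ch_i); b <- rand_pos(n_intra, ch_i)
      intra <- data.frame(chrom1 = ch_i, pos1 = pmin(a, b),
                          strand1 = sample(c("+", "-"), n_intra, TRUE),
                          chrom2 = ch_i, pos2 = pmax(a, b),
                          strand2 = sample(c("+", "-"), n_intra, TRUE),
                          line = line, co_located = FALSE)
      c1 <- rep("chr16a", n_inter); c2 <- rep("chr10a", n_inter)
      inter <- data.frame(chrom1 = c1, pos1 = rand_pos(n_inter, c1),
                          strand1 = sample(c("+", "-"), n_inter, TRUE),
                          chrom2 = c2, pos2 = rand_pos(n_inter, c2),
                          strand2 = sample(c("+", "-"), n_inter, TRUE),
                          line = line, co_located = FALSE)
      rbind(intra, inter)
    }
    rbind(mk("A", 40L, 8L), mk("B", 48L, 6L))
  })

  sv <- rbind(pericentric, bg)
  sv$class <- ifelse(sv$chrom1 == sv$chrom2, "intra", "inter")
  sv$source_id <- sprintf("sv_%03d", seq_len(nrow(sv)))
  rownames(sv) <- NULL
  sv
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the truth manifest as JSON
#'
#' @param truth a `truth_set` from [build_truth()].
#' @param path file path.
#' @return `read_truth` returns a `truth_set` equal to the one written.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$hotspots <- as.data.frame(x$hotspots)
  x$cnv <- as.data.frame(x$cnv)
  x$sv <- as.data.frame(x$sv)
  x$de <- as.data.frame(x$de)
  class(x) <- "truth_set"
  x
}
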