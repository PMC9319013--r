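#' Genome specification
#'
#' Describes the (toy or real) genome over which tracks are binned: an
#' ordered set of chromosomes with lengths, plus the two binning resolutions
#' used by the pipeline -- fine bins for Break-seq/DNA-seq coverage and
#' coarse bins for copy-number profiling.
#'
#' All genomic coordinates in this package are 0-based, half-open
#' (`[start, end)`), the BED convention.
#'
#' @param chromosomes data.frame with columns `name` (character) and
#'   `length` (integer bp).
#' @param bin_size_cov coverage bin width in bp (Break-seq / DNA-seq tracks).
#' @param bin_size_cnv copy-number bin width in bp (15 kb by default, the
#'   conventional resolution for shallow-WGS copy-number profiles).
#' @return an object of class `genome_spec`.
#' @export
#' @examples
#' genome_spec(data.frame(name = "chr1", length = 1e6))
genome_spec <- function(chromosomes, bin_size_cov = 100L, bin_size_cnv = 15000L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.integer(chromosomes$length)
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (anyDuplicated(chromosomes$name)) stop("duplicate chromosome names")
  if (bin_size_cov <= 0 || bin_size_cnv <= 0) stop("bin sizes must be > 0")
  structure(list(chromosomes = chromosomes[, c("name", "length")],
                 bin_size_cov = as.integer(bin_size_cov),
                 bin_size_cnv = as.integer(bin_size_cnv)),
            class = "genome_spec")
}

chrom_length <- function(spec, chrom) {
  i <- match(chrom, spec$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  spec$chromosomes$length[i]
}

#' Tile a genome into bins
#'
#' The terminal partial bin of each chromosome is kept (and flagged), not
#' dropped, so that total counts over a track are conserved.
#'
#' @param spec a [genome_spec()].
#' @param bin_size bin width in bp; defaults to the spec's coverage bin size.
#' @return data.frame with columns `chrom`, `start`, `end`, `partial`.
#' @export
genome_bins <- function(spec, bin_size = spec$bin_size_cov) {
  out <- lapply(seq_len(nrow(spec$chromosomes)), function(i) {
    len <- spec$chromosomes$length[i]
    starts <- seq.int(0L, len - 1L, by = bin_size)
    ends <- pmin(starts + bin_size, len)
    data.frame(chrom = spec$chromosomes$name[i], start = starts, end = ends,
               partial = ends - starts < bin_size)
  })
  do.call(rbind, out)
}

#' Build a random non-overlapping gene model set
#'
#' Genes are placed uniformly at random, without overlap, across the genome:
#' each gene is assigned to a chromosome with probability proportional to
#' chromosome length, spans are drawn log-normally around `mean_span`, and
#' starts are chosen by uniformly partitioning the free space left after the
#' spans are accounted for. Each gene carries 1-10 non-overlapping exons.
#'
#' @param spec a [genome_spec()].
#' @param n_genes number of genes to place.
#' @param seed integer seed; output is deterministic for a fixed seed.
#' @param mean_span mean gene span in bp.
#' @param span_sdlog log-normal sdlog of the span distribution.
#' @return a `gene_model_set`: list with data.frames `genes`
#'   (`gene_id, chrom, start, end, strand, tss, tes`) and `exons`
#'   (`gene_id, chrom, start, end`), 0-based half-open.
#' @export
build_genome <- function(spec, n_genes, seed, mean_span = 30000, span_sdlog = 0.5) {
  stopifnot(inherits(spec, "genome_spec"), n_genes >= 0)
  empty <- list(
    genes = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer(), strand = character(),
                       tss = integer(), tes = integer()),
    exons = data.frame(gene_id = character(), chrom = character(),
                       start = integer(), end = integer()))
  class(empty) <- "gene_model_set"
  if (n_genes == 0) return(empty)

  with_substream(seed, "gene_models", {
    chroms <- spec$chromosomes
    assignment <- sample(chroms$name, n_genes, replace = TRUE,
                         prob = chroms$length / sum(chroms$length))
    spans <- pmax(1000L, as.integer(round(
      rlnorm(n_genes, meanlog = log(mean_span), sdlog = span_sdlog))))
    genes <- vector("list", nrow(chroms))
    exons <- vector("list", nrow(chroms))
    idx0 <- 0L
    for (ci in seq_len(nrow(chroms))) {
      sel <- which(assignment == chroms$name[ci])
      if (!length(sel)) next
      len <- chroms$length[ci]
      sp <- spans[sel]
      free <- len - sum(sp)
      if (free < 0) {
        stop("genome too small for requested gene count: chromosome ",
             chroms$name[ci], " needs ", sum(sp), " bp for ", length(sel),
             " genes but is only ", len, " bp")
      }
      # uniform placement of non-overlapping intervals: split the free space
      gaps <- sort(runif(length(sp), 0, free))
      starts <- as.integer(round(gaps)) + c(0L, cumsum(sp[-length(sp)]))
      ends <- starts + sp
      strand <- sample(c("+", "-"), length(sp), replace = TRUE)
      ids <- sprintf("gene_%04d", idx0 + seq_along(sp))
      idx0 <- idx0 + length(sp)
      genes[[ci]] <- data.frame(gene_id = ids, chrom = chroms$name[ci],
                                start = starts, end = ends, strand = strand,
                                tss = ifelse(strand == "+", starts, ends),
                                tes = ifelse(strand == "+", ends, starts))
      exons[[ci]] <- do.call(rbind, lapply(seq_along(sp), function(g) {
        n_ex <- sample.int(10L, 1L)
        body <- ends[g] - starts[g]
        if (2L * n_ex - 1L >= body) n_ex <- 1L
        if (n_ex == 1L) {
          es <- starts[g]; ee <- ends[g]
        } else {
          # 2*n_ex - 2 interior cut points delimit alternating exons/introns
          cuts <- sort(sample.int(body - 1L, 2L * n_ex - 2L))
          bounds <- c(0L, cuts, body)
          es <- starts[g] + bounds[seq(1L, 2L * n_ex, by = 2L)]
          ee <- starts[g] + bounds[seq(2L, 2L * n_ex, by = 2L)]
        }
        data.frame(gene_id = ids[g], chrom = chroms$name[ci],
                   start = es, end = ee)
      }))
    }
    out <- list(genes = do.call(rbind, genes[!vapply(genes, is.null, TRUE)]),
                exons = do.call(rbind, exons[!vapply(exons, is.null, TRUE)]))
    rownames(out$genes) <- rownames(out$exons) <- NULL
    class(out) <- "gene_model_set"
    out
  })
}
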