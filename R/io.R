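#' Coverage track container
#'
#' A binned coverage track: one row per bin with `chrom`, `start`, `end`
#' (0-based half-open) and a non-negative `count`. Bins must be sorted and
#' non-overlapping with constant width except for the flagged terminal
#' partial bin of each chromosome.
#'
#' @param bins data.frame with columns `chrom`, `start`, `end`, `count`.
#' @param bin_size nominal bin width in bp.
#' @return a `coverage_track` (data.frame subclass with a `bin_size`
#'   attribute and a `total_count` attribute).
#' @export
coverage_track <- function(bins, bin_size) {
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(bins)))
  if (any(bins$count < 0)) stop("counts must be >= 0")
  if (any(bins$end <= bins$start)) stop("bins must have end > start")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE)) stop("bins must be sorted per chromosome")
    if (any(b$start[-1] < b$end[-nrow(b)])) stop("bins must not overlap")
    w <- b$end - b$start
    if (nrow(b) > 1 && any(w[-nrow(b)] != bin_size)) {
      stop("non-terminal bins must have width bin_size")
    }
  }
  structure(bins[, c("chrom", "start", "end", "count")],
            bin_size = as.integer(bin_size),
            total_count = sum(bins$count),
            class = c("coverage_track", "data.frame"))
}

track_bin_size <- function(track) attr(track, "bin_size")

df_to_granges <- function(df, extra = NULL) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
  if (!is.null(extra)) S4Vectors::mcols(gr) <- df[, extra, drop = FALSE]
  gr
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             as.data.frame(S4Vectors::mcols(gr)))
}

#' Read / write bedGraph coverage tracks
#'
#' Thin wrappers around [rtracklayer::import()]/[rtracklayer::export()] that
#' convert between the package's 0-based half-open data.frames and GRanges.
#'
#' @param track a [coverage_track()].
#' @param path file path.
#' @param bin_size nominal bin width of the track being read.
#' @return `read_bedgraph` returns a [coverage_track()].
#' @export
write_bedgraph <- function(track, path) {
  gr <- df_to_granges(track)
  S4Vectors::mcols(gr)$score <- track$count
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, bin_size) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- granges_to_df(gr)
  names(df)[names(df) == "score"] <- "count"
  coverage_track(df, bin_size)
}

#' Read / write interval sets as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name` and `score`.
#' @param path file path.
#' @return `read_bed` returns a data.frame with `chrom`, `start`, `end` plus
#'   any name/score columns present.
#' @export
write_bed <- function(intervals, path) {
  gr <- df_to_granges(intervals)
  if (!is.null(intervals$name)) S4Vectors::mcols(gr)$name <- intervals$name
  if (!is.null(intervals$score)) S4Vectors::mcols(gr)$score <- intervals$score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  granges_to_df(rtracklayer::import(path, format = "BED"))
}

#' Write / read gene models as GTF-like GFF2
#'
#' @param gene_models a `gene_model_set` from [build_genome()].
#' @param path file path.
#' @return `read_gene_models` returns a `gene_model_set`.
#' @export
write_gene_models <- function(gene_models, path) {
  g <- gene_models$genes
  e <- gene_models$exons
  rows <- rbind(
    data.frame(chrom = g$chrom, type = "gene", start = g$start, end = g$end,
               strand = g$strand, gene_id = g$gene_id),
    data.frame(chrom = e$chrom, type = "exon", start = e$start, end = e$end,
               strand = g$strand[match(e$gene_id, g$gene_id)],
               gene_id = e$gene_id))
  gr <- GenomicRanges::GRanges(rows$chrom,
                               IRanges::IRanges(rows$start + 1L, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$source <- "breakscape"
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  rtracklayer::export(gr, path, format = "gff2")
  invisible(path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff2")
  df <- granges_to_df(gr)
  df$strand <- as.character(BiocGenerics::strand(gr))
  g <- df[df$type == "gene", ]
  e <- df[df$type == "exon", ]
  g <- g[order(g$gene_id), ]
  genes <- data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
                      end = g$end, strand = g$strand,
                      tss = ifelse(g$strand == "+", g$start, g$end),
                      tes = ifelse(g$strand == "+", g$end, g$start))
  exons <- data.frame(gene_id = e$gene_id, chrom = e$chrom,
                      start = e$start, end = e$end)
  exons <- exons[order(exons$gene_id, exons$start), ]
  rownames(genes) <- rownames(exons) <- NULL
  structure(list(genes = genes, exons = exons), class = "gene_model_set")
}

#' Write / read a gene-level count matrix as TSV
#'
#' Columns are labelled `sample:group` so that group membership travels with
#' the matrix.
#'
#' @param counts integer matrix, genes x samples, with rownames = gene ids.
#' @param groups character vector of group labels, one per column.
#' @param path file path.
#' @return `read_count_matrix` returns `list(counts, groups)`.
#' @export
write_count_matrix <- function(counts, groups, path) {
  stopifnot(length(groups) == ncol(counts))
  out <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  names(out) <- c("gene_id", paste(colnames(counts), groups, sep = ":"))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  parts <- strsplit(colnames(m), ":", fixed = TRUE)
  groups <- vapply(parts, function(p) p[length(p)], "")
  colnames(m) <- vapply(parts, function(p) paste(p[-length(p)], collapse = ":"), "")
  list(counts = m, groups = groups)
}

#' Write / read a survival cohort table as TSV
#'
#' @param cohort data.frame with `time`, `event`, `marker`.
#' @param path file path.
#' @return `read_cohort` returns the cohort data.frame.
#' @export
write_cohort <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  validate_cohort(df)
  df
}
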