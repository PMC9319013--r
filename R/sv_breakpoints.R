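#' Write paired breakpoints as BEDPE
#'
#' Each end is written as a 1 bp interval at its breakpoint coordinate (the
#' interval start is the coordinate; convention documented in
#' [load_bedpe()]).
#'
#' @param sv data.frame with `chrom1`, `pos1`, `strand1`, `chrom2`, `pos2`,
#'   `strand2` and optionally `source_id`.
#' @param path file path.
#' @export
write_bedpe <- function(sv, path) {
  name <- if (is.null(sv$source_id)) sprintf("sv_%03d", seq_len(nrow(sv))) else sv$source_id
  out <- data.frame(sv$chrom1, sv$pos1, sv$pos1 + 1L,
                    sv$chrom2, sv$pos2, sv$pos2 + 1L,
                    name, 0L, sv$strand1, sv$strand2)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load paired structural-variant breakpoints from BEDPE
#'
#' BEDPE has no reader among the standard R track importers, so a minimal
#' one is provided. Per-end intervals are 0-based half-open; the breakpoint
#' coordinate of each end is the interval *start* (split-read callers emit
#' tight per-end intervals, and the start is stable). Records with either
#' end on an excluded contig (chrY, chrM, or an unassigned contig whose name
#' contains `"_"` or starts with `"Un"`) are dropped and counted. Ends are
#' canonically ordered (end1 <= end2 by chromosome, then position) and each
#' record is classed `intra` or `inter`.
#'
#' @param path BEDPE file with >= 6 columns.
#' @param excluded_contigs contig names always excluded.
#' @param unassigned_pattern regex marking unassigned contigs.
#' @return list with `breakpoints` (data.frame `chrom1, pos1, strand1,
#'   chrom2, pos2, strand2, class, source_id`), `n_excluded`,
#'   `excluded_contig_table`, and `malformed` (line numbers).
#' @export
load_bedpe <- function(path, excluded_contigs = c("chrY", "chrM"),
                       unassigned_pattern = "_|^Un") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  empty <- data.frame(chrom1 = character(), pos1 = integer(), strand1 = character(),
                      chrom2 = character(), pos2 = integer(), strand2 = character(),
                      class = character(), source_id = character())
  if (!length(lines)) {
    return(list(breakpoints = empty, n_excluded = 0L,
                excluded_contig_table = table(character()), malformed = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 6L
  malformed <- which(!ok)
  fields <- fields[ok]
  get <- function(i) vapply(fields, `[`, "", i)
  df <- data.frame(chrom1 = get(1), pos1 = suppressWarnings(as.integer(get(2))),
                   chrom2 = get(4), pos2 = suppressWarnings(as.integer(get(5))))
  nf <- lengths(fields)
  df$source_id <- ifelse(nf >= 7, vapply(fields, function(f) f[min(7, length(f))], ""),
                         sprintf("bedpe_%04d", seq_len(nrow(df))))
  df$strand1 <- ifelse(nf >= 9, vapply(fields, function(f) f[min(9, length(f))], ""), "*")
  df$strand2 <- ifelse(nf >= 10, vapply(fields, function(f) f[min(10, length(f))], ""), "*")
  bad <- is.na(df$pos1) | is.na(df$pos2)
  malformed <- sort(c(malformed, which(ok)[bad]))
  df <- df[!bad, , drop = FALSE]

  is_excluded <- function(ch) ch %in% excluded_contigs | grepl(unassigned_pattern, ch)
  drop <- is_excluded(df$chrom1) | is_excluded(df$chrom2)
  excluded_contig_table <- table(c(df$chrom1[drop][is_excluded(df$chrom1[drop])],
                                   df$chrom2[drop][is_excluded(df$chrom2[drop])]))
  kept <- df[!drop, , drop = FALSE]

  # canonical end ordering: end1 <= end2 by chromosome then position
  swap <- kept$chrom1 > kept$chrom2 |
    (kept$chrom1 == kept$chrom2 & kept$pos1 > kept$pos2)
  if (any(swap)) {
    tmp <- kept[swap, c("chrom1", "pos1", "strand1")]
    kept[swap, c("chrom1", "pos1", "strand1")] <-
      kept[swap, c("chrom2", "pos2", "strand2")]
    kept[swap, c("chrom2", "pos2", "strand2")] <- tmp
  }
  kept$class <- ifelse(kept$chrom1 == kept$chrom2, "intra", "inter")
  rownames(kept) <- NULL
  list(breakpoints = kept[, names(empty)], n_excluded = sum(drop),
       excluded_contig_table = excluded_contig_table, malformed = malformed)
}

#' Per-chromosome tally of intra- and inter-chromosomal events
#'
#' Each intra-chromosomal event adds 1 to its chromosome's intra count; each
#' inter-chromosomal event adds 1 to the inter count of *both* partner
#' chromosomes and 1 to the symmetric cell of the chromosome-pair matrix
#' (the table behind a Circos plot).
#'
#' @param breakpoints data.frame as returned by [load_bedpe()] (the
#'   `breakpoints` element) or the truth `sv` table.
#' @return list with `per_chromosome` (data.frame `chrom, intra, inter`),
#'   `pair_matrix` (symmetric, zero diagonal), `n_intra`, `n_inter`.
#' @export
classify_and_tally <- function(breakpoints) {
  bp <- breakpoints
  if (!"class" %in% names(bp)) {
    bp$class <- ifelse(bp$chrom1 == bp$chrom2, "intra", "inter")
  }
  chroms <- sort(unique(c(bp$chrom1, bp$chrom2)))
  intra <- vapply(chroms, function(ch) sum(bp$class == "intra" & bp$chrom1 == ch),
                  integer(1))
  inter <- vapply(chroms, function(ch) {
    sum(bp$class == "inter" & (bp$chrom1 == ch | bp$chrom2 == ch))
  }, integer(1))
  m <- matrix(0L, length(chroms), length(chroms), dimnames = list(chroms, chroms))
  ii <- bp$class == "inter"
  if (any(ii)) {
    for (k in which(ii)) {
      m[bp$chrom1[k], bp$chrom2[k]] <- m[bp$chrom1[k], bp$chrom2[k]] + 1L
      m[bp$chrom2[k], bp$chrom1[k]] <- m[bp$chrom2[k], bp$chrom1[k]] + 1L
    }
  }
  list(per_chromosome = data.frame(chrom = chroms, intra = intra, inter = inter,
                                   row.names = NULL),
       pair_matrix = m,
       n_intra = sum(bp$class == "intra"), n_inter = sum(ii))
}

#' Difference report between two SV tallies
#'
#' @param tally_a,tally_b results of [classify_and_tally()] (A = reference,
#'   e.g. the control line; B = comparison).
#' @return list with `per_chromosome` (total events per chromosome in each
#'   tally and their difference) and `total_a`, `total_b`, `percent_change`
#'   (`100 * (total_b - total_a) / total_a`, `NA` when `total_a` is 0).
#' @export
sv_delta <- function(tally_a, tally_b) {
  total_a <- tally_a$n_intra + tally_a$n_inter
  total_b <- tally_b$n_intra + tally_b$n_inter
  chroms <- sort(union(tally_a$per_chromosome$chrom, tally_b$per_chromosome$chrom))
  per <- data.frame(chrom = chroms,
                    a = rowSums(tally_merge(tally_a, chroms)),
                    b = rowSums(tally_merge(tally_b, chroms)), row.names = NULL)
  per$diff <- per$b - per$a
  list(per_chromosome = per, total_a = total_a, total_b = total_b,
       percent_change = if (total_a == 0) NA_real_ else 100 * (total_b - total_a) / total_a)
}

tally_merge <- function(tally, chroms) {
  t <- tally$per_chromosome
  i <- match(chroms, t$chrom)
  cbind(intra = ifelse(is.na(i), 0L, t$intra[i]),
        inter = ifelse(is.na(i), 0L, t$inter[i]))
}
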