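#' Strand-specific read coverage over gene bodies
#'
#' Counts stranded damage/repair reads over each gene, split by strand
#' relative to the gene: a read on the strand *opposite* the gene's
#' annotation overlaps the transcribed (template) strand and increments
#' `ts_count`; a same-strand read increments `nts_count`. This is the
#' standard Damage-seq/XR-seq convention; set `template_is_opposite =
#' FALSE` to flip it. Any >= 1 bp overlap counts, half-open coordinates;
#' a read overlapping several genes counts for each of them. Reads on
#' chromosomes absent from the gene set are skipped with a warning and
#' tallied in the skip report.
#'
#' @param reads BED6 data frame of stranded reads.
#' @param genes gene-model data frame.
#' @param template_is_opposite if `TRUE` (default) the transcribed strand
#'   is the strand opposite the gene's annotation.
#' @return list with `profile` (data frame `gene_id, ts_count, nts_count`)
#'   and `skipped` (data frame of unknown-chromosome tallies).
#' @export
transcribed_strand_coverage <- function(reads, genes,
                                        template_is_opposite = TRUE) {
  known <- reads$chrom %in% unique(genes$chrom)
  skipped <- data.frame(chrom = character(0), n_reads = integer(0))
  if (any(!known)) {
    tab <- table(reads$chrom[!known])
    skipped <- data.frame(chrom = names(tab), n_reads = as.integer(tab),
                          stringsAsFactors = FALSE)
    warning(sum(!known), " read(s) on unknown chromosome(s) skipped")
    reads <- reads[known, , drop = FALSE]
  }
  profile <- data.frame(gene_id = genes$gene_id,
                        ts_count = 0L, nts_count = 0L,
                        stringsAsFactors = FALSE)
  if (nrow(reads) > 0 && nrow(genes) > 0) {
    gr_genes <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
      strand = genes$strand)
    gr_reads <- GenomicRanges::GRanges(
      reads$chrom, IRanges::IRanges(reads$start + 1L, reads$end),
      strand = reads$strand)
    ov <- GenomicRanges::findOverlaps(gr_reads, gr_genes,
                                      ignore.strand = TRUE)
    same <- reads$strand[S4Vectors::queryHits(ov)] ==
      genes$strand[S4Vectors::subjectHits(ov)]
    ts_hit <- if (template_is_opposite) !same else same
    tally <- function(mask) {
      tab <- table(factor(S4Vectors::subjectHits(ov)[mask],
                          levels = seq_len(nrow(genes))))
      as.integer(tab)
    }
    profile$ts_count <- tally(ts_hit)
    profile$nts_count <- tally(!ts_hit)
  }
  list(profile = profile, skipped = skipped)
}

#' Normalize coverage to reads per kb per million mapped
#'
#' `norm = count / ((gene_length / 1000) * (library_size / 1e6))`, the
#' normalized read count used when comparing repair coverage between gene
#' sets.
#'
#' @param profile coverage data frame with `ts_count` and `nts_count`.
#' @param library_size total mapped reads in the library (> 0).
#' @param gene_length numeric vector of gene lengths (bp, > 0), aligned
#'   with `profile` rows.
#' @return `profile` with `ts_norm` and `nts_norm` columns added.
#' @export
normalize_coverage <- function(profile, library_size, gene_length) {
  if (length(library_size) != 1 || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  if (any(gene_length <= 0)) stop("gene lengths must be > 0")
  denom <- (gene_length / 1000) * (library_size / 1e6)
  profile$ts_norm <- profile$ts_count / denom
  profile$nts_norm <- profile$nts_count / denom
  profile
}
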