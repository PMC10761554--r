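#' GC fraction of a sequence
#'
#' `(#G + #C) / (#A + #C + #G + #T)`, case-insensitive; `N` bases are
#' excluded from the denominator. GC is computed over the full unspliced
#' gene-body sequence in the pipeline, because lesions target the genome,
#' not the mature transcript.
#'
#' @param sequence character scalar or `DNAString` over `{A,C,G,T,N}`.
#' @return fraction in `[0, 1]`.
#' @examples
#' gc_fraction("GCGC") # 1
#' gc_fraction("ATGN") # 1/3
#' @export
gc_fraction <- function(sequence) {
  ch <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  denom <- sum(ch %in% c("A", "C", "G", "T"))
  if (denom == 0) stop("gc_fraction undefined: empty or all-N sequence")
  sum(ch %in% c("G", "C")) / denom
}

#' Exon fraction of a gene model
#'
#' Length of the union of the gene's exon intervals divided by its genomic
#' span (`end - start`). Overlapping or book-ended exons are merged before
#' summing; a gene with no exons has fraction 0. This is the "exon
#' composition" used when contrasting repair-favourable architecture
#' between up- and down-regulated genes.
#'
#' @param gene one row of a gene-model data frame (needs `start`, `end`,
#'   `exon_starts`, `exon_ends`).
#' @return fraction in `[0, 1]`.
#' @export
exon_fraction <- function(gene) {
  ex <- parse_exons(gene$exon_starts, gene$exon_ends)
  if (nrow(ex) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(start = ex[, 1] + 1L, end = ex[, 2]))
  sum(IRanges::width(ir)) / (gene$end - gene$start)
}

#' Compute architecture features for all genes
#'
#' @param genes gene-model data frame.
#' @param sequences `DNAStringSet` with the gene chromosomes (optional; GC
#'   is `NA` when absent).
#' @return data frame with `gene_id, length_bp, gc_fraction, exon_fraction`.
#' @export
arch_features <- function(genes, sequences = NULL) {
  n <- nrow(genes)
  gc <- rep(NA_real_, n)
  ef <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.null(sequences)) {
      gc[i] <- gc_fraction(subseq_chr(sequences, genes$chrom[i],
                                      genes$start[i], genes$end[i]))
    }
    ef[i] <- exon_fraction(genes[i, ])
  }
  data.frame(gene_id = genes$gene_id,
             length_bp = genes$end - genes$start,
             gc_fraction = gc,
             exon_fraction = ef,
             stringsAsFactors = FALSE)
}

#' Tertile assignment
#'
#' Splits values into low/mid/high bins at the 33 1/3 and 66 2/3
#' percentiles (linear interpolation, `stats::quantile` type 7), or at
#' externally supplied boundaries -- e.g. the published gene-length cutoffs
#' 14,590 / 51,570 bp or GC cutoffs 41.6% / 49.5%, which are only
#' reproducible on the exact annotation universe they were computed on.
#' Values equal to a boundary go to `mid` (ties break to the lower bin).
#'
#' @param values numeric vector (at least 3 finite values unless
#'   `boundaries` is supplied).
#' @param boundaries optional length-2 ascending cutoffs.
#' @return list with `labels` (factor low/mid/high) and `boundaries`.
#' @export
tertile_assign <- function(values, boundaries = NULL) {
  if (!all(is.finite(values))) stop("tertile_assign: non-finite values")
  if (is.null(boundaries)) {
    if (length(values) < 3) stop("tertile_assign needs >= 3 values")
    boundaries <- unname(quantile(values, c(1 / 3, 2 / 3), type = 7))
  }
  if (length(boundaries) != 2 || boundaries[1] > boundaries[2]) {
    stop("boundaries must be an ascending pair")
  }
  lab <- ifelse(values < boundaries[1], "low",
                ifelse(values > boundaries[2], "high", "mid"))
  list(labels = factor(lab, levels = c("low", "mid", "high")),
       boundaries = boundaries)
}

#' Extract strand-aware promoters
#'
#' A promoter is the pure upstream flank of the gene start: for a `+`
#' strand gene `[max(0, start - flank), start)`, for a `-` strand gene
#' `[end, min(chrom_len, end + flank))`. Genes whose flank is clipped to
#' an empty interval at a chromosome edge are skipped with a warning.
#'
#' @param genes gene-model data frame.
#' @param flank_bp promoter length upstream of the gene start (default the
#'   conventional 3 kb).
#' @param chrom_sizes named integer vector of chromosome lengths covering
#'   all gene chromosomes.
#' @return BED6 data frame of promoters (name = gene_id, score = 0).
#' @export
extract_promoters <- function(genes, flank_bp = 3000L, chrom_sizes) {
  if (flank_bp <= 0) stop("flank_bp must be > 0")
  missing_chr <- setdiff(unique(genes$chrom), names(chrom_sizes))
  if (length(missing_chr)) {
    stop("chrom_sizes missing: ", paste(missing_chr, collapse = ", "))
  }
  len <- chrom_sizes[genes$chrom]
  plus <- genes$strand == "+"
  start <- ifelse(plus, pmax(0, genes$start - flank_bp), genes$end)
  end <- ifelse(plus, genes$start, pmin(len, genes$end + flank_bp))
  keep <- start < end
  if (any(!keep)) {
    warning(sum(!keep), " gene(s) at chromosome edges yield empty promoters",
            " and were skipped: ",
            paste(head(genes$gene_id[!keep], 5), collapse = ", "))
  }
  data.frame(chrom = genes$chrom, start = as.integer(start),
             end = as.integer(end), name = genes$gene_id, score = 0L,
             strand = genes$strand, stringsAsFactors = FALSE)[keep, ]
}

#' Fetch promoter sequences
#'
#' Extracts each promoter's sequence from the genome; minus-strand
#' promoters are reverse-complemented so sequences read 5'->3' on the
#' gene's sense strand. (Motif scanning is strand-symmetric, so the
#' orientation only affects reported hit strands.)
#'
#' @param promoters BED6 data frame from [extract_promoters()].
#' @param sequences `DNAStringSet`.
#' @return named character vector of sequences (names = gene ids).
#' @export
promoter_sequences <- function(promoters, sequences) {
  out <- character(nrow(promoters))
  for (i in seq_len(nrow(promoters))) {
    s <- subseq_chr(sequences, promoters$chrom[i],
                    promoters$start[i], promoters$end[i])
    if (promoters$strand[i] == "-") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    out[i] <- s
  }
  names(out) <- promoters$name
  out
}
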