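#' File input/output for the pipeline's plain-text formats
#'
#' All coordinates are 0-based half-open (BED semantics), both in BED6
#' files and in the gene-table TSV.
#'
#' @name damagetx-io
NULL

empty_bed6 <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             name = character(0), score = integer(0), strand = character(0),
             stringsAsFactors = FALSE)
}

# exon start/end comma strings -> 2-column integer matrix
parse_exons <- function(starts, ends) {
  if (is.na(starts) || starts == "" || starts == ".") {
    return(matrix(integer(0), ncol = 2))
  }
  s <- as.integer(strsplit(starts, ",", fixed = TRUE)[[1]])
  e <- as.integer(strsplit(ends, ",", fixed = TRUE)[[1]])
  if (length(s) != length(e)) stop("exon start/end lists differ in length")
  cbind(s, e)
}

# 0-based half-open subsequence of a named chromosome
subseq_chr <- function(sequences, chrom, start, end) {
  if (!chrom %in% names(sequences)) {
    stop("chromosome not in sequence set: ", chrom)
  }
  as.character(Biostrings::subseq(sequences[[chrom]], start + 1L, end))
}

#' Read and write the gene-model table
#'
#' Tab-separated with columns `gene_id, chrom, start, end, strand,
#' exon_starts, exon_ends`; exon columns are comma-separated absolute
#' coordinates, 0-based half-open.
#'
#' @param path file path.
#' @param genes gene-model data frame.
#' @return `read_gene_table` returns the validated data frame.
#' @export
read_gene_table <- function(path) {
  g <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(exon_starts = "character",
                                 exon_ends = "character"))
  need <- c("gene_id", "chrom", "start", "end", "strand",
            "exon_starts", "exon_ends")
  if (!all(need %in% names(g))) {
    stop("gene table ", path, " missing columns: ",
         paste(setdiff(need, names(g)), collapse = ", "))
  }
  validate_genes(g)
  g
}

validate_genes <- function(g) {
  bad <- which(!(g$start < g$end))
  if (length(bad)) stop("gene table: start >= end at row ", bad[1])
  if (!all(g$strand %in% c("+", "-"))) stop("gene table: invalid strand")
  for (i in seq_len(nrow(g))) {
    ex <- parse_exons(g$exon_starts[i], g$exon_ends[i])
    if (nrow(ex) && (any(ex[, 1] >= ex[, 2]) || any(ex[, 1] < g$start[i]) ||
                     any(ex[, 2] > g$end[i]))) {
      stop("gene table: exon outside gene span for ", g$gene_id[i])
    }
  }
  invisible(g)
}

#' @rdname read_gene_table
#' @export
write_gene_table <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write BED6 interval files
#'
#' Standard 6-column BED: chrom, start, end, name, score, strand, 0-based
#' half-open.
#'
#' @param path file path.
#' @param bed data frame with the six BED columns.
#' @return `read_bed6` returns a data frame with the six BED columns.
#' @export
read_bed6 <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) return(empty_bed6())
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(b) < 6) stop("BED6 file ", path, " has ", ncol(b), " columns")
  b <- b[, 1:6]
  names(b) <- c("chrom", "start", "end", "name", "score", "strand")
  bad <- which(!(b$start < b$end) | !(b$strand %in% c("+", "-")))
  if (length(bad)) {
    stop("malformed BED6 record at line ", bad[1], " of ", path)
  }
  b
}

#' @rdname read_bed6
#' @export
write_bed6 <- function(bed, path) {
  if (nrow(bed) == 0) {
    file.create(path)
    return(invisible(path))
  }
  write.table(bed[, c("chrom", "start", "end", "name", "score", "strand")],
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED12 file as gene models
#'
#' Block fields become exons (absolute coordinates). Records whose block
#' sizes/starts disagree with `blockCount`, or whose blocks leave the
#' chromStart/chromEnd span, are rejected with the offending record named.
#'
#' @param path file path.
#' @return a gene-model data frame (see [read_gene_table()]).
#' @export
read_bed12 <- function(path) {
  b <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(b) < 12) stop("BED12 file ", path, " has ", ncol(b), " columns")
  n <- nrow(b)
  exon_s <- character(n); exon_e <- character(n)
  for (i in seq_len(n)) {
    cnt <- b[i, 10]
    sizes <- as.integer(strsplit(as.character(b[i, 11]), ",")[[1]])
    offs <- as.integer(strsplit(as.character(b[i, 12]), ",")[[1]])
    if (length(sizes) != cnt || length(offs) != cnt) {
      stop("BED12 record ", i, " (", b[i, 4],
           "): blockCount disagrees with blockSizes/blockStarts")
    }
    s <- b[i, 2] + offs
    e <- s + sizes
    if (any(e > b[i, 3]) || any(s < b[i, 2])) {
      stop("BED12 record ", i, " (", b[i, 4], "): blocks leave gene span")
    }
    exon_s[i] <- paste(s, collapse = ",")
    exon_e[i] <- paste(e, collapse = ",")
  }
  g <- data.frame(gene_id = as.character(b[, 4]), chrom = as.character(b[, 1]),
                  start = b[, 2], end = b[, 3], strand = as.character(b[, 6]),
                  exon_starts = exon_s, exon_ends = exon_e,
                  stringsAsFactors = FALSE)
  validate_genes(g)
  g
}

#' Read and write count matrices
#'
#' Genes-by-samples TSV with a `gene_id` first column.
#'
#' @param path file path.
#' @param counts integer matrix with gene ids as row names.
#' @return `read_counts` returns an integer matrix.
#' @export
read_counts <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @export
write_counts <- function(counts, path) {
  d <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read differential-expression tables
#'
#' TSV with columns `gene_id, log2fc, padj` and optionally `cell_type` and
#' `agent` (or a combined `condition`).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_de_table <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(d))) {
    stop("DE table ", path, " missing columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  }
  ok <- is.na(d$padj) | (d$padj >= 0 & d$padj <= 1)
  if (!all(ok)) stop("DE table ", path, ": padj outside [0,1] at line ",
                     which(!ok)[1] + 1L)
  d
}
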