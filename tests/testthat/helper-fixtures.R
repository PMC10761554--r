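# Shared fixtures built in code (no binary files).

# gene-model row as a one-row data frame
make_gene <- function(gene_id = "gX", chrom = "chr1", start = 0, end = 100,
                      strand = "+", exons = list(c(0, 100))) {
  data.frame(
    gene_id = gene_id, chrom = chrom, start = start, end = end,
    strand = strand,
    exon_starts = paste(vapply(exons, `[`, numeric(1), 1), collapse = ","),
    exon_ends = paste(vapply(exons, `[`, numeric(1), 2), collapse = ","),
    stringsAsFactors = FALSE
  )
}

make_bed <- function(chrom, start, end, name = ".", score = 0L,
                     strand = "+") {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             score = score, strand = strand, stringsAsFactors = FALSE)
}

# near-deterministic "GG" motif and a calibrated threshold that admits
# only the consensus window
gg_motif <- function() {
  new_pwm(matrix(rep(c(0.01, 0.01, 0.97, 0.01), 2), nrow = 2, byrow = TRUE))
}

random_dna <- function(n, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# brute-force window rescoring oracle for scan_sequence
naive_scan <- function(sequence, logodds, threshold) {
  w <- nrow(logodds)
  ch <- strsplit(toupper(sequence), "")[[1]]
  comp_map <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  for (p in seq_len(length(ch) - w + 1L)) {
    win <- ch[p:(p + w - 1L)]
    if (any(!win %in% c("A", "C", "G", "T"))) next
    fs <- sum(vapply(seq_len(w), function(j) logodds[j, win[j]], numeric(1)))
    rc <- rev(unname(comp_map[win]))
    rs <- sum(vapply(seq_len(w), function(j) logodds[j, rc[j]], numeric(1)))
    if (fs >= threshold - 1e-9) {
      hits[[length(hits) + 1L]] <- data.frame(position = p - 1L,
                                              strand = "+", score = fs)
    }
    if (rs >= threshold - 1e-9) {
      hits[[length(hits) + 1L]] <- data.frame(position = p - 1L,
                                              strand = "-", score = rs)
    }
  }
  if (!length(hits)) {
    return(data.frame(position = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$position, out$strand), , drop = FALSE]
}

# quadratic all-pairs overlap oracle for transcribed_strand_coverage
naive_coverage <- function(reads, genes) {
  ts <- integer(nrow(genes)); nts <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    for (k in seq_len(nrow(reads))) {
      if (reads$chrom[k] != genes$chrom[i]) next
      if (reads$start[k] < genes$end[i] && reads$end[k] > genes$start[i]) {
        if (reads$strand[k] != genes$strand[i]) ts[i] <- ts[i] + 1L
        else nts[i] <- nts[i] + 1L
      }
    }
  }
  data.frame(gene_id = genes$gene_id, ts_count = ts, nts_count = nts,
             stringsAsFactors = FALSE)
}

# run one condition of the simulator and its DE analysis
sim_and_de <- function(cfg) {
  g <- simulate_genome(cfg)
  d <- simulate_damage(g$genes, g$sequences, cfg)
  r <- simulate_repair(d$damages, g$genes, cfg)
  e <- simulate_expression(g$genes, r$truth, cfg)
  nr <- cfg$n_replicates
  de <- nb_de_test(e$counts[, seq_len(nr), drop = FALSE],
                   e$counts[, nr + seq_len(nr), drop = FALSE])
  list(genome = g, damage = d, repair = r, expr = e, de = de,
       features = arch_features(g$genes, g$sequences))
}
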