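#' Simulator configuration
#'
#' Builds and validates the configuration for the forward simulator of the
#' damage -> repair -> transcription causal model. Defaults describe a
#' desk-scale study: a few hundred genes with log-normal lengths, agent
#' specific damage targets (dipyrimidines for UV, guanines for cisplatin
#' and BPDE) hit at a small per-site rate, exon-enhanced nucleotide
#' excision repair, and negative-binomial counts whose treated mean decays
#' exponentially with unrepaired transcribed-strand damage.
#'
#' @param n_genes number of genes to simulate.
#' @param length_lognorm_mu,length_lognorm_sigma mean and sd of log gene
#'   length (bp) on the natural-log scale.
#' @param exon_fraction_range length-2 vector, range of per-gene target
#'   exon fractions in `[0, 1]`.
#' @param gc_range length-2 vector, range of per-gene GC fractions.
#' @param agent one of `"UV"`, `"cisplatin"`, `"BPDE"`.
#' @param damage_rate probability that an individual target site carries a
#'   lesion (values above 1 are capped at use).
#' @param repair_prob_base probability that a lesion outside exons is
#'   repaired.
#' @param exon_repair_factor multiplier (`rho`) on `repair_prob_base` for
#'   lesions inside exons; the product is capped at 1.
#' @param suppression_beta per-residual-lesion exponential decay rate of
#'   the treated expression mean (transcribed strand only).
#' @param induced_gene_ids character vector of gene ids forming the induced
#'   damage-response program (may be empty).
#' @param induction_factor fold multiplier applied to induced genes' treated
#'   mean, before damage suppression.
#' @param nb_dispersion negative-binomial dispersion `alpha`
#'   (`var = mu + alpha * mu^2`).
#' @param baseline_mean_range range of per-gene baseline expression means.
#' @param n_replicates replicates per arm (control and treated).
#' @param seed root seed; all stages derive child seeds from it.
#' @param min_gene_length shortest gene the genome generator will emit, bp.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 200,
                       length_lognorm_mu = log(4000),
                       length_lognorm_sigma = 0.8,
                       exon_fraction_range = c(0.1, 0.9),
                       gc_range = c(0.35, 0.65),
                       agent = c("UV", "cisplatin", "BPDE"),
                       damage_rate = 0.01,
                       repair_prob_base = 0.5,
                       exon_repair_factor = 2,
                       suppression_beta = 0.1,
                       induced_gene_ids = character(0),
                       induction_factor = 4,
                       nb_dispersion = 0.05,
                       baseline_mean_range = c(50, 500),
                       n_replicates = 3,
                       seed = 1L,
                       min_gene_length = 200L) {
  agent <- match.arg(agent)
  chk_range <- function(x, nm, lo = -Inf, hi = Inf) {
    if (length(x) != 2 || any(!is.finite(x)) || x[1] > x[2] ||
        x[1] < lo || x[2] > hi) {
      stop_config(nm, " must be a finite ascending pair within [",
                  lo, ", ", hi, "]")
    }
  }
  if (n_genes < 1) stop_config("n_genes must be >= 1")
  chk_range(exon_fraction_range, "exon_fraction_range", 0, 1)
  chk_range(gc_range, "gc_range", 0, 1)
  chk_range(baseline_mean_range, "baseline_mean_range", lo = 1e-12)
  if (damage_rate < 0) stop_config("damage_rate must be >= 0")
  if (repair_prob_base < 0 || repair_prob_base > 1) {
    stop_config("repair_prob_base must be in [0, 1]")
  }
  if (exon_repair_factor < 0) stop_config("exon_repair_factor must be >= 0")
  if (suppression_beta < 0) stop_config("suppression_beta must be >= 0")
  if (induction_factor <= 0) stop_config("induction_factor must be > 0")
  if (nb_dispersion <= 0) stop_config("nb_dispersion must be > 0")
  if (n_replicates < 1) stop_config("n_replicates must be >= 1")
  structure(list(
    n_genes = as.integer(n_genes),
    length_lognorm_mu = length_lognorm_mu,
    length_lognorm_sigma = length_lognorm_sigma,
    exon_fraction_range = exon_fraction_range,
    gc_range = gc_range,
    agent = agent,
    damage_rate = damage_rate,
    repair_prob_base = repair_prob_base,
    exon_repair_factor = exon_repair_factor,
    suppression_beta = suppression_beta,
    induced_gene_ids = as.character(induced_gene_ids),
    induction_factor = induction_factor,
    nb_dispersion = nb_dispersion,
    baseline_mean_range = baseline_mean_range,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed),
    min_gene_length = as.integer(min_gene_length)
  ), class = "sim_config")
}

# Sample one gene's exon layout. Returns absolute (start, end) pairs,
# 0-based half-open, first exon anchored at the gene start and last at the
# gene end so the realized exon fraction equals round(f * L) / L.
sample_exons <- function(gstart, gend, exon_frac) {
  L <- gend - gstart
  ebp <- max(1L, round(exon_frac * L))
  if (ebp >= L) {
    return(cbind(start = gstart, end = gend))
  }
  ibp <- L - ebp
  k_max <- min(ebp, ibp + 1L, max(1L, L %/% 500L))
  k <- if (k_max <= 1L) 1L else sample.int(k_max, 1L)
  if (k == 1L) {
    # single exon at the 5' end, intron tail absorbed by anchoring rule:
    # keep exon at start and pad with a terminal exon of length 0 is not
    # allowed, so split into two exons unless that is impossible
    if (ebp >= 2L && ibp >= 1L) k <- 2L
  }
  if (k == 1L) {
    return(cbind(start = gstart, end = gstart + ebp))
  }
  part <- function(total, m) { # m positive parts summing to total
    if (m == 1L) return(total)
    cuts <- sort(sample.int(total - 1L, m - 1L))
    diff(c(0L, cuts, total))
  }
  exon_len <- part(ebp, k)
  intron_len <- part(ibp, k - 1L)
  starts <- gstart + cumsum(c(0L, exon_len[-k] + intron_len))
  cbind(start = starts, end = starts + exon_len)
}

#' Simulate a synthetic chromosome and gene models
#'
#' Places `n_genes` non-overlapping genes on one synthetic chromosome.
#' Gene lengths are log-normal; each gene draws a target GC fraction and
#' exon fraction uniformly from the configured ranges. Gene sequence is
#' sampled i.i.d. with `P(G) = P(C) = gc/2`; intergenic spacers use GC 0.4.
#' Coordinates are 0-based, half-open throughout.
#'
#' @param config a [sim_config()].
#' @param chrom chromosome name.
#' @param gene_prefix prefix for generated gene ids.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and `genes`
#'   (a gene-model data frame; see [read_gene_table()] for the column
#'   contract).
#' @export
simulate_genome <- function(config, chrom = "chrSim", gene_prefix = "g") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genome"), {
    n <- config$n_genes
    lens <- pmax(config$min_gene_length,
                 as.integer(round(rlnorm(n, config$length_lognorm_mu,
                                         config$length_lognorm_sigma))))
    gcs <- runif(n, config$gc_range[1], config$gc_range[2])
    efs <- runif(n, config$exon_fraction_range[1],
                 config$exon_fraction_range[2])
    strands <- sample(c("+", "-"), n, replace = TRUE)
    gaps <- sample(200:800, n + 1L, replace = TRUE)

    starts <- integer(n); ends <- integer(n)
    pos <- gaps[1]
    seq_parts <- character(2L * n + 1L)
    sample_dna <- function(len, gc) {
      p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
      paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
    }
    seq_parts[1] <- sample_dna(gaps[1], 0.4)
    exon_s <- character(n); exon_e <- character(n)
    for (i in seq_len(n)) {
      starts[i] <- pos
      ends[i] <- pos + lens[i]
      ex <- sample_exons(starts[i], ends[i], efs[i])
      exon_s[i] <- paste(ex[, "start"], collapse = ",")
      exon_e[i] <- paste(ex[, "end"], collapse = ",")
      seq_parts[2L * i] <- sample_dna(lens[i], gcs[i])
      seq_parts[2L * i + 1L] <- sample_dna(gaps[i + 1L], 0.4)
      pos <- ends[i] + gaps[i + 1L]
    }
    dna <- Biostrings::DNAStringSet(paste(seq_parts, collapse = ""))
    names(dna) <- chrom
    genes <- data.frame(
      gene_id = sprintf("%s%04d", gene_prefix, seq_len(n)),
      chrom = chrom,
      start = starts,
      end = ends,
      strand = strands,
      exon_starts = exon_s,
      exon_ends = exon_e,
      stringsAsFactors = FALSE
    )
    list(sequences = dna, genes = genes)
  })
}

#' Enumerate damage target sites on one strand
#'
#' UV photoproducts form at dipyrimidines (both bases pyrimidine, C or T);
#' cisplatin and BPDE adducts form at guanines. Positions are 0-based start
#' offsets of the target site *on the strand assessed*: for the minus
#' strand the reverse complement of `sequence` is scanned and offsets refer
#' to that reverse-complement coordinate frame.
#'
#' @param sequence character scalar or `DNAString` over `{A,C,G,T,N}`.
#' @param strand `"+"` or `"-"`.
#' @param agent `"UV"`, `"cisplatin"` or `"BPDE"`.
#' @return sorted integer vector of 0-based site starts (width 2 for UV,
#'   1 otherwise).
#' @examples
#' enumerate_target_sites("TTAG", "+", "UV")        # 0 (the TT)
#' enumerate_target_sites("TTAG", "+", "cisplatin") # 3 (the G)
#' @export
enumerate_target_sites <- function(sequence, strand = c("+", "-"),
                                   agent = c("UV", "cisplatin", "BPDE")) {
  strand <- match.arg(strand)
  agent <- match.arg(agent)
  s <- toupper(as.character(sequence))
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  if (agent == "UV") {
    if (length(ch) < 2L) return(integer(0))
    pyr <- ch %in% c("C", "T")
    hits <- which(pyr[-length(pyr)] & pyr[-1]) - 1L
  } else {
    hits <- which(ch == "G") - 1L
  }
  sort(unique(as.integer(hits)))
}

target_site_width <- function(agent) if (agent == "UV") 2L else 1L

#' Simulate lesion formation over gene bodies
#'
#' Each target site on each strand of each gene body is independently
#' damaged with probability `min(1, damage_rate)` -- damage formation is
#' dictated by target-nucleotide frequency, so longer genes accumulate more
#' lesions. The transcribed (template) strand of a gene is the genomic
#' strand opposite its annotation.
#'
#' @param genes gene-model data frame from [simulate_genome()].
#' @param sequences `DNAStringSet` holding the gene chromosomes.
#' @param config a [sim_config()].
#' @return list with `damages` (BED6-style data frame: chrom, start, end,
#'   name = host gene id, score, strand) and `truth` (per-gene data frame
#'   with target-site and damage counts per strand).
#' @export
simulate_damage <- function(genes, sequences, config) {
  stopifnot(inherits(config, "sim_config"))
  w <- target_site_width(config$agent)
  p_dmg <- min(1, config$damage_rate)
  with_seed(derive_seed(config$seed, paste0("damage_", config$agent)), {
    out <- vector("list", nrow(genes))
    truth <- data.frame(
      gene_id = genes$gene_id,
      n_target_sites_ts = 0L, n_target_sites_nts = 0L,
      damages_ts = 0L, damages_nts = 0L,
      stringsAsFactors = FALSE
    )
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      gseq <- subseq_chr(sequences, g$chrom, g$start, g$end)
      L <- g$end - g$start
      sites_p <- enumerate_target_sites(gseq, "+", config$agent)
      sites_m_rc <- enumerate_target_sites(gseq, "-", config$agent)
      # map minus-strand offsets (reverse-complement frame) back to genomic
      sites_m <- sort(L - w - sites_m_rc)
      # transcribed strand is opposite the gene's annotated strand
      if (g$strand == "+") {
        ts_sites <- sites_m; nts_sites <- sites_p
        ts_strand <- "-"; nts_strand <- "+"
      } else {
        ts_sites <- sites_p; nts_sites <- sites_m
        ts_strand <- "+"; nts_strand <- "-"
      }
      hit_ts <- ts_sites[runif(length(ts_sites)) < p_dmg]
      hit_nts <- nts_sites[runif(length(nts_sites)) < p_dmg]
      truth$n_target_sites_ts[i] <- length(ts_sites)
      truth$n_target_sites_nts[i] <- length(nts_sites)
      truth$damages_ts[i] <- length(hit_ts)
      truth$damages_nts[i] <- length(hit_nts)
      if (length(hit_ts) + length(hit_nts) > 0) {
        out[[i]] <- data.frame(
          chrom = g$chrom,
          start = g$start + c(hit_ts, hit_nts),
          end = g$start + c(hit_ts, hit_nts) + w,
          name = g$gene_id,
          score = 0L,
          strand = c(rep(ts_strand, length(hit_ts)),
                     rep(nts_strand, length(hit_nts))),
          stringsAsFactors = FALSE
        )
      }
    }
    damages <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(damages)) damages <- empty_bed6()
    list(damages = damages, truth = truth)
  })
}

#' Simulate nucleotide excision repair of lesions
#'
#' A lesion inside an exon of its host gene is repaired with probability
#' `min(1, exon_repair_factor * repair_prob_base)`, otherwise with
#' `repair_prob_base` -- NER is more efficient in exons than in introns.
#' Every repaired lesion emits one excision-product read (26 nt, the
#' centre of the NER excision oligo range) on the lesion's strand.
#'
#' @param damages lesion BED6 data frame from [simulate_damage()].
#' @param genes gene-model data frame.
#' @param config a [sim_config()].
#' @param read_length width of emitted repair reads, bp.
#' @return list with `repair_reads` (BED6 data frame), `residual_damages`
#'   (BED6 data frame of unrepaired lesions) and `truth` (per-gene repaired
#'   and residual counts per strand; `repaired + residual = damaged`
#'   exactly).
#' @export
simulate_repair <- function(damages, genes, config, read_length = 26L) {
  stopifnot(inherits(config, "sim_config"))
  p_exon <- min(1, config$exon_repair_factor * config$repair_prob_base)
  p_base <- config$repair_prob_base
  with_seed(derive_seed(config$seed, paste0("repair_", config$agent)), {
    truth <- data.frame(
      gene_id = genes$gene_id,
      repaired_ts = 0L, repaired_nts = 0L,
      residual_ts = 0L, residual_nts = 0L,
      stringsAsFactors = FALSE
    )
    if (nrow(damages) == 0) {
      return(list(repair_reads = empty_bed6(),
                  residual_damages = empty_bed6(), truth = truth))
    }
    gidx <- match(damages$name, genes$gene_id)
    if (anyNA(gidx)) stop("damage records reference unknown gene ids")
    in_exon <- logical(nrow(damages))
    for (j in unique(gidx)) {
      ex <- parse_exons(genes$exon_starts[j], genes$exon_ends[j])
      sel <- which(gidx == j)
      # a lesion is exonic if its start lies in a (merged) exon interval
      in_exon[sel] <- vapply(damages$start[sel], function(p) {
        any(p >= ex[, 1] & p < ex[, 2])
      }, logical(1))
    }
    p_rep <- ifelse(in_exon, p_exon, p_base)
    repaired <- runif(nrow(damages)) < p_rep
    ts <- damages$strand != genes$strand[gidx]
    agg <- function(mask) {
      tab <- table(factor(damages$name[mask], levels = genes$gene_id))
      as.integer(tab)
    }
    truth$repaired_ts <- agg(repaired & ts)
    truth$repaired_nts <- agg(repaired & !ts)
    truth$residual_ts <- agg(!repaired & ts)
    truth$residual_nts <- agg(!repaired & !ts)

    reads <- damages[repaired, , drop = FALSE]
    if (nrow(reads) > 0) {
      centre <- (reads$start + reads$end) %/% 2L
      reads$start <- pmax(0L, centre - read_length %/% 2L)
      reads$end <- reads$start + read_length
    }
    rownames(reads) <- NULL
    resid <- damages[!repaired, , drop = FALSE]
    rownames(resid) <- NULL
    list(repair_reads = reads, residual_damages = resid, truth = truth)
  })
}

#' Simulate expression counts under damage suppression
#'
#' Control replicate means are the per-gene baselines `mu_g`; treated means
#' are `mu_g * exp(-beta * residual_ts_g)`, times `induction_factor` for
#' genes in the induced program. Only unrepaired transcribed-strand lesions
#' suppress expression (the polymerase-blocking framing); non-transcribed
#' strand lesions are inert. Counts are negative binomial with dispersion
#' `alpha` (`var = mu + alpha * mu^2`).
#'
#' @param genes gene-model data frame.
#' @param residual_truth per-gene truth from [simulate_repair()] (needs
#'   `gene_id`, `residual_ts`).
#' @param config a [sim_config()].
#' @return list with `counts` (integer matrix genes x samples, control then
#'   treated replicates) and `truth` (gene_id, baseline_mean,
#'   expected_log2fc, induced).
#' @export
simulate_expression <- function(genes, residual_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  ridx <- match(genes$gene_id, residual_truth$gene_id)
  if (anyNA(ridx)) stop("residual truth missing genes")
  resid <- residual_truth$residual_ts[ridx]
  induced <- genes$gene_id %in% config$induced_gene_ids
  with_seed(derive_seed(config$seed, paste0("expression_", config$agent)), {
    n <- nrow(genes)
    mu0 <- runif(n, config$baseline_mean_range[1],
                 config$baseline_mean_range[2])
    mu1 <- mu0 * exp(-config$suppression_beta * resid) *
      ifelse(induced, config$induction_factor, 1)
    size <- 1 / config$nb_dispersion
    nr <- config$n_replicates
    ctrl <- matrix(rnbinom(n * nr, mu = rep(mu0, nr), size = size), nrow = n)
    trt <- matrix(rnbinom(n * nr, mu = rep(mu1, nr), size = size), nrow = n)
    counts <- cbind(ctrl, trt)
    rownames(counts) <- genes$gene_id
    colnames(counts) <- c(paste0("control_", seq_len(nr)),
                          paste0("treated_", seq_len(nr)))
    truth <- data.frame(
      gene_id = genes$gene_id,
      baseline_mean = mu0,
      expected_log2fc = log2(mu1 / mu0),
      induced = induced,
      stringsAsFactors = FALSE
    )
    list(counts = counts, truth = truth)
  })
}

#' Simulate a full comparative study and write its file bundle
#'
#' Mirrors the two-cell-type, three-agent comparative design: two synthetic
#' "cell types" (independent genomes sharing one gene-id universe) each
#' treated with UV, cisplatin and BPDE. Every condition runs the full
#' lesion -> repair -> expression cascade and the bundle is written as
#' plain-text FASTA / TSV / BED6 / JSON.
#'
#' @param config a [sim_config()]; `agent` is overridden per condition. If
#'   `induced_gene_ids` is empty, a shared induced program of
#'   `induced_frac` of genes is drawn.
#' @param out_dir directory to write the bundle into (created if needed).
#' @param cell_types names of the two pseudo-cell-types.
#' @param agents damaging agents to apply to each cell type.
#' @param induced_frac fraction of genes in the induced program when
#'   `config$induced_gene_ids` is empty.
#' @return (invisibly) a list with `manifest` (also written as JSON),
#'   per-cell-type `genomes`, and per-condition `results` (truth tables and
#'   file paths).
#' @export
simulate_study <- function(config, out_dir,
                           cell_types = c("cellA", "cellB"),
                           agents = c("UV", "cisplatin", "BPDE"),
                           induced_frac = 0.1) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  induced <- config$induced_gene_ids
  if (length(induced) == 0) {
    induced <- with_seed(derive_seed(config$seed, "induced_program"), {
      ids <- sprintf("g%04d", seq_len(config$n_genes))
      sort(sample(ids, max(1L, round(induced_frac * config$n_genes))))
    })
  }
  manifest <- list(root_seed = config$seed, cell_types = cell_types,
                   agents = agents, induced_gene_ids = induced,
                   files = list())
  genomes <- list(); results <- list()
  for (ct in cell_types) {
    ct_cfg <- config
    ct_cfg$seed <- derive_seed(config$seed, paste0("celltype_", ct))
    ct_cfg$induced_gene_ids <- induced
    genome <- simulate_genome(ct_cfg, chrom = paste0("chr_", ct))
    genomes[[ct]] <- genome
    fa <- file.path(out_dir, paste0(ct, ".fa"))
    gt <- file.path(out_dir, paste0(ct, "_genes.tsv"))
    Biostrings::writeXStringSet(genome$sequences, fa)
    write_gene_table(genome$genes, gt)
    manifest$files[[paste0(ct, "_fasta")]] <- basename(fa)
    manifest$files[[paste0(ct, "_genes")]] <- basename(gt)
    for (ag in agents) {
      cond <- paste(ct, ag, sep = "_")
      cfg <- ct_cfg
      cfg$agent <- ag
      dmg <- simulate_damage(genome$genes, genome$sequences, cfg)
      rep_ <- simulate_repair(dmg$damages, genome$genes, cfg)
      expr <- simulate_expression(genome$genes, rep_$truth, cfg)
      truth <- Reduce(function(a, b) merge(a, b, by = "gene_id", sort = FALSE),
                      list(dmg$truth, rep_$truth, expr$truth))
      truth <- truth[match(genome$genes$gene_id, truth$gene_id), ]
      paths <- c(
        damage = paste0(cond, "_damage.bed"),
        repair = paste0(cond, "_repair.bed"),
        counts = paste0(cond, "_counts.tsv"),
        truth = paste0(cond, "_truth.tsv")
      )
      write_bed6(dmg$damages, file.path(out_dir, paths["damage"]))
      write_bed6(rep_$repair_reads, file.path(out_dir, paths["repair"]))
      write_counts(expr$counts, file.path(out_dir, paths["counts"]))
      write.table(truth, file.path(out_dir, paths["truth"]),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$files[[cond]] <- as.list(paths)
      manifest$seeds[[cond]] <- cfg$seed
      results[[cond]] <- list(truth = truth, files = paths,
                              cell_type = ct, agent = ag)
    }
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(manifest = manifest, genomes = genomes, results = results,
                 out_dir = out_dir))
}
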