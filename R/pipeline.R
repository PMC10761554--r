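#' Default pipeline configuration
#'
#' Assembles the run configuration consumed by [run_pipeline()] and the
#' CLI: simulator settings plus analysis thresholds. Any element can be
#' overridden via `...`, a JSON config file, or CLI flags (flags win).
#'
#' @param seed root seed for the run.
#' @param ... overrides for individual config entries.
#' @return named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    # simulator
    n_genes = 60L, n_replicates = 3L,
    length_lognorm_mu = log(4000), length_lognorm_sigma = 0.8,
    exon_fraction_range = c(0.1, 0.9), gc_range = c(0.35, 0.65),
    damage_rate = 0.01, repair_prob_base = 0.5, exon_repair_factor = 2,
    suppression_beta = 0.1, induction_factor = 4, nb_dispersion = 0.05,
    baseline_mean_range = c(50, 500), induced_frac = 0.1,
    # analysis thresholds
    lfc_threshold = 0.7, alpha = 0.05, flank_bp = 3000L,
    n_iter = 1000L, p_cut = 1e-4, k_min = 5L,
    # stage toggles
    stages = c("simulate", "features", "de", "coverage",
               "stratify", "motif")
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  for (k in c("n_genes", "n_replicates", "flank_bp", "n_iter", "k_min")) {
    cfg[[k]] <- as.integer(cfg[[k]])
  }
  structure(cfg, class = "run_config")
}

read_run_config <- function(path, seed = NULL) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(default_run_config, c(list(seed = if (!is.null(seed)) seed
                                            else raw$seed %||% 1L),
                                       raw[setdiff(names(raw), "seed")]))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sim_config_from_run <- function(cfg) {
  sim_config(
    n_genes = cfg$n_genes,
    length_lognorm_mu = cfg$length_lognorm_mu,
    length_lognorm_sigma = cfg$length_lognorm_sigma,
    exon_fraction_range = cfg$exon_fraction_range,
    gc_range = cfg$gc_range,
    damage_rate = cfg$damage_rate,
    repair_prob_base = cfg$repair_prob_base,
    exon_repair_factor = cfg$exon_repair_factor,
    suppression_beta = cfg$suppression_beta,
    induction_factor = cfg$induction_factor,
    nb_dispersion = cfg$nb_dispersion,
    baseline_mean_range = cfg$baseline_mean_range,
    n_replicates = cfg$n_replicates,
    seed = cfg$seed
  )
}

#' Built-in example motif (synthetic stand-in)
#'
#' An 8-bp NBRE-like consensus (AAAGGTCA, the binding element of NR4
#' orphan nuclear receptors) with 85% consensus probability per position.
#' This is a synthetic stand-in constructed for the simulator path, not a
#' database matrix; supply a MEME or PFM file for real analyses.
#'
#' @param consensus_prob probability mass on the consensus base.
#' @return a [new_pwm()] object.
#' @export
example_pwm <- function(consensus_prob = 0.85) {
  consensus <- c("A", "A", "A", "G", "G", "T", "C", "A")
  off <- (1 - consensus_prob) / 3
  m <- matrix(off, nrow = length(consensus), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(consensus)) m[i, consensus[i]] <- consensus_prob
  new_pwm(m, name = "NBRE_synthetic")
}

#' Run the full pipeline on a synthetic study
#'
#' Executes the enabled stages in dependency order inside `out_dir`:
#' simulate the two-cell-type x three-agent study, compute architecture
#' features and promoters, call differential expression per condition,
#' aggregate strand-specific damage/repair coverage, run the stratified
#' statistics, test promoter motif enrichment of the up-regulated sets,
#' and write `report.json`. Everything derives from `config$seed`;
#' identical config + seed gives byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [default_run_config()] list.
#' @param quiet suppress progress messages.
#' @return (invisibly) the report list.
#' @export
run_pipeline <- function(out_dir, config = default_run_config(),
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[damagetx] ", ...)
  stages <- config$stages
  log_lines <- c(
    paste0("damagetx ", as.character(utils::packageVersion("damagetx"))),
    paste0("seed: ", config$seed),
    paste0("stages: ", paste(stages, collapse = ", ")),
    paste0("params: lfc>", config$lfc_threshold, ", alpha<", config$alpha,
           ", flank_bp=", config$flank_bp, ", n_iter=", config$n_iter,
           ", p_cut=", config$p_cut, ", k_min=", config$k_min)
  )

  if ("simulate" %in% stages) {
    say("simulating study")
    study <- simulate_study(sim_config_from_run(config), out_dir,
                            induced_frac = config$induced_frac)
  } else {
    manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                    simplifyVector = TRUE)
    study <- NULL
  }
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cell_types <- manifest$cell_types
  agents <- manifest$agents
  conds <- as.vector(outer(cell_types, agents, paste, sep = "_"))

  genomes <- lapply(cell_types, function(ct) {
    list(sequences = Biostrings::readDNAStringSet(
           file.path(out_dir, manifest$files[[paste0(ct, "_fasta")]])),
         genes = read_gene_table(
           file.path(out_dir, manifest$files[[paste0(ct, "_genes")]])))
  })
  names(genomes) <- cell_types

  if ("features" %in% stages) {
    say("computing architecture features and promoters")
    for (ct in cell_types) {
      g <- genomes[[ct]]
      feats <- arch_features(g$genes, g$sequences)
      write.table(feats, file.path(out_dir, paste0(ct, "_features.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      sizes <- setNames(Biostrings::width(g$sequences), names(g$sequences))
      prom <- suppressWarnings(
        extract_promoters(g$genes, config$flank_bp, sizes))
      write_bed6(prom, file.path(out_dir, paste0(ct, "_promoters.bed")))
    }
  }

  if ("de" %in% stages) {
    say("differential expression per condition")
    for (cond in conds) {
      counts <- read_counts(
        file.path(out_dir, manifest$files[[cond]]$counts))
      ctrl <- counts[, grep("^control_", colnames(counts)), drop = FALSE]
      trt <- counts[, grep("^treated_", colnames(counts)), drop = FALSE]
      de <- nb_de_test(ctrl, trt)
      de$status <- classify_deg(de$log2fc, de$padj,
                                config$lfc_threshold, config$alpha)
      write.table(de, file.path(out_dir, paste0(cond, "_de.tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("coverage" %in% stages) {
    say("strand-specific coverage")
    for (cond in conds) {
      ct <- sub("_(UV|cisplatin|BPDE)$", "", cond)
      genes <- genomes[[ct]]$genes
      for (kind in c("damage", "repair")) {
        bed <- read_bed6(file.path(out_dir, manifest$files[[cond]][[kind]]))
        cov <- transcribed_strand_coverage(bed, genes)
        prof <- normalize_coverage(cov$profile, max(1, nrow(bed)),
                                   genes$end - genes$start)
        write.table(prof,
                    file.path(out_dir, paste0(cond, "_", kind, "_cov.tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  if ("stratify" %in% stages) {
    say("stratified statistics")
    stats_rows <- list()
    for (cond in conds) {
      ct <- sub("_(UV|cisplatin|BPDE)$", "", cond)
      de <- read.delim(file.path(out_dir, paste0(cond, "_de.tsv")))
      feats <- read.delim(file.path(out_dir, paste0(ct, "_features.tsv")))
      dmg <- read.delim(file.path(out_dir, paste0(cond, "_damage_cov.tsv")))
      j <- merge(merge(de, feats, by = "gene_id"), dmg, by = "gene_id")
      for (feat in c("length_bp", "gc_fraction", "exon_fraction",
                     "ts_count")) {
        if (sd(j[[feat]]) == 0) next
        sp <- spearman_cor(j[[feat]], j$log2fc)
        stats_rows[[paste(cond, feat)]] <- data.frame(
          condition = cond, comparison = paste0("spearman_", feat),
          statistic = sp$rho, raw_p = sp$p, adj_p = NA_real_,
          stringsAsFactors = FALSE)
      }
      tert <- tertile_assign(j$length_bp)
      rc <- rank_compare(split(j$log2fc, tert$labels))
      stats_rows[[paste(cond, "tertiles")]] <- data.frame(
        condition = cond,
        comparison = paste0("length_", rc$comparisons$group1, "_vs_",
                            rc$comparisons$group2),
        statistic = rc$comparisons$statistic,
        raw_p = rc$comparisons$raw_p, adj_p = rc$comparisons$adj_p,
        stringsAsFactors = FALSE)
    }
    stats <- do.call(rbind, stats_rows)
    rownames(stats) <- NULL
    write.table(stats, file.path(out_dir, "stratified_stats.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("motif" %in% stages) {
    say("promoter motif enrichment")
    pwm <- example_pwm()
    for (ct in cell_types) {
      prom <- read_bed6(file.path(out_dir, paste0(ct, "_promoters.bed")))
      seqs <- promoter_sequences(prom, genomes[[ct]]$sequences)
      lo <- pwm_logodds(pwm)
      thr <- score_threshold(lo, pwm$background, p_cut = config$p_cut)
      hits <- promoter_hits(seqs, lo, thr)
      for (ag in agents) {
        cond <- paste(ct, ag, sep = "_")
        de <- read.delim(file.path(out_dir, paste0(cond, "_de.tsv")))
        up <- intersect(de$gene_id[de$status == "up"], names(hits))
        if (length(up) == 0) {
          res <- list(observed_ratio = NA, p_empirical = NA,
                      note = "no up-regulated genes with promoters")
        } else {
          er <- permutation_test_hits(
            hits, up, n_iter = config$n_iter,
            seed = derive_seed(config$seed, paste0("motif_", cond)))
          res <- er[c("observed_ratio", "p_empirical", "p_upper", "n_iter")]
          res$n_target <- length(up)
          hist_df <- data.frame(null_ratio = er$null_ratios)
          write.table(hist_df,
                      file.path(out_dir, paste0(cond, "_null_ratios.tsv")),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        }
        jsonlite::write_json(res,
                             file.path(out_dir,
                                       paste0(cond, "_enrichment.json")),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
      }
    }
  }

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  rep <- pipeline_report(out_dir, config)
  say("done")
  invisible(rep)
}

#' Summarize a completed (or partial) run directory
#'
#' Aggregates DEG counts per condition, three-agent Venn regions per cell
#' type, cross-condition consistency-set sizes, the correlation table, and
#' motif-enrichment p-values into `report.json`. Sections whose inputs are
#' missing are flagged `"skipped"` instead of failing.
#'
#' @param out_dir a run directory produced by [run_pipeline()].
#' @param config the run configuration (thresholds for recounting).
#' @return the report list (also written to `report.json`).
#' @export
pipeline_report <- function(out_dir, config = default_run_config()) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cell_types <- manifest$cell_types
  agents <- manifest$agents
  conds <- as.vector(outer(cell_types, agents, paste, sep = "_"))
  rep <- list(seed = manifest$root_seed)

  de_paths <- file.path(out_dir, paste0(conds, "_de.tsv"))
  if (all(file.exists(de_paths))) {
    tabs <- lapply(de_paths, read.delim)
    names(tabs) <- conds
    rep$deg_counts <- lapply(tabs, function(d) {
      list(up = sum(d$status == "up"), down = sum(d$status == "down"),
           ns = sum(d$status == "ns"))
    })
    grid <- build_status_grid(tabs, lfc_threshold = config$lfc_threshold,
                              alpha = config$alpha)
    rep$venn <- lapply(setNames(cell_types, cell_types), function(ct) {
      ov <- condition_overlap(grid, paste(ct, agents, sep = "_"))
      c(as.list(ov$regions), list(all3_genes = ov$all3_genes))
    })
    cs <- consistency_sets(grid, config$k_min)
    rep$consistency <- list(
      k_min = config$k_min,
      n_consistent = nrow(cs$set),
      n_stringent = length(cs$stringent),
      genes = cs$set$gene_id
    )
  } else {
    rep$deg_counts <- "skipped"
    rep$venn <- "skipped"
    rep$consistency <- "skipped"
  }

  st_path <- file.path(out_dir, "stratified_stats.tsv")
  rep$correlations <- if (file.exists(st_path)) {
    st <- read.delim(st_path)
    st[grepl("^spearman_", st$comparison), ]
  } else "skipped"

  enr_paths <- file.path(out_dir, paste0(conds, "_enrichment.json"))
  rep$enrichment <- if (all(file.exists(enr_paths))) {
    out <- lapply(enr_paths, jsonlite::read_json, simplifyVector = TRUE)
    names(out) <- conds
    out
  } else "skipped"

  missing <- names(rep)[vapply(rep, identical, logical(1), "skipped")]
  if (length(missing)) rep$missing_sections <- missing
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  rep
}

#' Command-line entry point
#'
#' `damagetx_cli(c("run-all", "--out", dir, "--seed", "7"))` runs the
#' pipeline; subcommands `simulate`, `features`, `de`, `coverage`,
#' `stratify`, `motif` run a single stage (plus its declared inputs from a
#' previous run in the same directory), and `report` rebuilds
#' `report.json`. Flags: `--out <dir>` (required), `--seed <int>`,
#' `--config <json>`, plus threshold overrides `--lfc`, `--alpha`,
#' `--flank-bp`, `--n-iter`, `--p-cut`, `--k-min`, `--n-genes`.
#'
#' @param args character vector of CLI arguments.
#' @return exit status, invisibly (0 on success, 1 on validation failure).
#' @export
damagetx_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: damagetx <subcommand> --out <dir> [--seed N] [--config f.json]",
    "  subcommands: simulate | features | de | coverage | stratify |",
    "               motif | run-all | report", sep = "\n")
  status <- tryCatch({
    if (length(args) < 1) stop(usage)
    sub <- args[1]
    opts <- parse_cli_flags(args[-1])
    if (is.null(opts$out)) stop("missing required flag: --out")
    valid <- c("simulate", "features", "de", "coverage", "stratify",
               "motif", "run-all", "report")
    if (!sub %in% valid) stop("unknown subcommand: ", sub, "\n", usage)
    cfg <- if (!is.null(opts$config)) {
      read_run_config(opts$config, seed = opts$seed)
    } else {
      default_run_config(seed = opts$seed %||% 1L)
    }
    for (k in c("lfc_threshold", "alpha", "flank_bp", "n_iter",
                "p_cut", "k_min", "n_genes")) {
      if (!is.null(opts[[k]])) cfg[[k]] <- opts[[k]]
    }
    if (sub == "report") {
      pipeline_report(opts$out, cfg)
    } else {
      cfg$stages <- if (sub == "run-all") {
        c("simulate", "features", "de", "coverage", "stratify", "motif")
      } else sub
      run_pipeline(opts$out, cfg, quiet = isTRUE(opts$quiet))
    }
    0L
  }, error = function(e) {
    message("damagetx error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  key_map <- c("--out" = "out", "--seed" = "seed", "--config" = "config",
               "--lfc" = "lfc_threshold", "--alpha" = "alpha",
               "--flank-bp" = "flank_bp", "--n-iter" = "n_iter",
               "--p-cut" = "p_cut", "--k-min" = "k_min",
               "--n-genes" = "n_genes")
  num_keys <- c("seed", "lfc_threshold", "alpha", "flank_bp", "n_iter",
                "p_cut", "k_min", "n_genes")
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--quiet") {
      opts$quiet <- TRUE
      i <- i + 1L
    } else if (a %in% names(key_map)) {
      if (i == length(args)) stop("flag ", a, " needs a value")
      k <- key_map[[a]]
      v <- args[i + 1L]
      opts[[k]] <- if (k %in% num_keys) as.numeric(v) else v
      i <- i + 2L
    } else {
      stop("unknown flag: ", a)
    }
  }
  opts
}
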