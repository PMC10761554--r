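test_that("sim_config validates its ranges and probabilities", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(exon_fraction_range = c(0.9, 0.1)), "ascending")
  expect_error(sim_config(gc_range = c(-0.1, 0.5)), "within")
  expect_error(sim_config(repair_prob_base = 1.5), "0, 1")
  expect_error(sim_config(damage_rate = -1), ">= 0")
  expect_error(sim_config(nb_dispersion = 0), "> 0")
  expect_error(sim_config(n_genes = 0), ">= 1")
})

test_that("simulate_genome honours degenerate ranges and determinism", {
  cfg <- sim_config(n_genes = 15, exon_fraction_range = c(1, 1),
                    gc_range = c(0, 0), seed = 3)
  g <- simulate_genome(cfg)
  # single exon spanning the full gene, exon fraction exactly 1
  for (i in seq_len(nrow(g$genes))) {
    ex <- cbind(as.integer(strsplit(g$genes$exon_starts[i], ",")[[1]]),
                as.integer(strsplit(g$genes$exon_ends[i], ",")[[1]]))
    expect_identical(nrow(ex), 1L)
    expect_identical(ex[1, 1], g$genes$start[i])
    expect_identical(ex[1, 2], g$genes$end[i])
    expect_equal(exon_fraction(g$genes[i, ]), 1.0)
    gene_seq <- substr(as.character(g$sequences[[1]]),
                       g$genes$start[i] + 1, g$genes$end[i])
    expect_false(grepl("[GC]", gene_seq))
  }
  # non-overlap, sorted placement
  expect_true(all(g$genes$start[-1] >= head(g$genes$end, -1)))
  # byte-identical under the same seed
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g$sequences), as.character(g2$sequences))
  expect_identical(g$genes, g2$genes)
})

test_that("realized GC and exon fraction track their configured ranges", {
  cfg <- sim_config(n_genes = 40, exon_fraction_range = c(0.3, 0.6),
                    gc_range = c(0.45, 0.55), seed = 8)
  g <- simulate_genome(cfg)
  fe <- arch_features(g$genes, g$sequences)
  # sampling noise on GC ~ sqrt(p q / L); genes are >= 200 bp
  expect_true(all(fe$gc_fraction > 0.45 - 0.15 & fe$gc_fraction < 0.55 + 0.15))
  # exon fraction exact up to 1-bp rounding granularity
  expect_true(all(fe$exon_fraction >= 0.3 - 0.01 &
                  fe$exon_fraction <= 0.6 + 0.01))
})

test_that("enumerate_target_sites matches hand-derived examples", {
  expect_identical(enumerate_target_sites("TTAG", "+", "UV"), 0L)
  expect_identical(enumerate_target_sites("TTAG", "+", "cisplatin"), 3L)
  expect_identical(enumerate_target_sites("AAAA", "+", "UV"), integer(0))
  expect_identical(enumerate_target_sites("AAAA", "-", "cisplatin"),
                   integer(0))
  expect_identical(enumerate_target_sites("CCCC", "-", "cisplatin"),
                   c(0L, 1L, 2L, 3L))
  # dipyrimidines over a mixed sequence: TT,TC,CT,CC all count
  expect_identical(enumerate_target_sites("TTCAG", "+", "UV"), c(0L, 1L))
  expect_error(enumerate_target_sites("ACGT", "+", "arsenic"))
})

test_that("simulate_damage respects rate extremes and binomial scaling", {
  cfg0 <- sim_config(n_genes = 10, damage_rate = 0, seed = 2)
  g <- simulate_genome(cfg0)
  d0 <- simulate_damage(g$genes, g$sequences, cfg0)
  expect_identical(nrow(d0$damages), 0L)

  cfg1 <- sim_config(n_genes = 10, damage_rate = 1, seed = 2)
  d1 <- simulate_damage(g$genes, g$sequences, cfg1)
  expect_identical(d1$truth$damages_ts, d1$truth$n_target_sites_ts)
  expect_identical(d1$truth$damages_nts, d1$truth$n_target_sites_nts)
  # emitted intervals agree with truth counts
  expect_identical(nrow(d1$damages),
                   sum(d1$truth$damages_ts + d1$truth$damages_nts))

  # binomial expectation at rate 0.1
  cfgb <- sim_config(n_genes = 40, damage_rate = 0.1, seed = 11)
  gb <- simulate_genome(cfgb)
  db <- simulate_damage(gb$genes, gb$sequences, cfgb)
  n_sites <- sum(db$truth$n_target_sites_ts + db$truth$n_target_sites_nts)
  total <- sum(db$truth$damages_ts + db$truth$damages_nts)
  expect_gt(n_sites, 5000)
  se <- sqrt(n_sites * 0.1 * 0.9)
  expect_lt(abs(total - 0.1 * n_sites), 3 * se)
})

test_that("mean damage count is non-decreasing in damage_rate", {
  cfg <- sim_config(n_genes = 20, seed = 5)
  g <- simulate_genome(cfg)
  totals <- vapply(c(0, 0.005, 0.02, 0.1, 0.5), function(r) {
    c2 <- cfg; c2$damage_rate <- r
    d <- simulate_damage(g$genes, g$sequences, c2)
    sum(d$truth$damages_ts + d$truth$damages_nts)
  }, numeric(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("simulate_repair conserves counts and applies the exon cap", {
  cfg <- sim_config(n_genes = 20, damage_rate = 0.05,
                    repair_prob_base = 0.5, exon_repair_factor = 2,
                    seed = 6)
  g <- simulate_genome(cfg)
  d <- simulate_damage(g$genes, g$sequences, cfg)
  r <- simulate_repair(d$damages, g$genes, cfg)
  # conservation, exact integers, per gene and strand
  expect_identical(r$truth$repaired_ts + r$truth$residual_ts,
                   d$truth$damages_ts)
  expect_identical(r$truth$repaired_nts + r$truth$residual_nts,
                   d$truth$damages_nts)
  expect_identical(nrow(r$repair_reads) + nrow(r$residual_damages),
                   nrow(d$damages))

  # capped exon repair: rho * base = 1 -> no residual lesion is exonic
  resid <- r$residual_damages
  for (k in seq_len(nrow(resid))) {
    gi <- match(resid$name[k], g$genes$gene_id)
    ex <- cbind(as.integer(strsplit(g$genes$exon_starts[gi], ",")[[1]]),
                as.integer(strsplit(g$genes$exon_ends[gi], ",")[[1]]))
    expect_false(any(resid$start[k] >= ex[, 1] & resid$start[k] < ex[, 2]))
  }
})

test_that("repair_prob_base = 1 clears every lesion", {
  cfg <- sim_config(n_genes = 10, damage_rate = 0.05, repair_prob_base = 1,
                    seed = 4)
  g <- simulate_genome(cfg)
  d <- simulate_damage(g$genes, g$sequences, cfg)
  r <- simulate_repair(d$damages, g$genes, cfg)
  expect_true(all(r$truth$residual_ts == 0))
  expect_true(all(r$truth$residual_nts == 0))
})

test_that("rho = 1 leaves exon and intron repair proportions comparable", {
  cfg <- sim_config(n_genes = 60, damage_rate = 0.2, repair_prob_base = 0.5,
                    exon_repair_factor = 1, seed = 13)
  g <- simulate_genome(cfg)
  d <- simulate_damage(g$genes, g$sequences, cfg)
  r <- simulate_repair(d$damages, g$genes, cfg)
  in_exon <- vapply(seq_len(nrow(d$damages)), function(k) {
    gi <- match(d$damages$name[k], g$genes$gene_id)
    ex <- cbind(as.integer(strsplit(g$genes$exon_starts[gi], ",")[[1]]),
                as.integer(strsplit(g$genes$exon_ends[gi], ",")[[1]]))
    any(d$damages$start[k] >= ex[, 1] & d$damages$start[k] < ex[, 2])
  }, logical(1))
  repaired <- !(paste(d$damages$start, d$damages$strand, d$damages$name) %in%
                  paste(r$residual_damages$start, r$residual_damages$strand,
                        r$residual_damages$name))
  p_ex <- mean(repaired[in_exon]); n_ex <- sum(in_exon)
  p_in <- mean(repaired[!in_exon]); n_in <- sum(!in_exon)
  se <- sqrt(p_ex * (1 - p_ex) / n_ex + p_in * (1 - p_in) / n_in)
  expect_lt(abs(p_ex - p_in), 3 * se)
})

test_that("simulate_expression encodes the suppression/induction link", {
  genes <- rbind(make_gene("a"), make_gene("b"), make_gene("c"))
  resid <- data.frame(gene_id = c("a", "b", "c"),
                      residual_ts = c(0L, 0L, 10L))
  # beta = 0 and no induction -> expected_log2fc = 0 everywhere
  cfg <- sim_config(n_genes = 3, suppression_beta = 0, seed = 1)
  e0 <- simulate_expression(genes, resid, cfg)
  expect_equal(e0$truth$expected_log2fc, rep(0, 3))
  # induced undamaged gene with factor 2 -> +1; residual 10 at beta 0.1 ->
  # -10 * 0.1 / ln 2
  cfg2 <- sim_config(n_genes = 3, suppression_beta = 0.1,
                     induced_gene_ids = "b", induction_factor = 2, seed = 1)
  e2 <- simulate_expression(genes, resid, cfg2)
  expect_equal(e2$truth$expected_log2fc,
               c(0, 1, -10 * 0.1 / log(2)), tolerance = 1e-12)
  expect_identical(dim(e2$counts), c(3L, 6L))
  # deterministic given seed
  e3 <- simulate_expression(genes, resid, cfg2)
  expect_identical(e2$counts, e3$counts)
})

test_that("simulate_study writes a consistent, reloadable bundle", {
  out <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 10, n_replicates = 2, seed = 21)
  res <- simulate_study(cfg, out)
  man <- jsonlite::read_json(file.path(out, "manifest.json"),
                             simplifyVector = TRUE)
  expect_setequal(man$cell_types, c("cellA", "cellB"))
  expect_length(res$results, 6)
  # every declared file exists and parses through its own reader
  for (ct in man$cell_types) {
    genes <- read_gene_table(file.path(out, man$files[[paste0(ct, "_genes")]]))
    expect_identical(nrow(genes), 10L)
    fa <- Biostrings::readDNAStringSet(
      file.path(out, man$files[[paste0(ct, "_fasta")]]))
    expect_length(fa, 1)
  }
  gene_ids <- lapply(man$cell_types, function(ct) {
    read_gene_table(file.path(out, man$files[[paste0(ct, "_genes")]]))$gene_id
  })
  # shared gene universe across cell types (consistency-scoring contract)
  expect_identical(gene_ids[[1]], gene_ids[[2]])

  for (cond in names(res$results)) {
    files <- res$results[[cond]]$files
    truth <- read.delim(file.path(out, files["truth"]))
    dmg <- read_bed6(file.path(out, files["damage"]))
    rep_ <- read_bed6(file.path(out, files["repair"]))
    counts <- read_counts(file.path(out, files["counts"]))
    expect_identical(rownames(counts), gene_ids[[1]])
    # residual = damage - repair, recomputed from the emitted BED files
    n_dmg <- if (nrow(dmg)) table(factor(dmg$name, levels = truth$gene_id))
             else table(factor(character(0), levels = truth$gene_id))
    n_rep <- if (nrow(rep_)) table(factor(rep_$name, levels = truth$gene_id))
             else table(factor(character(0), levels = truth$gene_id))
    expect_identical(as.integer(n_dmg) - as.integer(n_rep),
                     truth$residual_ts + truth$residual_nts)
  }
})

test_that("identical seed gives a byte-identical bundle", {
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 8, n_replicates = 2, seed = 33)
  simulate_study(cfg, out1)
  simulate_study(cfg, out2)
  for (f in setdiff(list.files(out1), "manifest.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
})
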