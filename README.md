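# damagetx

Comparative analysis of the transcriptional response to bulky,
transcription-blocking DNA damage — and a fully ground-truthed forward
simulator to verify every stage of it.

## The problem

UV photoproducts, cisplatin crosslinks and BPDE guanine adducts block
elongating RNA polymerase. Cells respond with a global transcriptional
shutdown from which only some genes escape, and which genes escape is
largely a matter of **gene architecture**: long genes accumulate more
transcribed-strand lesions (damage tracks target-nucleotide frequency),
and exon-rich genes are repaired faster by nucleotide excision repair
(NER), letting their expression recover. Identifying the genes that are
*consistently up-regulated* across damaging agents and cell types — and
the architectural and regulatory features that permit it — requires a
pipeline of per-condition DEG calls, cross-condition consistency
scoring, feature stratification, strand-specific damage/repair coverage,
and promoter motif enrichment against an empirical permutation null.

`damagetx` implements that pipeline for analysts working with
differential-expression tables, gene annotation, stranded
Damage-seq/XR-seq-style interval data, and position weight matrices. A
gene is called **up** when log2FC > 0.7 with adjusted p < 0.05 (down at
< −0.7); the consistency set collects genes up in ≥ k of the 2 cell
types × 3 agents = 6 conditions; motif enrichment compares the fraction
of target promoters containing a PWM hit against 1000 size-matched
random promoter sets, with `p = #(null ≥ observed) / n_iter`.

Because the original headline numbers depend on deposited sequencing
data and external tools, the package ships a forward simulator of the
causal chain — per-site Bernoulli damage at agent-specific targets
(dipyrimidines for UV, guanines for cisplatin/BPDE), exon-enhanced
repair, and negative-binomial counts whose treated mean decays as
`exp(-beta * residual transcribed-strand lesions)` — with complete
ground truth, so correlations, stratifications and enrichment can be
verified end to end at desk scale.

## Worked example

Simulate one treated condition with an induced damage-response program,
run the minimal DE test, and ask the architecture questions:

```r
library(damagetx)

cfg <- sim_config(n_genes = 300, seed = 7,
                  induced_gene_ids = sprintf("g%04d", seq(10, 300, by = 20)))
genome <- simulate_genome(cfg)
dmg    <- simulate_damage(genome$genes, genome$sequences, cfg)
rep    <- simulate_repair(dmg$damages, genome$genes, cfg)
expr   <- simulate_expression(genome$genes, rep$truth, cfg)

de     <- nb_de_test(expr$counts[, 1:3], expr$counts[, 4:6])
feats  <- arch_features(genome$genes, genome$sequences)
status <- classify_deg(de$log2fc, de$padj)
table(status)
#> status
#> down   ns   up
#>   32  249   19

spearman_cor(feats$length_bp, de$log2fc)$rho      # -0.502
spearman_cor(feats$exon_fraction, de$log2fc)$rho  #  0.293

tert <- tertile_assign(feats$length_bp)
rank_compare(split(de$log2fc, tert$labels))$group_stats
#>   group   n      median          q1          q3
#> 1   low 100  0.23642988 -0.03864255  0.49555971
#> 2   mid 100  0.09922852 -0.15081102  0.40307499
#> 3  high 100 -0.52600430 -0.92123389 -0.05908959
```

The simulator's causal model surfaces exactly the published qualitative
patterns: more transcribed-strand damage and greater length mean lower
log2FC (short-tertile median +0.24 vs long-tertile −0.53, pairwise
Mann–Whitney with Bonferroni, adjusted p = 4.5e-15), while higher exon
fraction — better repaired — correlates positively with log2FC. Note
the short tertile's *positive* median: under median-of-ratios
normalization a global shutdown re-centres lightly damaged genes above
zero, just as in real RNA-seq without spike-ins.

The full two-cell-type × three-agent study, with consistency sets, Venn
regions, stratified statistics and motif enrichment, is one call (or one
CLI invocation):

```r
rep <- run_pipeline("my_run", default_run_config(seed = 1, n_genes = 200))
rep$consistency$n_consistent   # genes up in >= 5 of 6 conditions
```

```sh
Rscript inst/cli/damagetx run-all --out my_run --seed 1 --n-genes 200
```

Every output is plain text (TSV/BED6/FASTA/JSON); identical config and
seed give byte-identical outputs.

## Package layout

| Area | Functions |
| --- | --- |
| Simulator | `sim_config`, `simulate_genome`, `enumerate_target_sites`, `simulate_damage`, `simulate_repair`, `simulate_expression`, `simulate_study` |
| Architecture | `gc_fraction`, `exon_fraction`, `arch_features`, `tertile_assign`, `extract_promoters`, `promoter_sequences` |
| DE / consistency | `classify_deg`, `build_status_grid`, `condition_overlap`, `consistency_sets`, `nb_de_test`, `size_factors` |
| Coverage | `transcribed_strand_coverage`, `normalize_coverage` |
| Statistics | `spearman_cor`, `rank_compare`, `signed_rank_vs_zero`, `bonferroni`, `p_stars` |
| Motifs | `new_pwm`, `read_meme`, `read_pfm`, `pwm_logodds`, `score_threshold`, `scan_sequence`, `occurrence_ratio`, `permutation_test` |
| Pipeline | `run_pipeline`, `pipeline_report`, `damagetx_cli`, `default_run_config` |

See `vignettes/damagetx-methods.Rmd` for the model, parameter meanings
and defaults, numerical choices, and what the synthetic tests do and do
not establish.
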