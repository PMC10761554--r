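#' Classify differential-expression status
#'
#' A gene is `up` when `log2fc > lfc_threshold` and `padj < alpha`, `down`
#' when `log2fc < -lfc_threshold` and `padj < alpha`, else `ns`. Both
#' inequalities are strict. A missing `padj` (e.g. removed by independent
#' filtering) yields `ns`, keeping cross-condition counts conservative.
#'
#' @param log2fc numeric vector of log2 fold changes (finite).
#' @param padj numeric vector of adjusted p-values in `[0,1]`, `NA` allowed.
#' @param lfc_threshold log2 fold-change cutoff (default 0.7).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return character vector over `{"up","down","ns"}`.
#' @examples
#' classify_deg(c(1.0, 0.7, -0.8, -2.0), c(0.01, 0.01, 0.04, 0.2))
#' @export
classify_deg <- function(log2fc, padj, lfc_threshold = 0.7, alpha = 0.05) {
  if (any(!is.finite(log2fc))) stop("classify_deg: non-finite log2fc")
  bad <- !is.na(padj) & (padj < 0 | padj > 1)
  if (any(bad)) stop("classify_deg: padj outside [0,1]")
  sig <- !is.na(padj) & padj < alpha
  ifelse(sig & log2fc > lfc_threshold, "up",
         ifelse(sig & log2fc < -lfc_threshold, "down", "ns"))
}

#' Build the gene-by-condition status grid
#'
#' @param de_tables named list of DE data frames (`gene_id, log2fc, padj`),
#'   one per condition; names are condition labels such as `"A549_UV"`.
#' @param gene_universe optional character vector fixing the row set;
#'   defaults to the union of gene ids. Genes absent from a condition's
#'   table are `ns`.
#' @param lfc_threshold,alpha passed to [classify_deg()].
#' @return character matrix genes x conditions over `{"up","down","ns"}`.
#' @export
build_status_grid <- function(de_tables, gene_universe = NULL,
                              lfc_threshold = 0.7, alpha = 0.05) {
  if (is.null(names(de_tables)) || any(names(de_tables) == "")) {
    stop("de_tables must be a named list of condition tables")
  }
  if (is.null(gene_universe)) {
    gene_universe <- sort(unique(unlist(lapply(de_tables, `[[`, "gene_id"))))
  }
  grid <- matrix("ns", nrow = length(gene_universe), ncol = length(de_tables),
                 dimnames = list(gene_universe, names(de_tables)))
  for (cond in names(de_tables)) {
    d <- de_tables[[cond]]
    st <- classify_deg(d$log2fc, d$padj, lfc_threshold, alpha)
    idx <- match(d$gene_id, gene_universe)
    keep <- !is.na(idx)
    grid[idx[keep], cond] <- st[keep]
  }
  grid
}

#' Three-agent Venn regions of up-regulated genes
#'
#' For one cell type, computes the 7 disjoint Venn regions of the per-agent
#' up-regulated gene sets plus the triple-intersection membership.
#'
#' @param grid status grid from [build_status_grid()].
#' @param conditions the three condition column names (one per agent).
#' @return list with `regions` (named counts: `UV_only`-style exclusive
#'   regions, pairwise-only, and `all3`), `counts` (per-agent set sizes)
#'   and `all3_genes`.
#' @export
condition_overlap <- function(grid, conditions) {
  if (length(conditions) != 3) stop("condition_overlap needs 3 conditions")
  if (!all(conditions %in% colnames(grid))) {
    stop("missing condition(s): ",
         paste(setdiff(conditions, colnames(grid)), collapse = ", "))
  }
  up <- grid[, conditions, drop = FALSE] == "up"
  key <- up[, 1] + 2L * up[, 2] + 4L * up[, 3]
  nm <- conditions
  lab <- c(paste0(nm[1], "_only"), paste0(nm[2], "_only"),
           paste0(nm[1], "&", nm[2]), paste0(nm[3], "_only"),
           paste0(nm[1], "&", nm[3]), paste0(nm[2], "&", nm[3]), "all3")
  regions <- setNames(integer(7), lab)
  tab <- table(factor(key, levels = 1:7))
  regions[] <- as.integer(tab)
  list(regions = regions,
       counts = setNames(colSums(up), nm),
       all3_genes = rownames(grid)[key == 7L])
}

#' Cross-condition consistency sets
#'
#' Genes up-regulated in at least `k_min` of the conditions in the grid;
#' with the full two-cell-type, three-agent design this reproduces the
#' "up in at least five of six conditions" consistently-up-regulated set,
#' and the all-conditions stringent set is reported alongside.
#'
#' @param grid status grid from [build_status_grid()].
#' @param k_min minimum number of conditions with `up` status.
#' @return list with `set` (data frame `gene_id, up_count`, sorted by
#'   decreasing up-count then gene id) and `stringent` (gene ids up in all
#'   conditions).
#' @export
consistency_sets <- function(grid, k_min) {
  m <- ncol(grid)
  if (k_min > m) stop("k_min exceeds the number of conditions (", m, ")")
  if (k_min < 1) stop("k_min must be >= 1")
  up_count <- rowSums(grid == "up")
  keep <- up_count >= k_min
  ids <- rownames(grid)[keep]
  cnt <- up_count[keep]
  o <- order(-cnt, ids)
  list(set = data.frame(gene_id = ids[o], up_count = as.integer(cnt[o]),
                        stringsAsFactors = FALSE),
       stringent = sort(rownames(grid)[up_count == m]))
}

#' Minimal negative-binomial differential-expression test
#'
#' Plumbing for the synthetic end-to-end path (the real study used a full
#' DE framework; this is deliberately minimal). Median-of-ratios size
#' factors; per-gene log2 fold change of normalized group means with a 0.5
#' pseudo-count; Wald test of the log mean ratio with moderated
#' method-of-moments dispersion (gene-wise estimates squeezed toward the
#' across-gene median, floored at 1e-8) against a t reference with
#' `n1 + n2 - 2 + prior_df` degrees of freedom; Benjamini-Hochberg
#' adjustment.
#'
#' @param control,treated integer count matrices (genes x replicates, >= 2
#'   replicates each, shared gene rows).
#' @param prior_df weight (pseudo-degrees-of-freedom) given to the
#'   across-gene median dispersion when moderating the noisy gene-wise
#'   estimates.
#' @return data frame `gene_id, log2fc, padj` plus `base_mean, pvalue`.
#'   Genes with all-zero counts get `log2fc = 0` and missing `padj`.
#' @export
nb_de_test <- function(control, treated, prior_df = 4) {
  if (ncol(control) < 2 || ncol(treated) < 2) {
    stop("nb_de_test needs >= 2 replicates per group")
  }
  if (nrow(control) != nrow(treated)) stop("group matrices differ in genes")
  counts <- cbind(control, treated)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  nc <- ncol(control); nt <- ncol(treated)
  mu_c <- rowMeans(norm[, seq_len(nc), drop = FALSE])
  mu_t <- rowMeans(norm[, nc + seq_len(nt), drop = FALSE])
  log2fc <- log2((mu_t + 0.5) / (mu_c + 0.5))

  v_c <- apply(norm[, seq_len(nc), drop = FALSE], 1, var)
  v_t <- apply(norm[, nc + seq_len(nt), drop = FALSE], 1, var)
  # gene-wise method-of-moments NB dispersion (var = mu + alpha mu^2),
  # moderated toward the across-gene median: with a handful of replicates
  # the raw MOM estimate is far too noisy to test against
  mu_pool <- (nc * mu_c + nt * mu_t) / (nc + nt)
  v_pool <- ((nc - 1) * v_c + (nt - 1) * v_t) / (nc + nt - 2)
  alpha_g <- pmax((v_pool - mu_pool) / mu_pool^2, 1e-8)
  alpha_g[!is.finite(alpha_g)] <- 1e-8
  df_resid <- nc + nt - 2
  alpha_med <- median(alpha_g[mu_pool > 0])
  alpha <- pmax((prior_df * alpha_med + df_resid * alpha_g) /
                  (prior_df + df_resid), 1e-8)

  # delta-method variance of log(mean): (1/mu + alpha) / n per group
  se_ln <- sqrt((1 / pmax(mu_c, 1e-8) + alpha) / nc +
                (1 / pmax(mu_t, 1e-8) + alpha) / nt)
  stat <- (log(mu_t + 0.5) - log(mu_c + 0.5)) / se_ln
  pval <- 2 * pt(-abs(stat), df = df_resid + prior_df)
  allzero <- rowSums(counts) == 0
  log2fc[allzero] <- 0
  pval[allzero] <- NA_real_
  padj <- rep(NA_real_, length(pval))
  ok <- !is.na(pval)
  padj[ok] <- p.adjust(pval[ok], method = "BH")
  data.frame(gene_id = rownames(counts), base_mean = mu_pool,
             log2fc = log2fc, pvalue = pval, padj = padj,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median across genes of the ratio of its
#' count to the gene's geometric mean over samples (genes with any zero
#' count are excluded from the reference, as usual).
#'
#' @param counts genes x samples matrix.
#' @return numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) return(rep(1, ncol(counts)))
  lg <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(lg)
  apply(lg, 2, function(x) exp(median(x - ref)))
}
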