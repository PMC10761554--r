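#' Spearman rank correlation
#'
#' Tie-corrected Spearman correlation (Pearson on midranks) with a p-value
#' from the large-sample t approximation, or exact permutation for small
#' tie-free samples (delegated to [stats::cor.test()]). Used for
#' damage-versus-expression and exon-fraction-versus-expression
#' correlations.
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @return list with `rho` and `p`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("spearman_cor needs equal-length vectors of length >= 3")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("spearman_cor: non-finite values")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop("spearman_cor undefined: zero variance in input")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman",
                    exact = length(x) <= 9)
  )
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Pairwise rank comparisons between groups
#'
#' All pairwise two-sided Mann-Whitney rank-sum tests between groups
#' (exact enumeration when both groups have <= 8 tie-free values, else the
#' normal approximation with tie and continuity correction), with
#' Bonferroni correction over the number of pairs, plus per-group boxplot
#' statistics. This is the group-contrast machinery behind the
#' length/GC-tertile and gene-set comparisons. The published figure
#' legends name the signed-rank test, but the bins compared are
#' independent gene sets for which no pairing exists, so the rank-sum test
#' is the applicable variant; see [signed_rank_vs_zero()] for the paired
#' one-sample mode.
#'
#' @param groups named list of >= 2 non-empty numeric vectors.
#' @return list with `comparisons` (data frame: group1, group2, statistic
#'   (Mann-Whitney U), raw_p, adj_p, n1, n2) and `group_stats` (data
#'   frame: group, n, median, q1, q3).
#' @export
rank_compare <- function(groups) {
  if (length(groups) < 2) stop("rank_compare needs >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("rank_compare: empty group")
  }
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    statistic = NA_real_, raw_p = NA_real_,
                    adj_p = NA_real_,
                    n1 = NA_integer_, n2 = NA_integer_,
                    stringsAsFactors = FALSE)
  for (k in seq_len(m)) {
    a <- groups[[pairs[1, k]]]
    b <- groups[[pairs[2, k]]]
    ties <- anyDuplicated(c(a, b)) > 0
    wt <- suppressWarnings(
      wilcox.test(a, b, exact = (length(a) <= 8 && length(b) <= 8 && !ties),
                  correct = TRUE)
    )
    res$statistic[k] <- unname(wt$statistic)
    res$raw_p[k] <- wt$p.value
    res$n1[k] <- length(a)
    res$n2[k] <- length(b)
  }
  res$adj_p <- bonferroni(res$raw_p)
  gs <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    median = vapply(groups, median, numeric(1)),
    q1 = vapply(groups, function(g) unname(quantile(g, 0.25)), numeric(1)),
    q3 = vapply(groups, function(g) unname(quantile(g, 0.75)), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(comparisons = res, group_stats = gs)
}

#' One-sample Wilcoxon signed-rank test against zero
#'
#' Tests whether a group's values (e.g. log2 fold changes within a tertile)
#' are symmetric about zero.
#'
#' @param values numeric vector.
#' @return list with `statistic` (V), `p`.
#' @export
signed_rank_vs_zero <- function(values) {
  if (length(values) < 1) stop("signed_rank_vs_zero: empty input")
  wt <- suppressWarnings(wilcox.test(values, mu = 0))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, p * m)` with `m = length(pvals)`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @examples
#' bonferroni(c(0.01, 0.02, 0.5)) # 0.03 0.06 1.00
#' @export
bonferroni <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("bonferroni: p-values outside [0, 1]")
  }
  pmin(1, pvals * length(pvals))
}

#' Significance stars
#'
#' Maps adjusted p-values to the star notation used in the figure legends.
#'
#' @param p numeric vector.
#' @return character vector (`"****"` < 1e-4, `"***"` < 1e-3, `"**"` <
#'   0.01, `"*"` < 0.05, else `"ns"`).
#' @export
p_stars <- function(p) {
  cut(p, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 0.05, Inf),
      labels = c("****", "***", "**", "*", "ns"), right = FALSE) |>
    as.character()
}
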