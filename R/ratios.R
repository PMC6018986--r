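#' Replicate-pairwise protein/mRNA log ratios for one condition
#'
#' For every feature present in both layers, forms all protein-replicate x
#' mRNA-replicate pairs (i, j) within a condition and returns the matrix of
#' natural-log ratios `log(protein_i / mrna_j)`. This is the
#' replicate-resolved object the ratio tests operate on.
#'
#' @param protein,mrna copy-number matrices (features x samples).
#' @param design a [sample_design()] covering both matrices' columns.
#' @param condition condition label.
#' @return numeric matrix features x replicate pairs of log ratios. Pairs
#'   touching a missing value are NA; features with fewer than 2 observed
#'   replicates in either layer are dropped entirely ("missing in either
#'   layer, entry absent"). Attributes `n_rep_protein`/`n_rep_mrna` give the
#'   per-feature observed replicate counts.
#' @export
pairwise_log_ratios <- function(protein, mrna, design, condition) {
  pcols <- intersect(cond_cols(design, condition), colnames(protein))
  mcols <- intersect(cond_cols(design, condition), colnames(mrna))
  stop_if(length(pcols) < 2 || length(mcols) < 2,
          "need >= 2 replicates in each layer for condition ", condition)
  common <- intersect(rownames(protein), rownames(mrna))
  p <- log(protein[common, pcols, drop = FALSE])
  m <- log(mrna[common, mcols, drop = FALSE])
  n_p <- rowSums(!is.na(p))
  n_m <- rowSums(!is.na(m))
  keep <- n_p >= 2 & n_m >= 2
  p <- p[keep, , drop = FALSE]
  m <- m[keep, , drop = FALSE]
  grid <- expand.grid(i = seq_along(pcols), j = seq_along(mcols))
  out <- p[, grid$i, drop = FALSE] - m[, grid$j, drop = FALSE]
  colnames(out) <- paste0(pcols[grid$i], "/", mcols[grid$j])
  attr(out, "n_rep_protein") <- n_p[keep]
  attr(out, "n_rep_mrna") <- n_m[keep]
  out
}

#' Protein copies per mRNA molecule
#'
#' Per-feature translation-efficiency summary for one condition: the median
#' over all protein-replicate x mRNA-replicate pairwise ratios
#' `protein_copies_i / mrna_copies_j`.
#'
#' @inheritParams pairwise_log_ratios
#' @return data.frame with columns `feature`, `ratio` (protein copies per
#'   mRNA molecule), `n_pairs`.
#' @examples
#' d <- sample_design(conditions = c("A", "B"), replicates = 3)
#' p <- matrix(100, 1, 6, dimnames = list("g1", d$sample))
#' m <- matrix(10, 1, 6, dimnames = list("g1", d$sample))
#' protein_per_mrna(p, m, d, "A")$ratio   # 10
#' @export
protein_per_mrna <- function(protein, mrna, design, condition) {
  lr <- pairwise_log_ratios(protein, mrna, design, condition)
  data.frame(
    feature = rownames(lr),
    ratio = exp(apply(lr, 1, median, na.rm = TRUE)),
    n_pairs = rowSums(!is.na(lr)),
    stringsAsFactors = FALSE
  )
}

#' Matched-replicate protein/mRNA log ratios for one condition
#'
#' One log-ratio profile per biological replicate,
#' `log(protein_i / mrna_i)` with protein and mRNA replicates matched by
#' replicate number. This is the replicate-resolved object the global
#' translation test correlates: profiles of distinct replicates share no
#' measurements, within or between conditions, so the two correlation groups
#' are exchangeable under the null.
#'
#' @inheritParams pairwise_log_ratios
#' @return numeric matrix features x replicates of log ratios (NA where
#'   either layer is missing).
#' @export
replicate_log_ratios <- function(protein, mrna, design, condition) {
  dd <- design[design$condition == condition, , drop = FALSE]
  stop_if(nrow(dd) < 2, "need >= 2 replicates for condition ", condition)
  stop_if(!all(dd$sample %in% colnames(protein)) ||
            !all(dd$sample %in% colnames(mrna)),
          "both layers must contain every replicate of ", condition)
  common <- intersect(rownames(protein), rownames(mrna))
  out <- log(protein[common, dd$sample, drop = FALSE]) -
    log(mrna[common, dd$sample, drop = FALSE])
  colnames(out) <- dd$sample
  out
}

#' Global translation-efficiency difference between two conditions
#'
#' Tests whether between-condition replicates are less correlated than
#' within-condition replicates in their protein-per-mRNA log-ratio profiles.
#' All within-condition and between-condition column pairs of the two
#' matched-replicate ratio matrices are correlated (Pearson, on features
#' present in both), correlations are Fisher z-transformed
#' (`z = atanh(r)`), and a two-sided two-sample t-test compares the
#' within-group and between-group z values.
#'
#' @param ratios_a,ratios_b matched-replicate log-ratio matrices from
#'   [replicate_log_ratios()] for the two conditions (features in rows).
#' @return list: `p_value`, `t_statistic`, `z_within`, `z_between`.
#' @export
global_translation_test <- function(ratios_a, ratios_b) {
  common <- intersect(rownames(ratios_a), rownames(ratios_b))
  stop_if(length(common) < 3, "need >= 3 shared features")
  a <- ratios_a[common, , drop = FALSE]
  b <- ratios_b[common, , drop = FALSE]
  fisher_z <- function(r) {
    cap <- 1 - 1e-12
    if (any(abs(r) >= 1)) {
      warning("|r| = 1 encountered; Fisher z clipped")
      r <- pmin(pmax(r, -cap), cap)
    }
    atanh(r)
  }
  within_z <- fisher_z(c(
    cor(a, use = "pairwise.complete.obs")[upper.tri(diag(ncol(a)))],
    cor(b, use = "pairwise.complete.obs")[upper.tri(diag(ncol(b)))]
  ))
  between_z <- fisher_z(as.vector(cor(a, b,
                                      use = "pairwise.complete.obs")))
  stop_if(length(within_z) < 2 || length(between_z) < 2,
          "need >= 2 correlations in each group")
  tt <- t.test(within_z, between_z)
  list(p_value = tt$p.value, t_statistic = unname(tt$statistic),
       z_within = within_z, z_between = between_z)
}

#' Per-feature test for protein/mRNA ratio changes between conditions
#'
#' Welch-form t-statistic on the replicate-pairwise log ratios of two
#' conditions, with the test manually restricted to the degrees of freedom
#' the biological replicates actually supply. The n_P x n_M pairwise log
#' ratios of a condition decompose as `p_i - m_j`, so (i) their sample
#' variance is a *biased* estimate of `sigma_p^2 + sigma_m^2`
#' (`E[s2_pairs] = [n_M(n_P-1) sigma_p^2 + n_P(n_M-1) sigma_m^2] /
#' (n_P n_M - 1)`, which is 3/4 of the target for 3 x 3) and is rescaled
#' accordingly; (ii) the variance of the group mean is
#' `sigma_p^2/n_P + sigma_m^2/n_M`, not the pairwise-count 1/(n_P n_M); and
#' (iii) the reference distribution uses
#' `df = (n_P^A - 1) + (n_M^A - 1) + (n_P^B - 1) + (n_M^B - 1)` — the count
#' of independent biological observations minus estimated means (8 for a
#' full 3 vs 3 design), never the 9 + 9 pair count. Null simulations show
#' this combination holds the 5% level. Features with zero within-group
#' variance in both groups are skipped.
#'
#' @param ratios_a,ratios_b matrices from [pairwise_log_ratios()].
#' @param df_override optional integer overriding the restricted df.
#' @return data.frame: `feature`, `log2_ratio_fc` (condition A over B),
#'   `statistic`, `df`, `p_value`, `fdr` (Benjamini-Hochberg across
#'   features).
#' @export
ratio_change_test <- function(ratios_a, ratios_b, df_override = NULL) {
  rep_attr <- function(x, which, rows) {
    v <- attr(x, which)
    stop_if(is.null(v), "ratio matrices must come from pairwise_log_ratios()")
    v[match(rows, rownames(x))]
  }
  common <- intersect(rownames(ratios_a), rownames(ratios_b))
  a <- ratios_a[common, , drop = FALSE]
  b <- ratios_b[common, , drop = FALSE]
  npA <- rep_attr(ratios_a, "n_rep_protein", common)
  nmA <- rep_attr(ratios_a, "n_rep_mrna", common)
  npB <- rep_attr(ratios_b, "n_rep_protein", common)
  nmB <- rep_attr(ratios_b, "n_rep_mrna", common)
  df <- if (!is.null(df_override)) rep(df_override, length(common)) else {
    (npA - 1) + (nmA - 1) + (npB - 1) + (nmB - 1)
  }
  mA <- rowMeans(a, na.rm = TRUE); mB <- rowMeans(b, na.rm = TRUE)
  # debias the pairwise variance towards sigma_p^2 + sigma_m^2, then scale
  # to the variance of the group mean (sigma_p^2/n_P + sigma_m^2/n_M)
  unbias <- function(np, nm) 2 * (np * nm - 1) / (nm * (np - 1) + np * (nm - 1))
  hmean <- function(np, nm) (1 / np + 1 / nm) / 2
  vA <- apply(a, 1, var, na.rm = TRUE) * unbias(npA, nmA) * hmean(npA, nmA)
  vB <- apply(b, 1, var, na.rm = TRUE) * unbias(npB, nmB) * hmean(npB, nmB)
  se <- sqrt(vA + vB)
  stat <- (mA - mB) / se
  skip <- is.na(se) | se == 0
  if (any(skip)) {
    message(sum(skip), " feature(s) with zero variance in both groups ",
            "skipped")
    stat[skip] <- NA
  }
  p <- 2 * pt(-abs(stat), df)
  data.frame(
    feature = common,
    log2_ratio_fc = (mA - mB) / log(2),
    statistic = stat,
    df = df,
    p_value = p,
    fdr = p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Flag features with consistent ratio changes against a reference condition
#'
#' A feature is flagged when, in *both* comparisons against the reference
#' (e.g. CV vs EN and ENR vs EN), its ratio change passes `fdr < fdr_cutoff`
#' and `|fold change| > fc_cutoff` with the same direction.
#'
#' @param test_a,test_b results of [ratio_change_test()] for the two
#'   comparisons (both versus the same reference condition).
#' @param fdr_cutoff FDR threshold (strict `<`).
#' @param fc_cutoff fold-change threshold on the condition-level ratio fold
#'   change (strict `>`, applied to the absolute fold change).
#' @return character vector of flagged feature ids.
#' @export
ratio_significance_filter <- function(test_a, test_b, fdr_cutoff = 0.05,
                                      fc_cutoff = 3) {
  common <- intersect(test_a$feature, test_b$feature)
  a <- test_a[match(common, test_a$feature), ]
  b <- test_b[match(common, test_b$feature), ]
  lfc_cut <- log2(fc_cutoff)
  hit <- !is.na(a$fdr) & !is.na(b$fdr) &
    a$fdr < fdr_cutoff & b$fdr < fdr_cutoff &
    abs(a$log2_ratio_fc) > lfc_cut & abs(b$log2_ratio_fc) > lfc_cut &
    sign(a$log2_ratio_fc) == sign(b$log2_ratio_fc)
  common[hit]
}
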