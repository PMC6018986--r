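#' Simulate spike-in anchored proteome and transcriptome measurements
#'
#' Generates a complete expression layer for a multi-condition study with
#' known ground truth. True mRNA copy numbers per cell are drawn log-normally;
#' each gene gets a log-normal protein-per-mRNA ratio, so true protein copies
#' are `ratio * mRNA copies`. A fraction of genes is differential across
#' conditions (log-normal fold changes on the mRNA layer, propagated to
#' protein), and a designated subset of "ratio-shift" genes has its protein
#' copies multiplied by `ratio_shift_fold` in the last condition only, leaving
#' mRNA untouched — a planted translation-efficiency change.
#'
#' Measurement model: protein intensity is `gain_s * copies * exp(eps)` with
#' multiplicative log-normal noise (`sd(log) = sqrt(log(1 + noise_cv^2))`);
#' the per-sample gain `gain_s` is shared by spike-ins and endogenous
#' proteins, so spike-in calibration can remove it. mRNA counts are negative
#' binomial around `depth_s * count_per_copy * copies`, with ERCC-style
#' spike-ins obeying the same linear count model. Low intensities are censored
#' to missing with a logistic detection-limit model (probability 0.9 well
#' below the limit, 0.05 well above). `noise_cv = 0` switches every source of
#' noise off, giving exact identities for testing.
#'
#' Two proteome matrices are produced: an `unfractionated` run that carries
#' the spike-in panel, and a deeper `fractionated` run (higher gain, lower
#' detection limit) quantified against the first via two-stage regression.
#'
#' @param design a [sample_design()] data.frame.
#' @param n_features number of endogenous genes (>= 100).
#' @param spike_panel protein spike-in [spikein_panel()]; the default spans
#'   4.5 orders of magnitude placed to overlap the endogenous copy-number
#'   range, so part of the panel is subject to detection-limit censoring as
#'   with a real UPS2 standard.
#' @param ercc_panel RNA spike-in panel (defaults to a 92-species ERCC-like
#'   panel spanning 5.5 orders of magnitude down to sub-count inputs).
#' @param noise_cv coefficient of variation of multiplicative measurement
#'   noise (0 disables all noise).
#' @param missing_rate detection-limit quantile: roughly the fraction of
#'   protein intensities subject to censoring (0 disables missingness;
#'   must be < 0.5).
#' @param gain intensity units per molecule in the unfractionated run.
#' @param frac_diff fraction of genes differential between conditions.
#' @param diff_log2_sd sd of per-condition log2 fold changes for differential
#'   genes.
#' @param frac_ratio_shift fraction of genes with a planted protein/mRNA
#'   ratio shift.
#' @param ratio_shift_fold multiplicative protein-copy shift in the last
#'   condition for ratio-shift genes.
#' @param count_per_copy expected read count per mRNA molecule.
#' @param nb_dispersion negative binomial dispersion of counts.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with elements `protein_unfrac`, `protein_frac` (intensity
#'   matrices, NA = missing), `counts` (mRNA count matrix incl. ERCC rows),
#'   `design`, `spike_panel`, `ercc_panel`, and `truth` — a list with
#'   `true_protein_copies`, `true_mrna_copies` (feature x condition),
#'   `ratio_shift_genes`, `ratio_shift_fold`, `diff_genes`.
#' @examples
#' sim <- simulate_expression(sample_design(), n_features = 200, seed = 1)
#' dim(sim$protein_unfrac)
#' @export
simulate_expression <- function(design = sample_design(),
                                n_features = 2000,
                                spike_panel = spikein_panel(
                                  log10_range = c(2, 6.5)),
                                ercc_panel = spikein_panel(
                                  n = 92, n_levels = 23,
                                  log10_range = c(-2, 3.5), prefix = "ERCC"),
                                noise_cv = 0.2,
                                missing_rate = 0.1,
                                gain = 100,
                                frac_diff = 0.3,
                                diff_log2_sd = 1.5,
                                frac_ratio_shift = 0.075,
                                ratio_shift_fold = 8,
                                count_per_copy = 10,
                                nb_dispersion = 0.02,
                                seed = NULL) {
  stop_if(n_features < 100, "n_features must be >= 100")
  stop_if(missing_rate < 0 || missing_rate >= 0.5,
          "missing_rate must be in [0, 0.5)")
  stop_if(noise_cv < 0, "noise_cv must be >= 0")
  conds <- unique(design$condition)
  n_samp <- nrow(design)
  genes <- sprintf("gene%05d", seq_len(n_features))

  with_seed(seed, {
    ## --- ground truth ------------------------------------------------------
    mrna_base <- 10^rnorm(n_features, mean = 1.3, sd = 0.8)     # copies/cell
    ratio <- 10^rnorm(n_features, mean = 3, sd = 0.5)           # protein/mRNA
    diff_genes <- sort(sample(genes, round(frac_diff * n_features)))
    log2fc <- matrix(0, n_features, length(conds),
                     dimnames = list(genes, conds))
    idx_diff <- match(diff_genes, genes)
    for (j in seq_along(conds)[-1]) {
      log2fc[idx_diff, j] <- rnorm(length(idx_diff), 0, diff_log2_sd)
    }
    true_mrna <- mrna_base * 2^log2fc
    true_prot <- true_mrna * ratio
    n_shift <- round(frac_ratio_shift * n_features)
    ratio_shift_genes <- sort(sample(setdiff(genes, diff_genes), n_shift))
    true_prot[match(ratio_shift_genes, genes), length(conds)] <-
      true_prot[match(ratio_shift_genes, genes), length(conds)] *
      ratio_shift_fold

    sigma <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    lnoise <- function(n) if (sigma > 0) exp(rnorm(n, 0, sigma)) else rep(1, n)
    gain_jitter <- function() {
      if (sigma > 0) exp(rnorm(n_samp, 0, noise_cv / 4)) else rep(1, n_samp)
    }

    ## --- proteome runs -----------------------------------------------------
    make_protein <- function(run_gain, censor_q) {
      gain_s <- run_gain * gain_jitter()
      copies <- rbind(true_prot[, match(design$condition, conds), drop = FALSE],
                      matrix(spike_panel$amount, nrow(spike_panel), n_samp))
      rownames(copies) <- c(genes, spike_panel$id)
      m <- sweep(copies, 2, gain_s, `*`) * lnoise(length(copies))
      colnames(m) <- design$sample
      if (missing_rate > 0) {
        lg <- log10(m)
        thr <- quantile(lg, missing_rate)
        p_miss <- 0.05 + 0.85 * stats::plogis(-(lg - thr) / 0.3)
        m[runif(length(m)) < p_miss] <- NA
      }
      m
    }
    protein_unfrac <- make_protein(gain, missing_rate)
    protein_frac <- make_protein(gain * 5, missing_rate / 2)

    ## --- transcriptome -----------------------------------------------------
    depth_s <- if (sigma > 0) exp(rnorm(n_samp, 0, 0.15)) else rep(1, n_samp)
    mu <- rbind(true_mrna[, match(design$condition, conds), drop = FALSE],
                matrix(ercc_panel$amount, nrow(ercc_panel), n_samp))
    rownames(mu) <- c(genes, ercc_panel$id)
    mu <- sweep(mu * count_per_copy, 2, depth_s, `*`)
    counts <- if (sigma > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
             nrow(mu), ncol(mu), dimnames = dimnames(mu))
    } else mu
    colnames(counts) <- design$sample

    list(
      protein_unfrac = protein_unfrac,
      protein_frac = protein_frac,
      counts = counts,
      design = design,
      spike_panel = spike_panel,
      ercc_panel = ercc_panel,
      truth = list(
        true_protein_copies = true_prot,
        true_mrna_copies = true_mrna,
        ratio_shift_genes = ratio_shift_genes,
        ratio_shift_fold = ratio_shift_fold,
        diff_genes = diff_genes
      )
    )
  })
}
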