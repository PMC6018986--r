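#' Simulate a complete synthetic multi-omics study
#'
#' Bundles [simulate_expression()] and [simulate_regulatory_landscape()]
#' under one seed: a proteome/transcriptome layer with spike-ins and planted
#' ratio shifts, and a chromatin layer with a planted driver motif,
#' coordinated TADs and a TF protein table.
#'
#' @param design a [sample_design()].
#' @param expression_args,landscape_args named lists of overrides passed on
#'   to the two generators.
#' @param seed integer seed (children are derived per layer).
#' @return list with `expression`, `landscape`, `design`, `seed`.
#' @export
simulate_study <- function(design = sample_design(),
                           expression_args = list(),
                           landscape_args = list(),
                           seed = NULL) {
  expr <- do.call(simulate_expression,
                  c(list(design = design, seed = child_seed(seed, 1)),
                    expression_args))
  land <- do.call(simulate_regulatory_landscape,
                  c(list(design = design, seed = child_seed(seed, 2)),
                    landscape_args))
  list(expression = expr, landscape = land, design = design, seed = seed)
}

#' Write a simulated study to disk
#'
#' Emits the study as plain interoperable files: FASTA genome, BED3+name
#' peaks and TADs, BED6 TSS, TSV matrices and spike tables, a JASPAR motif
#' file, a TSV motif-to-TF map and a JSON ground-truth sidecar.
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(...) file.path(dir, ...)
  ex <- study$expression; la <- study$landscape
  write_matrix_tsv(ex$protein_unfrac, fp("protein_unfractionated.tsv"))
  write_matrix_tsv(ex$protein_frac, fp("protein_fractionated.tsv"))
  write_matrix_tsv(ex$counts, fp("mrna_counts.tsv"))
  write_spike_table(ex$spike_panel, fp("spike_protein.tsv"))
  write_spike_table(ex$ercc_panel, fp("spike_rna.tsv"))
  write.table(study$design, fp("design.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_genome_fasta(la$genome, fp("genome.fa"))
  write_bed(la$peaks, fp("peaks.bed"))
  write_bed(la$tads, fp("tads.bed"))
  tssbed <- data.frame(chrom = la$tss$chrom, start = la$tss$pos,
                       end = la$tss$pos + 1, name = la$tss$gene,
                       score = 0, strand = la$tss$strand)
  write_bed(tssbed, fp("tss.bed"))
  write_matrix_tsv(la$peak_counts, fp("peak_counts.tsv"))
  write_matrix_tsv(la$tf_protein, fp("tf_protein.tsv"))
  write_jaspar(la$motifs, fp("motifs.jaspar"))
  write.table(la$motif_tf_map, fp("motif_tf_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  # gene sets for enrichment runs: the truly most-upregulated genes (last vs
  # second-last condition, mRNA truth) plus size-matched random decoy sets
  conds <- colnames(ex$truth$true_mrna_copies)
  lfc <- log2(ex$truth$true_mrna_copies[, conds[length(conds)]] /
                ex$truth$true_mrna_copies[, conds[length(conds) - 1]])
  n_set <- min(100L, floor(length(lfc) / 4))
  sets <- with_seed(child_seed(study$seed, 9), {
    s <- list(true_up = names(sort(lfc, decreasing = TRUE))[seq_len(n_set)])
    for (k in 1:3) s[[paste0("decoy", k)]] <- sample(names(lfc), n_set)
    s
  })
  write_gmt(sets, fp("gene_sets.gmt"))
  truth <- c(la$truth[c("driver_motif_id", "driver_tf", "driver_peaks",
                        "coordinated_tads", "differential_tfs", "up_genes",
                        "promoter_planted_genes")],
             list(ratio_shift_genes = ex$truth$ratio_shift_genes,
                  ratio_shift_fold = ex$truth$ratio_shift_fold))
  jsonlite::write_json(truth, fp("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Motif-driver selection from differential chromatin signal
#'
#' The full inference chain on a chromatin layer: differential TF protein
#' expression (permutation-FDR t-test, EN-like vs reference contrast) filters
#' the motif database to dynamically expressed TFs; peak counts are
#' normalized and turned into noise-stabilized log2 fold changes; motif
#' best-match scores are computed under the significantly changing peaks;
#' LASSO pre-selection plus iterative random-forest residual-variance
#' selection, stability-filtered over independently seeded repeats, yields
#' the driver motifs; each is labelled with its most significant TF and its
#' score/fold-change correlation.
#'
#' @param peaks interval data.frame with `name`.
#' @param peak_counts peak count matrix.
#' @param genome named character vector of chromosome sequences.
#' @param motifs named list of `pwm` objects.
#' @param motif_tf_map data.frame `motif`, `tf`.
#' @param tf_protein TF protein intensity matrix (linear scale).
#' @param design a [sample_design()].
#' @param contrast length-2 conditions (A, B); fold changes are A over B and
#'   the default contrasts the last condition against the one before it.
#' @param tf_fdr_cutoff motif filter on TF differential FDR (default 0.01).
#' @param peak_q_cutoff significance cutoff defining the regression peaks.
#' @param repeats,n_trees,nfolds selection parameters (see
#'   [stability_select()]).
#' @param prior_count,s0,n_perm differential parameters.
#' @param seed integer seed.
#' @return list of class `driver_selection`: `selection` (a
#'   [stability_select()] table plus `tf` and `cor_fc` columns), `candidates`
#'   (motifs surviving the TF filter), `fold_changes` (the
#'   [count_fold_changes()] table), `tf_diff`, `scores` (normalized score
#'   matrix under significant peaks), `contrast`.
#' @export
select_driver_motifs <- function(peaks, peak_counts, genome, motifs,
                                 motif_tf_map, tf_protein, design,
                                 contrast = NULL,
                                 tf_fdr_cutoff = 0.01,
                                 peak_q_cutoff = 0.05,
                                 repeats = 5, n_trees = 5000, nfolds = 10,
                                 prior_count = 4, s0 = 0.1, n_perm = 1000,
                                 seed = NULL) {
  conds <- unique(design$condition)
  if (is.null(contrast)) {
    contrast <- c(conds[length(conds)], conds[length(conds) - 1])
  }
  tf_diff <- permutation_fdr_ttest(
    log2(tf_protein), cond_cols(design, contrast[1]),
    cond_cols(design, contrast[2]), s0 = s0, n_perm = n_perm,
    seed = child_seed(seed, 11))
  candidates <- filter_motifs_by_tf_dynamics(motif_tf_map, tf_diff,
                                             fdr_cutoff = tf_fdr_cutoff)
  stop_if(length(candidates) < 2,
          "fewer than 2 motifs pass the TF expression filter")
  fc <- count_fold_changes(peak_counts, design, contrast,
                           prior_count = prior_count, s0 = s0,
                           n_perm = n_perm, seed = child_seed(seed, 12))
  sig <- !is.na(fc$q) & fc$q < peak_q_cutoff
  stop_if(sum(sig) < nfolds * 3,
          "too few significant peaks (", sum(sig), ") for selection")
  sig_peaks <- peaks[match(fc$feature[sig], peaks$name), ]
  seqs <- interval_sequences(genome, sig_peaks)
  scores <- motif_score_matrix(seqs, motifs[candidates])
  response <- fc$log2fc[sig]
  sel <- stability_select(scores, response, repeats = repeats,
                          n_trees = n_trees, nfolds = nfolds,
                          seed = child_seed(seed, 13))
  if (nrow(sel) > 0) {
    sel$tf <- vapply(sel$motif, label_tf, "", motif_tf_map, tf_diff)
    sel$cor_fc <- vapply(sel$motif, function(m) {
      motif_fc_correlation(scores[, m], response)
    }, numeric(1))
  }
  structure(
    list(selection = sel, candidates = candidates, fold_changes = fc,
         tf_diff = tf_diff, scores = scores, contrast = contrast),
    class = "driver_selection"
  )
}

#' @export
print.driver_selection <- function(x, ...) {
  cat("driver motif selection (", x$contrast[1], " vs ", x$contrast[2],
      "): ", length(x$candidates), " candidate motifs, ",
      sum(!is.na(x$fold_changes$q) & x$fold_changes$q < 0.05),
      " significant peaks\n", sep = "")
  print(x$selection)
  invisible(x)
}
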