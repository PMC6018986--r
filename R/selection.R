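#' Keep motifs linked to dynamically expressed transcription factors
#'
#' A motif survives when at least one of its linked TFs changes protein
#' expression at `q < fdr_cutoff` (strict). Motifs with no linked TF in the
#' expression results are dropped with a message.
#'
#' @param motif_tf_map data.frame with columns `motif`, `tf`.
#' @param protein_diff a [permutation_fdr_ttest()] result on TF protein
#'   expression (columns `feature`, `q`).
#' @param fdr_cutoff default 0.01.
#' @return character vector of retained motif ids.
#' @export
filter_motifs_by_tf_dynamics <- function(motif_tf_map, protein_diff,
                                         fdr_cutoff = 0.01) {
  q <- setNames(protein_diff$q, protein_diff$feature)
  map <- motif_tf_map
  map$q <- q[map$tf]
  unlinked <- setdiff(map$motif[is.na(map$q)],
                      map$motif[!is.na(map$q)])
  if (length(unlinked)) {
    message(length(unlinked),
            " motif(s) without a scored TF link dropped")
  }
  keep <- tapply(map$q, map$motif, function(v) any(!is.na(v) & v < fdr_cutoff))
  sort(names(keep)[keep])
}

#' LASSO pre-selection of motifs
#'
#' Ten-fold cross-validated L1-penalized linear regression of the fold-change
#' response on the motif score matrix (glmnet, predictors standardized
#' internally). Motifs with a nonzero coefficient at the minimum-CV-error
#' penalty are retained.
#'
#' @param scores peaks x motifs score matrix.
#' @param response numeric log2 fold-change vector, one per peak row.
#' @param nfolds CV folds (default 10).
#' @param seed integer seed (fold assignment).
#' @return character vector of selected motif ids (empty for a degenerate
#'   constant response).
#' @export
lasso_preselect <- function(scores, response, nfolds = 10, seed = NULL) {
  stop_if(nrow(scores) != length(response),
          "response length must match score rows")
  stop_if(nrow(scores) < nfolds * 3, "need >= 3 peaks per CV fold")
  if (sd(response) == 0) return(character())
  fit <- with_seed(seed, {
    glmnet::cv.glmnet(scores, response, nfolds = nfolds,
                      standardize = TRUE)
  })
  cf <- coef(fit, s = "lambda.min")[-1, 1]   # drop intercept
  colnames(scores)[cf != 0]
}

#' Iterative random-forest selection of driver motifs
#'
#' One repeat of the greedy residual-variance loop:
#' \enumerate{
#'   \item fit a random-forest regression of the current residual on all
#'     remaining motif scores (out-of-bag permutation importance);
#'   \item take the motif with the largest importance (percent increase in
#'     out-of-bag MSE);
#'   \item fit a single-predictor forest of the residual on that motif alone;
#'     if its out-of-bag R-squared is not positive the motif explains no
#'     residual variance on its own and the loop stops *without* selecting
#'     it;
#'   \item otherwise record the motif, subtract the single-predictor model's
#'     out-of-bag predictions from the residual, remove the motif, and
#'     repeat while at least two candidates remain.
#' }
#'
#' @param scores peaks x motifs score matrix (>= 1 motif; a singleton
#'   candidate set skips straight to the single-predictor evaluation).
#' @param response numeric fold-change vector.
#' @param n_trees trees per forest (default 5000; smaller forests are
#'   appropriate for repeated simulation studies).
#' @param seed integer seed.
#' @return data.frame with one row per selected motif, in selection order:
#'   `motif`, `pct_inc_mse` (importance at selection, percent of the OOB MSE),
#'   `sd_pct_inc_mse` (standard error of that importance across trees, same
#'   scale), `single_r2` (OOB R-squared of the single-motif model).
#' @export
iterative_rf_select <- function(scores, response, n_trees = 5000,
                                seed = NULL) {
  stop_if(ncol(scores) < 1, "need >= 1 candidate motif")
  stop_if(nrow(scores) != length(response), "response/score size mismatch")
  with_seed(seed, {
    remaining <- colnames(scores)
    residual <- response
    sel <- list()
    while (length(remaining) >= 1) {
      rf <- randomForest::randomForest(
        scores[, remaining, drop = FALSE], residual,
        ntree = n_trees, importance = TRUE)
      oob_mse <- unname(rf$mse[n_trees])
      imp_mat <- randomForest::importance(rf, type = 1, scale = FALSE)
      imp_raw <- setNames(imp_mat[, 1], rownames(imp_mat))
      best <- remaining[which.max(imp_raw)]
      # a 1-predictor forest with tiny leaves just memorizes noise, which
      # biases its out-of-bag R^2 towards 0; coarse leaves give an honest
      # estimate of the variance this single motif can explain
      single <- randomForest::randomForest(
        scores[, best, drop = FALSE], residual, ntree = n_trees,
        nodesize = max(5L, round(length(residual) / 20)))
      r2 <- unname(single$rsq[n_trees])
      if (!is.finite(r2) || r2 <= 0) break
      sel[[best]] <- data.frame(
        motif = best,
        pct_inc_mse = 100 * unname(imp_raw[best]) / oob_mse,
        sd_pct_inc_mse = 100 * unname(rf$importanceSD[best]) / oob_mse,
        single_r2 = r2,
        stringsAsFactors = FALSE
      )
      residual <- residual - single$predicted   # out-of-bag predictions
      remaining <- setdiff(remaining, best)
    }
    out <- if (length(sel)) do.call(rbind, sel) else
      data.frame(motif = character(), pct_inc_mse = numeric(),
                 sd_pct_inc_mse = numeric(), single_r2 = numeric(),
                 stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}

#' Stability selection of driver motifs
#'
#' Runs [lasso_preselect()] followed by [iterative_rf_select()] `repeats`
#' times with distinct seeds (re-randomizing both the CV folds and the
#' forests) and keeps only motifs selected in every repeat. All
#' ever-selected motifs are reported with their stability counts.
#'
#' @param scores peaks x motifs *normalized* score matrix (see
#'   [motif_score_matrix()]).
#' @param response numeric fold-change vector.
#' @param repeats number of independently seeded repeats (>= 2 for a real
#'   stability filter; 1 returns that single run).
#' @param n_trees trees per forest.
#' @param nfolds LASSO CV folds.
#' @param seed integer base seed; repeat k uses a seed derived from it.
#' @return data.frame of class `selection_result`, one row per ever-selected
#'   motif ordered by stability then importance: `motif`, `stability` (count
#'   of repeats), `selected` (TRUE iff stability == repeats), `pct_inc_mse`,
#'   `sd_pct_inc_mse`, `single_r2` (averaged over the repeats that selected
#'   the motif), `first_rank` (selection position in the first selecting
#'   repeat); attribute `repeats`.
#' @export
stability_select <- function(scores, response, repeats = 5, n_trees = 5000,
                             nfolds = 10, seed = NULL) {
  stop_if(repeats < 1, "repeats must be >= 1")
  runs <- lapply(seq_len(repeats), function(k) {
    sk <- child_seed(seed, k)
    pre <- lasso_preselect(scores, response, nfolds = nfolds, seed = sk)
    if (length(pre) < 1) {
      return(data.frame(motif = character(), pct_inc_mse = numeric(),
                        sd_pct_inc_mse = numeric(), single_r2 = numeric(),
                        stringsAsFactors = FALSE))
    }
    iterative_rf_select(scores[, pre, drop = FALSE], response,
                        n_trees = n_trees, seed = sk)
  })
  all_sel <- unique(unlist(lapply(runs, `[[`, "motif")))
  if (length(all_sel) == 0) {
    out <- data.frame(motif = character(), stability = integer(),
                      selected = logical(), pct_inc_mse = numeric(),
                      sd_pct_inc_mse = numeric(), single_r2 = numeric(),
                      first_rank = integer(), stringsAsFactors = FALSE)
    return(structure(out, repeats = repeats,
                     class = c("selection_result", "data.frame")))
  }
  per_motif <- lapply(all_sel, function(m) {
    hits <- lapply(runs, function(r) r[r$motif == m, , drop = FALSE])
    nhit <- sum(vapply(hits, nrow, 0L) > 0)
    hit_rows <- do.call(rbind, hits)
    first <- which(vapply(hits, nrow, 0L) > 0)[1]
    data.frame(
      motif = m,
      stability = nhit,
      selected = nhit == repeats,
      pct_inc_mse = mean(hit_rows$pct_inc_mse),
      sd_pct_inc_mse = mean(hit_rows$sd_pct_inc_mse),
      single_r2 = mean(hit_rows$single_r2),
      first_rank = match(m, runs[[first]]$motif),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, per_motif)
  out <- out[order(-out$stability, -out$pct_inc_mse), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, repeats = repeats,
            class = c("selection_result", "data.frame"))
}

#' @export
print.selection_result <- function(x, ...) {
  cat("stability selection over", attr(x, "repeats"), "repeats:",
      sum(x$selected), "stable motif(s) of", nrow(x), "ever selected\n")
  print.data.frame(x)
  invisible(x)
}

#' Correlation of a motif's best score with the fold-change response
#'
#' @param score numeric vector of per-peak motif scores.
#' @param response numeric log2 fold-change vector.
#' @return Pearson r, or NA (with a message) for a constant score column.
#' @export
motif_fc_correlation <- function(score, response) {
  ok <- is.finite(score) & is.finite(response)
  if (sum(ok) < 3 || sd(score[ok]) == 0 || sd(response[ok]) == 0) {
    message("correlation undefined (constant or too-short input)")
    return(NA_real_)
  }
  cor(score[ok], response[ok])
}

#' Label a motif with its most significant transcription factor
#'
#' Among the motif's linked TFs, picks the one with the smallest differential
#' protein q-value; ties go to the larger absolute log2 fold change, then to
#' the lexicographically smaller TF id.
#'
#' @param motif motif id.
#' @param motif_tf_map data.frame with columns `motif`, `tf`.
#' @param protein_diff a [permutation_fdr_ttest()] result with columns
#'   `feature`, `q`, `log2fc`.
#' @return TF id, or NA when no link has a scored q-value.
#' @export
label_tf <- function(motif, motif_tf_map, protein_diff) {
  tfs <- motif_tf_map$tf[motif_tf_map$motif == motif]
  i <- match(tfs, protein_diff$feature)
  ok <- !is.na(i)
  if (!any(ok)) return(NA_character_)
  tfs <- tfs[ok]; i <- i[ok]
  o <- order(protein_diff$q[i], -abs(protein_diff$log2fc[i]), tfs)
  tfs[o[1]]
}
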