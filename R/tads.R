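#' TAD-level percentage agreement of fold-change direction
#'
#' Assigns each peak to the TAD containing its midpoint, keeps TADs with at
#' least `min_peaks` assigned peaks, and computes per TAD the percentage of
#' member peaks whose log2 fold-change sign matches the sign of the TAD's
#' mean fold change. Zero fold changes count as disagreeing (conservative);
#' TADs whose mean fold change is exactly 0 are skipped with a message.
#'
#' Because the reference sign is estimated from the same member peaks, the
#' expected agreement of a fully random TAD exceeds 50% at small peak counts;
#' the shuffle null of [tad_empirical_fdr()] reproduces exactly this bias, so
#' the empirical FDR stays calibrated.
#'
#' @param peaks interval data.frame with a `name` column.
#' @param fc named numeric vector of log2 fold changes, names matching
#'   `peaks$name`.
#' @param tads interval data.frame of non-overlapping TADs with `name`.
#' @param min_peaks minimum member peaks (default 20).
#' @return data.frame of class `tad_agreement`: `tad`, `n_peaks`,
#'   `mean_log2fc`, `agreement` (percent in [0, 100]), `direction`
#'   ("activated"/"repressed"); attribute `assignment` maps peak name to TAD.
#' @export
tad_agreement <- function(peaks, fc, tads, min_peaks = 20) {
  assign <- assign_peaks_to_tads(peaks, tads)
  fc <- fc[assign$peak]
  stop_if(anyNA(fc), "every assigned peak needs a fold change")
  tab <- compute_agreements(fc, assign$tad, min_peaks)
  structure(tab, assignment = assign,
            class = c("tad_agreement", class(tab)))
}

assign_peaks_to_tads <- function(peaks, tads) {
  validate_intervals(peaks)
  validate_intervals(tads)
  mid <- floor((peaks$start + peaks$end) / 2)
  mid_gr <- GenomicRanges::GRanges(peaks$chrom,
                                   IRanges::IRanges(mid + 1, mid + 1))
  tad_gr <- intervals_to_gr(tads)
  ov <- GenomicRanges::findOverlaps(mid_gr, tad_gr)
  stop_if(anyDuplicated(S4Vectors::queryHits(ov)) > 0,
          "TADs overlap: a peak midpoint fell into more than one TAD")
  data.frame(
    peak = peaks$name[S4Vectors::queryHits(ov)],
    tad = tads$name[S4Vectors::subjectHits(ov)],
    chrom = peaks$chrom[S4Vectors::queryHits(ov)],
    stringsAsFactors = FALSE
  )
}

# Vectorized per-TAD agreement over a peak->TAD assignment.
compute_agreements <- function(fc, tad_of_peak, min_peaks) {
  f <- factor(tad_of_peak)
  n <- as.vector(table(f))
  keep_tads <- levels(f)[n >= min_peaks]
  idx <- tad_of_peak %in% keep_tads
  f2 <- factor(tad_of_peak[idx], levels = keep_tads)
  v <- fc[idx]
  mean_fc <- as.vector(rowsum(v, f2) / as.vector(table(f2)))
  agree_n <- as.vector(rowsum(
    as.numeric(sign(v) == sign(mean_fc)[as.integer(f2)]), f2))
  n2 <- as.vector(table(f2))
  out <- data.frame(
    tad = keep_tads,
    n_peaks = n2,
    mean_log2fc = mean_fc,
    agreement = 100 * agree_n / n2,
    direction = ifelse(mean_fc > 0, "activated",
                       ifelse(mean_fc < 0, "repressed", NA)),
    stringsAsFactors = FALSE
  )
  zero <- mean_fc == 0
  if (any(zero)) {
    message(sum(zero), " TAD(s) with mean fold change exactly 0 skipped")
    out <- out[!zero, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Empirical FDR for TAD agreement via fold-change shuffling
#'
#' Builds a null by permuting the fold-change values across all assigned
#' peaks genome-wide (`n_shuffles` times; TAD membership fixed) and
#' recomputing agreements. For an agreement threshold t,
#' `FDR(t) = mean_shuffles #\{null TADs with agreement >= t\} /
#' #\{observed TADs with agreement >= t\}`. The significance cutoff is the
#' smallest observed agreement with `FDR <= alpha`; each TAD also gets the
#' FDR at its own agreement, monotonized to be non-increasing in agreement.
#'
#' @param tab a [tad_agreement()] result (carries the peak assignment).
#' @param fc the same named fold-change vector given to [tad_agreement()].
#' @param n_shuffles number of shuffles (>= 10, default 100).
#' @param alpha FDR level for the cutoff (default 0.05).
#' @param min_peaks must match the value used for `tab`.
#' @param within_chrom if TRUE, shuffle fold changes only within each
#'   chromosome (peak names are matched to chromosomes via `tab`'s
#'   assignment order); default FALSE, genome-wide.
#' @param seed integer seed.
#' @return `tab` with extra columns `fdr` and `significant`, and attributes
#'   `cutoff` (agreement threshold, NA when nothing passes) and
#'   `null_agreements`.
#' @export
tad_empirical_fdr <- function(tab, fc, n_shuffles = 100, alpha = 0.05,
                              min_peaks = 20, within_chrom = FALSE,
                              seed = NULL) {
  stop_if(!inherits(tab, "tad_agreement"),
          "tab must come from tad_agreement()")
  stop_if(n_shuffles < 10, "n_shuffles must be >= 10")
  assign <- attr(tab, "assignment")
  v <- fc[assign$peak]
  chrom_of <- if (within_chrom) assign$chrom else NULL
  null_agree <- with_seed(seed, {
    unlist(lapply(seq_len(n_shuffles), function(k) {
      vp <- if (is.null(chrom_of)) sample(v) else {
        out <- v
        for (ch in unique(chrom_of)) {
          i <- chrom_of == ch
          out[i] <- sample(v[i])
        }
        out
      }
      compute_agreements(vp, assign$tad, min_peaks)$agreement
    }))
  })
  obs <- tab$agreement
  fdr_at <- function(t) {
    n_null <- sum(null_agree >= t) / n_shuffles
    n_obs <- sum(obs >= t)
    if (n_obs == 0) return(NA_real_)
    min(n_null / n_obs, 1)
  }
  fdr <- vapply(obs, fdr_at, numeric(1))
  # monotonize: FDR non-increasing in agreement
  o <- order(obs, decreasing = TRUE)
  fdr[o] <- pmin(cummax(fdr[o]), 1)
  passing <- obs[!is.na(fdr) & fdr <= alpha]
  cutoff <- if (length(passing)) min(passing) else NA_real_
  tab$fdr <- fdr
  tab$significant <- !is.na(cutoff) & obs >= cutoff
  attr(tab, "cutoff") <- cutoff
  attr(tab, "null_agreements") <- null_agree
  tab
}

#' @export
print.tad_agreement <- function(x, ...) {
  cat("TAD agreement table:", nrow(x), "TADs")
  if (!is.null(x$significant)) {
    cat(";", sum(x$significant), "significant at cutoff",
        signif(attr(x, "cutoff"), 4))
  }
  cat("\n")
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
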