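#' Log-odds score matrix of a PWM
#'
#' Probability columns get a pseudocount and are renormalized, then converted
#' to log2 odds against the background base composition:
#' `log2(((p + pc) / (1 + 4 pc)) / bg)`.
#'
#' @param pwm a [random_pwm()]/[read_jaspar()] `pwm` object.
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param pseudocount added to each probability before normalization.
#' @return 4 x L numeric matrix of log2-odds scores (rows A/C/G/T).
#' @export
pwm_logodds <- function(pwm, background = rep(0.25, 4),
                        pseudocount = 1e-3) {
  stop_if(!inherits(pwm, "pwm"), "need a pwm object")
  stop_if(length(background) != 4 || any(background <= 0),
          "background must be 4 positive frequencies")
  p <- sweep(pwm$mat + pseudocount, 2,
             colSums(pwm$mat + pseudocount), `/`)
  log2(p / background)
}

# Reverse-complement a 4 x L score matrix: complement rows, reverse columns.
revcomp_logodds <- function(lo) {
  lo[4:1, rev(seq_len(ncol(lo))), drop = FALSE]
}

#' Best-match PWM score of sequences
#'
#' The maximum log2-odds score over all offsets of both strands. The reverse
#' strand is scored by scanning with the reverse-complemented score matrix,
#' which is identical to scanning the reverse complement of the sequence.
#' Sequences shorter than the motif give NA.
#'
#' @param seqs character vector of A/C/G/T sequences.
#' @inheritParams pwm_logodds
#' @return numeric vector of best-match scores (log2 odds).
#' @examples
#' p <- new_pwm("flat", matrix(0.25, 4, 6))
#' scan_best_match("ACGTACGTACGT", p)   # 0: uniform motif, uniform background
#' @export
scan_best_match <- function(seqs, pwm, background = rep(0.25, 4),
                            pseudocount = 1e-3) {
  lo <- pwm_logodds(pwm, background, pseudocount)
  .scan_best_cpp(as.character(seqs), lo, revcomp_logodds(lo))
}

#' Score of the consensus sequence
#'
#' Sum over positions of the best log2-odds score per column — the maximum
#' score any sequence can reach. Useful for setting scan thresholds relative
#' to a motif's optimum (e.g. consensus minus 2 bits).
#'
#' @inheritParams pwm_logodds
#' @export
consensus_score <- function(pwm, background = rep(0.25, 4),
                            pseudocount = 1e-3) {
  sum(apply(pwm_logodds(pwm, background, pseudocount), 2, max))
}

#' Per-peak best-match scores for a motif database
#'
#' Scans every sequence with every motif and min-max normalizes each motif
#' column to [0, 1] across peaks, so that scores of motifs with different
#' lengths and information contents are comparable in a joint regression.
#' The raw log2-odds matrix is retained in attribute `raw`.
#'
#' @param seqs named character vector of peak sequences.
#' @param motifs named list of `pwm` objects.
#' @inheritParams pwm_logodds
#' @return peaks x motifs matrix of normalized scores (attribute `raw` holds
#'   the unnormalized log2-odds scores). Constant columns normalize to 0.
#' @export
motif_score_matrix <- function(seqs, motifs, background = rep(0.25, 4),
                               pseudocount = 1e-3) {
  stop_if(length(motifs) < 1, "no motifs")
  raw <- vapply(motifs, function(p) {
    scan_best_match(seqs, p, background, pseudocount)
  }, numeric(length(seqs)))
  if (length(seqs) == 1L) raw <- matrix(raw, nrow = 1,
                                        dimnames = list(NULL, names(motifs)))
  rownames(raw) <- names(seqs)
  norm <- apply(raw, 2, function(v) {
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1]) / diff(rng)
  })
  rownames(norm) <- names(seqs)
  attr(norm, "raw") <- raw
  norm
}

#' Extract interval sequences from a genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param x interval data.frame (0-based half-open).
#' @return named character vector (names from `x$name` when present).
#' @export
interval_sequences <- function(genome, x) {
  validate_intervals(x)
  stop_if(!all(x$chrom %in% names(genome)), "interval chrom not in genome")
  out <- substring(genome[x$chrom], x$start + 1, x$end)
  names(out) <- if (!is.null(x$name)) x$name else NULL
  out
}

#' Fraction of genes with a motif hit in their promoter
#'
#' Scans a TSS-anchored promoter window for each gene and reports the
#' fraction whose best-match score reaches `score_threshold`.
#'
#' @param genes character vector of gene ids (e.g. upregulated genes).
#' @param tss TSS table (`gene`, `chrom`, `pos`).
#' @param genome named character vector of chromosomes.
#' @param pwm a `pwm` object.
#' @param score_threshold log2-odds threshold (`>=` counts as a hit).
#' @param flank promoter half-width in bp around the TSS.
#' @return fraction in [0, 1]; NA (with a warning) for an empty gene list.
#' @export
promoter_motif_fraction <- function(genes, tss, genome, pwm,
                                    score_threshold, flank = 500) {
  genes <- intersect(genes, tss$gene)
  if (length(genes) == 0) {
    warning("empty gene list: promoter motif fraction undefined")
    return(NA_real_)
  }
  tt <- tss[match(genes, tss$gene), ]
  win <- data.frame(
    chrom = tt$chrom,
    start = pmax(tt$pos - flank, 0),
    end = pmin(tt$pos + flank, nchar(genome)[match(tt$chrom, names(genome))]),
    name = tt$gene,
    stringsAsFactors = FALSE
  )
  sc <- scan_best_match(interval_sequences(genome, win), pwm)
  mean(sc >= score_threshold, na.rm = TRUE)
}

#' Read and write JASPAR-format PWM files
#'
#' The textual JASPAR layout: a `>` header with motif id (and optionally a
#' TF name), followed by four lines `A [ ... ]` / `C` / `G` / `T` of
#' per-position counts or probabilities. Columns are normalized to
#' probabilities on read.
#'
#' @param path file path.
#' @return `read_jaspar` returns a named list of `pwm` objects; the header's
#'   second token, when present, seeds the motif's TF links.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  stop_if(length(heads) == 0, "no JASPAR records in ", path)
  out <- lapply(seq_along(heads), function(k) {
    h <- heads[k]
    toks <- strsplit(sub("^>\\s*", "", lines[h]), "\\s+")[[1]]
    block <- lines[(h + 1):(h + 4)]
    rows <- lapply(block, function(ln) {
      nums <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", ln)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    })
    mat <- do.call(rbind, rows)
    mat <- sweep(mat, 2, colSums(mat), `/`)
    new_pwm(toks[1], mat, tfs = if (length(toks) > 1) toks[2] else character())
  })
  names(out) <- vapply(out, function(p) p$id, "")
  out
}

#' @rdname read_jaspar
#' @param motifs named list of `pwm` objects.
#' @export
write_jaspar <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in motifs) {
    writeLines(paste0(">", p$id,
                      if (length(p$tfs)) paste0(" ", p$tfs[1])), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s  [ %s ]", b,
                         paste(sprintf("%.6f", p$mat[b, ]),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
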