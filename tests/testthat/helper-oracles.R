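# Independent brute-force oracles used across tests. These deliberately share
# no code with the package implementations they check.

# Exhaustive two-strand PWM best-match: walk every offset on the forward
# sequence and on the literal reverse complement.
oracle_scan <- function(seq, pwm, background = rep(0.25, 4),
                        pseudocount = 1e-3) {
  score_one <- function(s, mat) {
    bases <- strsplit(s, "")[[1]]
    L <- ncol(mat)
    if (length(bases) < L) return(NA_real_)
    p <- sweep(mat + pseudocount, 2, colSums(mat + pseudocount), `/`)
    lo <- log2(p / background)
    best <- -Inf
    for (o in seq_len(length(bases) - L + 1)) {
      w <- bases[o:(o + L - 1)]
      idx <- match(w, c("A", "C", "G", "T"))
      if (anyNA(idx)) next
      sc <- sum(lo[cbind(idx, seq_len(L))])
      if (sc > best) best <- sc
    }
    best
  }
  rc <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  fw <- score_one(seq, pwm$mat)
  rv <- score_one(rc(seq), pwm$mat)
  out <- max(fw, rv, na.rm = FALSE)
  if (is.na(fw)) NA_real_ else out
}

# All-pairs nearest-TSS search with the package's tie-break rule applied
# by explicit sorting.
oracle_nearest <- function(peaks, tss) {
  mid <- floor((peaks$start + peaks$end) / 2)
  out <- data.frame(gene = rep(NA_character_, nrow(peaks)),
                    distance = rep(NA_real_, nrow(peaks)),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(peaks))) {
    tt <- tss[tss$chrom == peaks$chrom[i], , drop = FALSE]
    if (nrow(tt) == 0) next
    d <- abs(tt$pos - mid[i])
    cand <- tt[d == min(d), , drop = FALSE]
    cand <- cand[order(cand$pos, cand$gene), , drop = FALSE]
    out$gene[i] <- cand$gene[1]
    out$distance[i] <- min(d)
  }
  out
}

# Full running-sum GSEA enrichment score, O(N) per call.
oracle_es <- function(ranked, gene_set, weight_p) {
  hit <- names(ranked) %in% gene_set
  n <- length(ranked)
  nh <- sum(hit)
  w <- abs(ranked)^weight_p
  step <- numeric(n)
  step[hit] <- if (sum(w[hit]) > 0) w[hit] / sum(w[hit]) else 1 / nh
  step[!hit] <- -1 / (n - nh)
  run <- cumsum(step)
  hi <- max(run)
  lo <- min(run)
  # tie on |extremum| resolves to the positive excursion, as in the package
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo
}

rand_seqs <- function(n, len_range = c(20, 60)) {
  lens <- len_range[1] +
    floor(runif(n) * (len_range[2] - len_range[1] + 1))
  vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
}

tiny_design <- function() sample_design(conditions = c("A", "B"),
                                        replicates = 3)

# TAD world on one chromosome: n_tads contiguous 10 kb TADs, ppt peaks each.
tad_world <- function(n_tads, ppt) {
  tads <- data.frame(chrom = "chr1",
                     start = (seq_len(n_tads) - 1) * 10000,
                     end = seq_len(n_tads) * 10000,
                     name = sprintf("tad%03d", seq_len(n_tads)),
                     stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1",
                      start = rep((seq_len(n_tads) - 1) * 10000,
                                  each = ppt) +
                        rep(seq_len(ppt) * floor(9000 / ppt), n_tads),
                      stringsAsFactors = FALSE)
  peaks$end <- peaks$start + 100
  peaks$name <- sprintf("peak%05d", seq_len(nrow(peaks)))
  list(tads = tads, peaks = peaks)
}
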