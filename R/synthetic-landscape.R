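#' Random position weight matrix
#'
#' Columns are drawn with one dominant base (probability 0.7-0.95), giving
#' motifs of realistic information content (~1-1.5 bits per position).
#'
#' @param id motif identifier.
#' @param length motif length in bp.
#' @param tfs character vector of linked transcription factor ids.
#' @param min_dom,max_dom range of the dominant-base probability per column;
#'   push both towards 1 for a near-deterministic, high-information motif.
#' @return object of class `pwm`: list with `id`, `mat` (4 x L probability
#'   matrix, rows A/C/G/T, columns summing to 1) and `tfs`.
#' @export
random_pwm <- function(id, length = 12, tfs = character(),
                       min_dom = 0.7, max_dom = 0.95) {
  stop_if(length < 4, "motif length must be >= 4")
  stop_if(min_dom <= 0.25 || max_dom >= 1 || min_dom > max_dom,
          "dominant-base probabilities must satisfy 0.25 < min <= max < 1")
  mat <- vapply(seq_len(length), function(j) {
    p <- runif(1, min_dom, max_dom)
    rest <- runif(3)
    col <- rep(0, 4)
    dom <- sample.int(4, 1)
    col[dom] <- p
    col[-dom] <- (1 - p) * rest / sum(rest)
    col
  }, numeric(4))
  rownames(mat) <- c("A", "C", "G", "T")
  new_pwm(id, mat, tfs)
}

#' @rdname random_pwm
#' @param mat 4 x L probability matrix (rows A/C/G/T).
#' @export
new_pwm <- function(id, mat, tfs = character()) {
  stop_if(!is.matrix(mat) || nrow(mat) != 4 || ncol(mat) < 4,
          "PWM matrix must be 4 x L with L >= 4")
  stop_if(any(mat < 0) || any(abs(colSums(mat) - 1) > 1e-6),
          "PWM columns must be probabilities summing to 1")
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(id = id, mat = mat, tfs = tfs), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$id, "length", ncol(x$mat),
      if (length(x$tfs)) paste0("(TFs: ", paste(x$tfs, collapse = ","), ")"),
      "\n")
  invisible(x)
}

# Sample k instance strings from a PWM's probability columns.
sample_pwm_instances <- function(pwm, k) {
  L <- ncol(pwm$mat)
  bases <- c("A", "C", "G", "T")
  m <- vapply(seq_len(L), function(j) {
    sample(bases, k, replace = TRUE, prob = pwm$mat[, j])
  }, character(k))
  if (k == 1L) m <- matrix(m, nrow = 1)
  apply(m, 1, paste, collapse = "")
}

revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Replace non-overlapping [start, end) segments (0-based half-open) of one
# chromosome string in a single pass.
splice_segments <- function(seqstr, starts, ends, replacements) {
  if (length(starts) == 0) return(seqstr)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; replacements <- replacements[o]
  stop_if(any(starts[-1] < ends[-length(ends)]),
          "segments to splice must not overlap")
  n <- nchar(seqstr)
  gaps_start <- c(0, ends)
  gaps_end <- c(starts, n)
  gaps <- substring(seqstr, gaps_start + 1, gaps_end)
  pieces <- character(2 * length(starts) + 1)
  pieces[seq(1, length(pieces), by = 2)] <- gaps
  pieces[seq(2, length(pieces), by = 2)] <- replacements
  paste(pieces, collapse = "")
}

#' Simulate a regulatory landscape with a planted driver motif
#'
#' Generates, on a synthetic genome: non-overlapping fixed-width peaks laid
#' out on a jittered grid; TADs tiling each chromosome; a motif database of
#' one driver PWM plus decoys; genes with TSS placed in inter-peak gaps; a
#' peak-by-sample negative-binomial count matrix; and a TF protein-expression
#' table.
#'
#' The causal structure planted is: instances of the *driver* PWM are embedded
#' (random offset and strand, one per peak) in `frac_driver_peaks` of peaks,
#' and exactly those peaks receive a `driver_effect` log2-unit mean shift in
#' the last ("EN"-like) condition. Decoy PWMs are embedded in random peaks,
#' uncorrelated with fold change. A subset of TADs is "coordinated": all
#' member peaks share an extra same-sign shift. The driver's TF is strongly
#' differential in the TF protein table; a fraction of decoy TFs is also
#' differential so that expression filtering alone cannot isolate the driver.
#' Driver instances are additionally planted in compact promoter windows
#' (+/- `promoter_halfwidth` around the TSS) of `promoter_plant_frac` of a
#' designated "upregulated" gene subset.
#'
#' @param design a [sample_design()].
#' @param genome named character vector of chromosomes (default: a fresh
#'   4 x 500 kb [synthetic_genome()]).
#' @param n_peaks,n_motifs,n_tads,n_genes counts of planted elements.
#' @param driver_effect log2-unit count shift of driver peaks in the last
#'   condition.
#' @param frac_driver_peaks fraction of peaks carrying a driver instance.
#' @param frac_coordinated_tads fraction of TADs with coordinated shifts.
#' @param coordinated_effect log2-unit magnitude of the coordinated shift.
#' @param peak_width peak width in bp.
#' @param frac_diff_peaks,diff_peak_sd fraction and log2-sd of background
#'   differential peaks (condition shifts unrelated to motif content).
#' @param decoy_plant_frac fraction of peaks in which each decoy is planted.
#' @param frac_diff_tfs fraction of decoy TFs that are differential.
#' @param driver_tf_log2fc planted log2 fold change of the driver TF protein
#'   (default 2.5, i.e. > 4-fold).
#' @param promoter_halfwidth half-width of promoter planting windows in bp.
#' @param promoter_plant_frac fraction of upregulated genes whose promoter
#'   receives a driver instance.
#' @param nb_dispersion negative binomial dispersion of peak counts.
#' @param seed integer seed.
#' @return list with `genome` (instances spliced in), `peaks`, `tads`, `tss`
#'   (interval data.frames), `peak_counts` (matrix), `motifs` (named list of
#'   [random_pwm()] objects), `motif_tf_map` (data.frame motif/tf),
#'   `tf_protein` (TF intensity matrix), `design`, and `truth` with
#'   `driver_motif_id`, `driver_peaks`, `coordinated_tads`, `tad_signs`,
#'   `differential_tfs`, `true_log2fc`, `up_genes`, `promoter_planted_genes`.
#' @examples
#' land <- simulate_regulatory_landscape(n_peaks = 200, n_motifs = 5,
#'                                       n_tads = 20, n_genes = 50, seed = 1)
#' land$truth$driver_motif_id
#' @export
simulate_regulatory_landscape <- function(design = sample_design(),
                                          genome = NULL,
                                          n_peaks = 2000,
                                          n_motifs = 50,
                                          n_tads = 200,
                                          n_genes = 300,
                                          driver_effect = 2.0,
                                          frac_driver_peaks = 0.3,
                                          frac_coordinated_tads = 0.05,
                                          coordinated_effect = 1.0,
                                          peak_width = 400,
                                          frac_diff_peaks = 0.2,
                                          diff_peak_sd = 1.0,
                                          decoy_plant_frac = 0.3,
                                          frac_diff_tfs = 0.3,
                                          driver_tf_log2fc = 2.5,
                                          promoter_halfwidth = 150,
                                          promoter_plant_frac = 0.6,
                                          nb_dispersion = 0.05,
                                          seed = NULL) {
  stop_if(n_motifs < 2, "need >= 2 motifs (1 driver + >= 1 decoy)")
  with_seed(seed, {
    if (is.null(genome)) genome <- synthetic_genome()
    chroms <- names(genome)
    chrom_len <- nchar(genome)
    conds <- unique(design$condition)
    en <- conds[length(conds)]

    ## --- geometry ----------------------------------------------------------
    per_chrom <- table(factor(rep(chroms, length.out = n_peaks),
                              levels = chroms))
    spacing <- floor(chrom_len / pmax(as.integer(per_chrom), 1L))
    stop_if(any(spacing < 2 * peak_width),
            "peak geometry conflict: chromosomes too short for n_peaks ",
            "non-overlapping peaks of ", peak_width, " bp")
    peaks <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      k <- as.integer(per_chrom[ci]); sp <- spacing[ci]
      start <- (seq_len(k) - 1L) * sp +
        floor(runif(k, 0, sp - peak_width))
      data.frame(chrom = chroms[ci], start = start,
                 end = start + peak_width, stringsAsFactors = FALSE)
    }))
    peaks$name <- sprintf("peak%05d", seq_len(nrow(peaks)))

    tads_per_chrom <- table(factor(rep(chroms, length.out = n_tads),
                                   levels = chroms))
    tads <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      k <- as.integer(tads_per_chrom[ci])
      w <- floor(chrom_len[ci] / k)
      data.frame(chrom = chroms[ci], start = (seq_len(k) - 1L) * w,
                 end = seq_len(k) * w, stringsAsFactors = FALSE)
    }))
    tads$name <- sprintf("tad%04d", seq_len(nrow(tads)))

    ## TSS in inter-peak gaps wide enough to host a promoter window
    tss <- do.call(rbind, lapply(chroms, function(ch) {
      p <- peaks[peaks$chrom == ch, ]
      gap_start <- c(0, p$end)
      gap_end <- c(p$start, chrom_len[ch])
      ok <- (gap_end - gap_start) >= (2 * promoter_halfwidth + 20)
      data.frame(chrom = ch,
                 pos = floor((gap_start[ok] + gap_end[ok]) / 2),
                 stringsAsFactors = FALSE)
    }))
    stop_if(nrow(tss) < n_genes,
            "not enough inter-peak gaps to place ", n_genes, " genes")
    tss <- tss[sort(sample.int(nrow(tss), n_genes)), ]
    tss$gene <- sprintf("gene%05d", seq_len(n_genes))
    tss$strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    rownames(tss) <- NULL

    ## --- motifs and planting -----------------------------------------------
    motif_ids <- sprintf("M%03d", seq_len(n_motifs))
    tf_ids <- sprintf("TF%03d", seq_len(n_motifs))
    # the driver is a near-deterministic high-information motif, so planted
    # instances (sampled from its columns) score close to the consensus
    motifs <- lapply(seq_len(n_motifs), function(i) {
      if (i == 1L) {
        random_pwm(motif_ids[i], length = 10, tfs = tf_ids[i],
                   min_dom = 0.99, max_dom = 0.999)
      } else {
        random_pwm(motif_ids[i], length = sample(8:14, 1), tfs = tf_ids[i])
      }
    })
    names(motifs) <- motif_ids
    # some motifs link to a second TF
    extra <- sample(seq_len(n_motifs), max(1, round(0.2 * n_motifs)))
    for (i in extra) motifs[[i]]$tfs <- c(motifs[[i]]$tfs,
                                          sample(tf_ids[-i], 1))
    motif_tf_map <- do.call(rbind, lapply(motifs, function(p) {
      data.frame(motif = p$id, tf = p$tfs, stringsAsFactors = FALSE)
    }))
    rownames(motif_tf_map) <- NULL
    driver <- motif_ids[1]

    ## coordinated TADs are chosen first so driver instances can be planted
    ## outside them: otherwise repressed TADs would be diluted by activated
    ## driver peaks and neither planting would be cleanly recoverable
    n_coord <- ceiling(frac_coordinated_tads * n_tads)
    coord_tads <- sort(sample.int(n_tads, n_coord))
    tad_signs <- sample(c(-1, 1), n_coord, replace = TRUE)
    peak_mid <- floor((peaks$start + peaks$end) / 2)
    coord_members <- lapply(coord_tads, function(ti) {
      which(peaks$chrom == tads$chrom[ti] &
              peak_mid >= tads$start[ti] & peak_mid < tads$end[ti])
    })

    peak_seqs <- substring(genome[peaks$chrom], peaks$start + 1, peaks$end)
    n_driver <- round(frac_driver_peaks * n_peaks)
    driver_candidates <- setdiff(seq_len(n_peaks), unlist(coord_members))
    stop_if(length(driver_candidates) < n_driver,
            "not enough peaks outside coordinated TADs for driver planting")
    driver_peaks <- sort(sample(driver_candidates, n_driver))
    plant_in <- function(seqs, rows, pwm) {
      if (length(rows) == 0) return(seqs)
      ins <- sample_pwm_instances(pwm, length(rows))
      minus <- runif(length(rows)) < 0.5
      ins[minus] <- revcomp_str(ins[minus])
      L <- ncol(pwm$mat)
      off <- floor(runif(length(rows), 0, peak_width - L + 1))
      tmp <- seqs[rows]
      substring(tmp, off + 1, off + L) <- ins
      seqs[rows] <- tmp
      seqs
    }
    peak_seqs <- plant_in(peak_seqs, driver_peaks, motifs[[driver]])
    for (m in motif_ids[-1]) {
      rows <- sample.int(n_peaks, round(decoy_plant_frac * n_peaks))
      peak_seqs <- plant_in(peak_seqs, rows, motifs[[m]])
    }

    ## promoter planting for the upregulated-gene subset
    up_genes <- sort(sample(tss$gene, max(5, round(0.25 * n_genes))))
    planted_genes <- sort(sample(up_genes,
                                 round(promoter_plant_frac *
                                         length(up_genes))))
    prom_start <- tss$pos - promoter_halfwidth
    prom_end <- tss$pos + promoter_halfwidth
    prom_seqs <- substring(genome[tss$chrom], prom_start + 1, prom_end)
    prow <- match(planted_genes, tss$gene)
    if (length(prow)) {
      ins <- sample_pwm_instances(motifs[[driver]], length(prow))
      minus <- runif(length(prow)) < 0.5
      ins[minus] <- revcomp_str(ins[minus])
      L <- ncol(motifs[[driver]]$mat)
      off <- floor(runif(length(prow), 0, 2 * promoter_halfwidth - L + 1))
      tmp <- prom_seqs[prow]
      substring(tmp, off + 1, off + L) <- ins
      prom_seqs[prow] <- tmp
    }

    ## splice modified segments back into the genome
    for (ch in chroms) {
      pk <- which(peaks$chrom == ch)
      pr <- which(tss$chrom == ch)
      genome[ch] <- splice_segments(
        genome[ch],
        c(peaks$start[pk], prom_start[pr]),
        c(peaks$end[pk], prom_end[pr]),
        c(peak_seqs[pk], prom_seqs[pr])
      )
    }

    ## --- peak counts --------------------------------------------------------
    base_log2 <- rnorm(n_peaks, mean = log2(100), sd = 1)
    shift <- matrix(0, n_peaks, length(conds),
                    dimnames = list(peaks$name, conds))
    shift[driver_peaks, en] <- shift[driver_peaks, en] + driver_effect
    diff_peaks <- sample.int(n_peaks, round(frac_diff_peaks * n_peaks))
    shift[diff_peaks, en] <- shift[diff_peaks, en] +
      rnorm(length(diff_peaks), 0, diff_peak_sd)

    for (k in seq_along(coord_tads)) {
      shift[coord_members[[k]], en] <- shift[coord_members[[k]], en] +
        tad_signs[k] * coordinated_effect
    }

    sf <- exp(rnorm(nrow(design), 0, 0.15))
    mu <- 2^(base_log2 + shift[, match(design$condition, conds), drop = FALSE])
    mu <- sweep(mu, 2, sf, `*`)
    peak_counts <- matrix(
      rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion),
      nrow(mu), ncol(mu),
      dimnames = list(peaks$name, design$sample)
    )

    ## --- TF protein table ---------------------------------------------------
    n_tf <- length(tf_ids)
    tf_base <- 10^rnorm(n_tf, 6, 0.8)
    tf_shift <- matrix(0, n_tf, length(conds),
                       dimnames = list(tf_ids, conds))
    diff_tfs <- c(1L, sample((2:n_tf), round(frac_diff_tfs * (n_tf - 1))))
    tf_shift[1, en] <- driver_tf_log2fc
    others <- setdiff(diff_tfs, 1L)
    tf_shift[others, en] <- sample(c(-1, 1), length(others), TRUE) *
      rnorm(length(others), 1.5, 0.4)
    tf_protein <- tf_base * 2^(tf_shift[, match(design$condition, conds),
                                        drop = FALSE]) *
      exp(rnorm(n_tf * nrow(design), 0, 0.1))
    dimnames(tf_protein) <- list(tf_ids, design$sample)

    list(
      genome = genome,
      peaks = peaks,
      tads = tads,
      tss = tss,
      peak_counts = peak_counts,
      motifs = motifs,
      motif_tf_map = motif_tf_map,
      tf_protein = tf_protein,
      design = design,
      truth = list(
        driver_motif_id = driver,
        driver_tf = tf_ids[1],
        driver_peaks = peaks$name[driver_peaks],
        coordinated_tads = tads$name[coord_tads],
        tad_signs = setNames(tad_signs, tads$name[coord_tads]),
        differential_tfs = tf_ids[sort(diff_tfs)],
        true_log2fc = setNames(shift[, en] - shift[, conds[length(conds) - 1]],
                               peaks$name),
        up_genes = up_genes,
        promoter_planted_genes = planted_genes,
        promoter_halfwidth = promoter_halfwidth
      )
    )
  })
}
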