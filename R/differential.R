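#' Replicate-presence filter
#'
#' Keeps features observed (non-missing) in all replicates of at least one
#' condition — the standard "identified in all triplicates of one sample"
#' rule for label-free proteomics.
#'
#' @param x intensity matrix (NA = missing).
#' @param design a [sample_design()].
#' @return the filtered matrix.
#' @export
presence_filter <- function(x, design) {
  check_matrix(x)
  design <- check_design(design, x)
  keep <- Reduce(`|`, lapply(unique(design$condition), function(cc) {
    rowSums(!is.na(x[, cond_cols(design, cc), drop = FALSE])) ==
      length(cond_cols(design, cc))
  }))
  x[keep, , drop = FALSE]
}

#' Detection-limit imputation of missing intensities
#'
#' Implements the downshifted-Gaussian imputation used for proteomics data
#' under the assumption that values are missing because they fell below the
#' instrument's detection limit. Per sample, missing log-intensities are
#' drawn from `Normal(mean_obs - shift * sd_obs, (width * sd_obs)^2)` where
#' `mean_obs`/`sd_obs` summarize that sample's observed values.
#'
#' @param x matrix of log-scale intensities with NAs.
#' @param shift downshift in observed-sd multiples (default 1.8).
#' @param width width of the imputation distribution in observed-sd
#'   fractions (default 0.3).
#' @param min_observed refuse to impute samples with fewer observed values.
#' @param seed integer seed; same seed, same imputations.
#' @return completed matrix.
#' @export
detection_limit_impute <- function(x, shift = 1.8, width = 0.3,
                                   min_observed = 10, seed = NULL) {
  check_matrix(x)
  with_seed(seed, {
    for (s in colnames(x)) {
      obs <- x[, s][!is.na(x[, s])]
      miss <- which(is.na(x[, s]))
      if (length(miss) == 0) next
      stop_if(length(obs) < min_observed,
              "sample ", s, " has fewer than ", min_observed,
              " observed values; refusing to impute")
      x[miss, s] <- rnorm(length(miss),
                          mean = mean(obs) - shift * sd(obs),
                          sd = width * sd(obs))
    }
    x
  })
}

# All distinct two-group label assignments of size nA from n columns,
# excluding the observed assignment and its complement (which reproduce the
# observed statistics up to sign). Sampled when more than n_max exist.
permutation_assignments <- function(n, nA, n_max, seed = NULL) {
  n_all <- choose(n, nA)
  obs <- seq_len(nA)
  if (n_all <= n_max + 2) {
    sets <- combn(n, nA, simplify = FALSE)
  } else {
    sets <- with_seed(seed, {
      unique(replicate(ceiling(n_max * 1.2) + 2,
                       sort(sample.int(n, nA)), simplify = FALSE))
    })
  }
  is_obs <- vapply(sets, function(s) {
    setequal(s, obs) || setequal(s, setdiff(seq_len(n), obs))
  }, logical(1))
  sets <- sets[!is_obs]
  if (length(sets) > n_max) sets <- sets[seq_len(n_max)]
  sets
}

#' Permutation-FDR moderated t-test
#'
#' The adapted two-sample t-test used for label-free proteomics: the
#' statistic `d = (mean_A - mean_B) / (se + s0)` adds a small fudge factor
#' `s0` to the Welch standard error so that low-variance features cannot
#' reach huge statistics on tiny absolute changes. The null distribution is
#' built by permuting group labels (all distinct assignments when fewer than
#' `n_perm` exist, excluding the observed labelling and its mirror); the
#' q-value of a feature is the average number of permuted `|d|` values at or
#' above its `|d|`, divided by the observed count at or above it, made
#' non-increasing in `|d|` and capped at 1.
#'
#' @param x matrix of log-scale values (features x samples).
#' @param group_a,group_b column names of the two groups (>= 2 each).
#' @param s0 variance stabilizer on the log scale (default 0.1).
#' @param n_perm maximum number of permutations (>= 100 by contract; all
#'   distinct assignments are used when fewer exist).
#' @param seed integer seed for permutation sampling.
#' @return data.frame of class `differential_result`: `feature`, `log2fc`
#'   (A over B, assuming log2 input), `stat`, `q`, plus attribute
#'   `comparison`.
#' @export
permutation_fdr_ttest <- function(x, group_a, group_b, s0 = 0.1,
                                  n_perm = 1000, seed = NULL) {
  check_matrix(x)
  stop_if(length(group_a) < 2 || length(group_b) < 2,
          "need >= 2 replicates per group")
  stop_if(n_perm < 100, "n_perm must be >= 100")
  cols <- c(group_a, group_b)
  stop_if(!all(cols %in% colnames(x)), "group columns missing from matrix")
  m <- x[, cols, drop = FALSE]
  nA <- length(group_a)
  dstat <- function(idxA) {
    a <- m[, idxA, drop = FALSE]
    b <- m[, -idxA, drop = FALSE]
    se <- sqrt(apply(a, 1, var) / ncol(a) + apply(b, 1, var) / ncol(b))
    (rowMeans(a) - rowMeans(b)) / (se + s0)
  }
  d_obs <- dstat(seq_len(nA))
  perms <- permutation_assignments(ncol(m), nA, n_perm, seed = seed)
  if (length(perms) == 0) {
    warning("no non-trivial label permutations available; q = 1")
    return(structure(
      data.frame(feature = rownames(m),
                 log2fc = rowMeans(m[, seq_len(nA), drop = FALSE]) -
                   rowMeans(m[, -seq_len(nA), drop = FALSE]),
                 stat = d_obs, q = rep(1, nrow(m)),
                 stringsAsFactors = FALSE, row.names = NULL),
      comparison = paste0(paste(group_a, collapse = ","), " vs ",
                          paste(group_b, collapse = ",")),
      class = c("differential_result", "data.frame")
    ))
  }
  d_perm <- vapply(perms, dstat, numeric(nrow(m)))

  ad <- abs(d_obs)
  ord <- order(ad, decreasing = TRUE)
  obs_count <- seq_along(ord)                     # |d_obs| >= threshold
  thr <- ad[ord]
  # mean over permutations of #{|d_perm| >= thr}, via one sorted pass
  all_perm <- sort(abs(as.vector(d_perm)))
  ge_count <- length(all_perm) -
    findInterval(thr, all_perm, left.open = TRUE)
  q_raw <- (ge_count / length(perms)) / obs_count
  q_mono <- pmin(cummax(q_raw), 1)
  q <- numeric(length(ad))
  q[ord] <- q_mono
  q[is.na(d_obs)] <- NA
  structure(
    data.frame(
      feature = rownames(m),
      log2fc = rowMeans(m[, seq_len(nA), drop = FALSE]) -
        rowMeans(m[, -seq_len(nA), drop = FALSE]),
      stat = d_obs,
      q = q,
      stringsAsFactors = FALSE,
      row.names = NULL
    ),
    comparison = paste0(paste(group_a, collapse = ","), " vs ",
                        paste(group_b, collapse = ",")),
    class = c("differential_result", "data.frame")
  )
}

#' Normalized, noise-stabilized fold changes for count matrices
#'
#' Median-of-ratios normalization (geometric-mean reference over features
#' with no zero count) followed by pseudocount-shrunken log2 fold changes:
#' `log2((mean_norm_A + prior) / (mean_norm_B + prior))`. Large `prior_count`
#' pulls low-count fold changes toward 0, stabilizing noisy features.
#' Significance comes from [permutation_fdr_ttest()] on
#' `log2(norm_count + prior)`.
#'
#' @param counts count matrix (peaks/features x samples).
#' @param design a [sample_design()].
#' @param contrast length-2 character: conditions (A, B) to compare.
#' @param prior_count pseudocount on normalized counts (default 4).
#' @param s0,n_perm,seed passed to [permutation_fdr_ttest()].
#' @return data.frame of class `fold_change_table`: `feature`, `log2fc`,
#'   `mean_norm`, `stat`, `q`; attribute `size_factors`.
#' @export
count_fold_changes <- function(counts, design, contrast, prior_count = 4,
                               s0 = 0.1, n_perm = 1000, seed = NULL) {
  check_matrix(counts, "counts")
  design <- check_design(design, counts)
  stop_if(any(colSums(counts) == 0), "sample with all-zero counts")
  sf <- median_of_ratios_size_factors(counts)
  norm <- sweep(counts, 2, sf, `/`)
  ga <- cond_cols(design, contrast[1])
  gb <- cond_cols(design, contrast[2])
  stop_if(length(ga) < 2 || length(gb) < 2,
          "contrast conditions need >= 2 replicates each")
  mA <- rowMeans(norm[, ga, drop = FALSE])
  mB <- rowMeans(norm[, gb, drop = FALSE])
  lfc <- log2((mA + prior_count) / (mB + prior_count))
  test <- permutation_fdr_ttest(log2(norm + prior_count), ga, gb,
                                s0 = s0, n_perm = n_perm, seed = seed)
  structure(
    data.frame(
      feature = rownames(counts),
      log2fc = lfc,
      mean_norm = rowMeans(norm),
      stat = test$stat,
      q = test$q,
      stringsAsFactors = FALSE,
      row.names = NULL
    ),
    size_factors = sf,
    contrast = paste(contrast, collapse = " vs "),
    class = c("fold_change_table", "data.frame")
  )
}

#' @rdname count_fold_changes
#' @export
median_of_ratios_size_factors <- function(counts) {
  ref_ok <- rowSums(counts == 0) == 0
  stop_if(sum(ref_ok) < 1, "no feature without zeros for the reference")
  logref <- rowMeans(log(counts[ref_ok, , drop = FALSE]))
  sf <- apply(counts[ref_ok, , drop = FALSE], 2, function(v) {
    exp(median(log(v) - logref))
  })
  stop_if(any(sf <= 0), "non-positive size factor")
  sf
}

#' Condition-signature Pearson correlation between two expression matrices
#'
#' Restricts both matrices to a significant-feature subset and computes
#' Pearson correlations of log intensities for every cross-matrix sample
#' pair — the standard way to ask which in vitro condition resembles which
#' reference tissue.
#'
#' @param x,y log-scale intensity matrices sharing the feature namespace.
#' @param features feature subset (>= 3) defining the signature.
#' @return matrix of correlations, samples of `x` by samples of `y`;
#'   correlations against constant vectors are NA.
#' @export
signature_correlation <- function(x, y, features) {
  stop_if(length(features) < 3, "signature needs >= 3 features")
  common <- intersect(intersect(features, rownames(x)), rownames(y))
  stop_if(length(common) < 3, "fewer than 3 signature features shared")
  a <- x[common, , drop = FALSE]
  b <- y[common, , drop = FALSE]
  out <- suppressWarnings(cor(a, b, use = "pairwise.complete.obs"))
  out[!is.finite(out)] <- NA
  out
}
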