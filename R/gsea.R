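#' Order a ranking metric for preranked enrichment
#'
#' Sorts a named metric decreasingly, breaking ties by gene id (ascending),
#' so the ranking is strictly reproducible.
#'
#' @param metric named numeric vector (gene -> signed metric, e.g. log2 FC).
#' @return the sorted named vector.
#' @export
rank_genes <- function(metric) {
  stop_if(is.null(names(metric)) || anyDuplicated(names(metric)) > 0,
          "metric must be named with unique gene ids")
  stop_if(any(!is.finite(metric)), "metric must be finite")
  metric[order(-metric, names(metric), method = "radix")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; at a gene-set member ("hit") the running sum rises
#' by `|metric|^weight_p` normalized by the total over hits, at a non-member
#' it falls by `1 / (N - N_hits)`. The enrichment score is the extremum of
#' the running sum (largest absolute deviation from zero); the leading edge
#' is the set members at or before a positive extremum (or at or after a
#' negative one).
#'
#' @param ranked sorted named metric from [rank_genes()] or [read_rnk()].
#' @param gene_set character vector of member gene ids; must intersect the
#'   ranking and must not cover it entirely.
#' @param weight_p hit-weight exponent (0 = classic KS; default 1).
#' @return list: `es`, `leading_edge` (character vector), `running`
#'   (numeric, the full running sum).
#' @export
enrichment_score <- function(ranked, gene_set, weight_p = 1) {
  n <- length(ranked)
  hit <- names(ranked) %in% gene_set
  nh <- sum(hit)
  stop_if(nh == 0, "gene set does not intersect the ranked list")
  stop_if(nh == n, "gene set covers the whole ranked list")
  w <- abs(ranked)^weight_p
  inc <- numeric(n)
  inc[hit] <- if (sum(w[hit]) > 0) w[hit] / sum(w[hit]) else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  i_max <- which.max(running)
  i_min <- which.min(running)
  # on an exact tie of |max| and |min| the positive excursion wins; the
  # tolerance keeps the choice stable under floating-point summation order
  es <- if (abs(running[i_max]) >= abs(running[i_min]) - 1e-12) {
    running[i_max]
  } else {
    running[i_min]
  }
  leading <- if (es >= 0) {
    names(ranked)[seq_len(i_max)][hit[seq_len(i_max)]]
  } else {
    names(ranked)[i_min:n][hit[i_min:n]]
  }
  list(es = unname(es), leading_edge = leading, running = unname(running))
}

# O(k log k) ES from sorted hit positions; equals enrichment_score()$es.
# Used for the permutation null where the full running sum is not needed.
es_from_positions <- function(pos, w_all, n, weight_p) {
  k <- length(pos)
  w <- w_all[pos]
  tot <- sum(w)
  cw <- if (tot > 0) cumsum(w) / tot else seq_len(k) / k
  step <- 1 / (n - k)
  miss_before <- (pos - seq_len(k)) * step
  tops <- cw - miss_before
  bottoms <- c(0, cw[-k]) - miss_before
  hi <- max(tops)
  lo <- min(bottoms)
  # tolerance so exact-tie cases resolve like the running-sum path despite
  # different floating-point summation order
  if (abs(hi) >= abs(lo) - 1e-12) hi else lo
}

#' Preranked GSEA with gene-set permutation FDR
#'
#' For every gene set, a null enrichment-score distribution is built from
#' `n_perm` random same-size gene sets drawn from the ranked universe.
#' `NES = ES / mean(|null ES| of matching sign)`; the nominal p-value is the
#' add-one-corrected fraction of null `|ES| >= |ES_obs|`. FDR q-values use
#' the standard NES-based ratio: for a set with NES*, the fraction of pooled
#' sign-matched null NES at least as extreme, divided by the fraction of
#' observed NES at least as extreme, capped at 1 and monotonized within each
#' sign.
#'
#' @param ranked sorted named metric (see [rank_genes()]).
#' @param gene_sets named list of character vectors.
#' @param n_perm gene-set permutations per set (>= 100; default 10000).
#' @param weight_p hit-weight exponent.
#' @param seed integer seed.
#' @return data.frame of class `gsea_result`: `set`, `size` (genes in the
#'   ranking), `es`, `nes`, `p_value`, `fdr`, `leading_edge`
#'   (comma-separated).
#' @export
gsea_permutation_fdr <- function(ranked, gene_sets, n_perm = 10000,
                                 weight_p = 1, seed = NULL) {
  stop_if(n_perm < 100, "n_perm must be >= 100")
  n <- length(ranked)
  w_all <- abs(ranked)^weight_p
  res <- lapply(names(gene_sets), function(nm) {
    gs <- intersect(gene_sets[[nm]], names(ranked))
    if (length(gs) == 0 || length(gs) == n) {
      return(list(set = nm, size = length(gs), es = NA_real_,
                  null = numeric(), leading = character()))
    }
    sc <- enrichment_score(ranked, gs, weight_p)
    list(set = nm, size = length(gs), es = sc$es,
         leading = sc$leading_edge)
  })
  nulls <- with_seed(seed, {
    lapply(res, function(r) {
      if (is.na(r$es)) return(numeric())
      vapply(seq_len(n_perm), function(b) {
        es_from_positions(sort(sample.int(n, r$size)), w_all, n, weight_p)
      }, numeric(1))
    })
  })
  es <- vapply(res, `[[`, numeric(1), "es")
  nes <- rep(NA_real_, length(es))
  p <- rep(NA_real_, length(es))
  null_nes <- vector("list", length(es))
  for (i in seq_along(es)) {
    nu <- nulls[[i]]
    if (is.na(es[i]) || length(nu) == 0) next
    same <- nu[sign(nu) == sign(es[i])]
    denom <- if (length(same)) mean(abs(same)) else mean(abs(nu))
    nes[i] <- es[i] / denom
    p[i] <- (1 + sum(abs(nu) >= abs(es[i]))) / (n_perm + 1)
    pos_m <- if (sum(nu > 0)) mean(nu[nu > 0]) else NA
    neg_m <- if (sum(nu < 0)) mean(abs(nu[nu < 0])) else NA
    null_nes[[i]] <- c(if (!is.na(pos_m)) nu[nu > 0] / pos_m,
                       if (!is.na(neg_m)) nu[nu < 0] / neg_m)
  }
  pool <- unlist(null_nes)
  fdr <- rep(NA_real_, length(es))
  for (i in seq_along(es)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      f_null <- mean(pool >= nes[i])
      f_obs <- mean(nes[!is.na(nes)] >= nes[i])
    } else {
      f_null <- mean(pool <= nes[i])
      f_obs <- mean(nes[!is.na(nes)] <= nes[i])
    }
    fdr[i] <- min(f_null / f_obs, 1)
  }
  # monotonize within sign: more extreme NES never has larger q
  for (sgn in c(1, -1)) {
    idx <- which(!is.na(nes) & sign(nes) == sgn)
    if (length(idx) > 1) {
      o <- idx[order(abs(nes[idx]), decreasing = TRUE)]
      fdr[o] <- cummax(fdr[o])
    }
  }
  structure(
    data.frame(
      set = vapply(res, `[[`, "", "set"),
      size = vapply(res, `[[`, 0L, "size"),
      es = es,
      nes = nes,
      p_value = p,
      fdr = fdr,
      leading_edge = vapply(res, function(r) {
        paste(r$leading, collapse = ",")
      }, ""),
      stringsAsFactors = FALSE
    ),
    class = c("gsea_result", "data.frame")
  )
}

#' @export
print.gsea_result <- function(x, ...) {
  cat("preranked GSEA:", nrow(x), "gene sets;",
      sum(x$fdr < 0.05, na.rm = TRUE), "at FDR < 0.05\n")
  print.data.frame(x[, setdiff(names(x), "leading_edge")])
  invisible(x)
}
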