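#' Study design for a cell-type-enriched organoid experiment
#'
#' Encodes the condition/replicate layout the generator and all differential
#' routines share. Defaults mirror a three-condition organoid study:
#' stem-cell-enriched ("CV"), reference ("ENR") and enterocyte-enriched ("EN")
#' cultures, three biological replicates each.
#'
#' @param conditions ordered character vector of condition labels (>= 2).
#' @param replicates number of biological replicates per condition (>= 2).
#' @return data.frame with columns `sample`, `condition`, `replicate`.
#' @examples
#' sample_design()
#' @export
sample_design <- function(conditions = c("CV", "ENR", "EN"), replicates = 3) {
  stop_if(length(conditions) < 2 || anyDuplicated(conditions) > 0,
          "need >= 2 distinct condition labels")
  stop_if(replicates < 2, "need >= 2 replicates per condition")
  data.frame(
    sample = paste(rep(conditions, each = replicates),
                   rep(seq_len(replicates), length(conditions)), sep = "_"),
    condition = rep(conditions, each = replicates),
    replicate = rep(seq_len(replicates), length(conditions)),
    stringsAsFactors = FALSE
  )
}

#' Spike-in standard panel
#'
#' A panel of spike-in species with known input amounts, log-spaced over
#' several orders of magnitude, in the style of the UPS2 protein standard
#' (48 proteins in 8 abundance groups) or the ERCC RNA mix.
#'
#' @param n number of spike-in species.
#' @param n_levels number of distinct amount levels (>= 8); species are
#'   distributed evenly over levels.
#' @param log10_range numeric length-2: log10 of smallest/largest amount.
#'   Must span at least 4 orders of magnitude.
#' @param prefix id prefix.
#' @param ids,amounts alternatively, give explicit ids and amounts.
#' @return data.frame of class `spikein_panel` with columns `id`, `amount`
#'   (arbitrary but consistent units, e.g. amol or molecules per cell).
#' @examples
#' spikein_panel()
#' @export
spikein_panel <- function(n = 48, n_levels = 8, log10_range = c(0, 4.5),
                          prefix = "UPS", ids = NULL, amounts = NULL) {
  if (is.null(ids)) {
    stop_if(n_levels < 8, "panel needs >= 8 distinct amount levels")
    stop_if(diff(log10_range) < 4,
            "panel amounts must span >= 4 orders of magnitude")
    levels <- 10^seq(log10_range[1], log10_range[2], length.out = n_levels)
    amounts <- rep(levels, length.out = n)
    ids <- sprintf("%s%03d", prefix, seq_len(n))
  }
  stop_if(any(amounts <= 0), "spike-in amounts must be strictly positive")
  stop_if(anyDuplicated(ids) > 0, "spike-in ids must be unique")
  structure(
    data.frame(id = ids, amount = amounts, stringsAsFactors = FALSE),
    class = c("spikein_panel", "data.frame")
  )
}

#' Random synthetic genome
#'
#' Uniform-composition A/C/G/T chromosomes used as scaffold for synthetic
#' peaks, TADs and promoters.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length length of each chromosome in bp.
#' @param seed integer seed.
#' @return named character vector of chromosome sequences.
#' @export
synthetic_genome <- function(n_chrom = 4, chrom_length = 500000, seed = NULL) {
  stop_if(n_chrom < 1 || chrom_length < 1000, "genome too small")
  with_seed(seed, {
    setNames(
      vapply(seq_len(n_chrom), function(i) {
        paste(sample(c("A", "C", "G", "T"), chrom_length, replace = TRUE),
              collapse = "")
      }, ""),
      paste0("chr", seq_len(n_chrom))
    )
  })
}
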