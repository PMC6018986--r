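# Interval data.frames use BED conventions throughout: 0-based half-open
# [start, end). Conversion to 1-based closed IRanges happens only inside.

intervals_to_gr <- function(x) {
  validate_intervals(x)
  GenomicRanges::GRanges(
    x$chrom,
    IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Union of peak sets
#'
#' Merges overlapping or book-ended intervals across any number of peak sets
#' (e.g. ATAC plus each histone mark) into a single sorted set, retaining
#' which input sets contributed to each merged interval.
#'
#' @param ... interval data.frames (chrom/start/end, optional name), or a
#'   single list of them. Names of the arguments/list become provenance
#'   labels.
#' @return interval data.frame with columns `chrom`, `start`, `end`, `name`
#'   (`union%05d`) and `sources` (comma-separated contributing set labels),
#'   sorted by (chrom, start).
#' @examples
#' a <- data.frame(chrom = "chr1", start = 10, end = 20)
#' b <- data.frame(chrom = "chr1", start = 15, end = 30)
#' peak_union(atac = a, k27ac = b)
#' @export
peak_union <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.data.frame(sets[[1]]) == FALSE) {
    sets <- sets[[1]]
  }
  stop_if(length(sets) == 0, "no peak sets given")
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  grl <- lapply(sets, intervals_to_gr)
  all_gr <- suppressWarnings(do.call(c, unname(grl)))
  merged <- GenomicRanges::reduce(GenomicRanges::sort(all_gr))
  hit <- lapply(grl, function(g) {
    unique(S4Vectors::queryHits(GenomicRanges::findOverlaps(merged, g)))
  })
  sources <- vapply(seq_along(merged), function(i) {
    paste(names(sets)[vapply(hit, function(h) i %in% h, logical(1))],
          collapse = ",")
  }, "")
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = GenomicRanges::start(merged) - 1,
    end = GenomicRanges::end(merged),
    sources = sources,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out$name <- sprintf("union%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[c("chrom", "start", "end", "name", "sources")]
}

#' Extend intervals to a fixed width around their center
#'
#' Replaces each interval by `[center - width/2, center + width/2)` with
#' `center = floor((start + end) / 2)`, truncating at chromosome bounds
#' (clamping does not shift the window). Used to give broad histone marks a
#' uniform footprint before motif scanning.
#'
#' @param x interval data.frame.
#' @param width target width in bp.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return interval data.frame with adjusted start/end.
#' @export
extend_to_width <- function(x, width = 1000, chrom_sizes) {
  validate_intervals(x)
  stop_if(width <= 0, "width must be positive")
  stop_if(!all(x$chrom %in% names(chrom_sizes)),
          "chrom_sizes missing some chromosomes")
  center <- floor((x$start + x$end) / 2)
  x$start <- pmax(center - floor(width / 2), 0)
  x$end <- pmin(center + ceiling(width / 2),
                unname(chrom_sizes[x$chrom]))
  x
}

#' Nearest-TSS assignment (single-nearest-gene rule)
#'
#' Assigns each interval the gene whose TSS is closest to the interval
#' midpoint. Equidistant candidates are resolved deterministically: smaller
#' TSS coordinate first, then lexicographically smaller gene id.
#'
#' @param x interval data.frame.
#' @param tss data.frame with columns `gene`, `chrom`, `pos` (and optionally
#'   `strand`).
#' @return data.frame: interval `name` (or row index), `gene`, `distance`
#'   (bp, `|TSS - midpoint|`); intervals on chromosomes without any TSS get
#'   NA with a message.
#' @export
nearest_tss <- function(x, tss) {
  validate_intervals(x)
  stop_if(!all(c("gene", "chrom", "pos") %in% names(tss)),
          "tss needs columns gene, chrom, pos")
  mid <- floor((x$start + x$end) / 2)
  gene <- rep(NA_character_, nrow(x))
  dist <- rep(NA_real_, nrow(x))
  for (ch in unique(x$chrom)) {
    rows <- which(x$chrom == ch)
    tt <- tss[tss$chrom == ch, , drop = FALSE]
    if (nrow(tt) == 0) {
      message("no TSS on chromosome ", ch, "; ", length(rows),
              " interval(s) unassigned")
      next
    }
    # candidate order encodes the tie-break: position, then gene id
    tt <- tt[order(tt$pos, tt$gene), , drop = FALSE]
    pos <- tt$pos
    below <- findInterval(mid[rows], pos)   # last TSS with pos <= mid
    for (k in seq_along(rows)) {
      i <- rows[k]
      cand <- unique(pmin(pmax(c(below[k], below[k] + 1), 1), length(pos)))
      dd <- abs(pos[cand] - mid[i])
      best_d <- min(dd)
      # all genes at any position achieving best_d, in tie-break order
      at_best <- which(abs(pos - mid[i]) == best_d)
      gene[i] <- tt$gene[at_best[1]]
      dist[i] <- best_d
    }
  }
  data.frame(
    name = if (!is.null(x$name)) x$name else as.character(seq_len(nrow(x))),
    gene = gene,
    distance = dist,
    stringsAsFactors = FALSE
  )
}

#' Classify intervals as TSS-proximal or distal
#'
#' Labels an interval TSS-proximal iff its nearest-TSS distance is strictly
#' below `cutoff` (promoters vs enhancers at the conventional 500 bp).
#'
#' @inheritParams nearest_tss
#' @param cutoff distance cutoff in bp (strict inequality).
#' @return the [nearest_tss()] data.frame plus a `class` column with values
#'   `"TSS-proximal"` / `"distal"` (NA where unassigned).
#' @export
classify_promoter_proximal <- function(x, tss, cutoff = 500) {
  nt <- nearest_tss(x, tss)
  nt$class <- ifelse(is.na(nt$distance), NA_character_,
                     ifelse(nt$distance < cutoff, "TSS-proximal", "distal"))
  nt
}
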