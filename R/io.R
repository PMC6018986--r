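#' Read and write feature-by-sample matrices as TSV
#'
#' Matrices are stored with a header row of sample ids and the feature id in
#' the first column. Missing values are written as `NA`.
#'
#' @param path file path.
#' @param x numeric matrix with feature row names and sample column names.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  check_matrix(m, path)
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(x, path) {
  check_matrix(x)
  df <- data.frame(feature = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write BED intervals
#'
#' Intervals use BED conventions: 0-based half-open `[start, end)` coordinates,
#' columns chrom/start/end/name (BED3+name) with an optional strand column
#' (BED6, used for TSS tables).
#'
#' @param path file path.
#' @param x interval data.frame with columns `chrom`, `start`, `end` and
#'   optionally `name`, `score`, `strand`.
#' @return `read_bed` returns a data.frame with columns `chrom`, `start`,
#'   `end`, and `name`/`score`/`strand` when present in the file.
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  nc <- ncol(df)
  stop_if(nc < 3, "BED file must have at least 3 columns: ", path)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (nc >= 4) names(df)[4] <- "name"
  if (nc >= 5) names(df)[5] <- "score"
  if (nc >= 6) names(df)[6] <- "strand"
  validate_intervals(df, path)
  df
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: fill gaps so e.g. strand lands in column 6
  need <- c("chrom", "start", "end", "name", "score", "strand")
  upto <- max(match(cols, need))
  out <- x[need[seq_len(upto)]]
  if (!is.null(out$name) && anyNA(out$name)) out$name[is.na(out$name)] <- "."
  if (!is.null(out$score) && anyNA(out$score)) out$score[is.na(out$score)] <- 0
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

validate_intervals <- function(x, path = NULL) {
  stop_if(!is.data.frame(x) || !all(c("chrom", "start", "end") %in% names(x)),
          "intervals need columns chrom, start, end")
  bad <- which(!(x$start >= 0 & x$start < x$end))
  stop_if(length(bad) > 0,
          "malformed interval (need 0 <= start < end) at line ",
          bad[1], if (!is.null(path)) paste0(" of ", path))
  invisible(x)
}

#' Read and write spike-in panel tables
#'
#' Two-column TSV: spike-in id and known input amount (e.g. amol).
#'
#' @param path file path.
#' @param panel a `spikein_panel` data.frame with columns `id` and `amount`.
#' @return `read_spike_table` returns a [spikein_panel()]-shaped data.frame.
#' @export
read_spike_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stop_if(!all(c("id", "amount") %in% names(df)),
          "spike table needs columns 'id' and 'amount'")
  spikein_panel(ids = df$id, amounts = df$amount)
}

#' @rdname read_spike_table
#' @export
write_spike_table <- function(panel, path) {
  write.table(panel[c("id", "amount")], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    stop_if(length(f) < 3, "GMT line with fewer than 3 fields")
    unique(f[-(1:2)])
  })
  names(out) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a preranked list (RNK format)
#'
#' Two-column TSV without header: gene id and signed ranking metric.
#' The returned vector is sorted for [enrichment_score()]: metric decreasing,
#' ties broken by gene id (stable, ascending).
#'
#' @param path file path.
#' @return named numeric vector sorted by decreasing metric.
#' @export
read_rnk <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  rank_genes(setNames(df[[2]], df[[1]]))
}

#' @rdname read_rnk
#' @param metric named numeric vector (gene -> signed metric).
#' @export
write_rnk <- function(metric, path) {
  write.table(data.frame(names(metric), unname(metric)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genome as FASTA
#'
#' @param genome named character vector or list of A/C/G/T strings.
#' @param path output file.
#' @return `read_genome_fasta` returns a named character vector of sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}
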