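# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without clobbering the caller's RNG stream.
# seed = NULL leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed; keeps results < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_matrix <- function(x, what = "matrix") {
  stop_if(!is.matrix(x) || !is.numeric(x), what, " must be a numeric matrix")
  stop_if(is.null(rownames(x)) || anyDuplicated(rownames(x)) > 0,
          what, " must have unique row names (feature ids)")
  stop_if(is.null(colnames(x)) || anyDuplicated(colnames(x)) > 0,
          what, " must have unique column names (sample ids)")
  invisible(x)
}

# Match a design data.frame to matrix columns and return it in column order.
check_design <- function(design, x) {
  stop_if(!is.data.frame(design) ||
            !all(c("sample", "condition") %in% names(design)),
          "design must be a data.frame with columns 'sample' and 'condition'")
  stop_if(!all(colnames(x) %in% design$sample),
          "all matrix columns must appear in design$sample")
  design[match(colnames(x), design$sample), , drop = FALSE]
}

cond_cols <- function(design, condition) {
  design$sample[design$condition == condition]
}

geomean <- function(x) exp(mean(log(x)))
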