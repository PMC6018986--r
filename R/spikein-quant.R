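#' Spike-in calibration regression
#'
#' Ordinary least squares of log10 known amount on log10 measured intensity
#' for the spike-in species detected in one sample. The fitted affine map
#' converts any intensity on the same scale to an absolute amount.
#'
#' @param intensities named numeric vector of measured intensities for
#'   spike-in features (NA = not detected) in one sample, named by spike id.
#' @param panel a [spikein_panel()].
#' @return list of class `spikein_fit`: `slope`, `intercept`, `r_squared`,
#'   `n_spikes`. Predict absolute amounts with `predict(fit, intensities)`.
#' @examples
#' panel <- spikein_panel()
#' fit <- fit_spikein_regression(setNames(panel$amount, panel$id), panel)
#' c(fit$slope, fit$intercept)   # identity calibration: 1, 0
#' @export
fit_spikein_regression <- function(intensities, panel) {
  common <- intersect(names(intensities)[!is.na(intensities) &
                                           intensities > 0], panel$id)
  stop_if(length(common) < 5,
          "need >= 5 detected spike-ins, got ", length(common))
  amt <- panel$amount[match(common, panel$id)]
  stop_if(diff(range(log10(amt))) < 2,
          "detected spike-in amounts must span >= 2 orders of magnitude")
  fit <- lm(log10(amt) ~ log10(intensities[common]))
  slope <- unname(coef(fit)[2])
  if (slope <= 0) warning("spike-in calibration failure: slope <= 0")
  structure(
    list(slope = slope, intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n_spikes = length(common)),
    class = "spikein_fit"
  )
}

#' @param object a `spikein_fit`.
#' @param newdata numeric vector of intensities.
#' @param ... unused.
#' @rdname fit_spikein_regression
#' @export
predict.spikein_fit <- function(object, newdata, ...) {
  out <- 10^(object$intercept + object$slope * log10(newdata))
  out[!is.finite(out)] <- NA
  out
}

#' @export
print.spikein_fit <- function(x, ...) {
  cat(sprintf(
    "spike-in calibration: log10(amount) = %.3f + %.3f * log10(intensity)",
    x$intercept, x$slope),
    sprintf("(R^2 = %.4f, n = %d)\n", x$r_squared, x$n_spikes))
  invisible(x)
}

#' Two-stage absolute protein quantification
#'
#' Stage 1 calibrates the unfractionated run against the spike-in panel with
#' [fit_spikein_regression()], converting its intensities to absolute
#' abundances. Stage 2 regresses (per sample, log10-log10 OLS) those stage-1
#' abundances on the intensities of the same features in the deep
#' fractionated run and applies the map to every fractionated feature. A
#' feature detected only in the unfractionated run keeps its stage-1
#' abundance, so the table covers the union of the two runs; the
#' `provenance` attribute records which stage produced each value. Any
#' common multiplicative rescaling of a sample's intensities is absorbed by
#' the regression intercepts, so copy numbers are invariant to per-sample
#' gain.
#'
#' @param unfractionated intensity matrix carrying the spike-in rows.
#' @param fractionated deep intensity matrix to be quantified.
#' @param panel protein [spikein_panel()].
#' @param min_overlap minimum shared features required for stage 2.
#' @return copy-number matrix (features x samples, panel amount units) over
#'   the union of endogenous features of both runs, with attributes
#'   `calibration` (per-sample list of stage-1 and stage-2
#'   slope/intercept/R^2) and `provenance` (character matrix: "stage2",
#'   "stage1" or NA per value).
#' @export
absolute_quant_two_stage <- function(unfractionated, fractionated, panel,
                                     min_overlap = 50) {
  check_matrix(unfractionated, "unfractionated")
  check_matrix(fractionated, "fractionated")
  stop_if(!identical(colnames(unfractionated), colnames(fractionated)),
          "the two runs must have identical sample columns")
  endo_f <- setdiff(rownames(fractionated), panel$id)
  endo_u <- setdiff(rownames(unfractionated), panel$id)
  endo <- union(endo_f, endo_u)
  out <- matrix(NA_real_, length(endo), ncol(fractionated),
                dimnames = list(endo, colnames(fractionated)))
  prov <- matrix(NA_character_, length(endo), ncol(fractionated),
                 dimnames = dimnames(out))
  calib <- vector("list", ncol(fractionated))
  names(calib) <- colnames(fractionated)
  for (s in colnames(fractionated)) {
    fit1 <- fit_spikein_regression(unfractionated[, s], panel)
    stage1 <- predict(fit1, unfractionated[endo_u, s])
    shared <- intersect(names(stage1)[!is.na(stage1)],
                        endo_f[!is.na(fractionated[endo_f, s]) &
                                 fractionated[endo_f, s] > 0])
    stop_if(length(shared) < min_overlap,
            "stage 2 needs >= ", min_overlap, " shared features in sample ",
            s, ", got ", length(shared))
    fit2 <- lm(log10(stage1[shared]) ~ log10(fractionated[shared, s]))
    r2 <- summary(fit2)$r.squared
    if (r2 < 0.5) {
      warning("stage-2 calibration R^2 < 0.5 in sample ", s,
              " (", signif(r2, 3), "); result returned anyway")
    }
    pred <- 10^(coef(fit2)[1] +
                  coef(fit2)[2] * log10(fractionated[endo_f, s]))
    pred[!is.finite(pred)] <- NA
    out[endo_f, s] <- pred
    prov[endo_f, s][!is.na(pred)] <- "stage2"
    # fall back to the directly calibrated unfractionated measurement where
    # the deep run did not observe the feature
    fill <- endo_u[!is.na(stage1) & is.na(out[endo_u, s])]
    out[fill, s] <- stage1[fill]
    prov[fill, s] <- "stage1"
    calib[[s]] <- list(
      stage1 = fit1[c("slope", "intercept", "r_squared", "n_spikes")],
      stage2 = list(slope = unname(coef(fit2)[2]),
                    intercept = unname(coef(fit2)[1]), r_squared = r2,
                    n_shared = length(shared))
    )
  }
  attr(out, "calibration") <- calib
  attr(out, "provenance") <- prov
  out
}

#' Absolute mRNA quantification against an RNA spike-in panel
#'
#' Single-stage per-sample log10-log10 OLS of known spike-in input amounts on
#' their read counts, applied to all features. Zero-count features are
#' reported as missing (their abundance is below the detection floor, not
#' zero).
#'
#' @param counts count matrix including the spike-in rows.
#' @param ercc_panel RNA [spikein_panel()].
#' @return copy-number matrix (features x samples, panel amount units) with
#'   attribute `calibration` (per-sample slope/intercept/R^2).
#' @export
mrna_absolute_quant <- function(counts, ercc_panel) {
  check_matrix(counts, "counts")
  endo <- setdiff(rownames(counts), ercc_panel$id)
  out <- matrix(NA_real_, length(endo), ncol(counts),
                dimnames = list(endo, colnames(counts)))
  calib <- vector("list", ncol(counts))
  names(calib) <- colnames(counts)
  for (s in colnames(counts)) {
    fit <- fit_spikein_regression(counts[, s], ercc_panel)
    v <- counts[endo, s]
    v[v <= 0] <- NA
    out[, s] <- predict(fit, v)
    calib[[s]] <- fit[c("slope", "intercept", "r_squared", "n_spikes")]
  }
  attr(out, "calibration") <- calib
  out
}
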