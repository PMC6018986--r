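test_that("spike-in regression recovers exact affine calibrations", {
  panel <- spikein_panel(n = 8, n_levels = 8, log10_range = c(0, 4.2))
  # identity: intensity == amount
  fit <- fit_spikein_regression(setNames(panel$amount, panel$id), panel)
  expect_equal(fit$slope, 1, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # amount = intensity / 10 on every point: slope 1, intercept -1 (log10)
  fit2 <- fit_spikein_regression(setNames(panel$amount * 10, panel$id), panel)
  expect_equal(fit2$slope, 1, tolerance = 1e-10)
  expect_equal(fit2$intercept, -1, tolerance = 1e-10)
  # gain 50: recovered amounts equal truth to < 1e-9 relative error
  fit3 <- fit_spikein_regression(setNames(panel$amount * 50, panel$id), panel)
  rec <- predict(fit3, panel$amount * 50)
  expect_lt(max(abs(rec - panel$amount) / panel$amount), 1e-9)
})

test_that("spike-in regression enforces its preconditions", {
  panel <- spikein_panel(n = 8, n_levels = 8, log10_range = c(0, 4.2))
  few <- setNames(c(10, 20, 30, NA, NA, NA, NA, NA), panel$id)
  expect_error(fit_spikein_regression(few, panel), ">= 5")
  # negative relation -> calibration failure flagged
  expect_warning(
    fit_spikein_regression(setNames(rev(panel$amount), panel$id), panel),
    "slope")
})

test_that("two-stage quantification is invariant to run-level rescaling", {
  sim <- simulate_expression(n_features = 150, noise_cv = 0.1,
                             missing_rate = 0, seed = 8)
  same <- absolute_quant_two_stage(sim$protein_unfrac, sim$protein_unfrac,
                                   sim$spike_panel)
  tripled <- absolute_quant_two_stage(sim$protein_unfrac,
                                      3 * sim$protein_unfrac,
                                      sim$spike_panel)
  expect_equal(same, tripled, tolerance = 1e-8, ignore_attr = TRUE)
  # stage 2 on the identical matrix is the identity map
  cal <- attr(same, "calibration")
  expect_equal(cal[[1]]$stage2$r_squared, 1, tolerance = 1e-10)
})

test_that("noiseless synthetic study is recovered exactly in both layers", {
  sim <- simulate_expression(n_features = 120, noise_cv = 0, missing_rate = 0,
                             seed = 4)
  prot <- absolute_quant_two_stage(sim$protein_unfrac, sim$protein_frac,
                                   sim$spike_panel)
  truth <- sim$truth$true_protein_copies
  for (s in colnames(prot)) {
    cc <- sim$design$condition[sim$design$sample == s]
    expect_equal(unname(prot[rownames(truth), s]), unname(truth[, cc]),
                 tolerance = 1e-6)
  }
  mr <- mrna_absolute_quant(sim$counts, sim$ercc_panel)
  mtruth <- sim$truth$true_mrna_copies
  for (s in colnames(mr)) {
    cc <- sim$design$condition[sim$design$sample == s]
    expect_equal(unname(mr[rownames(mtruth), s]), unname(mtruth[, cc]),
                 tolerance = 1e-6)
  }
})

test_that("zero counts quantify as missing, never as zero copies", {
  sim <- simulate_expression(n_features = 100, noise_cv = 0, missing_rate = 0,
                             count_per_copy = 1, seed = 5)
  counts <- sim$counts
  counts["gene00001", ] <- 0
  mr <- mrna_absolute_quant(counts, sim$ercc_panel)
  expect_true(all(is.na(mr["gene00001", ])))
  expect_false(anyNA(mr["gene00002", ]))
})

test_that("noisy mRNA quantification keeps median relative error under 25%", {
  sim <- simulate_expression(n_features = 1000, seed = 17)
  mr <- mrna_absolute_quant(sim$counts, sim$ercc_panel)
  truth <- sim$truth$true_mrna_copies
  err <- unlist(lapply(colnames(mr), function(s) {
    cc <- sim$design$condition[sim$design$sample == s]
    abs(mr[rownames(truth), s] - truth[, cc]) / truth[, cc]
  }))
  expect_lt(median(err, na.rm = TRUE), 0.25)
})

test_that("protein_per_mrna takes the median over all replicate pairs", {
  d <- tiny_design()
  p <- matrix(100, 2, 6, dimnames = list(c("g1", "g2"), d$sample))
  m <- matrix(10, 2, 6, dimnames = dimnames(p))
  expect_equal(protein_per_mrna(p, m, d, "A")$ratio, c(10, 10))
  # hand-enumerated 2x2 case: pairs {10, 90/11, 110/9, 10} -> median 10
  d2 <- sample_design(conditions = c("A", "B"), replicates = 2)
  p2 <- matrix(c(90, 110), 1, 4, dimnames = list("g1", d2$sample))
  m2 <- matrix(c(9, 11), 1, 4, dimnames = list("g1", d2$sample))
  expect_equal(protein_per_mrna(p2, m2, d2, "A")$ratio, 10)
  expect_equal(protein_per_mrna(p2, m2, d2, "A")$n_pairs, 4L)
  # replicate order never matters
  perm <- c("A_3", "A_1", "A_2", "B_1", "B_2", "B_3")
  p3 <- matrix(c(5, 50, 500, 1, 1, 1), 1, 6,
               dimnames = list("g1", d$sample))
  m3 <- matrix(c(2, 3, 4, 1, 1, 1), 1, 6, dimnames = list("g1", d$sample))
  expect_equal(protein_per_mrna(p3, m3, d, "A")$ratio,
               protein_per_mrna(p3[, perm, drop = FALSE],
                                m3[, perm, drop = FALSE], d, "A")$ratio)
})

test_that("swapping the layers gives the reciprocal pairwise-ratio median", {
  d2 <- sample_design(conditions = c("A", "B"), replicates = 2)
  p <- matrix(c(90, 110), 1, 4, dimnames = list("g1", d2$sample))
  m <- matrix(c(9, 11), 1, 4, dimnames = list("g1", d2$sample))
  fwd <- protein_per_mrna(p, m, d2, "A")$ratio
  swp <- protein_per_mrna(m, p, d2, "A")$ratio
  # median commutes with the reciprocal for an even pair count only through
  # the log scale; the pairwise medians are exact reciprocals here
  expect_equal(swp, 1 / fwd)
})

test_that("ratio change test handles degenerate and null inputs correctly", {
  d <- tiny_design()
  p <- matrix(exp(rnorm(300 * 6)), 300, 6,
              dimnames = list(sprintf("g%03d", 1:300), d$sample))
  m <- matrix(exp(rnorm(300 * 6)), 300, 6, dimnames = dimnames(p))
  ra <- pairwise_log_ratios(p, m, d, "A")
  rb <- pairwise_log_ratios(p, m, d, "B")
  # identical ratio sets -> statistic 0, p 1
  same <- ratio_change_test(ra, ra)
  expect_true(all(same$statistic == 0))
  expect_true(all(same$p_value == 1))
  # df counts biological replicates across layers, never the 9 + 9 pairs
  res <- ratio_change_test(ra, rb)
  expect_true(all(res$df == 8))
  expect_lt(max(res$df), 16)
  # constant ratios in both groups are skipped, not scored
  pc <- matrix(2, 3, 6, dimnames = list(c("g1", "g2", "g3"), d$sample))
  mc <- matrix(1, 3, 6, dimnames = dimnames(pc))
  expect_message(
    rc <- ratio_change_test(pairwise_log_ratios(pc, mc, d, "A"),
                            pairwise_log_ratios(pc, mc, d, "B")),
    "zero variance")
  expect_true(all(is.na(rc$statistic)))
})

test_that("the significance filter demands both arms in the same direction", {
  mk <- function(fc, fdr) {
    data.frame(feature = paste0("g", seq_along(fc)),
               log2_ratio_fc = log2(abs(fc)) * sign(fc),
               statistic = 1, df = 8, p_value = fdr, fdr = fdr,
               stringsAsFactors = FALSE)
  }
  # g1: FC 4 in one arm but 2 in the other -> fails; g2: 5 & 4 -> flagged;
  # g3: strong but opposite directions -> fails
  a <- mk(c(4, 5, 8), c(0.01, 0.01, 0.001))
  b <- mk(c(2, 4, -8), c(0.01, 0.02, 0.001))
  expect_equal(ratio_significance_filter(a, b), "g2")
})

test_that("global translation test matches the Fisher transform", {
  d <- tiny_design()
  set.seed(42)
  r <- exp(rnorm(200))
  p <- r * matrix(exp(rnorm(200 * 6, 0, 0.3)), 200, 6,
                  dimnames = list(sprintf("g%03d", 1:200), d$sample))
  m <- matrix(exp(rnorm(200 * 6, 0, 0.3)), 200, 6, dimnames = dimnames(p))
  ra <- replicate_log_ratios(p, m, d, "A")
  rb <- replicate_log_ratios(p, m, d, "B")
  out <- global_translation_test(ra, rb)
  expect_equal(out$z_within[1], atanh(cor(ra[, 1], ra[, 2])))
  expect_length(out$z_within, 6)    # 3 within A + 3 within B
  expect_length(out$z_between, 9)
  expect_equal(atanh(0.5), 0.5493061, tolerance = 1e-6)
})
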