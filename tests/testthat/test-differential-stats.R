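test_that("presence filter keeps features complete in at least one condition", {
  d <- tiny_design()
  m <- matrix(1, 4, 6, dimnames = list(paste0("g", 1:4), d$sample))
  m["g2", c("B_1", "B_2", "B_3")] <- NA         # complete in A only -> kept
  m["g3", c("A_1", "B_2")] <- NA                # 2/3 everywhere -> dropped
  m["g4", c("A_1", "A_2", "A_3", "B_1")] <- NA  # complete nowhere -> dropped
  out <- presence_filter(m, d)
  expect_setequal(rownames(out), c("g1", "g2"))
  # fully observed matrix passes through unchanged
  full <- matrix(rnorm(12), 2, 6, dimnames = list(c("x", "y"), d$sample))
  expect_identical(presence_filter(full, d), full)
})

test_that("detection-limit imputation is seeded and below the observed range", {
  d <- tiny_design()
  m <- matrix(rnorm(600, 20, 2), 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), d$sample))
  expect_identical(detection_limit_impute(m, seed = 1), m)  # nothing missing
  # hard detection-limit censoring, the regime the downshifted Gaussian is
  # designed for: everything under the per-sample 20% quantile is missing
  set.seed(31)
  lg <- matrix(rnorm(500 * 40, 20, 1), 500, 40,
               dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:40)))
  lg[sweep(lg, 2, apply(lg, 2, quantile, 0.2), `<`)] <- NA
  imp1 <- detection_limit_impute(lg, seed = 99)
  imp2 <- detection_limit_impute(lg, seed = 99)
  expect_identical(imp1, imp2)
  expect_false(anyNA(imp1))
  below_q01 <- vapply(colnames(lg), function(s) {
    obs <- lg[!is.na(lg[, s]), s]
    filled <- imp1[is.na(lg[, s]), s]
    mean(filled) < quantile(obs, 0.01)
  }, logical(1))
  expect_gte(mean(below_q01), 0.95)
  # refuses a sample with almost nothing observed
  tiny <- matrix(NA_real_, 20, 6, dimnames = list(paste0("g", 1:20), d$sample))
  tiny[1:5, ] <- 1
  expect_error(detection_limit_impute(tiny, seed = 1), "refusing")
})

test_that("permutation t-test statistics behave under s0, label swap and order", {
  d <- tiny_design()
  set.seed(10)
  m <- matrix(rnorm(1200, 10), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), d$sample))
  ga <- paste0("A_", 1:3); gb <- paste0("B_", 1:3)
  res <- permutation_fdr_ttest(m, ga, gb, seed = 1)
  # s0 -> infinity kills every statistic
  big <- permutation_fdr_ttest(m, ga, gb, s0 = 1e9, seed = 1)
  expect_lt(max(abs(big$stat)), 1e-6)
  expect_equal(sum(big$q < 0.05), 0)
  # swapping groups negates statistics, q unchanged
  swp <- permutation_fdr_ttest(m, gb, ga, seed = 1)
  expect_equal(swp$stat, -res$stat)
  expect_equal(swp$q, res$q)
  # feature order does not matter
  perm <- sample(nrow(m))
  shuf <- permutation_fdr_ttest(m[perm, ], ga, gb, seed = 1)
  expect_equal(shuf$q[match(res$feature, shuf$feature)], res$q)
  expect_true(all(res$q >= 0 & res$q <= 1))
})

test_that("planted 4-fold shifts are recovered at q < 0.05", {
  d <- tiny_design()
  set.seed(77)
  sd_log2 <- sqrt(log(1 + 0.2^2)) / log(2)   # noise_cv 0.2 on the log2 scale
  m <- rnorm(1000, 10, 1) +                  # per-feature baseline
    matrix(rnorm(1000 * 6, 0, sd_log2), 1000, 6)
  dimnames(m) <- list(sprintf("g%04d", 1:1000), d$sample)
  planted <- sprintf("g%04d", 1:100)
  m[planted, 1:3] <- m[planted, 1:3] + 2     # 4-fold on the log2 scale
  res <- permutation_fdr_ttest(m, paste0("A_", 1:3), paste0("B_", 1:3),
                               seed = 3)
  sens <- mean(res$q[match(planted, res$feature)] < 0.05)
  expect_gte(sens, 0.8)
})

test_that("count fold changes follow median-of-ratios and the pseudocount", {
  d2 <- sample_design(conditions = c("A", "B"), replicates = 3)
  # hand case: one changing feature among constant ones keeps size factors 1
  counts <- rbind(f1 = c(16, 16, 16, 4, 4, 4),
                  f2 = rep(100, 6),
                  f3 = rep(50, 6),
                  f4 = rep(8, 6))
  colnames(counts) <- d2$sample
  fc <- count_fold_changes(counts, d2, c("A", "B"), prior_count = 1,
                           seed = 1)
  expect_equal(unname(attr(fc, "size_factors")), rep(1, 6))
  expect_equal(fc$log2fc[fc$feature == "f1"], log2(17 / 5), tolerance = 1e-10)
  expect_equal(fc$log2fc[fc$feature == "f2"], 0)
  # doubling one sample's counts doubles its size factor relative to the
  # others (size factors are defined up to a common scale) and leaves the
  # fold changes exactly unchanged when prior_count = 0
  counts2 <- counts
  counts2[, 1] <- counts2[, 1] * 2
  fc2 <- count_fold_changes(counts2, d2, c("A", "B"), prior_count = 0,
                            seed = 1)
  fc0 <- count_fold_changes(counts, d2, c("A", "B"), prior_count = 0,
                            seed = 1)
  sf2 <- attr(fc2, "size_factors"); sf0 <- attr(fc0, "size_factors")
  expect_equal(unname(sf2[1] / sf2[2]), unname(2 * sf0[1] / sf0[2]),
               tolerance = 1e-12)
  expect_equal(fc2$log2fc, fc0$log2fc, tolerance = 1e-12)
  # prior_count -> infinity shrinks every fold change to 0
  fcinf <- count_fold_changes(counts, d2, c("A", "B"), prior_count = 1e12,
                              seed = 1)
  expect_lt(max(abs(fcinf$log2fc)), 1e-6)
  # all-zero sample is rejected
  bad <- counts; bad[, 1] <- 0
  expect_error(count_fold_changes(bad, d2, c("A", "B")), "all-zero")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  counts <- matrix(rnbinom(500 * 6, mu = 150, size = 10) + 1, 500, 6,
                   dimnames = list(sprintf("g%03d", 1:500), paste0("s", 1:6)))
  ours <- median_of_ratios_size_factors(counts)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("signature correlation matches the textbook Pearson computation", {
  x <- matrix(c(1, 2, 3, 4, 5), 5, 1, dimnames = list(paste0("g", 1:5), "sx"))
  y <- matrix(c(2, 4, 5, 4, 5), 5, 1, dimnames = list(paste0("g", 1:5), "sy"))
  r <- signature_correlation(x, y, paste0("g", 1:5))
  expect_equal(unname(r[1, 1]), 0.7746, tolerance = 1e-4)
  expect_equal(unname(signature_correlation(x, -x, paste0("g", 1:5))[1, 1]),
               -1)
  expect_equal(unname(diag(signature_correlation(cbind(x, y), cbind(x, y),
                                                 paste0("g", 1:5)))),
               c(1, 1))
  # constant vector -> NA, not an error
  cst <- matrix(1, 5, 1, dimnames = list(paste0("g", 1:5), "sc"))
  expect_true(is.na(signature_correlation(x, cst, paste0("g", 1:5))[1, 1]))
  expect_error(signature_correlation(x, y, c("g1", "g2")), ">= 3")
})
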