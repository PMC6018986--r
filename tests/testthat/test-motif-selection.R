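test_that("best-match scanning agrees exactly with exhaustive enumeration", {
  set.seed(3)
  # uniform PWM on uniform background scores 0 everywhere
  flat <- new_pwm("flat", matrix(0.25, 4, 6))
  expect_equal(scan_best_match("ACGTACGTACGTACGT", flat), 0, tolerance = 1e-12)
  # strand symmetry: a sequence and its reverse complement score identically
  p <- random_pwm("m", 8)
  s <- rand_seqs(1, c(40, 40))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(scan_best_match(s, p), scan_best_match(rc, p),
               tolerance = 1e-10)
  # 50 random (sequence, PWM) pairs against the brute-force oracle
  for (i in 1:50) {
    pw <- random_pwm(paste0("m", i), sample(4:10, 1))
    sq <- rand_seqs(1)
    expect_equal(scan_best_match(sq, pw), oracle_scan(sq, pw),
                 tolerance = 1e-9)
  }
  # shorter than the motif -> missing
  expect_true(is.na(scan_best_match("ACG", random_pwm("x", 8))))
})

test_that("appending a consensus site never lowers the best-match score", {
  set.seed(4)
  for (i in 1:10) {
    p <- random_pwm(paste0("m", i), 9)
    cons <- paste(c("A", "C", "G", "T")[apply(p$mat, 2, which.max)],
                  collapse = "")
    s <- rand_seqs(1)
    expect_gte(scan_best_match(paste0(s, cons), p), scan_best_match(s, p))
  }
})

test_that("motif score matrices are normalized per motif with raw retained", {
  set.seed(6)
  seqs <- setNames(rand_seqs(30, c(50, 50)), paste0("p", 1:30))
  motifs <- list(a = random_pwm("a", 6), b = random_pwm("b", 8))
  sc <- motif_score_matrix(seqs, motifs)
  expect_equal(dim(sc), c(30, 2))
  expect_true(all(sc >= 0 & sc <= 1))
  expect_true(any(sc == 0) && any(sc == 1))
  raw <- attr(sc, "raw")
  expect_equal(order(raw[, "a"]), order(sc[, "a"]))
})

test_that("TF expression filtering keeps motifs with a significant linked TF", {
  map <- data.frame(motif = c("m1", "m2", "m3", "m3", "m4"),
                    tf = c("t1", "t2", "t3a", "t3b", "t_unscored"),
                    stringsAsFactors = FALSE)
  diffres <- data.frame(feature = c("t1", "t2", "t3a", "t3b"),
                        q = c(0.005, 0.01, 0.5, 0.002),
                        log2fc = c(2, 1, 0.2, -3), stringsAsFactors = FALSE)
  expect_message(kept <- filter_motifs_by_tf_dynamics(map, diffres),
                 "without a scored TF")
  expect_setequal(kept, c("m1", "m3"))   # q = 0.01 exactly is dropped
})

test_that("TF labelling picks minimum q, then |log2fc|, then the name", {
  map <- data.frame(motif = "m", tf = c("t1", "t2", "t3"),
                    stringsAsFactors = FALSE)
  diffres <- data.frame(feature = c("t1", "t2", "t3"),
                        q = c(0.2, 1e-6, 1e-6),
                        log2fc = c(1, 1, 3), stringsAsFactors = FALSE)
  expect_equal(label_tf("m", map, diffres), "t3")
  diffres$q <- c(0.2, 1e-6, 0.5)
  expect_equal(label_tf("m", map, diffres), "t2")
  expect_true(is.na(label_tf("m", map[0, ], diffres)))
})

test_that("LASSO pre-selection finds a planted linear signal", {
  set.seed(9)
  x <- matrix(runif(500 * 21), 500, 21,
              dimnames = list(NULL, paste0("m", 1:21)))
  y <- 2 * x[, 1]
  expect_equal(lasso_preselect(x, y, seed = 2), "m1")
  # degenerate constant response selects nothing
  expect_equal(lasso_preselect(x, rep(1, 500), seed = 2), character())
  expect_error(lasso_preselect(x[1:20, ], y[1:20]), "fold")
})

test_that("LASSO matches soft-thresholded OLS on an orthonormal design", {
  set.seed(14)
  n <- 200; p <- 8
  q <- qr.Q(qr(matrix(rnorm(n * p), n, p)))
  x <- q * sqrt(n)                       # columns with unit variance, X'X = nI
  colnames(x) <- paste0("m", 1:p)
  beta <- c(3, -2, 1.5, rep(0, p - 3))
  y <- drop(x %*% beta) + rnorm(n, 0, 0.5)
  fit <- glmnet::glmnet(x, y, standardize = FALSE, intercept = FALSE,
                        thresh = 1e-14)
  lam <- fit$lambda[10]
  got <- as.numeric(coef(fit, s = lam, exact = FALSE))[-1]
  ols <- drop(crossprod(x, y)) / n
  soft <- sign(ols) * pmax(abs(ols) - lam, 0)
  expect_equal(got, unname(soft), tolerance = 1e-6)
})

test_that("a response driven by one motif selects that motif first", {
  set.seed(15)
  x <- matrix(runif(600 * 5), 600, 5, dimnames = list(NULL, paste0("m", 1:5)))
  y <- x[, 3]^2                          # monotone in motif 3 alone
  sel <- iterative_rf_select(x, y, n_trees = 300, seed = 4)
  expect_equal(sel$motif[1], "m3")
  expect_equal(which.max(c(sel$pct_inc_mse[1], 0)), 1L)
  expect_gt(sel$single_r2[1], 0)
})

test_that("stability selection intersects repeats and reports counts", {
  set.seed(16)
  x <- matrix(runif(500 * 6), 500, 6, dimnames = list(NULL, paste0("m", 1:6)))
  y <- 3 * x[, 2] + rnorm(500, 0, 0.3)
  sel <- stability_select(x, y, repeats = 3, n_trees = 300, seed = 21)
  expect_s3_class(sel, "selection_result")
  expect_true("m2" %in% sel$motif[sel$selected])
  expect_true(all(sel$selected == (sel$stability == 3)))
  # repeats = 1 equals that single run
  one <- stability_select(x, y, repeats = 1, n_trees = 300, seed = 21)
  pre <- lasso_preselect(x, y, seed = orgdriver:::child_seed(21, 1))
  single <- iterative_rf_select(x[, pre, drop = FALSE], y, n_trees = 300,
                                seed = orgdriver:::child_seed(21, 1))
  expect_setequal(one$motif[one$selected], single$motif)
})

test_that("duplicating a decoy cannot displace the driver", {
  la <- simulate_regulatory_landscape(n_peaks = 800, n_motifs = 8,
                                      n_tads = 80, n_genes = 100, seed = 61)
  fc <- count_fold_changes(la$peak_counts, la$design, c("EN", "ENR"),
                           seed = 62)
  sig <- !is.na(fc$q) & fc$q < 0.05
  sp <- la$peaks[match(fc$feature[sig], la$peaks$name), ]
  sc <- motif_score_matrix(interval_sequences(la$genome, sp), la$motifs)
  sc2 <- cbind(sc, M002_copy = sc[, "M002"])
  sel <- stability_select(sc2, fc$log2fc[sig], repeats = 3, n_trees = 300,
                          seed = 63)
  expect_true(la$truth$driver_motif_id %in% sel$motif[sel$selected])
})

test_that("score/fold-change correlation flags undefined cases", {
  expect_message(r <- motif_fc_correlation(rep(1, 50), rnorm(50)),
                 "undefined")
  expect_true(is.na(r))
  set.seed(2)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100, 0, 0.1)
  expect_equal(motif_fc_correlation(x, y), cor(x, y))
})

test_that("promoter scanning recovers the planted motif fraction", {
  la <- simulate_regulatory_landscape(n_peaks = 600, n_motifs = 4,
                                      n_tads = 60, n_genes = 400, seed = 71)
  drv <- la$motifs[[la$truth$driver_motif_id]]
  thr <- consensus_score(drv) - 2
  pf <- promoter_motif_fraction(la$truth$up_genes, la$tss, la$genome, drv,
                                thr, flank = la$truth$promoter_halfwidth)
  expect_gt(pf, 0.5)
  expect_lt(pf, 0.7)
  # degenerate thresholds and inputs
  expect_equal(promoter_motif_fraction(la$truth$up_genes, la$tss, la$genome,
                                       drv, -Inf,
                                       flank = la$truth$promoter_halfwidth),
               1)
  expect_equal(promoter_motif_fraction(la$truth$up_genes, la$tss, la$genome,
                                       drv, Inf,
                                       flank = la$truth$promoter_halfwidth),
               0)
  expect_warning(out <- promoter_motif_fraction(character(), la$tss,
                                                la$genome, drv, thr),
                 "empty")
  expect_true(is.na(out))
})
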