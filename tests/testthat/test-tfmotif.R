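test_that("recovery AUC integrates the step curve with top-packed normalization", {
  expr <- setNames(10:1, paste0("g", 1:10))
  # regulon genes at ranks 1 and 3, top_frac 0.5 -> 5 ranks considered:
  # cumulative counts (1,1,2,2,2) sum 8; best packing (1,2,2,2,2) sum 9
  expect_equal(recovery_auc(expr, c("g1", "g3"), top_frac = 0.5), 8 / 9)
  # all regulon genes at the top -> 1; none in the top fraction -> 0
  expect_equal(recovery_auc(expr, c("g1", "g2"), top_frac = 0.5), 1)
  expect_equal(recovery_auc(expr, c("g9", "g10"), top_frac = 0.5), 0)
  expect_error(recovery_auc(expr, c("absent"), top_frac = 0.5), "empty regulon")
  # invariant to monotone transformation of expression
  set.seed(2)
  e2 <- setNames(rnorm(40), paste0("g", 1:40))
  reg <- paste0("g", sample(40, 8))
  expect_equal(recovery_auc(e2, reg, 0.2), recovery_auc(exp(e2), reg, 0.2))
  expect_equal(recovery_auc(e2, reg, 0.2),
               recovery_auc(rank(e2) + 100, reg, 0.2))
})

test_that("regulon AUC matrix agrees with the per-cell computation", {
  set.seed(8)
  ge <- matrix(rexp(50 * 6), 50, 6,
               dimnames = list(paste0("g", 1:50), paste0("c", 1:6)))
  regs <- list(R1 = list(tf_name = "R1", targets = paste0("g", 1:12)),
               R2 = list(tf_name = "R2", targets = paste0("g", 30:45)))
  auc <- regulon_auc_matrix(ge, regs, top_frac = 0.2)
  for (cc in 1:6) for (rr in 1:2)
    expect_equal(auc[rr, cc],
                 recovery_auc(ge[, cc], regs[[rr]], top_frac = 0.2))
})

test_that("activity binarization separates clean mixtures and flags outliers", {
  set.seed(4)
  auc <- c(rnorm(60, 0.1, 0.02), rnorm(40, 0.8, 0.02))
  b <- binarize_activity(auc)
  expect_gt(b$threshold, 0.2)
  expect_lt(b$threshold, 0.7)
  expect_equal(b$active, rep(c(0L, 1L), c(60, 40)))
  # constant row: fallback, all inactive, warning
  expect_warning(b0 <- binarize_activity(rep(0.5, 20)), "constant")
  expect_equal(sum(b0$active), 0L)
  # single outlier: only the outlier is called active
  x <- c(rep(0.1, 29), 0.9)
  b1 <- binarize_activity(x)
  expect_equal(which(b1$active == 1L), 30L)
})

test_that("PWM max score is the sum of positionwise log-odds maxima", {
  pfm <- write_lines_tmp(c(">M1", "10", "0", "0", "0"), ".pfm")
  rec <- suppressWarnings(read_jaspar_pfm(pfm, pseudocount = 1))[[1]]
  expect_equal(pwm_max_score(rec), log2((11 / 14) / 0.25))
  # uniform PWM scores 0 everywhere
  unif <- consensus_pwm("U", "A", hit = 5, miss = 5, pseudo = 0)
  expect_equal(pwm_max_score(unif), 0)
  # max dominates every enumerated k-mer, k <= 6
  pwm <- consensus_pwm("T1", "ACGTAC")
  kmers <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), 6))
  lo <- log2(pwm$matrix / 0.25)
  scores <- apply(kmers, 1, function(km)
    sum(lo[cbind(match(km, c("A", "C", "G", "T")), 1:6)]))
  expect_equal(max(scores), pwm_max_score(pwm), tolerance = 1e-12)
  expect_true(all(scores <= pwm_max_score(pwm) + 1e-12))
  zerop <- consensus_pwm("Z", "AC", pseudo = 0, miss = 0)
  expect_error(pwm_max_score(zerop), "zero probability")
})

test_that("peak scanning finds planted consensus on both strands", {
  pwm <- consensus_pwm("T1", "ACGTACGTACGT")
  bg <- random_dna(200, seed = 31)
  planted <- paste0(substr(bg, 1, 80), "ACGTACGTACGT", substr(bg, 93, 200))
  hits <- scan_peak(planted, pwm)
  expect_true(any(hits$offset == 80 & hits$strand == "+"))
  expect_equal(max(hits$score_fraction), 1)
  # reverse-complemented consensus hits on the minus strand
  planted_rc <- paste0(substr(bg, 1, 80), revcomp_chr("ACGTACGTACGT"),
                       substr(bg, 93, 200))
  hits_rc <- scan_peak(planted_rc, pwm)
  expect_true(any(hits_rc$offset == 80 & hits_rc$strand == "-"))
  # windows containing N are skipped; short sequences yield nothing
  expect_equal(nrow(scan_peak("ACGTNACGT", pwm)), 0L)
  expect_equal(nrow(scan_peak("ACG", pwm)), 0L)
})

test_that("scan_peak matches the brute-force window scorer", {
  set.seed(17)
  for (i in 1:10) {
    cons <- paste(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                  collapse = "")
    pwm <- consensus_pwm(paste0("T", i), cons, hit = 60, miss = 10)
    seqs <- random_dna(200)
    got <- scan_peak(seqs, pwm, match_fraction = 0.8)
    want <- brute_force_scan(seqs, pwm, match_fraction = 0.8)
    expect_equal(got$offset, want$offset)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-12)
  }
})

test_that("regulon building respects correlation and size thresholds", {
  set.seed(6)
  n <- 80
  driver <- rnorm(n)
  ge <- rbind(TFX = driver + rnorm(n, sd = 0.2),
              t(sapply(1:12, function(i) driver + rnorm(n, sd = 0.3))),
              t(sapply(1:10, function(i) rnorm(n))))
  rownames(ge) <- c("TFX", paste0("tgt", 1:12), paste0("noise", 1:10))
  colnames(ge) <- paste0("c", 1:n)
  regs <- build_regulons(ge, "TFX", min_size = 10)
  expect_true("TFX" %in% names(regs))
  expect_gte(sum(paste0("tgt", 1:12) %in% regs$TFX$targets), 10)
  # TF uncorrelated with everything -> no regulon at min_size 10
  ge2 <- ge; ge2["TFX", ] <- rnorm(n)
  expect_length(build_regulons(ge2, "TFX", min_size = 10), 0)
  # corr_min = 1 keeps only perfect correlates
  regs1 <- build_regulons(ge, "TFX", corr_min = 1, min_size = 1)
  expect_equal(regs1$TFX$targets, "TFX")
  expect_warning(build_regulons(ge, "MISSING"), "absent")
})

test_that("active-region mask combines hits, activity and fragments monotonically", {
  hits <- list(TF1 = c(1L), TF2 = c(2L))
  act <- rbind(TF1 = c(1L, 0L, 0L), TF2 = c(0L, 0L, 0L))
  colnames(act) <- paste0("c", 1:3)
  ca <- matrix(1, 3, 3)
  mask <- label_active_regions(hits, act, ca_counts = ca)
  expect_equal(unname(mask[1, ]), c(1L, 0L, 0L))  # active TF in cell 1 only
  expect_equal(unname(mask[2, ]), c(0L, 0L, 0L))  # TF2 never active
  expect_equal(unname(mask[3, ]), c(0L, 0L, 0L))  # no motif
  # fragment requirement suppresses cells without coverage
  ca0 <- ca; ca0[1, 1] <- 0
  mask0 <- label_active_regions(hits, act, ca_counts = ca0)
  expect_equal(unname(mask0[1, ]), c(0L, 0L, 0L))
  mask_nofrag <- label_active_regions(hits, act, ca_counts = ca0,
                                      require_fragment = FALSE)
  expect_equal(unname(mask_nofrag[1, ]), c(1L, 0L, 0L))
  # monotone: activating another TF with a hit can only add 1s
  act2 <- act; act2["TF2", ] <- 1L
  mask2 <- label_active_regions(hits, act2, ca_counts = ca)
  expect_true(all(mask2 >= mask))
  expect_warning(label_active_regions(list(), act, ca_counts = ca), "empty")
})
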