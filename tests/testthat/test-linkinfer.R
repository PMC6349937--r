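test_that("weighted Spearman matches classic Spearman and the direct formula", {
  expect_equal(weighted_spearman(1:5, 5:1, rep(1, 5)), -1)
  expect_equal(weighted_spearman(c(2, 9, 4, 7), c(2, 9, 4, 7),
                                 c(3, 1, 1, 2)), 1)
  # direct weighted-Pearson-on-ranks oracle for an unequal-weight case
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4); w <- c(1, 1, 1, 4)
  rx <- rank(x); ry <- rank(y); wn <- w / sum(w)
  mx <- sum(wn * rx); my <- sum(wn * ry)
  oracle <- sum(wn * (rx - mx) * (ry - my)) /
    sqrt(sum(wn * (rx - mx)^2) * sum(wn * (ry - my)^2))
  expect_equal(weighted_spearman(x, y, w), oracle, tolerance = 1e-15)
  expect_warning(out <- weighted_spearman(rep(1, 4), 1:4, rep(1, 4)),
                 "constant")
  expect_true(is.na(out))
})

test_that("equal-weight weighted Spearman equals cor(method='spearman')", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    expect_equal(weighted_spearman(x, y, rep(1, n)),
                 cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
})

test_that("Wilcoxon exact path reproduces enumeration, ties fall to normal", {
  # most extreme split of 6 distinct values: one-sided mass 1/20 each tail
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$method, "exact")
  # identical multisets: maximal symmetry, p = 1 (tie-corrected normal path)
  same <- wilcoxon_rank_sum(c(1, 2, 2, 5), c(1, 2, 2, 5), min_group = 3)
  expect_equal(same$p.value, 1)
  expect_equal(same$method, "normal")
  # exact path agrees with full enumeration on random tie-free draws
  set.seed(3)
  for (i in 1:20) {
    a <- sample(1:100, sample(3:6, 1)); b <- sample(101:200, sample(3:6, 1)) / 7
    p_pkg <- wilcoxon_rank_sum(a, b)$p.value
    expect_equal(p_pkg, enumerate_wilcoxon_p(a, b), tolerance = 1e-12)
    # and with the reference implementation
    expect_equal(p_pkg, wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_rank_sum(1:2, 3:6), "min_group")
})

# a one-gene locus: promoter peak at the TSS plus two distal peaks
linkage_fixture <- function(n_cells = 60, seed = 5) {
  set.seed(seed)
  promoter <- rnorm(n_cells, 10, 2)
  ca <- rbind(prom = promoter,
              same = promoter,                       # identical signal
              indep = rnorm(n_cells, 10, 2))         # independent
  colnames(ca) <- paste0("c", seq_len(n_cells))
  peaks <- genomic_intervals(rep("chr1", 3),
                             c(999000, 1200000, 1500000),
                             c(1001000, 1200500, 1500500),
                             name = rownames(ca))
  genes <- data.frame(gene_id = "gT", chrom = "chr1", start = 1000000,
                      end = 1002000, strand = "+", tss = 1000000)
  list(ca = ca, peaks = peaks, genes = genes)
}

test_that("strategy 1 links identical distal signal, not independent noise", {
  fx <- linkage_fixture()
  H <- matrix(1, 1, ncol(fx$ca))   # single all-equal-weight signature
  links <- strategy1_links(fx$ca, fx$peaks, fx$genes, H)
  expect_true(any(links$peak_index == 2))            # rho = 1 with promoter
  got <- links[links$peak_index == 2, ]
  expect_equal(got$statistic, 1, tolerance = 1e-12)
  expect_equal(got$strategy, 1L)
  expect_true(all(links$statistic > 0.25))
  # a gene with no peaks within 1 Mb yields nothing
  far_genes <- data.frame(gene_id = "gF", chrom = "chr9", start = 1e6,
                          end = 1e6 + 100, strand = "+", tss = 1e6)
  expect_equal(nrow(strategy1_links(fx$ca, fx$peaks, far_genes, H)), 0L)
})

test_that("independent peaks rarely pass the strategy-1 threshold", {
  # Monte-Carlo null: promoter and distal rows independent
  set.seed(21)
  n <- 100
  hits <- 0
  H <- matrix(1, 1, n)
  for (r in 1:200) {
    fx_ca <- rbind(prom = rnorm(n), distal = rnorm(n))
    rho <- weighted_spearman(fx_ca[1, ], fx_ca[2, ], H[1, ])
    if (rho > 0.25) hits <- hits + 1
  }
  expect_lt(hits / 200, 0.1)   # far below coin-flip linkage
})

test_that("strategy 2 requires positive expression-accessibility correlation", {
  fx <- linkage_fixture()
  H <- matrix(1, 1, ncol(fx$ca))
  ge <- rbind(gT = 2 * fx$ca["same", ] + 3)   # proportional to distal peak 2
  links <- strategy2_links(fx$ca, ge, fx$peaks, fx$genes, H)
  expect_true(any(links$peak_index == 2 & links$statistic == 1))
  # perfectly anti-correlated expression is NOT linked (one-sided screen)
  ge_neg <- rbind(gT = -fx$ca["same", ])
  links_neg <- strategy2_links(fx$ca, ge_neg, fx$peaks, fx$genes, H)
  expect_false(any(links_neg$peak_index == 2))
  # equal weights reduce to the classic Spearman screen
  rho_classic <- cor(ge["gT", ], fx$ca["indep", ], method = "spearman")
  if (rho_classic <= 0.25)
    expect_false(any(links$peak_index == 3))
})

test_that("strategy 3 recovers a planted expression shift and skips degenerate masks", {
  set.seed(9)
  n <- 100
  on <- rep(c(1L, 0L), each = n / 2)
  mask <- rbind(planted = on,
                allon = rep(1L, n),
                allzero = rep(0L, n))
  colnames(mask) <- paste0("c", 1:n)
  expr <- rnorm(n, 5) + 5 * on
  ge <- rbind(gT = expr)
  colnames(ge) <- colnames(mask)
  peaks <- genomic_intervals(rep("chr1", 3), c(1.2e6, 1.3e6, 1.4e6),
                             c(1.2e6, 1.3e6, 1.4e6) + 500)
  genes <- data.frame(gene_id = "gT", chrom = "chr1", start = 1e6,
                      end = 1e6 + 2000, strand = "+", tss = 1e6)
  res <- strategy3_links(ge, mask, peaks, genes)
  expect_equal(res$links$peak_index, 1L)
  expect_lt(res$links$statistic, 0.05)
  expect_equal(res$n_untested, 2L)          # all-on and all-zero partitions
  # LinkMatrix row is the peak's mask row
  expect_equal(unname(res$link_matrix[1, ]), on)
  expect_equal(res$links$n_cells_on, sum(on))
})

test_that("Pearson screen counts signed significant correlations", {
  set.seed(13)
  n <- 50
  base <- matrix(rnorm(5 * n), 5)
  ca <- base + rnorm(5 * n, sd = 0.3)
  ge <- base + rnorm(5 * n, sd = 0.3)      # positively coupled pairs only
  colnames(ca) <- colnames(ge) <- paste0("c", 1:n)
  pairs <- data.frame(peak_index = 1:5, gene_index = 1:5)
  scr <- pairwise_correlation_screen(ca, ge, pairs)
  expect_equal(scr$n_sig_neg, 0L)
  expect_gt(scr$n_sig_pos, 0L)
  # hand-computed r for a 4-point pair
  x <- c(1, 4, 2, 8); y <- c(2, 5, 1, 9)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  one <- pairwise_correlation_screen(matrix(x, 1), matrix(y, 1),
                                     data.frame(peak_index = 1, gene_index = 1))
  expect_equal(one$table$r, r_hand, tolerance = 1e-12)
  # null data: significant fraction bounded by the FDR (within 2 SE)
  set.seed(14)
  ca0 <- matrix(rnorm(200 * 40), 200)
  ge0 <- matrix(rnorm(200 * 40), 200)
  scr0 <- pairwise_correlation_screen(ca0, ge0,
                                      data.frame(peak_index = 1:200,
                                                 gene_index = 1:200))
  frac0 <- (scr0$n_sig_pos + scr0$n_sig_neg) / 200
  expect_lte(frac0, 0.10 + 2 * sqrt(0.1 * 0.9 / 200))
})

test_that("link distance histogram bins peak-midpoint-to-TSS distances", {
  peaks <- genomic_intervals("chr1", c(1000250, 1500000),
                             c(1000750, 1500500))
  genes <- data.frame(gene_id = "g", chrom = "chr1", start = 1e6,
                      end = 1e6 + 100, strand = "+", tss = 1e6)
  links <- data.frame(peak_index = 1L, gene_id = "g", strategy = 3L,
                      statistic = 0.01, signature_index = NA, n_cells_on = 5L)
  h <- link_distance_distribution(links, peaks, genes)
  expect_equal(unname(h[1]), 1L)          # midpoint 500 bp away -> first bin
  expect_equal(sum(h), 1L)
  far <- links; far$peak_index <- 2L
  expect_error(link_distance_distribution(far, peaks, genes,
                                          max_distance = 1e5), "beyond")
})
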