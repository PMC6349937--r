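test_that("read_bed maps fields verbatim and rejects malformed lines", {
  p <- write_lines_tmp(c("chr1\t100\t200", "chr2\t0\t50\tpk\t0\t-"), ".bed")
  iv <- read_bed(p)
  expect_equal(iv$chrom, c("chr1", "chr2"))
  expect_equal(iv$start, c(100L, 0L))
  expect_equal(iv$end, c(200L, 50L))
  expect_equal(iv$strand, c(".", "-"))

  expect_warning(empty <- read_bed(write_lines_tmp(character(0), ".bed")),
                 "empty")
  expect_equal(nrow(empty), 0L)

  bad <- write_lines_tmp("chr1\t200\t100", ".bed")
  expect_error(read_bed(bad), "line 1")
})

test_that("gene annotation readers apply the strand-aware TSS rule once", {
  gtf <- write_lines_tmp(c(
    'chr1\tsrc\tgene\t1001\t5000\t.\t-\t.\tgene_id "gA";',
    'chr1\tsrc\tgene\t100\t900\t.\t+\t.\tgene_id "gB";'), ".gtf")
  g <- read_gene_annotation(gtf, "gtf")
  gA <- g[g$gene_id == "gA", ]
  # GTF 1-based closed [1001,5000] -> 0-based half-open [1000,5000); minus
  # strand TSS = end - 1
  expect_equal(gA$start, 1000L)
  expect_equal(gA$end, 5000L)
  expect_equal(gA$tss, 4999L)
  expect_equal(g$tss[g$gene_id == "gB"], 99L)

  # duplicated gene keeps the longest interval
  dup <- write_lines_tmp(c(
    'chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\tgene_id "gC";',
    'chr1\tsrc\ttranscript\t101\t900\t.\t+\t.\tgene_id "gC";'), ".gtf")
  gd <- read_gene_annotation(dup, "gtf")
  expect_equal(nrow(gd), 1L)
  expect_equal(gd$end, 900L)

  # tss_table rows become degenerate 1-bp intervals usable downstream
  tt <- write_lines_tmp(c("gene_id\tchrom\ttss\tstrand",
                          "gX\tchr2\t1000\t+"), ".tsv")
  gt <- read_gene_annotation(tt, "tss_table")
  expect_equal(gt$start, 1000L)
  expect_equal(gt$end, 1001L)
  expect_equal(gt$tss, 1000L)
  pk <- genomic_intervals("chr2", 1200, 1700)
  expect_equal(assign_peak_target_genes(pk, gt, window = 5000)[[1]], "gX")

  nogid <- write_lines_tmp("chr1\tsrc\tgene\t1\t10\t.\t+\t.\tfoo bar", ".gtf")
  expect_error(read_gene_annotation(nogid, "gtf"), "gene_id")
})

test_that("count matrices read from dense and MatrixMarket with sidecars", {
  dense <- write_lines_tmp(c("feature\tc1\tc2", "g1\t1\t0", "g2\t2\t3"))
  m <- read_count_matrix(dense)
  expect_equal(unname(m), matrix(c(1, 2, 0, 3), 2))
  expect_equal(rownames(m), c("g1", "g2"))

  mm <- write_lines_tmp(c("%%MatrixMarket matrix coordinate integer general",
                          "2 3 1", "2 1 7"), ".mtx")
  rn <- write_lines_tmp(c("p1", "p2"))
  cn <- write_lines_tmp(c("c1", "c2", "c3"))
  sm <- read_count_matrix(mm, rn, cn)
  expect_equal(dim(sm), c(2L, 3L))
  expect_equal(as.numeric(sm["p2", "c1"]), 7)
  expect_equal(sum(sm), 7)

  # zero stored entries still give the declared shape
  mm0 <- write_lines_tmp(c("%%MatrixMarket matrix coordinate integer general",
                           "2 3 0"), ".mtx")
  expect_equal(sum(read_count_matrix(mm0, rn, cn)), 0)

  cn_bad <- write_lines_tmp(c("c1", "c2"))
  expect_error(read_count_matrix(mm, rn, cn_bad), "length")
  neg <- write_lines_tmp(c("feature\tc1", "g1\t-1"))
  expect_error(read_count_matrix(neg), "negative")
})

test_that("JASPAR PFMs normalize with pseudocount over every cell", {
  pfm <- write_lines_tmp(c(">M1", "10", "0", "0", "0"), ".pfm")
  rec <- suppressWarnings(read_jaspar_pfm(pfm, pseudocount = 1))[[1]]
  # (10+1)/(10+4*1) for A, 1/14 for the rest
  expect_equal(as.numeric(rec$matrix[, 1]), c(11, 1, 1, 1) / 14)
  expect_equal(sum(rec$matrix[, 1]), 1, tolerance = 1e-9)

  unif <- write_lines_tmp(c(">U", "5 5", "5 5", "5 5", "5 5"), ".pfm")
  expect_true(all(suppressWarnings(read_jaspar_pfm(unif))[[1]]$matrix == 0.25))

  broken <- write_lines_tmp(c(">B", "1 2", "1 2", "1 2"), ".pfm")
  expect_error(read_jaspar_pfm(broken), "4 count rows")
  uneven <- write_lines_tmp(c(">B", "1 2", "1 2", "1 2", "1"), ".pfm")
  expect_error(read_jaspar_pfm(uneven), "unequal")
})

test_that("BEDPE anchors normalize to canonical order", {
  p <- write_lines_tmp(c(
    "chr1\t100\t200\tchr1\t5000\t5200\tI1\t3",
    "chr2\t9000\t9100\tchr2\t100\t300",          # reversed anchors
    "chr3\t10\t20\tchr1\t50\t60"), ".bedpe")     # interchromosomal
  b <- read_bedpe(p)
  expect_equal(nrow(b), 3L)
  expect_equal(b$start1[2], 100L)   # swapped into canonical order
  expect_equal(b$start2[2], 9000L)
  expect_equal(b$chrom1[3], "chr1") # ordered by chromosome
  expect_equal(b$score[1], 3)
  bad <- write_lines_tmp("chr1\t100\tx\tchr1\t1\t2", ".bedpe")
  expect_error(read_bedpe(bad), "malformed")
})

test_that("link tables round-trip through write_links", {
  peaks <- genomic_intervals(c("chr1", "chr1"), c(100, 900),
                             c(600, 1400))
  links <- data.frame(peak_index = c(2L, 1L), gene_id = c("gA", "gA"),
                      strategy = 3L, statistic = c(0.01, 0.002),
                      signature_index = NA_integer_,
                      n_cells_on = c(10L, 20L))
  path <- tempfile(fileext = ".tsv")
  write_links(links, peaks, path)
  back <- read_links(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$start, c(100L, 900L))   # sorted by (gene, chrom, start)
  expect_equal(back$n_cells_on, c(20L, 10L))
  # identity on content under a second round trip
  path2 <- tempfile(fileext = ".tsv")
  links2 <- data.frame(peak_index = match(back$start, peaks$start),
                       gene_id = back$gene_id, strategy = back$strategy,
                       statistic = back$statistic,
                       signature_index = NA_integer_,
                       n_cells_on = back$n_cells_on)
  write_links(links2, peaks, path2)
  expect_identical(readLines(path), readLines(path2))
  # empty set: header only
  write_links(links[0, ], peaks, path)
  expect_equal(length(readLines(path)), 1L)
})
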