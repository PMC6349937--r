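#' Bundle paired accessibility and expression matrices
#'
#' @param ca peaks x cells raw fragment count matrix.
#' @param ge genes x cells raw count matrix.
#' @param peaks \code{genomic_intervals} table, one row per CA row.
#' @param genes gene table from \code{\link{read_gene_annotation}}, one
#'   row per GE row.
#' @return A list of class \code{omics_pair} with elements \code{ca},
#'   \code{ge}, \code{peaks}, \code{genes}, \code{cells}.
#' @export
omics_pair <- function(ca, ge, peaks, genes) {
  if (is.null(colnames(ca))) colnames(ca) <- paste0("cell", seq_len(ncol(ca)))
  if (is.null(colnames(ge))) colnames(ge) <- colnames(ca)
  if (!identical(colnames(ca), colnames(ge)))
    stop("CA and GE matrices must share an identical cell ordering")
  if (nrow(ca) != nrow(peaks))
    stop("CA rows (", nrow(ca), ") != peak intervals (", nrow(peaks), ")")
  if (nrow(ge) != nrow(genes))
    stop("GE rows (", nrow(ge), ") != gene records (", nrow(genes), ")")
  structure(list(ca = ca, ge = ge, peaks = peaks, genes = genes,
                 cells = colnames(ca)),
            class = "omics_pair")
}

#' @export
print.omics_pair <- function(x, ...) {
  cat("omics_pair:", nrow(x$ca), "peaks x", length(x$cells), "cells (CA);",
      nrow(x$ge), "genes (GE)\n")
  invisible(x)
}

#' Filter sparsely detected peaks and genes
#'
#' Retains peaks detected -- fragment count >= \code{ca_min_fragments},
#' i.e. strictly more than one fragment at the default -- in at least
#' \code{min_cell_fraction} of cells, and genes with at least one count
#' in at least \code{min_cell_fraction} of cells.  The cell set is
#' unchanged.  The detection boundary is inclusive (>= the fraction);
#' set \code{strict = TRUE} for a strict > boundary.
#'
#' @param pair an \code{omics_pair}.
#' @param min_cell_fraction minimum fraction of cells a feature must be
#'   detected in (default 0.10).
#' @param ca_min_fragments minimum fragment count for a peak to count as
#'   detected in a cell (default 2).
#' @param strict use a strict > comparison on the cell fraction.
#' @return The filtered \code{omics_pair}.
#' @export
filter_features <- function(pair, min_cell_fraction = 0.10,
                            ca_min_fragments = 2, strict = FALSE) {
  n <- length(pair$cells)
  cmp <- if (strict) `>` else `>=`
  frac_ca <- Matrix::rowSums(pair$ca >= ca_min_fragments) / n
  frac_ge <- Matrix::rowSums(pair$ge >= 1) / n
  keep_ca <- cmp(frac_ca, min_cell_fraction)
  keep_ge <- cmp(frac_ge, min_cell_fraction)
  if (!any(keep_ca) || !any(keep_ge))
    stop("empty matrix after filtering")
  omics_pair(pair$ca[keep_ca, , drop = FALSE],
             pair$ge[keep_ge, , drop = FALSE],
             pair$peaks[keep_ca, , drop = FALSE],
             pair$genes[keep_ge, , drop = FALSE])
}

#' Pooled (deconvolution) size factors
#'
#' Cell-pool deconvolution estimator of per-cell size factors: cells are
#' ordered on a ring by library size; for every pool size and every ring
#' position the pooled count vector is compared to the average
#' pseudo-cell, yielding one linear equation in the member cells'
#' factors (the pool's summed factor equals the median ratio of pooled
#' counts to the pseudo-cell).  The stacked system is solved by least
#' squares, with low-weight library-size anchor equations for
#' identifiability, and rescaled to mean 1.
#'
#' @param counts features x cells count matrix; no all-zero cells.
#' @param pool_sizes integer pool sizes (default \code{c(21,26,31,36,41)}).
#' @return Numeric vector of positive size factors, mean 1, named by cell.
#' @export
pooled_size_factors <- function(counts, pool_sizes = c(21L, 26L, 31L, 36L, 41L)) {
  n <- ncol(counts)
  lib <- Matrix::colSums(counts)
  if (any(lib == 0)) stop("all-zero cell in count matrix")
  if (n < min(pool_sizes) + 1L) {
    warning("fewer cells (", n, ") than smallest pool size; ",
            "falling back to library-size factors")
    f <- lib / mean(lib)
    names(f) <- colnames(counts)
    return(f)
  }
  pool_sizes <- pool_sizes[pool_sizes < n]
  ref <- Matrix::rowMeans(counts)
  use <- ref > 0
  ref <- ref[use]
  cmat <- as.matrix(counts[use, , drop = FALSE])
  ord <- order(lib)                       # ring ordering by library size
  ratio_rows <- list()
  rhs <- numeric(0)
  k <- 0L
  for (s in pool_sizes) {
    for (i in seq_len(n)) {
      members <- ord[((i - 1L + seq_len(s) - 1L) %% n) + 1L]
      pooled <- rowSums(cmat[, members, drop = FALSE])
      r <- stats::median(pooled / ref)
      k <- k + 1L
      ratio_rows[[k]] <- members
      rhs[k] <- r
    }
  }
  A <- matrix(0, nrow = k, ncol = n)
  for (j in seq_len(k)) A[j, ratio_rows[[j]]] <- 1
  # low-weight anchors tie the solution to library size, removing the
  # null space when pools overlap heavily
  w <- sqrt(.Machine$double.eps)
  A <- rbind(A, diag(w, n))
  rhs <- c(rhs, w * lib / mean(lib) * 1)
  f <- stats::lsfit(A, rhs, intercept = FALSE)$coefficients
  if (any(f <= 0)) {
    pos <- f[f > 0]
    if (length(pos) == 0L) stop("size factor estimation failed: no positive solution")
    warning(sum(f <= 0), " non-positive size factor(s) clipped")
    f[f <= 0] <- min(pos) * 0.01
  }
  f <- f / mean(f)
  names(f) <- colnames(counts)
  f
}

#' Normalize a count matrix by per-cell size factors
#'
#' @param counts features x cells matrix.
#' @param size_factors positive per-cell factors (length = n cells).
#' @param log1p take \code{log1p} of the normalized values.
#' @return Normalized real matrix.
#' @export
normalize_counts <- function(counts, size_factors, log1p = FALSE) {
  if (length(size_factors) != ncol(counts))
    stop("size_factors length != number of cells")
  if (any(size_factors <= 0)) stop("size factors must be positive")
  out <- sweep(as.matrix(counts), 2, size_factors, "/")
  if (log1p) out <- log1p(out)
  out
}

#' Counts per million
#'
#' @param counts features x cells matrix with positive cell totals.
#' @return Matrix where each column sums to 1e6.
#' @export
cpm <- function(counts) {
  tot <- Matrix::colSums(counts)
  zero <- which(tot == 0)
  if (length(zero))
    stop("zero-total cell(s): ",
         paste(colnames(counts)[zero] %||% zero, collapse = ", "))
  sweep(as.matrix(counts), 2, tot, "/") * 1e6
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign putative target genes to peaks by TSS proximity
#'
#' A gene is assigned to a peak when its TSS falls within \code{window}
#' bp of the peak body, i.e. TSS in the half-open interval
#' \code{[peak$start - window, peak$end + window)}.
#'
#' @param peaks \code{genomic_intervals} table.
#' @param genes gene table with \code{chrom} and \code{tss} columns.
#' @param window flank size in bp (default 5000).
#' @return A list, one element per peak, of gene_id character vectors.
#' @export
assign_peak_target_genes <- function(peaks, genes, window = 5000) {
  out <- rep(list(character(0)), nrow(peaks))
  idx <- split(seq_len(nrow(genes)), genes$chrom)
  for (i in seq_len(nrow(peaks))) {
    g <- idx[[peaks$chrom[i]]]
    if (is.null(g)) next
    tss <- genes$tss[g]
    hit <- tss >= peaks$start[i] - window & tss < peaks$end[i] + window
    out[[i]] <- genes$gene_id[g[hit]]
  }
  names(out) <- if (!is.null(peaks$name)) peaks$name else NULL
  out
}

#' Classify genes by overlapping histone-mark sets
#'
#' Chromatin-state classes from the marks found at a gene's regulatory
#' region: \emph{active} = (H3K4me3 or H3K4me1) and H3K27ac, without
#' H3K27me3; \emph{bivalent} = (H3K4me3 or H3K4me1) together with
#' H3K27me3; \emph{inactive} = H3K27me3 alone (no H3K4me3/H3K4me1/
#' H3K27ac); anything else is \emph{unclassified}.  Bivalent takes
#' precedence over inactive.
#'
#' @param mark_sets named list; each element a character vector of marks
#'   drawn from H3K4me3, H3K4me1, H3K27ac, H3K27me3.
#' @return Named character vector of classes.
#' @export
classify_genes_by_marks <- function(mark_sets) {
  known <- c("H3K4me3", "H3K4me1", "H3K27ac", "H3K27me3")
  vapply(mark_sets, function(m) {
    if (length(setdiff(m, known)))
      stop("unknown mark name(s): ", paste(setdiff(m, known), collapse = ", "))
    k4 <- any(c("H3K4me3", "H3K4me1") %in% m)
    ac <- "H3K27ac" %in% m
    me3 <- "H3K27me3" %in% m
    if (k4 && me3) "bivalent"
    else if (k4 && ac && !me3) "active"
    else if (me3 && !k4 && !ac) "inactive"
    else "unclassified"
  }, character(1))
}

#' Per-cell accessibility density in a genomic context
#'
#' Mean CPM, per cell, over the peaks that overlap a region set (e.g.
#' regions carrying a given histone modification).
#'
#' @param ca_cpm peaks x cells CPM matrix (from \code{\link{cpm}}).
#' @param region_set \code{genomic_intervals} table of context regions.
#' @param peaks \code{genomic_intervals} table matching \code{ca_cpm} rows.
#' @param cell_first average over cells within each peak before averaging
#'   peaks (default FALSE: per-cell means over peaks).
#' @return Named numeric vector, one mean density per cell (or per peak
#'   mean when \code{cell_first}).
#' @export
context_density <- function(ca_cpm, region_set, peaks, cell_first = FALSE) {
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(intervals_to_granges(peaks),
                                intervals_to_granges(region_set)))
  sel <- unique(S4Vectors::queryHits(ov))
  if (length(sel) == 0L) {
    warning("no peaks overlap the region set")
    return(numeric(0))
  }
  sub <- ca_cpm[sel, , drop = FALSE]
  if (cell_first) rowMeans(sub) else colMeans(sub)
}
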