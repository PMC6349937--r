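#' Weighted Spearman correlation
#'
#' Ranks both vectors (average ranks for ties) and computes the weighted
#' Pearson correlation of the rank vectors.  With equal weights this
#' reduces exactly to the classic Spearman correlation.  Weighting
#' guards the screen against underestimating correlations driven by a
#' cell subpopulation: each NMF signature's exposures are used as
#' weights so that cells belonging to that signature dominate.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param w non-negative weights, positive sum.
#' @return rho in [-1, 1]; \code{NA} with a warning when \code{x} or
#'   \code{y} is constant.
#' @export
weighted_spearman <- function(x, y, w = rep(1, length(x))) {
  n <- length(x)
  if (length(y) != n || length(w) != n) stop("x, y, w must share a length")
  if (n < 3L) stop("need at least 3 observations")
  if (any(w < 0) || sum(w) <= 0) stop("weights must be >= 0 with positive sum")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("constant input: weighted Spearman undefined")
    return(NA_real_)
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  weighted_pearson(rx, ry, w)
}

# weighted Pearson correlation of two vectors
weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sxx <- sum(w * (x - mx)^2)
  syy <- sum(w * (y - my)^2)
  if (sxx <= 0 || syy <= 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# peaks whose body overlaps [tss - flank, tss + flank] for each gene;
# returns list of integer peak indices parallel to genes rows
.peaks_near_tss <- function(peaks, genes, flank) {
  by_chr <- split(seq_len(nrow(peaks)), peaks$chrom)
  lapply(seq_len(nrow(genes)), function(g) {
    p <- by_chr[[genes$chrom[g]]]
    if (is.null(p)) return(integer(0))
    tss <- genes$tss[g]
    p[peaks$start[p] <= tss + flank & peaks$end[p] > tss - flank]
  })
}

.empty_links <- function() {
  data.frame(peak_index = integer(0), gene_id = character(0),
             strategy = integer(0), statistic = numeric(0),
             signature_index = integer(0), n_cells_on = integer(0),
             stringsAsFactors = FALSE)
}

# shared machinery for strategies 1 and 2: for each gene, correlate a
# response vector against each distal peak under every signature's
# exposure weights; link when the max rho exceeds the threshold
.correlation_strategy <- function(ca_norm, peaks, genes, H_exposures,
                                  response_for_gene, strategy,
                                  rho_threshold, window, promoter_window) {
  stopifnot(ncol(H_exposures) == ncol(ca_norm))
  distal_idx <- .peaks_near_tss(peaks, genes, window)
  promoter_idx <- .peaks_near_tss(peaks, genes, promoter_window)
  n_sig <- nrow(H_exposures)
  # pre-rank all peak rows once; weighted Pearson is then cheap per signature
  peak_ranks <- t(apply(ca_norm, 1, rank, ties.method = "average"))
  skipped <- 0L
  res <- vector("list", nrow(genes))
  for (g in seq_len(nrow(genes))) {
    resp <- response_for_gene(g, promoter_idx[[g]], peak_ranks)
    if (is.null(resp)) { skipped <- skipped + 1L; next }
    distal <- setdiff(distal_idx[[g]], promoter_idx[[g]])
    if (length(distal) == 0L) next
    best_rho <- rep(-Inf, length(distal))
    best_sig <- rep(NA_integer_, length(distal))
    for (s in seq_len(n_sig)) {
      w <- H_exposures[s, ]
      if (sum(w) <= 0) next
      for (ri in seq_len(nrow(resp))) {
        rr <- resp[ri, ]
        if (stats::var(rr) == 0) next
        rho <- apply(peak_ranks[distal, , drop = FALSE], 1,
                     weighted_pearson, y = rr, w = w)
        upd <- !is.na(rho) & rho > best_rho
        best_rho[upd] <- rho[upd]
        best_sig[upd] <- s
      }
    }
    hit <- is.finite(best_rho) & best_rho > rho_threshold
    if (any(hit))
      res[[g]] <- data.frame(peak_index = distal[hit],
                             gene_id = genes$gene_id[g],
                             strategy = strategy,
                             statistic = best_rho[hit],
                             signature_index = best_sig[hit],
                             n_cells_on = NA_integer_,
                             stringsAsFactors = FALSE)
  }
  if (skipped > 0L)
    message(skipped, " gene(s) skipped (no usable response)")
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) .empty_links() else out
}

#' Strategy 1: promoter-to-distal accessibility correlation links
#'
#' For every gene, peaks overlapping the promoter (TSS +/-
#' \code{promoter_window}) are correlated against each distal peak
#' within \code{window} of the TSS using the weighted Spearman
#' correlation, once per NMF signature with that signature's exposure
#' row as weights.  A distal peak is linked to the gene when the
#' maximum correlation over signatures and promoter peaks exceeds
#' \code{rho_threshold}.
#'
#' @param ca_norm normalized peaks x cells accessibility matrix.
#' @param peaks,genes interval and gene tables matching \code{ca_norm}.
#' @param H_exposures signatures x cells exposure matrix from
#'   \code{\link{nmf_factorize}} of the accessibility matrix.
#' @param rho_threshold one-sided positive threshold (default 0.25).
#' @param window distal search window around the TSS in bp (default 1e6).
#' @param promoter_window promoter half-width in bp (default 2000).
#' @return A link data.frame (peak_index, gene_id, strategy, statistic =
#'   rho, signature_index, n_cells_on).
#' @export
strategy1_links <- function(ca_norm, peaks, genes, H_exposures,
                            rho_threshold = 0.25, window = 1e6,
                            promoter_window = 2000) {
  .correlation_strategy(
    ca_norm, peaks, genes, H_exposures,
    response_for_gene = function(g, prom, peak_ranks) {
      if (length(prom) == 0L) return(NULL)
      peak_ranks[prom, , drop = FALSE]
    },
    strategy = 1L, rho_threshold = rho_threshold, window = window,
    promoter_window = promoter_window)
}

#' Strategy 2: expression-to-distal accessibility correlation links
#'
#' As \code{\link{strategy1_links}}, but the response is the gene's
#' normalized expression vector and the exposure weights come from the
#' NMF of the expression matrix.
#'
#' @param ca_norm normalized peaks x cells accessibility matrix.
#' @param ge_norm normalized genes x cells expression matrix.
#' @param peaks,genes interval and gene tables.
#' @param H_exposures signatures x cells exposure matrix from the GE NMF.
#' @param rho_threshold,window,promoter_window see
#'   \code{\link{strategy1_links}}.
#' @return A link data.frame.
#' @export
strategy2_links <- function(ca_norm, ge_norm, peaks, genes, H_exposures,
                            rho_threshold = 0.25, window = 1e6,
                            promoter_window = 2000) {
  stopifnot(nrow(ge_norm) == nrow(genes))
  .correlation_strategy(
    ca_norm, peaks, genes, H_exposures,
    response_for_gene = function(g, prom, peak_ranks) {
      e <- ge_norm[g, ]
      if (stats::var(e) == 0) return(NULL)
      matrix(rank(e, ties.method = "average"), nrow = 1)
    },
    strategy = 2L, rho_threshold = rho_threshold, window = window,
    promoter_window = promoter_window)
}

#' Wilcoxon rank-sum test
#'
#' Exact p-value by the null rank-sum distribution when the combined
#' sample size is at most \code{exact_max} and tie-free; otherwise the
#' normal approximation with mid-ranks, tie-corrected variance,
#' continuity correction and an Edgeworth fourth-moment correction
#' (the Mann-Whitney null is platykurtic at small sizes; the correction
#' term uses the closed-form excess kurtosis and vanishes as the
#' samples grow).
#'
#' @param a,b numeric samples.
#' @param alternative \code{"two.sided"}, \code{"less"} or
#'   \code{"greater"} (a vs b).
#' @param exact force (TRUE) or forbid (FALSE) the exact path; default
#'   \code{NULL} chooses automatically.
#' @param exact_max largest combined n for the exact path (default 12).
#' @param min_group minimum size of each group (default 3).
#' @return List with \code{p.value}, \code{statistic} (rank-sum W of
#'   \code{a}, Mann-Whitney U form), and \code{method}.
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "less", "greater"),
                              exact = NULL, exact_max = 12L, min_group = 3L) {
  alternative <- match.arg(alternative)
  na <- length(a); nb <- length(b)
  if (na < min_group || nb < min_group)
    stop("group smaller than min_group = ", min_group)
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0L
  r <- rank(pooled, ties.method = "average")
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2   # Mann-Whitney U of a
  if (is.null(exact)) exact <- (na + nb) <= exact_max && !ties
  if (exact && ties)
    stop("exact path requested but ties present")
  if (exact) {
    p <- switch(alternative,
      two.sided = {
        if (U > na * nb / 2)
          min(1, 2 * stats::pwilcox(U - 1, na, nb, lower.tail = FALSE))
        else
          min(1, 2 * stats::pwilcox(U, na, nb))
      },
      greater = stats::pwilcox(U - 1, na, nb, lower.tail = FALSE),
      less = stats::pwilcox(U, na, nb))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    ntot <- na + nb
    tie_tab <- table(r)
    sigma2 <- (na * nb / 12) *
      ((ntot + 1) - sum(tie_tab^3 - tie_tab) / (ntot * (ntot - 1)))
    if (sigma2 <= 0) return(list(p.value = 1, statistic = U,
                                 method = "degenerate"))
    sigma <- sqrt(sigma2)
    # closed-form excess kurtosis of the tie-free Mann-Whitney null
    g2 <- -1.2 * (na^2 + nb^2 + na * nb + na + nb) /
      (na * nb * (ntot + 1))
    cdf <- function(u) {               # P(U' <= u), continuity-corrected
      z <- (u + 0.5 - mu) / sigma
      min(1, max(0, stats::pnorm(z) -
                   g2 / 24 * (z^3 - 3 * z) * stats::dnorm(z)))
    }
    p <- switch(alternative,
      two.sided = min(1, 2 * min(cdf(U), 1 - cdf(U - 1))),
      greater = 1 - cdf(U - 1),
      less = cdf(U))
    method <- "normal"
  }
  list(p.value = p, statistic = U, method = method)
}

#' Strategy 3: per-cell active-region Wilcoxon links
#'
#' For each gene and each peak within \code{window} of its TSS, cells
#' are partitioned by the peak's active-region mask; a Wilcoxon
#' rank-sum test asks whether the gene's normalized expression differs
#' between cells where the region is active and cells where it is not.
#' A link is assigned when p < \code{alpha}.  The per-cell on/off state
#' of a link is the peak's mask row, yielding a binary links x cells
#' matrix.
#'
#' @param ge_norm normalized genes x cells expression matrix.
#' @param active_region_mask binary peaks x cells matrix from
#'   \code{\link{label_active_regions}}.
#' @param peaks,genes interval and gene tables.
#' @param window search window around the TSS in bp (default 1e6).
#' @param alpha p-value threshold (default 0.05, uncorrected).
#' @param min_group minimum cells on each side of the partition
#'   (default 3); smaller partitions are recorded as untested.
#' @param adjust optional p-value adjustment method passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"none"}).
#' @return List with \code{links} (link data.frame, statistic = p),
#'   \code{link_matrix} (binary links x cells matrix), \code{n_tested},
#'   \code{n_untested}.
#' @export
strategy3_links <- function(ge_norm, active_region_mask, peaks, genes,
                            window = 1e6, alpha = 0.05, min_group = 3L,
                            adjust = "none") {
  stopifnot(ncol(ge_norm) == ncol(active_region_mask),
            nrow(active_region_mask) == nrow(peaks),
            nrow(ge_norm) == nrow(genes))
  near <- .peaks_near_tss(peaks, genes, window)
  mask <- as.matrix(active_region_mask)
  n_tested <- 0L; n_untested <- 0L
  rows <- list(); k <- 0L
  for (g in seq_len(nrow(genes))) {
    ps <- near[[g]]
    if (length(ps) == 0L) next
    expr <- ge_norm[g, ]
    for (p in ps) {
      on <- mask[p, ] >= 1
      n_on <- sum(on); n_off <- sum(!on)
      if (n_on < min_group || n_off < min_group) {
        n_untested <- n_untested + 1L
        next
      }
      n_tested <- n_tested + 1L
      pv <- wilcoxon_rank_sum(expr[on], expr[!on], exact = FALSE,
                              min_group = min_group)$p.value
      k <- k + 1L
      rows[[k]] <- list(peak_index = p, gene_id = genes$gene_id[g],
                        p = pv, n_on = n_on)
    }
  }
  if (k == 0L)
    return(list(links = .empty_links(),
                link_matrix = matrix(0L, 0, ncol(ge_norm)),
                n_tested = n_tested, n_untested = n_untested))
  pvals <- vapply(rows, `[[`, 0, "p")
  padj <- stats::p.adjust(pvals, method = adjust)
  keep <- which(padj < alpha)
  links <- data.frame(
    peak_index = vapply(rows, `[[`, 0L, "peak_index")[keep],
    gene_id = vapply(rows, `[[`, "", "gene_id")[keep],
    strategy = 3L,
    statistic = pvals[keep],
    signature_index = NA_integer_,
    n_cells_on = vapply(rows, `[[`, 0L, "n_on")[keep],
    stringsAsFactors = FALSE)
  lm <- mask[links$peak_index, , drop = FALSE]
  lm <- (lm >= 1) + 0L
  rownames(lm) <- paste0(links$gene_id, ":", links$peak_index)
  colnames(lm) <- colnames(ge_norm)
  list(links = links, link_matrix = lm,
       n_tested = n_tested, n_untested = n_untested)
}

#' Pearson correlation screen over peak-gene pairs
#'
#' Per-pair Pearson correlation with a two-sided t-test p-value,
#' Benjamini-Hochberg adjusted; reports how many significant
#' correlations are positive versus negative.
#'
#' @param ca_norm normalized peaks x cells matrix.
#' @param ge_norm normalized genes x cells matrix.
#' @param pairs data.frame with columns \code{peak_index},
#'   \code{gene_index}.
#' @param fdr BH false discovery rate (default 0.10).
#' @return List with \code{table} (pair, r, p, q) and counts
#'   \code{n_sig_pos}, \code{n_sig_neg}, \code{n_skipped}.
#' @export
pairwise_correlation_screen <- function(ca_norm, ge_norm, pairs, fdr = 0.10) {
  n <- ncol(ca_norm)
  r <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    x <- ca_norm[pairs$peak_index[i], ]
    y <- ge_norm[pairs$gene_index[i], ]
    if (stats::var(x) == 0 || stats::var(y) == 0) next
    r[i] <- stats::cor(x, y)
  }
  ok <- !is.na(r)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- rep(NA_real_, length(p))
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  sig <- ok & q < fdr
  list(table = data.frame(pairs, r = r, p = p, q = q),
       n_sig_pos = sum(sig & r > 0), n_sig_neg = sum(sig & r < 0),
       n_skipped = sum(!ok))
}

#' Histogram of link peak-to-TSS distances
#'
#' @param links a link data.frame.
#' @param peaks,genes interval and gene tables.
#' @param bin_width histogram bin width in bp (default 1e4).
#' @param max_distance histogram range (default 1e6).
#' @return Named integer vector of counts per distance bin.
#' @export
link_distance_distribution <- function(links, peaks, genes,
                                       bin_width = 1e4, max_distance = 1e6) {
  if (nrow(links) == 0L) stop("empty link set")
  tss <- genes$tss[match(links$gene_id, genes$gene_id)]
  mid <- (peaks$start[links$peak_index] + peaks$end[links$peak_index]) / 2
  d <- abs(mid - tss)
  d <- d[d <= max_distance]
  if (length(d) == 0L) stop("all links beyond max_distance")
  breaks <- seq(0, max_distance, by = bin_width)
  counts <- table(cut(d, breaks = breaks, include.lowest = TRUE,
                      right = FALSE))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}
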