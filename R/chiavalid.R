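#' Is a single link supported by a chromatin interaction?
#'
#' A link is supported when some interaction has one anchor overlapping
#' the link's peak and the other anchor overlapping the gene's promoter
#' (TSS +/- \code{promoter_window}), in either anchor assignment.
#' Anchors may be widened by \code{anchor_slop} bp on both sides; the
#' supported set grows monotonically with the slop.
#'
#' @param peak one-row \code{genomic_intervals} slice (or list with
#'   chrom/start/end) for the link's peak.
#' @param gene one-row gene record with \code{chrom} and \code{tss}.
#' @param interactions BEDPE data.frame from \code{\link{read_bedpe}}.
#' @param promoter_window promoter half-width in bp (default 2000).
#' @param anchor_slop anchor widening in bp (default 0).
#' @return TRUE/FALSE.
#' @export
link_supported <- function(peak, gene, interactions,
                           promoter_window = 2000, anchor_slop = 0) {
  if (nrow(interactions) == 0L) return(FALSE)
  ov <- function(chrom, s, e, a_chrom, a_s, a_e) {
    chrom == a_chrom & s < a_e + anchor_slop & e > a_s - anchor_slop
  }
  ps <- peak$start; pe <- peak$end; pc <- peak$chrom
  gs <- gene$tss - promoter_window
  ge_ <- gene$tss + promoter_window + 1
  gc_ <- gene$chrom
  with(interactions,
    any((ov(pc, ps, pe, chrom1, start1, end1) &
           ov(gc_, gs, ge_, chrom2, start2, end2)) |
        (ov(pc, ps, pe, chrom2, start2, end2) &
           ov(gc_, gs, ge_, chrom1, start1, end1))))
}

#' Proportion of links validated by chromatin interactions
#'
#' @param links link data.frame (with \code{peak_index},
#'   \code{gene_id}, \code{strategy}).
#' @param peaks,genes interval and gene tables.
#' @param interactions BEDPE data.frame.
#' @param promoter_window,anchor_slop see \code{\link{link_supported}}.
#' @return data.frame with one row per strategy: \code{strategy},
#'   \code{n_links}, \code{n_supported}, \code{proportion}.
#' @export
validation_proportion <- function(links, peaks, genes, interactions,
                                  promoter_window = 2000, anchor_slop = 0) {
  if (nrow(links) == 0L) stop("empty link set")
  gi <- match(links$gene_id, genes$gene_id)
  supported <- vapply(seq_len(nrow(links)), function(i) {
    link_supported(peaks[links$peak_index[i], ], genes[gi[i], ],
                   interactions, promoter_window, anchor_slop)
  }, logical(1))
  res <- lapply(split(seq_len(nrow(links)), links$strategy), function(idx) {
    data.frame(strategy = links$strategy[idx[1L]],
               n_links = length(idx),
               n_supported = sum(supported[idx]),
               proportion = mean(supported[idx]))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Three-way overlap of links found by the strategies
#'
#' Links are keyed by (peak_index, gene_id); the seven regions of the
#' three-set Venn diagram are counted.
#'
#' @param links_by_strategy list of up to three link data.frames, named
#'   by strategy.
#' @return Named integer vector: \code{only1, only2, only3, s12, s13,
#'   s23, s123} plus \code{union}.
#' @export
strategy_overlap <- function(links_by_strategy) {
  key <- function(df)
    if (nrow(df) == 0L) character(0) else
      unique(paste(df$peak_index, df$gene_id, sep = "|"))
  ks <- lapply(links_by_strategy, key)
  while (length(ks) < 3L) ks <- c(ks, list(character(0)))
  a <- ks[[1L]]; b <- ks[[2L]]; c_ <- ks[[3L]]
  u <- union(union(a, b), c_)
  m <- cbind(u %in% a, u %in% b, u %in% c_)
  code <- m[, 1] + 2 * m[, 2] + 4 * m[, 3]
  cnt <- function(x) sum(code == x)
  c(only1 = cnt(1), only2 = cnt(2), only3 = cnt(4),
    s12 = cnt(3), s13 = cnt(5), s23 = cnt(6), s123 = cnt(7),
    union = length(u))
}
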