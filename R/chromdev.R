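#' Motif-by-peak annotation matrix
#'
#' @param motif_hit_index named list (by motif/TF) of integer peak
#'   indices.
#' @param n_peaks total number of peaks.
#' @return Binary motifs x peaks matrix.
#' @export
annotate_motif_peaks <- function(motif_hit_index, n_peaks) {
  M <- matrix(0L, length(motif_hit_index), n_peaks,
              dimnames = list(names(motif_hit_index), NULL))
  for (i in seq_along(motif_hit_index)) {
    idx <- motif_hit_index[[i]]
    if (any(idx > n_peaks)) stop("hit index exceeds n_peaks")
    M[i, idx] <- 1L
  }
  M
}

#' Sample accessibility-matched background peak sets
#'
#' Peaks are binned on mean accessibility (quantile bins; 2-D bins when
#' GC content is supplied) and each of the B background draws replaces
#' every peak with a uniform draw from its own bin, so background sets
#' preserve the accessibility (and GC) profile of the foreground.
#'
#' @param peak_mean_accessibility per-peak mean accessibility.
#' @param gc_content optional per-peak GC fraction for 2-D binning.
#' @param B number of background sets (default 50).
#' @param n_bins bins per dimension (default 25).
#' @param seed RNG seed.
#' @return Integer matrix of dim (n_peaks, B): column b holds the b-th
#'   background peak for every peak.
#' @export
sample_background_peaks <- function(peak_mean_accessibility,
                                    gc_content = NULL, B = 50L,
                                    n_bins = 25L, seed = 1L) {
  n <- length(peak_mean_accessibility)
  if (n < n_bins) stop("need at least n_bins peaks")
  qbin <- function(x, k) {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = k + 1)))
    if (length(br) < 2L) return(rep(1L, length(x)))
    as.integer(cut(x, breaks = br, include.lowest = TRUE))
  }
  bin <- qbin(peak_mean_accessibility, n_bins)
  if (!is.null(gc_content))
    bin <- paste(bin, qbin(gc_content, n_bins))
  members <- split(seq_len(n), bin)
  set.seed(seed)
  out <- matrix(NA_integer_, n, B)
  singles <- 0L
  for (g in members) {
    if (length(g) == 1L) {
      out[g, ] <- g
      singles <- singles + 1L
      next
    }
    out[g, ] <- sample(g, length(g) * B, replace = TRUE)
  }
  if (singles > 0L)
    warning(singles, " singleton bin(s): peaks map to themselves")
  out
}

#' Per-cell chromatin accessibility deviation z-scores
#'
#' For each motif and cell, the observed aggregate fragment count over
#' the motif's peaks is compared to the count expected from the cell's
#' sequencing depth and the motif peaks' pooled share of all fragments:
#' raw deviation = (observed - expected) / expected.  The raw deviation
#' is then z-scored against the raw deviations of the B
#' accessibility-matched background peak sets, removing technical
#' depth/accessibility structure.  Motif variability is the standard
#' deviation of its z-score row across cells.
#'
#' @param ca_counts peaks x cells fragment counts.
#' @param motif_annotation binary motifs x peaks matrix from
#'   \code{\link{annotate_motif_peaks}}.
#' @param background_sets matrix from
#'   \code{\link{sample_background_peaks}}; \code{NULL} skips
#'   background normalization and returns raw deviations as z.
#' @return List of class \code{deviation_result}: \code{deviations}
#'   (motifs x cells z), \code{raw} (motifs x cells raw deviations),
#'   \code{variability} (per motif), \code{dropped} (motif names with
#'   zero expectation).
#' @export
compute_deviations <- function(ca_counts, motif_annotation,
                               background_sets = NULL) {
  X <- as.matrix(ca_counts)
  A <- motif_annotation
  stopifnot(ncol(A) == nrow(X))
  cell_tot <- colSums(X)
  grand <- sum(cell_tot)
  peak_tot <- rowSums(X)
  raw_dev <- function(ann) {
    obs <- ann %*% X                                  # motifs x cells
    frac <- (ann %*% peak_tot) / grand                # motif share of fragments
    expect <- frac %*% t(cell_tot)
    (obs - expect) / expect
  }
  frac0 <- (A %*% peak_tot) / grand
  keep <- which(frac0 > 0)
  dropped <- rownames(A)[setdiff(seq_len(nrow(A)), keep)]
  if (length(dropped))
    warning("motif(s) with zero expected counts dropped: ",
            paste(dropped, collapse = ", "))
  A <- A[keep, , drop = FALSE]
  raw <- raw_dev(A)
  if (!is.null(background_sets)) {
    B <- ncol(background_sets)
    bg_raw <- array(NA_real_, dim = c(nrow(A), ncol(X), B))
    for (b in seq_len(B)) {
      map <- background_sets[, b]
      # background annotation: motif peaks replaced by matched peaks
      Ab <- matrix(0L, nrow(A), nrow(X))
      for (m in seq_len(nrow(A))) {
        tgt <- map[which(A[m, ] == 1L)]
        Ab[m, unique(tgt)] <- 1L
      }
      ok <- rowSums(Ab * rep(peak_tot, each = nrow(Ab))) > 0
      if (any(ok))
        bg_raw[ok, , b] <- raw_dev(Ab[, , drop = FALSE])[ok, ]
    }
    mu <- apply(bg_raw, c(1, 2), mean, na.rm = TRUE)
    sdv <- apply(bg_raw, c(1, 2), stats::sd, na.rm = TRUE)
    sdv[sdv == 0 | is.na(sdv)] <- 1
    z <- (raw - mu) / sdv
  } else z <- raw
  rownames(z) <- rownames(raw) <- rownames(A)
  colnames(z) <- colnames(raw) <- colnames(X)
  structure(list(deviations = z, raw = raw,
                 variability = compute_variability(z),
                 dropped = dropped),
            class = "deviation_result")
}

#' Per-motif variability of deviation z-scores
#'
#' @param deviations motifs x cells z-score matrix (or a
#'   \code{deviation_result}).
#' @return Named numeric vector: sample standard deviation of each row.
#' @export
compute_variability <- function(deviations) {
  if (inherits(deviations, "deviation_result"))
    deviations <- deviations$deviations
  if (ncol(deviations) < 2L) stop("need >= 2 cells")
  apply(deviations, 1, stats::sd)
}
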