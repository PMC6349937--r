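#' Build co-expression regulons for transcription factors
#'
#' A documented simplification of the SCENIC regulon step: a TF's
#' candidate targets are the genes whose Spearman correlation with the
#' TF's own expression across cells is at least \code{corr_min}.  When
#' motif context is supplied (a motif hit index plus peak and gene
#' tables), candidates are pruned to genes having a peak with a
#' qualifying motif of that TF within \code{tss_window} bp of their
#' TSS.  The TF's own gene is always a member.  Regulons smaller than
#' \code{min_size} are dropped.
#'
#' @param ge_norm normalized genes x cells expression matrix with
#'   rownames = gene ids.
#' @param tf_names character vector of TF gene ids.
#' @param motif_hit_index optional named list (by TF) of peak index
#'   vectors from \code{\link{build_motif_hit_index}}.
#' @param peaks,genes interval and gene tables; required with
#'   \code{motif_hit_index}.
#' @param corr_min minimum Spearman correlation (default 0.3).
#' @param min_size minimum regulon size including the TF gene
#'   (default 10).
#' @param tss_window TSS window for motif pruning in bp (default 1e4).
#' @return Named list of regulons; each a list with \code{tf_name},
#'   \code{targets} (character vector including the TF gene) and
#'   \code{provenance}.
#' @export
build_regulons <- function(ge_norm, tf_names, motif_hit_index = NULL,
                           peaks = NULL, genes = NULL, corr_min = 0.3,
                           min_size = 10L, tss_window = 1e4) {
  gene_ids <- rownames(ge_norm)
  ranks <- t(apply(ge_norm, 1, rank, ties.method = "average"))
  out <- list()
  for (tf in tf_names) {
    if (!tf %in% gene_ids) {
      warning("TF gene absent from expression matrix: ", tf)
      next
    }
    rtf <- ranks[tf, ]
    if (stats::var(rtf) == 0) next
    ok <- apply(ranks, 1, function(rg) stats::var(rg) > 0)
    rho <- rep(NA_real_, length(gene_ids))
    rho[ok] <- apply(ranks[ok, , drop = FALSE], 1, stats::cor, y = rtf)
    cand <- gene_ids[!is.na(rho) & rho >= corr_min & gene_ids != tf]
    if (!is.null(motif_hit_index)) {
      hit_peaks <- motif_hit_index[[tf]]
      if (is.null(hit_peaks)) hit_peaks <- integer(0)
      if (length(hit_peaks) && !is.null(peaks) && !is.null(genes)) {
        near <- unique(unlist(
          assign_peak_target_genes(peaks[hit_peaks, , drop = FALSE],
                                   genes, window = tss_window)))
        cand <- intersect(cand, near)
      } else cand <- character(0)
    }
    targets <- union(tf, cand)
    if (length(targets) < min_size) next
    out[[tf]] <- list(tf_name = tf, targets = targets,
                      provenance = sprintf(
                        "co-expression rho >= %.2f%s", corr_min,
                        if (is.null(motif_hit_index)) "" else " + motif pruning"))
  }
  out
}

#' Area under the recovery curve of a regulon in one cell
#'
#' Genes are ranked by expression in the cell (descending; ties broken
#' by stable gene order).  The recovery curve counts regulon genes
#' cumulatively over the top \code{ceiling(top_frac * n)} ranks; its
#' area is normalized by the maximum achievable area (all regulon genes
#' packed at the top), so a perfectly packed regulon scores 1 and a
#' regulon absent from the top fraction scores 0.  Being rank-based,
#' the score is invariant to monotone transformations of expression.
#'
#' @param expression numeric vector of one cell's expression, named or
#'   ordered as the gene universe.
#' @param regulon a regulon from \code{\link{build_regulons}}, or a
#'   character vector of gene ids, or integer gene indices.
#' @param top_frac fraction of top-ranked genes integrated over
#'   (default 0.05).
#' @return AUC in [0, 1].
#' @export
recovery_auc <- function(expression, regulon, top_frac = 0.05) {
  n <- length(expression)
  m <- ceiling(top_frac * n)
  if (m < 1L) stop("top_frac too small: empty top set")
  if (is.list(regulon)) regulon <- regulon$targets
  if (is.character(regulon)) {
    if (is.null(names(expression))) stop("named expression vector required")
    member <- names(expression) %in% regulon
  } else member <- seq_len(n) %in% regulon
  R <- sum(member)
  if (R == 0L) stop("empty regulon (no genes in the universe)")
  ord <- order(-expression, seq_len(n))   # stable tie-break by gene order
  cum <- cumsum(member[ord][seq_len(m)])
  area <- sum(cum)
  max_cum <- pmin(seq_len(m), R)
  area / sum(max_cum)
}

#' AUC matrix for all regulons and cells
#'
#' @param ge_norm normalized genes x cells matrix with rownames.
#' @param regulons list from \code{\link{build_regulons}}.
#' @param top_frac see \code{\link{recovery_auc}}.
#' @return TFs x cells matrix of AUC scores.
#' @export
regulon_auc_matrix <- function(ge_norm, regulons, top_frac = 0.05) {
  gene_ids <- rownames(ge_norm)
  n <- length(gene_ids)
  m <- ceiling(top_frac * n)
  auc <- matrix(NA_real_, length(regulons), ncol(ge_norm),
                dimnames = list(names(regulons), colnames(ge_norm)))
  member <- lapply(regulons, function(r) gene_ids %in% r$targets)
  for (c_i in seq_len(ncol(ge_norm))) {
    ord <- order(-ge_norm[, c_i], seq_len(n))[seq_len(m)]
    for (t_i in seq_along(regulons)) {
      mem <- member[[t_i]]
      R <- sum(mem)
      cum <- cumsum(mem[ord])
      auc[t_i, c_i] <- sum(cum) / sum(pmin(seq_len(m), R))
    }
  }
  auc
}

#' Binarize a TF's per-cell AUC scores
#'
#' Fits a two-component univariate Gaussian mixture to the AUC
#' distribution and places the threshold where the posterior flips
#' between components (searched between the component means).  When the
#' components are indistinct (mean separation below half the summed
#' standard deviations) the fit falls back to mean + 2 sd, so a lone
#' outlier cell is still called active while unimodal rows come out all
#' inactive.
#'
#' @param auc numeric vector of one TF's AUC scores across >= 10 cells.
#' @param n_restarts EM restarts (default 10).
#' @param seed seed for the restart initializations.
#' @return List with \code{threshold} and \code{active} (0/1 integer
#'   vector; \code{active = AUC >= threshold}).
#' @export
binarize_activity <- function(auc, n_restarts = 10L, seed = 1L) {
  n <- length(auc)
  if (n < 10L) stop("need >= 10 cells to binarize")
  if (stats::var(auc) == 0) {
    warning("constant AUC row: all cells called inactive")
    return(list(threshold = Inf, active = rep(0L, n)))
  }
  fit <- .em_mixture2(auc, n_restarts = n_restarts, seed = seed)
  thr <- NULL
  if (!is.null(fit)) {
    lo <- which.min(fit$mu); hi <- which.max(fit$mu)
    sg <- sqrt(fit$sigma2)
    if (abs(fit$mu[hi] - fit$mu[lo]) >= 0.5 * (sg[lo] + sg[hi])) {
      # smallest point between the means where the posterior flips
      grid <- seq(fit$mu[lo], fit$mu[hi], length.out = 512L)
      d_lo <- fit$pi[lo] * stats::dnorm(grid, fit$mu[lo], sg[lo])
      d_hi <- fit$pi[hi] * stats::dnorm(grid, fit$mu[hi], sg[hi])
      flips <- which(d_hi >= d_lo)
      if (length(flips)) thr <- grid[flips[1L]]
    }
  }
  if (is.null(thr)) {                     # indistinct components
    thr <- mean(auc) + 2 * stats::sd(auc)
    if (all(auc < thr)) return(list(threshold = thr, active = rep(0L, n)))
  }
  list(threshold = thr, active = as.integer(auc >= thr))
}

# two-component univariate Gaussian mixture by EM with random restarts;
# a variance floor keeps near-degenerate components (many tied values)
# fittable
.em_mixture2 <- function(x, n_restarts = 10L, max_iter = 300L,
                         tol = 1e-8, seed = 1L) {
  n <- length(x)
  vfloor <- max(1e-10, 1e-6 * stats::var(x))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    mu <- sample(x, 2L)
    if (mu[1L] == mu[2L]) mu <- range(x)
    s2 <- rep(stats::var(x) / 4 + vfloor, 2L)
    p <- c(0.5, 0.5)
    ll_prev <- -Inf; ll <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- p[1L] * stats::dnorm(x, mu[1L], sqrt(s2[1L]))
      d2 <- p[2L] * stats::dnorm(x, mu[2L], sqrt(s2[2L]))
      tot <- pmax(d1 + d2, .Machine$double.xmin)
      z <- d1 / tot
      ll <- sum(log(tot))
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * (1 + abs(ll))) break
      ll_prev <- ll
      n1 <- sum(z); n2 <- n - n1
      if (n1 < 1e-8 || n2 < 1e-8) break
      mu <- c(sum(z * x) / n1, sum((1 - z) * x) / n2)
      s2 <- pmax(c(sum(z * (x - mu[1L])^2) / n1,
                   sum((1 - z) * (x - mu[2L])^2) / n2), vfloor)
      p <- c(n1 / n, n2 / n)
    }
    if (is.finite(ll) && (is.null(best) || ll > best$ll))
      best <- list(mu = mu, sigma2 = s2, pi = p, ll = ll)
  }
  best
}

#' Per-cell TF activity from regulon AUC scores
#'
#' @param auc TFs x cells AUC matrix from \code{\link{regulon_auc_matrix}}.
#' @return List of class \code{tf_activity} with \code{auc},
#'   \code{active} (TFs x cells binary) and \code{threshold} per TF.
#' @export
tf_activity <- function(auc) {
  act <- matrix(0L, nrow(auc), ncol(auc), dimnames = dimnames(auc))
  thr <- setNames(rep(NA_real_, nrow(auc)), rownames(auc))
  for (i in seq_len(nrow(auc))) {
    b <- binarize_activity(auc[i, ])
    act[i, ] <- b$active
    thr[i] <- b$threshold
  }
  structure(list(auc = auc, active = act, threshold = thr),
            class = "tf_activity")
}

.BASES <- c("A", "C", "G", "T")

# 4 x L log2-odds matrix from a pwm_record
.log_odds <- function(pwm, background = rep(0.25, 4)) {
  p <- pwm$matrix
  if (any(p == 0))
    stop("zero probability in PWM '", pwm$tf_name,
         "': use a positive pseudocount")
  log2(p / background)
}

#' Maximum attainable PWM log-odds score
#'
#' The sum over motif positions of the per-position maximum of the
#' log2(probability / background) matrix.
#'
#' @param pwm a \code{pwm_record}.
#' @param background background base probabilities (A, C, G, T).
#' @return Maximum score (real).
#' @export
pwm_max_score <- function(pwm, background = rep(0.25, 4)) {
  sum(apply(.log_odds(pwm, background), 2, max))
}

#' Minimum attainable PWM log-odds score
#' @inheritParams pwm_max_score
#' @return Minimum score (real).
#' @export
pwm_min_score <- function(pwm, background = rep(0.25, 4)) {
  sum(apply(.log_odds(pwm, background), 2, min))
}

#' Scan a sequence for PWM matches on both strands
#'
#' Every window of motif length on the forward and reverse-complement
#' strand is scored with the log2-odds matrix; windows containing N are
#' skipped.  A window is a hit when its score fraction reaches
#' \code{match_fraction}.  Because log-odds scores can be negative, the
#' fraction is computed on the score shifted to the minimum attainable
#' score by default -- (score - min) / (max - min) -- which keeps a
#' "fraction of the highest possible score" well defined; set
#' \code{fraction_type = "ratio"} for the literal score / max ratio.
#'
#' @param sequence a character string over A, C, G, T, N (case
#'   insensitive).
#' @param pwm a \code{pwm_record}.
#' @param match_fraction minimum score fraction (default 0.95).
#' @param fraction_type \code{"shifted"} (default) or \code{"ratio"}.
#' @param background background base probabilities.
#' @return data.frame with columns \code{offset} (0-based window start
#'   on the forward strand), \code{strand}, \code{score},
#'   \code{score_fraction}.
#' @export
scan_peak <- function(sequence, pwm, match_fraction = 0.95,
                      fraction_type = c("shifted", "ratio"),
                      background = rep(0.25, 4)) {
  fraction_type <- match.arg(fraction_type)
  lo <- .log_odds(pwm, background)
  L <- ncol(lo)
  smax <- sum(apply(lo, 2, max))
  smin <- sum(apply(lo, 2, min))
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), score_fraction = numeric(0))
  chars <- strsplit(toupper(sequence), "")[[1L]]
  n <- length(chars)
  if (n < L) return(empty)
  code <- match(chars, .BASES)           # NA for N or other letters
  frac_of <- function(s) {
    if (fraction_type == "shifted") {
      if (smax == smin) return(rep(1, length(s)))
      (s - smin) / (smax - smin)
    } else s / smax
  }
  scan_strand <- function(code_vec, strand) {
    nw <- length(code_vec) - L + 1L
    if (nw < 1L) return(empty)
    scores <- numeric(nw)
    has_n <- logical(nw)                  # windows containing N are skipped
    for (j in seq_len(L)) {
      cj <- code_vec[j:(j + nw - 1L)]
      nas <- is.na(cj)
      has_n <- has_n | nas
      cj[nas] <- 1L
      scores <- scores + lo[cbind(cj, j)]
    }
    scores[has_n] <- NA_real_
    fr <- frac_of(scores)
    hit <- which(!is.na(scores) & fr >= match_fraction)
    if (length(hit) == 0L) return(empty)
    off <- if (strand == "+") hit - 1L else (length(code_vec) - (hit + L - 1L))
    data.frame(offset = off, strand = strand, score = scores[hit],
               score_fraction = fr[hit])
  }
  rc <- rev(5L - code)                    # A<->T (1<->4), C<->G (2<->3)
  out <- rbind(scan_strand(code, "+"), scan_strand(rc, "-"))
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Build the peak-to-TF motif hit index
#'
#' Scans every peak sequence with every PWM and records, per TF, the
#' peaks carrying at least one qualifying match, with the best score
#' fraction.
#'
#' @param peak_sequences character vector of peak sequences (or a
#'   \code{Biostrings::DNAStringSet}).
#' @param pwms list of \code{pwm_record}s.
#' @param match_fraction,fraction_type,background see
#'   \code{\link{scan_peak}}.
#' @return Named list (by TF) of integer peak-index vectors, with a
#'   parallel \code{"best_fraction"} attribute per TF.
#' @export
build_motif_hit_index <- function(peak_sequences, pwms,
                                  match_fraction = 0.95,
                                  fraction_type = "shifted",
                                  background = rep(0.25, 4)) {
  if (methods::is(peak_sequences, "XStringSet"))
    peak_sequences <- as.character(peak_sequences)
  out <- list()
  for (pw in pwms) {
    hits <- integer(0)
    best <- numeric(0)
    for (p in seq_along(peak_sequences)) {
      h <- scan_peak(peak_sequences[p], pw, match_fraction,
                     fraction_type, background)
      if (nrow(h) > 0L) {
        hits <- c(hits, p)
        best <- c(best, max(h$score_fraction))
      }
    }
    attr(hits, "best_fraction") <- best
    out[[pw$tf_name]] <- hits
  }
  out
}

#' Label accessible regions as active per cell
#'
#' A peak is active in a cell when some TF both has a qualifying motif
#' hit in the peak and is called active in that cell -- and, by
#' default, the peak shows at least one fragment in that cell.  The
#' mask is monotone in TF activity: adding an active TF with a hit can
#' only switch cells on.
#'
#' @param motif_hit_index named list from
#'   \code{\link{build_motif_hit_index}}.
#' @param activity a \code{tf_activity} object (or TFs x cells binary
#'   matrix with TF rownames).
#' @param ca_counts peaks x cells raw counts; required when
#'   \code{require_fragment}.
#' @param n_peaks number of peaks (rows of the mask).
#' @param require_fragment additionally require a fragment in the cell
#'   (default TRUE).
#' @return Binary peaks x cells matrix.
#' @export
label_active_regions <- function(motif_hit_index, activity, ca_counts = NULL,
                                 n_peaks = if (!is.null(ca_counts)) nrow(ca_counts) else NULL,
                                 require_fragment = TRUE) {
  active <- if (inherits(activity, "tf_activity")) activity$active else activity
  if (is.null(n_peaks)) stop("n_peaks required when ca_counts absent")
  n_cells <- ncol(active)
  hits_mat <- matrix(0L, nrow(active), n_peaks,
                     dimnames = list(rownames(active), NULL))
  for (tf in rownames(active)) {
    idx <- motif_hit_index[[tf]]
    if (length(idx)) hits_mat[tf, idx] <- 1L
  }
  if (sum(hits_mat) == 0L)
    warning("empty motif hit index: all-zero activity mask")
  mask <- (t(hits_mat) %*% active > 0) + 0L   # peaks x cells
  if (require_fragment) {
    if (is.null(ca_counts)) stop("ca_counts required with require_fragment")
    mask <- mask * ((as.matrix(ca_counts) >= 1) + 0L)
  }
  colnames(mask) <- colnames(active)
  mask
}
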