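#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius loss ||V - WH|| by Lee-Seung multiplicative
#' updates from multiple random restarts.  The best restart (lowest
#' final loss) supplies W and H; every restart's W is kept for the mean
#' Amari distance, and a consensus connectivity matrix is averaged over
#' restarts (cells connected when the argmax of their H column agrees).
#' All-zero rows or columns of V are dropped with a warning before
#' factorization; the returned object records the kept indices.
#'
#' Initialization is uniform random, scaled so E[WH] matches the matrix
#' mean; the restart seeds are derived from \code{seed + restart index},
#' so a fixed seed gives a bitwise-reproducible result.
#'
#' @param V non-negative features x cells matrix.
#' @param K factorization rank (>= 1, < min(dim(V))).
#' @param n_restarts random restarts (default 20).
#' @param max_iter maximum update iterations per restart (default 1000).
#' @param tol relative loss-change convergence tolerance, checked every
#'   10 iterations (default 1e-6).
#' @param seed master seed for the restart initializations.
#' @return An object of class \code{nmf_result}: \code{W}, \code{H},
#'   \code{K}, \code{frobenius_error} (relative, best restart),
#'   \code{restart_errors}, \code{restart_W}, \code{consensus},
#'   \code{mean_amari}, \code{kept_rows}, \code{kept_cols}.
#' @export
nmf_factorize <- function(V, K, n_restarts = 20L, max_iter = 1000L,
                          tol = 1e-6, seed = 1L) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  kept_rows <- which(rowSums(V) > 0)
  kept_cols <- which(colSums(V) > 0)
  if (length(kept_rows) < nrow(V) || length(kept_cols) < ncol(V)) {
    warning("dropping ", nrow(V) - length(kept_rows), " all-zero row(s) and ",
            ncol(V) - length(kept_cols), " all-zero column(s)")
    V <- V[kept_rows, kept_cols, drop = FALSE]
  }
  n <- nrow(V); m <- ncol(V)
  if (K >= min(n, m)) stop("K must be smaller than both matrix dimensions")
  if (K < 1L) stop("K must be >= 1")
  eps <- 1e-10
  normV <- sqrt(sum(V^2))
  best <- NULL
  errors <- numeric(n_restarts)
  Ws <- vector("list", n_restarts)
  conn_sum <- matrix(0, m, m)
  sc <- 2 * sqrt(mean(V) / K)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    W <- matrix(stats::runif(n * K), n, K) * sc
    H <- matrix(stats::runif(K * m), K, m) * sc
    loss_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V) / (crossprod(W) %*% H + eps))
      W <- W * (tcrossprod(V, H) / (W %*% tcrossprod(H) + eps))
      if (it %% 10L == 0L || it == max_iter) {
        loss <- sqrt(sum((V - W %*% H)^2))
        if (is.finite(loss_prev) &&
            abs(loss_prev - loss) <= tol * max(loss_prev, eps)) break
        loss_prev <- loss
      }
    }
    err <- sqrt(sum((V - W %*% H)^2)) / normV
    errors[r] <- err
    Ws[[r]] <- W
    assign_r <- apply(H, 2, which.max)
    conn_sum <- conn_sum + outer(assign_r, assign_r, "==")
    if (is.null(best) || err < best$err)
      best <- list(W = W, H = H, err = err)
  }
  consensus <- conn_sum / n_restarts
  mean_amari <- if (n_restarts > 1L) {
    pairs <- utils::combn(n_restarts, 2L)
    mean(apply(pairs, 2, function(ij)
      amari_distance(Ws[[ij[1L]]], Ws[[ij[2L]]])))
  } else 0
  structure(list(W = best$W, H = best$H, K = K,
                 frobenius_error = best$err, restart_errors = errors,
                 restart_W = Ws, consensus = consensus,
                 mean_amari = mean_amari,
                 kept_rows = kept_rows, kept_cols = kept_cols),
            class = "nmf_result")
}

#' @export
print.nmf_result <- function(x, ...) {
  cat("nmf_result: K =", x$K, "|", nrow(x$W), "features x", ncol(x$H),
      "cells | relative Frobenius error", signif(x$frobenius_error, 4),
      "| mean Amari", signif(x$mean_amari, 4), "\n")
  invisible(x)
}

#' Amari distance between two factor matrices
#'
#' Computed from the column cross-correlation matrix C of the two W
#' matrices as 1 - (sum of row maxima + sum of column maxima) / (2K).
#' The distance is 0 exactly when the columns of one matrix are a
#' permutation and positive rescaling of the other's, symmetric in its
#' arguments, and grows toward 1 as the column spaces decouple.
#'
#' @param W1,W2 feature x K non-negative matrices with equal dimensions
#'   and no zero columns.
#' @return Non-negative distance.
#' @export
amari_distance <- function(W1, W2) {
  if (!all(dim(W1) == dim(W2))) stop("W1 and W2 must share dimensions")
  if (any(apply(W1, 2, stats::sd) == 0) || any(apply(W2, 2, stats::sd) == 0))
    stop("zero/constant column in factor matrix")
  K <- ncol(W1)
  C <- stats::cor(W1, W2)
  1 - (sum(apply(C, 1, max)) + sum(apply(C, 2, max))) / (2 * K)
}

#' Cophenetic correlation of a consensus matrix
#'
#' Average-linkage hierarchical clustering of the consensus
#' dissimilarities (1 - consensus); the coefficient is the Pearson
#' correlation between the cophenetic distances of the dendrogram and
#' the original dissimilarities.  Values near 1 indicate stable
#' cluster structure across restarts.
#'
#' @param consensus symmetric matrix with entries in [0, 1] and unit
#'   diagonal.
#' @return Correlation in [-1, 1]; a degenerate (constant-distance)
#'   consensus returns 1 by convention with a warning.
#' @export
cophenetic_coefficient <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) {
    warning("constant consensus distances: cophenetic coefficient ",
            "undefined, returning 1 by convention")
    return(1)
  }
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(cd) == 0) {
    warning("constant cophenetic distances: returning 1 by convention")
    return(1)
  }
  stats::cor(d, cd)
}

#' Select the NMF factorization rank
#'
#' Factorizes V at every K in \code{k_range} and scores each rank by
#' three criteria: the relative Frobenius-error drop from the previous
#' rank (elbow; the raw error always falls with K, so the drop is what
#' is minimized-over), the mean Amari distance across restarts (small =
#' stable), and the cophenetic correlation of the consensus matrix
#' (large = stable).  Each criterion ranks the candidate Ks; the
#' selected K has the best (smallest) mean rank, ties resolved toward
#' the smaller K.
#'
#' @param V non-negative matrix.
#' @param k_range integer vector of candidate ranks (default 2:6).
#' @param n_restarts,max_iter,tol,seed passed to
#'   \code{\link{nmf_factorize}}.
#' @return List with \code{K} (selected rank), \code{metrics}
#'   (data.frame: K, frobenius_error, frobenius_drop, mean_amari,
#'   cophenetic, mean_rank) and \code{fits} (named list of
#'   \code{nmf_result}s).
#' @export
select_rank <- function(V, k_range = 2:6, n_restarts = 20L,
                        max_iter = 1000L, tol = 1e-6, seed = 1L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) >= min(dim(V)))
    stop("k_range exceeds matrix dimensions")
  fits <- lapply(k_range, function(k)
    nmf_factorize(V, k, n_restarts = n_restarts, max_iter = max_iter,
                  tol = tol, seed = seed))
  names(fits) <- paste0("K", k_range)
  err <- vapply(fits, `[[`, 0, "frobenius_error")
  # baseline error one rank below the smallest candidate, for the first drop
  base_k <- min(k_range) - 1L
  base_err <- if (base_k >= 1L)
    nmf_factorize(V, base_k, n_restarts = max(5L, n_restarts %/% 2L),
                  max_iter = max_iter, tol = tol, seed = seed)$frobenius_error
  else 1
  prev <- c(base_err, err[-length(err)])
  drop <- (prev - err) / pmax(prev, .Machine$double.eps)
  amari <- vapply(fits, `[[`, 0, "mean_amari")
  coph <- vapply(fits, function(f)
    suppressWarnings(cophenetic_coefficient(f$consensus)), 0)
  score <- rank(-drop, ties.method = "min") +
    rank(amari, ties.method = "min") +
    rank(-coph, ties.method = "min")
  # stability metrics saturate when several ranks are all stable; the
  # error elbow still discriminates there, so it arbitrates score ties
  # (remaining ties fall to the smaller K)
  cand <- which(score == min(score))
  best <- k_range[cand[which.max(drop[cand])]]
  metrics <- data.frame(K = k_range, frobenius_error = err,
                        frobenius_drop = drop, mean_amari = amari,
                        cophenetic = coph, mean_rank = score / 3)
  list(K = best, metrics = metrics, fits = fits)
}

#' Extract signature-exclusive features from W
#'
#' Rows of W are normalized to sum 1; a feature belongs to signature s
#' when its normalized weight on s reaches \code{exclusivity}, i.e. it
#' contributes (almost) exclusively to that one signature.  Features
#' meeting the threshold for no signature, and all-zero rows, are
#' unassigned.
#'
#' @param W features x K matrix from the best factorization.
#' @param exclusivity normalized-weight threshold in (0.5, 1]
#'   (default 0.75).
#' @return List of length K of integer feature-index vectors, plus an
#'   \code{"unassigned"} attribute.
#' @export
extract_signature_features <- function(W, exclusivity = 0.75) {
  rs <- rowSums(W)
  norm <- W / ifelse(rs > 0, rs, 1)
  assigned <- apply(norm, 1, function(x) {
    j <- which(x >= exclusivity)
    if (length(j) == 1L) j else NA_integer_
  })
  assigned[rs == 0] <- NA_integer_
  out <- lapply(seq_len(ncol(W)), function(s) which(assigned == s))
  names(out) <- colnames(W) %||% paste0("signature", seq_len(ncol(W)))
  attr(out, "unassigned") <- which(is.na(assigned))
  out
}

#' Cross-rank signature similarity by non-negative least squares
#'
#' Regresses each signature (column) of the higher-rank W onto the
#' columns of the lower-rank W under a non-negativity constraint and
#' normalizes each coefficient column to sum 1, giving the mixing
#' proportions with which rank-K signatures compose each rank-K'
#' signature.
#'
#' @param W_k features x K matrix (lower rank).
#' @param W_k1 features x K' matrix (next rank), same feature rows.
#' @return K x K' column-stochastic non-negative matrix.
#' @export
rank_similarity <- function(W_k, W_k1) {
  if (nrow(W_k) != nrow(W_k1)) stop("W matrices must share feature rows")
  K <- ncol(W_k); K1 <- ncol(W_k1)
  out <- matrix(0, K, K1)
  for (j in seq_len(K1)) {
    coef <- pracma::lsqnonneg(W_k, W_k1[, j])$x
    s <- sum(coef)
    out[, j] <- if (s > 0) coef / s else coef
  }
  out
}
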