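# shared small fixtures, built in code

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# a tiny deterministic omics pair: 4 peaks, 3 genes, 6 cells
tiny_pair <- function() {
  ca <- matrix(c(2, 0, 3, 2, 1, 2,
                 0, 0, 1, 0, 0, 0,
                 5, 4, 6, 5, 4, 5,
                 2, 2, 2, 2, 2, 2), nrow = 4, byrow = TRUE,
               dimnames = list(paste0("p", 1:4), paste0("c", 1:6)))
  ge <- matrix(c(4, 5, 6, 3, 4, 5,
                 0, 0, 0, 0, 0, 1,
                 9, 7, 8, 9, 8, 7), nrow = 3, byrow = TRUE,
               dimnames = list(paste0("g", 1:3), paste0("c", 1:6)))
  peaks <- genomic_intervals(rep("chr1", 4),
                             c(1000, 5000, 9000, 20000),
                             c(1500, 5500, 9500, 20500),
                             name = paste0("p", 1:4))
  genes <- data.frame(gene_id = paste0("g", 1:3), chrom = "chr1",
                      start = c(1200, 8000, 30000),
                      end = c(3200, 10000, 32000),
                      strand = c("+", "-", "+"),
                      tss = c(1200, 9999, 30000),
                      stringsAsFactors = FALSE)
  omics_pair(ca, ge, peaks, genes)
}

# consensus-style PWM record without file round trip
consensus_pwm <- function(name, consensus, hit = 85, miss = 5, pseudo = 1) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  counts <- matrix(miss, 4, L, dimnames = list(bases, NULL))
  cc <- strsplit(consensus, "")[[1]]
  counts[cbind(match(cc, bases), seq_len(L))] <- hit
  probs <- sweep(counts + pseudo, 2, colSums(counts + pseudo), "/")
  structure(list(tf_name = name, matrix = probs, pseudocount = pseudo),
            class = "pwm_record")
}

# irregular random PFM: counts drawn independently per cell, so window
# score fractions never sit exactly on round thresholds
random_pwm <- function(name, k, pseudo = 1) {
  counts <- matrix(sample(1:60, 4 * k, replace = TRUE), 4, k,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  probs <- sweep(counts + pseudo, 2, colSums(counts + pseudo), "/")
  structure(list(tf_name = name, matrix = probs, pseudocount = pseudo),
            class = "pwm_record")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(s)
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))

# independent brute-force PWM scanner used as oracle against scan_peak
brute_force_scan <- function(sequence, pwm, match_fraction = 0.95) {
  lo <- log2(pwm$matrix / 0.25)
  L <- ncol(lo)
  smax <- sum(apply(lo, 2, max)); smin <- sum(apply(lo, 2, min))
  score_of <- function(word) {
    idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
    if (anyNA(idx)) return(NA_real_)
    sum(lo[cbind(idx, seq_len(L))])
  }
  seqs <- list(`+` = toupper(sequence),
               `-` = revcomp_chr(toupper(sequence)))
  hits <- list()
  n <- nchar(sequence)
  for (st in names(seqs)) {
    s <- seqs[[st]]
    for (i in seq_len(n - L + 1)) {
      sc <- score_of(substr(s, i, i + L - 1))
      if (is.na(sc)) next
      fr <- (sc - smin) / (smax - smin)
      if (fr >= match_fraction) {
        off <- if (st == "+") i - 1L else n - (i + L - 1L)
        hits[[length(hits) + 1]] <- data.frame(
          offset = off, strand = st, score = sc, score_fraction = fr)
      }
    }
  }
  if (!length(hits))
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0), score_fraction = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(out$offset, out$strand), , drop = FALSE]
}

# exact two-sided Wilcoxon p by full enumeration of rank assignments
enumerate_wilcoxon_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(na)])
  splits <- utils::combn(na + nb, na)
  w_all <- apply(splits, 2, function(ix) sum(r[ix]))
  mu <- na * (na + nb + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
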