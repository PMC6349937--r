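# Synthetic paired-omics generator.  The design plants three layers of
# ground truth -- cell types, per-type TF programs, and peak->gene
# regulatory links -- in a block-structured genome so that every
# motif-bearing peak has a known, isolated neighbourhood:
#   * link blocks:    one target gene + one motif-bearing peak whose
#                     accessibility and the gene's expression both track
#                     the resident TF's activity (the planted link);
#   * decoy blocks:   one motif-bearing peak next to flat genes -- honest
#                     null tests for the link inference;
#   * program blocks: TF genes and their co-expression target genes,
#                     motif-free, feeding regulon discovery;
# plus motif-free promoter and background peaks.  Blocks are spaced
# 3 Mb apart so 1 Mb search windows never cross blocks.

#' Configuration for the synthetic paired-omics generator
#'
#' Defaults describe the benchmark condition used throughout the
#' package: 300 cells in 3 equal types, 500 genes, 2000 peaks, 10 TFs,
#' 100 planted links with a 1.0 log2 expression effect, sparse Poisson
#' accessibility and over-dispersed negative-binomial expression with
#' dropout.
#'
#' @param n_cells,n_cell_types,n_genes,n_peaks,n_tfs,n_links problem sizes.
#' @param link_effect_size log2 fold change on target expression when
#'   the linked region is active.
#' @param ca_mean_fragments baseline Poisson mean of peak fragments.
#' @param ca_activity_multiplier fold increase of accessibility at
#'   type-active peaks.
#' @param ge_mean_counts baseline negative-binomial mean of gene counts.
#' @param ge_dispersion negative-binomial size parameter.
#' @param dropout_rate Bernoulli zeroing probability on GE counts.
#' @param tf_effect_size log2 on/off contrast of TF genes and program
#'   targets between cells of the TF's active type and the rest
#'   (lineage-marker scale).
#' @param activity_sigma standard deviation of the per-cell log-normal
#'   TF activity fluctuation shared by a TF's gene and all its program
#'   targets; this shared factor is what makes regulon co-expression
#'   discoverable, mimicking cell-to-cell TF activity variation.
#' @param tf_program_size co-expressed target genes per TF.
#' @param n_decoy_peaks motif-bearing peaks planted next to flat genes.
#' @param motif_length,peak_width sequence dimensions in bp.
#' @param seed RNG seed.
#' @return A list of class \code{synth_config}.
#' @export
synth_config <- function(n_cells = 300L, n_cell_types = 3L, n_genes = 500L,
                         n_peaks = 2000L, n_tfs = 10L, n_links = 100L,
                         link_effect_size = 1.0, ca_mean_fragments = 2,
                         ca_activity_multiplier = 4, ge_mean_counts = 5,
                         ge_dispersion = 2, dropout_rate = 0.15,
                         tf_effect_size = 4, activity_sigma = 0.8,
                         tf_program_size = 20L,
                         n_decoy_peaks = 30L, motif_length = 12L,
                         peak_width = 500L, seed = 17L) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("n_cells", "n_cell_types", "n_genes", "n_peaks",
                       "n_tfs", "n_links", "motif_length", "peak_width")]) <= 0))
    stop("all counts must be positive")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (cfg$n_links > cfg$n_peaks) stop("more links than peaks: infeasible")
  ngene_needed <- cfg$n_links + cfg$n_tfs +
    cfg$n_tfs * cfg$tf_program_size + 2L * cfg$n_decoy_peaks
  if (cfg$n_genes < ngene_needed)
    stop("n_genes too small: need at least ", ngene_needed)
  if (cfg$n_peaks < cfg$n_links + cfg$n_decoy_peaks + cfg$n_genes)
    stop("n_peaks too small for planted + decoy + promoter peaks")
  structure(cfg, class = "synth_config")
}

.random_consensus <- function(n, len) {
  repeat {
    cons <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")
    if (!anyDuplicated(cons)) return(cons)
  }
}

.consensus_pfm <- function(name, consensus, hit_count = 85, miss_count = 5,
                           pseudocount = 1) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(consensus)
  counts <- matrix(miss_count, 4, L, dimnames = list(bases, NULL))
  cc <- strsplit(consensus, "")[[1L]]
  counts[cbind(match(cc, bases), seq_len(L))] <- hit_count
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts + pseudocount), "/")
  structure(list(tf_name = name, matrix = probs, pseudocount = pseudocount),
            class = "pwm_record")
}

.revcomp <- function(s) chartr("ACGT", "TGCA",
                               paste(rev(strsplit(s, "")[[1L]]), collapse = ""))

#' Generate a synthetic paired CA/GE data set with planted truth
#'
#' See \code{\link{synth_config}} for the generative model.  Cell types
#' are assigned in equal proportions; each TF is active in exactly one
#' type; peak fragment counts are Poisson with a type-dependent rate at
#' planted/decoy/boosted-promoter peaks; gene counts are negative
#' binomial with a \code{2^effect} mean shift in cells where the gene's
#' planted regulatory region (or TF program) is active, thinned by
#' Bernoulli dropout.  All draws come from the seeded generator, so a
#' fixed seed reproduces the data byte for byte.
#'
#' @param config a \code{synth_config}.
#' @return A list with \code{pair} (an \code{omics_pair}), \code{pwms},
#'   \code{peak_sequences} and \code{truth} (cell types, TF activity,
#'   planted links, motif placements, peak roles).
#' @export
generate_paired_omics <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n_types <- config$n_cell_types
  n_cells <- config$n_cells
  cell_type <- rep(seq_len(n_types), length.out = n_cells)
  cells <- sprintf("cell%03d", seq_len(n_cells))

  tf_names <- paste0("TF", seq_len(config$n_tfs))
  tf_type <- setNames(((seq_len(config$n_tfs) - 1L) %% n_types) + 1L,
                      tf_names)
  # TFs x cells planted activity
  tf_active <- outer(tf_type, cell_type, "==") + 0L
  dimnames(tf_active) <- list(tf_names, cells)

  consensus <- .random_consensus(config$n_tfs, config$motif_length)
  pwms <- lapply(seq_len(config$n_tfs), function(i)
    .consensus_pfm(tf_names[i], consensus[i]))
  names(pwms) <- tf_names

  ## ---- gene roles ------------------------------------------------------
  n_prog <- config$n_tfs * config$tf_program_size
  n_flat_decoy <- 2L * config$n_decoy_peaks
  roles <- c(rep("linked", config$n_links), rep("tf", config$n_tfs),
             rep("program", n_prog), rep("decoy_flat", n_flat_decoy))
  roles <- c(roles, rep("flat", config$n_genes - length(roles)))
  gene_id <- character(config$n_genes)
  gene_id[roles == "tf"] <- tf_names
  gene_id[roles != "tf"] <- sprintf("gene%04d", which(roles != "tf"))
  gene_tf <- rep(NA_integer_, config$n_genes)   # driving TF per gene
  gene_tf[roles == "linked"] <-
    ((seq_len(config$n_links) - 1L) %% config$n_tfs) + 1L
  gene_tf[roles == "tf"] <- seq_len(config$n_tfs)
  gene_tf[roles == "program"] <-
    rep(seq_len(config$n_tfs), each = config$tf_program_size)
  gene_effect <- rep(0, config$n_genes)
  gene_effect[roles == "linked"] <- config$link_effect_size
  gene_effect[roles %in% c("tf", "program")] <- config$tf_effect_size

  ## ---- genome layout ---------------------------------------------------
  block_size <- 3e6
  blocks_per_chrom <- 20L
  # one block per linked gene and per decoy peak; the rest of the genes
  # are packed five per block (they carry no motif peaks)
  n_pack <- sum(!roles %in% c("linked", "decoy_flat"))
  n_blocks <- config$n_links + config$n_decoy_peaks + ceiling(n_pack / 5) + 1L
  block_chrom <- paste0("chrS", ((seq_len(n_blocks) - 1L) %/% blocks_per_chrom) + 1L)
  block_pos <- ((seq_len(n_blocks) - 1L) %% blocks_per_chrom) * block_size

  gene_chrom <- character(config$n_genes)
  gene_tss <- numeric(config$n_genes)
  b <- 0L
  for (i in which(roles == "linked")) {
    b <- b + 1L
    gene_chrom[i] <- block_chrom[b]
    gene_tss[i] <- block_pos[b] + 1.5e6
  }
  decoy_block <- integer(config$n_decoy_peaks)
  di <- which(roles == "decoy_flat")
  for (j in seq_len(config$n_decoy_peaks)) {
    b <- b + 1L
    decoy_block[j] <- b
    g1 <- di[2L * j - 1L]; g2 <- di[2L * j]
    gene_chrom[c(g1, g2)] <- block_chrom[b]
    gene_tss[g1] <- block_pos[b] + 1.3e6
    gene_tss[g2] <- block_pos[b] + 1.7e6
  }
  pack <- which(!roles %in% c("linked", "decoy_flat"))
  for (k in seq_along(pack)) {
    if ((k - 1L) %% 5L == 0L) b <- b + 1L
    gene_chrom[pack[k]] <- block_chrom[b]
    gene_tss[pack[k]] <- block_pos[b] + 3e5 + ((k - 1L) %% 5L) * 5e5
  }
  genes <- data.frame(gene_id = gene_id, chrom = gene_chrom,
                      start = as.integer(gene_tss),
                      end = as.integer(gene_tss + 2000),
                      strand = "+", tss = as.integer(gene_tss),
                      stringsAsFactors = FALSE)

  ## ---- peak layout -----------------------------------------------------
  w <- config$peak_width
  peak_chrom <- character(0); peak_start <- numeric(0)
  peak_role <- character(0); peak_tf <- integer(0); peak_gene <- integer(0)
  # planted link peaks: 50-500 kb downstream of their gene's TSS
  li <- which(roles == "linked")
  off <- sample(seq(5e4, 5e5, by = 1e3), length(li), replace = TRUE)
  peak_chrom <- c(peak_chrom, gene_chrom[li])
  peak_start <- c(peak_start, gene_tss[li] + off)
  peak_role <- c(peak_role, rep("planted", length(li)))
  peak_tf <- c(peak_tf, gene_tf[li])
  peak_gene <- c(peak_gene, li)
  # decoy peaks at their block centres
  peak_chrom <- c(peak_chrom, block_chrom[decoy_block])
  peak_start <- c(peak_start, block_pos[decoy_block] + 1.5e6)
  peak_role <- c(peak_role, rep("decoy", config$n_decoy_peaks))
  peak_tf <- c(peak_tf, ((seq_len(config$n_decoy_peaks) - 1L) %%
                           config$n_tfs) + 1L)
  peak_gene <- c(peak_gene, rep(NA_integer_, config$n_decoy_peaks))
  # one motif-free promoter peak per gene
  peak_chrom <- c(peak_chrom, gene_chrom)
  peak_start <- c(peak_start, gene_tss - w / 2)
  peak_role <- c(peak_role, rep("promoter", config$n_genes))
  peak_tf <- c(peak_tf, gene_tf)          # promoter tracks its gene's TF
  peak_gene <- c(peak_gene, seq_len(config$n_genes))
  # background peaks at random positions in used blocks
  n_bg <- config$n_peaks - length(peak_role)
  bg_block <- sample(seq_len(n_blocks), n_bg, replace = TRUE)
  peak_chrom <- c(peak_chrom, block_chrom[bg_block])
  peak_start <- c(peak_start, block_pos[bg_block] +
                    round(stats::runif(n_bg, 0, block_size - w)))
  peak_role <- c(peak_role, rep("background", n_bg))
  peak_tf <- c(peak_tf, rep(NA_integer_, n_bg))
  peak_gene <- c(peak_gene, rep(NA_integer_, n_bg))

  peaks <- genomic_intervals(peak_chrom, as.integer(peak_start),
                             as.integer(peak_start + w),
                             name = sprintf("peak%04d", seq_along(peak_role)))
  n_peaks <- nrow(peaks)

  ## ---- peak sequences with planted motifs ------------------------------
  seqs <- vapply(seq_len(n_peaks), function(i)
    paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = ""),
    "")
  motif_tab <- list()
  carries <- which(peak_role %in% c("planted", "decoy"))
  for (i in carries) {
    t <- peak_tf[i]
    offm <- sample.int(w - config$motif_length, 1L)
    strand <- sample(c("+", "-"), 1L)
    ins <- if (strand == "+") consensus[t] else .revcomp(consensus[t])
    substr(seqs[i], offm + 1L, offm + config$motif_length) <- ins
    motif_tab[[length(motif_tab) + 1L]] <-
      data.frame(peak_index = i, tf = tf_names[t], offset = offm,
                 strand = strand, stringsAsFactors = FALSE)
  }
  motif_tab <- do.call(rbind, motif_tab)
  names(seqs) <- peaks$name

  ## ---- count matrices --------------------------------------------------
  # accessibility: type-elevated at planted/decoy peaks and at promoter
  # peaks of boosted genes
  lam <- matrix(config$ca_mean_fragments, n_peaks, n_cells)
  typed <- which(!is.na(peak_tf))
  for (i in typed) {
    active_cells <- cell_type == tf_type[peak_tf[i]]
    if (peak_role[i] == "promoter" && gene_effect[peak_gene[i]] == 0) next
    lam[i, active_cells] <- lam[i, active_cells] * config$ca_activity_multiplier
  }
  ca <- matrix(stats::rpois(n_peaks * n_cells, lam), n_peaks, n_cells,
               dimnames = list(peaks$name, cells))

  # shared per-(TF, cell) activity factor: type on/off contrast times
  # log-normal cell-to-cell fluctuation; a TF's own gene and all its
  # program targets ride the same factor, so they co-fluctuate
  act_factor <- 2^(config$tf_effect_size * tf_active) *
    exp(matrix(stats::rnorm(config$n_tfs * n_cells, 0, config$activity_sigma),
               config$n_tfs, n_cells))
  mu <- matrix(config$ge_mean_counts, config$n_genes, n_cells)
  for (i in which(roles %in% c("tf", "program")))
    mu[i, ] <- mu[i, ] * act_factor[gene_tf[i], ]
  # linked genes shift by the planted link effect when their region's
  # TF is active in the cell (deterministic, at the configured effect)
  for (i in which(roles == "linked")) {
    active_cells <- cell_type == tf_type[gene_tf[i]]
    mu[i, active_cells] <- mu[i, active_cells] * 2^gene_effect[i]
  }
  ge <- matrix(stats::rnbinom(config$n_genes * n_cells,
                              mu = mu, size = config$ge_dispersion),
               config$n_genes, n_cells,
               dimnames = list(gene_id, cells))
  if (config$dropout_rate > 0) {
    keep <- matrix(stats::rbinom(length(ge), 1L, 1 - config$dropout_rate),
                   nrow(ge), ncol(ge))
    ge <- ge * keep
  }

  truth <- list(
    cell_type = setNames(cell_type, cells),
    tf_type = tf_type,
    tf_active = tf_active,
    links = data.frame(peak_index = which(peak_role == "planted"),
                       gene_id = gene_id[li],
                       tf = tf_names[gene_tf[li]],
                       effect = config$link_effect_size,
                       stringsAsFactors = FALSE),
    motifs = motif_tab,
    peak_role = peak_role,
    gene_role = roles,
    consensus = setNames(consensus, tf_names))

  list(pair = omics_pair(ca, ge, peaks, genes), pwms = pwms,
       peak_sequences = seqs, truth = truth, config = config)
}

#' Score inferred links against the planted truth
#'
#' Exact (peak_index, gene_id) pair matching.
#'
#' @param inferred link data.frame with \code{peak_index},
#'   \code{gene_id}.
#' @param truth the \code{truth} element from
#'   \code{\link{generate_paired_omics}} (or its \code{links} table).
#' @return List with \code{precision}, \code{recall}, \code{f1},
#'   \code{n_true_positive}, \code{n_inferred}, \code{n_truth}, and
#'   \code{empty_inferred} flag (precision reported 0 when no links
#'   were inferred).
#' @export
evaluate_links <- function(inferred, truth) {
  tl <- if (is.data.frame(truth)) truth else truth$links
  if (is.null(tl) || nrow(tl) == 0L) stop("empty truth link set")
  tk <- paste(tl$peak_index, tl$gene_id, sep = "|")
  ik <- unique(paste(inferred$peak_index, inferred$gene_id, sep = "|"))
  tp <- sum(ik %in% tk)
  empty <- length(ik) == 0L
  precision <- if (empty) 0 else tp / length(ik)
  recall <- tp / length(tk)
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_true_positive = tp, n_inferred = length(ik), n_truth = length(tk),
       empty_inferred = empty)
}
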