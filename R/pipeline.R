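#' Run the full regulatory-link pipeline from a configuration
#'
#' Chains the stages -- simulate (or load), filter, normalize, TF
#' activity, link inference, NMF of the link matrix, chromatin
#' accessibility deviations, and (when interactions are supplied)
#' ChIA-PET validation -- writing per-stage outputs and a reproducibility
#' manifest to \code{out_dir}.  One master seed fans out deterministic
#' per-stage seeds, so rerunning a config reproduces the manifest's
#' parameter hash and outputs.
#'
#' @param config a named list (or path to a YAML file) with optional
#'   elements: \code{seed} (master seed, default 1), \code{simulate}
#'   (list of \code{\link{synth_config}} overrides; presence triggers
#'   simulation), \code{input} (list of file paths: \code{ca_matrix},
#'   \code{ge_matrix} + name sidecars, \code{peaks} BED,
#'   \code{genes} TSS table, \code{pfm}, \code{sequences} FASTA),
#'   \code{stages} (subset of simulate, filter, normalize, tfactivity,
#'   link, nmf, deviations, validate), \code{params} (stage parameter
#'   overrides: \code{min_cell_fraction}, \code{rho_threshold},
#'   \code{alpha}, \code{window}, \code{match_fraction},
#'   \code{k_range}, \code{n_restarts}, ...), and \code{interactions}
#'   (BEDPE path for validation).
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("screglink_")) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  p <- config$params %||% list()
  all_stages <- c("simulate", "filter", "normalize", "tfactivity", "link",
                  "nmf", "deviations", "validate")
  stages <- config$stages %||% setdiff(all_stages, "validate")
  if (is.null(config$simulate) && is.null(config$input) &&
      any(c("simulate", "filter") %in% stages))
    stop("config needs either a 'simulate' block or an 'input' block")
  if ("validate" %in% stages && is.null(config$interactions))
    stop("validate stage requested but no 'interactions' BEDPE given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "screglink",
                   version = as.character(utils::packageVersion("screglink")),
                   seed = seed, stages = stages, dims = list())
  res <- list()

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (isTRUE(sim_args)) sim_args <- list()
    sim_args$seed <- sim_args$seed %||% seed
    sim <- generate_paired_omics(do.call(synth_config, sim_args))
    res$sim <- sim
    pair <- sim$pair
    pwms <- sim$pwms
    seqs <- sim$peak_sequences
    utils::write.table(
      data.frame(cell = names(sim$truth$cell_type),
                 cell_type = sim$truth$cell_type),
      file.path(out_dir, "truth_cell_types.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth$links,
                       file.path(out_dir, "truth_links.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    inp <- config$input
    ca <- read_count_matrix(inp$ca_matrix, inp$ca_row_names, inp$cell_names)
    ge <- read_count_matrix(inp$ge_matrix, inp$ge_row_names, inp$cell_names)
    peaks <- read_bed(inp$peaks)
    genes <- read_gene_annotation(inp$genes,
                                  dialect = inp$gene_dialect %||% "tss_table")
    pair <- omics_pair(ca, ge, peaks, genes)
    pwms <- if (!is.null(inp$pfm)) read_jaspar_pfm(inp$pfm) else NULL
    seqs <- if (!is.null(inp$sequences))
      as.character(Biostrings::readDNAStringSet(inp$sequences)) else NULL
  }
  manifest$dims$input <- c(peaks = nrow(pair$ca), genes = nrow(pair$ge),
                           cells = length(pair$cells))

  if ("filter" %in% stages) {
    pair <- filter_features(pair,
                            min_cell_fraction = p$min_cell_fraction %||% 0.10,
                            ca_min_fragments = p$ca_min_fragments %||% 2)
    manifest$dims$filter <- c(peaks = nrow(pair$ca), genes = nrow(pair$ge))
  }
  kept_peaks <- match(pair$peaks$name, names(seqs) %||% pair$peaks$name)

  ca_norm <- ge_norm <- NULL
  if ("normalize" %in% stages) {
    sf_ge <- pooled_size_factors(pair$ge)
    sf_ca <- pooled_size_factors(pair$ca)
    ge_norm <- normalize_counts(pair$ge, sf_ge)
    ca_norm <- normalize_counts(pair$ca, sf_ca)
    res$size_factors <- list(ca = sf_ca, ge = sf_ge)
    manifest$dims$normalize <- c(cells = length(sf_ge))
  }

  mask <- NULL; hit_index <- NULL
  if ("tfactivity" %in% stages) {
    if (is.null(pwms) || is.null(seqs))
      stop("tfactivity stage needs PWMs and peak sequences")
    tf_names <- intersect(names(pwms), rownames(ge_norm))
    regs <- build_regulons(ge_norm, tf_names,
                           corr_min = p$corr_min %||% 0.3,
                           min_size = p$min_regulon_size %||% 10L)
    auc <- regulon_auc_matrix(ge_norm, regs,
                              top_frac = p$top_frac %||% 0.05)
    act <- tf_activity(auc)
    hit_index <- build_motif_hit_index(
      seqs[kept_peaks], pwms[names(regs)],
      match_fraction = p$match_fraction %||% 0.95)
    mask <- label_active_regions(hit_index, act, ca_counts = pair$ca,
                                 require_fragment = p$require_fragment %||% TRUE)
    res$regulons <- regs; res$activity <- act; res$mask <- mask
    res$hit_index <- hit_index
    utils::write.table(auc, file.path(out_dir, "tf_auc.tsv"),
                       sep = "\t", quote = FALSE)
    manifest$dims$tfactivity <- c(regulons = length(regs),
                                  mask_on = sum(mask))
  }

  if ("link" %in% stages) {
    s3 <- strategy3_links(ge_norm, mask, pair$peaks, pair$genes,
                          window = p$window %||% 1e6,
                          alpha = p$alpha %||% 0.05,
                          min_group = p$min_group %||% 3L)
    res$links <- s3
    write_links(s3$links, pair$peaks, file.path(out_dir, "links_s3.tsv"))
    manifest$dims$link <- c(links = nrow(s3$links), tested = s3$n_tested)
  }

  if ("nmf" %in% stages && nrow(res$links$link_matrix) > 2L) {
    sel <- select_rank(res$links$link_matrix,
                       k_range = p$k_range %||% 2:6,
                       n_restarts = p$n_restarts %||% 20L,
                       seed = seed + 1000L)
    res$nmf <- sel
    utils::write.table(sel$metrics, file.path(out_dir, "nmf_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$dims$nmf <- c(K = sel$K)
  }

  if ("deviations" %in% stages && !is.null(hit_index)) {
    ann <- annotate_motif_peaks(hit_index, nrow(pair$ca))
    bg <- sample_background_peaks(rowMeans(as.matrix(pair$ca)),
                                  B = p$background_sets %||% 50L,
                                  n_bins = p$bins %||% 25L,
                                  seed = seed + 2000L)
    dev <- compute_deviations(pair$ca, ann, bg)
    res$deviations <- dev
    utils::write.table(
      data.frame(tf = names(dev$variability),
                 variability = dev$variability),
      file.path(out_dir, "tf_variability.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$dims$deviations <- c(motifs = nrow(dev$deviations))
  }

  if ("validate" %in% stages) {
    inter <- read_bedpe(config$interactions)
    val <- validation_proportion(res$links$links, pair$peaks, pair$genes,
                                 inter,
                                 promoter_window = p$promoter_window %||% 2000,
                                 anchor_slop = p$anchor_slop %||% 0)
    res$validation <- val
    utils::write.table(val, file.path(out_dir, "validation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$dims$validate <- c(proportion = val$proportion[1L])
  }

  # parameter hash: md5 of the canonical serialized config
  cfg_file <- file.path(out_dir, "config_canonical.json")
  jsonlite::write_json(config[order(names(config))], cfg_file,
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest$parameter_hash <- unname(tools::md5sum(cfg_file))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  res$pair <- pair
  res$out_dir <- out_dir
  invisible(res)
}
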