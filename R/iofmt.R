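# Coordinate convention: all intervals in this package are BED-style,
# 0-based half-open [start, end).  GTF input (1-based closed) is converted
# on read, exactly once.

#' Construct a genomic interval table
#'
#' The canonical in-memory representation of genomic intervals used
#' throughout the package: a data.frame with columns \code{chrom},
#' \code{start}, \code{end}, \code{strand}, interpreted as 0-based
#' half-open coordinates.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; 0-based half-open, \code{end > start}.
#' @param strand character vector over \code{"+"}, \code{"-"}, \code{"."}.
#' @param name optional interval names.
#' @return A data.frame of class \code{genomic_intervals}.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", name = NULL) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-integer interval coordinates")
  if (any(start < 0)) stop("interval start must be >= 0")
  if (any(end <= start)) stop("interval end must be > start")
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  strand <- rep_len(as.character(strand), length(chrom))
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   strand = strand, stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

#' Convert an interval table to a GRanges object
#'
#' Adds 1 to \code{start} to move from 0-based half-open to the 1-based
#' closed convention GRanges uses; the reverse conversion subtracts it.
#'
#' @param intervals a \code{genomic_intervals} data.frame.
#' @return A \code{GRanges} object.
#' @export
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1L,
                              end = intervals$end),
    strand = ifelse(intervals$strand == ".", "*", intervals$strand))
}

#' Read a BED file of genomic intervals
#'
#' Reads the first three (plus optional strand, column 6) fields of a
#' BED file.  Coordinates are kept verbatim: BED is already 0-based
#' half-open, the package's internal convention.
#'
#' @param path path to a tab-separated BED file (>= 3 columns).
#' @return A \code{genomic_intervals} data.frame in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty BED file: ", path)
    return(genomic_intervals(character(0), integer(0), integer(0))[0, ])
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L))
    stop("BED line ", which(ncol < 3L)[1L], ": fewer than 3 columns")
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | end <= start | start < 0)
  if (length(bad))
    stop("BED line ", bad[1L], ": malformed coordinates (need integer ",
         "0-based half-open with end > start)")
  strand <- rep(".", length(lines))
  has6 <- ncol >= 6L
  strand[has6] <- vapply(fields[has6], `[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "."
  name <- rep(NA_character_, length(lines))
  has4 <- ncol >= 4L
  name[has4] <- vapply(fields[has4], `[`, "", 4L)
  genomic_intervals(chrom, start, end, strand, name = name)
}

#' Read a gene annotation into a TSS-aware gene table
#'
#' Supports two dialects: \code{"gtf"} (gene models; 1-based closed
#' coordinates converted to 0-based half-open on read) and
#' \code{"tss_table"} (tab-separated columns \code{gene_id}, \code{chrom},
#' \code{tss}, \code{strand}; \code{tss} already 0-based).  The TSS is
#' strand-aware: \code{start} for "+" or "." (logged once as a default),
#' \code{end - 1} for "-".  A gene id seen more than once keeps its
#' longest interval with a warning.
#'
#' @param path path to the annotation file.
#' @param dialect \code{"gtf"} or \code{"tss_table"}.
#' @return A data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{tss}.
#' @export
read_gene_annotation <- function(path, dialect = c("gtf", "tss_table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "gtf") {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    keep <- vapply(fields, function(f) length(f) >= 9L && f[3L] == "gene",
                   logical(1))
    # fall back to transcript/exon features when no explicit gene lines
    if (!any(keep))
      keep <- vapply(fields, function(f) length(f) >= 9L, logical(1))
    fields <- fields[keep]
    if (length(fields) == 0L) stop("no usable feature lines in GTF: ", path)
    attr9 <- vapply(fields, `[`, "", 9L)
    m <- regmatches(attr9, regexpr('gene_id[ ="]+[^";]+', attr9))
    if (length(m) != length(attr9))
      stop("GTF feature without gene_id attribute in ", path)
    gene_id <- sub('^gene_id[ ="]+', "", m)
    gene_id <- gsub('"', "", gene_id)
    chrom <- vapply(fields, `[`, "", 1L)
    start1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 4L)))
    end1 <- suppressWarnings(as.integer(vapply(fields, `[`, "", 5L)))
    if (any(is.na(start1) | is.na(end1)))
      stop("malformed GTF coordinates in ", path)
    strand <- vapply(fields, `[`, "", 7L)
    df <- data.frame(gene_id = gene_id, chrom = chrom,
                     start = start1 - 1L, end = end1,  # 1-based closed -> 0-based half-open
                     strand = strand, stringsAsFactors = FALSE)
    # merge multiple features of one gene to its full span
    df <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
      data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
                 start = min(g$start), end = max(g$end),
                 strand = g$strand[1L], stringsAsFactors = FALSE)
    }))
    rownames(df) <- NULL
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "tss", "strand")
    if (!all(need %in% names(df)))
      stop("tss_table needs columns: ", paste(need, collapse = ", "))
    df$tss <- as.integer(df$tss)
    # a TSS-only record becomes the degenerate 1-bp interval [tss, tss+1)
    df <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                     start = df$tss, end = df$tss + 1L,
                     strand = df$strand, stringsAsFactors = FALSE)
  }
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    warning("duplicated gene_id(s): keeping longest interval for ",
            paste(unique(df$gene_id[dup]), collapse = ", "))
    df <- df[order(df$gene_id, -(df$end - df$start)), ]
    df <- df[!duplicated(df$gene_id), ]
  }
  if (!all(df$strand %in% c("+", "-", "."))) df$strand[!df$strand %in% c("+", "-")] <- "."
  df$tss <- ifelse(df$strand == "-", df$end - 1L, df$start)
  rownames(df) <- NULL
  df[, c("gene_id", "chrom", "start", "end", "strand", "tss")]
}

#' Read a feature-by-cell count matrix
#'
#' Either a dense delimited file (header row of cell ids, first column of
#' feature ids) or a MatrixMarket triplet file accompanied by row-name and
#' column-name sidecar files (one name per line).
#'
#' @param path path to the matrix file.
#' @param row_names_path,col_names_path sidecar name files; required for
#'   MatrixMarket input, ignored for dense input.
#' @return A non-negative integer matrix (dense, or \code{dgCMatrix} for
#'   MatrixMarket input) with unique dimnames; rows are features,
#'   columns are cells.
#' @export
read_count_matrix <- function(path, row_names_path = NULL,
                              col_names_path = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^%%MatrixMarket", first)) {
    if (is.null(row_names_path) || is.null(col_names_path))
      stop("MatrixMarket input needs row_names_path and col_names_path")
    m <- Matrix::readMM(path)
    rn <- readLines(row_names_path)
    cn <- readLines(col_names_path)
    if (length(rn) != nrow(m))
      stop("row-name file length ", length(rn), " != matrix rows ", nrow(m))
    if (length(cn) != ncol(m))
      stop("column-name file length ", length(cn), " != matrix columns ",
           ncol(m))
    dimnames(m) <- list(rn, cn)
    m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1L]])
    storage.mode(m) <- "double"
  }
  if (anyNA(m)) stop("non-numeric entries in count matrix ", path)
  if (any(m < 0)) stop("negative entries in count matrix ", path)
  if (anyDuplicated(rownames(m))) stop("duplicate row names in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate column names in ", path)
  m
}

#' Read JASPAR-style position frequency matrices
#'
#' Each record is a \code{">name"} header followed by four count rows
#' (A, C, G, T) of equal length.  Counts are converted to per-position
#' probabilities after adding \code{pseudocount} to every cell, so each
#' column of the returned matrix sums to 1.
#'
#' @param path path to the PFM file.
#' @param pseudocount value added to every count cell before
#'   normalization (default 1).
#' @return A list of \code{pwm_record} objects, each with elements
#'   \code{tf_name}, \code{matrix} (4 x L probability matrix with rows
#'   A, C, G, T) and \code{pseudocount}.
#' @export
read_jaspar_pfm <- function(path, pseudocount = 1) {
  if (!file.exists(path)) stop("PFM file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (length(heads) == 0L) stop("no '>' headers in PFM file ", path)
  out <- vector("list", length(heads))
  bounds <- c(heads, length(lines) + 1L)
  for (i in seq_along(heads)) {
    name <- sub("^>\\s*", "", lines[heads[i]])
    name <- strsplit(name, "[ \t]")[[1L]][1L]
    body <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) != 4L)
      stop("PFM '", name, "': expected 4 count rows, got ", length(body))
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*\\[?|\\]$", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("PFM '", name, "': rows of unequal length")
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (anyNA(counts) || any(counts < 0))
      stop("PFM '", name, "': malformed counts")
    if (ncol(counts) < 4L)
      warning("PFM '", name, "' shorter than 4 positions")
    probs <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
    out[[i]] <- structure(
      list(tf_name = name, matrix = probs, pseudocount = pseudocount),
      class = "pwm_record")
  }
  names(out) <- vapply(out, `[[`, "", "tf_name")
  out
}

#' Read chromatin interactions from a BEDPE file
#'
#' Anchor pairs are normalized to canonical order: anchor1 precedes
#' anchor2 by (chrom, start).  Interchromosomal pairs are retained.
#'
#' @param path path to a BEDPE file (>= 6 columns).
#' @return A data.frame with columns \code{chrom1,start1,end1,
#'   chrom2,start2,end2,score}.
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop("BEDPE file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L)
    return(data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), chrom2 = character(0),
                      start2 = integer(0), end2 = integer(0),
                      score = numeric(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 6L))
    stop("BEDPE line ", which(lengths(fields) < 6L)[1L],
         ": fewer than 6 columns")
  getn <- function(k) suppressWarnings(as.integer(vapply(fields, `[`, "", k)))
  df <- data.frame(
    chrom1 = vapply(fields, `[`, "", 1L), start1 = getn(2L), end1 = getn(3L),
    chrom2 = vapply(fields, `[`, "", 4L), start2 = getn(5L), end2 = getn(6L),
    stringsAsFactors = FALSE)
  df$score <- NA_real_
  has8 <- lengths(fields) >= 8L
  df$score[has8] <- suppressWarnings(
    as.numeric(vapply(fields[has8], `[`, "", 8L)))
  bad <- which(is.na(df$start1) | is.na(df$end1) | is.na(df$start2) |
                 is.na(df$end2) | df$end1 <= df$start1 | df$end2 <= df$start2)
  if (length(bad)) stop("BEDPE line ", bad[1L], ": malformed coordinates")
  swap <- df$chrom2 < df$chrom1 |
    (df$chrom1 == df$chrom2 & df$start2 < df$start1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "start1", "end1")]
    df[swap, c("chrom1", "start1", "end1")] <-
      df[swap, c("chrom2", "start2", "end2")]
    df[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  df
}

#' Write an inferred link table to a TSV file
#'
#' Columns: peak chrom/start/end, gene_id, strategy, statistic,
#' p_or_rho, n_cells_on; rows ordered by (gene_id, chrom, start) so
#' output is stable across runs.
#'
#' @param links a link data.frame as produced by the strategy functions
#'   (must carry \code{peak_index}, \code{gene_id}, \code{strategy},
#'   \code{statistic}, \code{n_cells_on}).
#' @param peaks the \code{genomic_intervals} table the
#'   \code{peak_index} column refers to.
#' @param path output file path.
#' @return Invisibly, the path written.
#' @export
write_links <- function(links, peaks, path) {
  tab <- data.frame(
    chrom = peaks$chrom[links$peak_index],
    start = peaks$start[links$peak_index],
    end = peaks$end[links$peak_index],
    gene_id = links$gene_id,
    strategy = links$strategy,
    statistic = links$statistic,
    p_or_rho = links$statistic,
    n_cells_on = links$n_cells_on,
    stringsAsFactors = FALSE)
  tab <- tab[order(tab$gene_id, tab$chrom, tab$start), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a link table written by \code{write_links}
#' @param path path to the TSV file.
#' @return The link table data.frame.
#' @export
read_links <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
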