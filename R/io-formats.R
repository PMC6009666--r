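#' Read and write FASTA sequence files
#'
#' `read_fasta` returns a named character vector of uppercased sequences and
#' rejects bases outside A, C, G, T, N with the offending record and
#' position. `write_fasta` writes a named character vector.
#'
#' @param path File path.
#' @param uppercase Uppercase sequences on ingest (default TRUE).
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path, uppercase = TRUE) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  if (uppercase) seqs <- toupper(seqs)
  names(seqs) <- sub("\\s.*$", "", names(x))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTN]", seqs[[i]])
    if (bad > 0)
      stop("record '", names(seqs)[i], "' contains invalid base '",
           substr(seqs[[i]], bad, bad), "' at position ", bad)
  }
  seqs
}

#' @param seqs Named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

.check_intervals <- function(df, what = "interval") {
  if (any(df$start < 0)) stop(what, " with negative start coordinate")
  bad <- which(df$start >= df$end)
  if (length(bad))
    stop(what, " with start >= end at row ", bad[1],
         " (", df$chrom[bad[1]], ":", df$start[bad[1]], "-", df$end[bad[1]], ")")
  df
}

#' Read ENCODE narrowPeak files
#'
#' Parses the 10-column BED6+4 narrowPeak format; column 7 (signalValue) is
#' exposed as `signal` and used as the peak score downstream. Coordinates
#' are 0-based half-open, as in BED.
#'
#' @param path File path.
#' @param normalize_chrom Add a "chr" prefix to bare chromosome names.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `signal`, `pvalue`, `qvalue`, `peak`.
#' @export
read_narrowpeak <- function(path, normalize_chrom = FALSE) {
  x <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(x) < 10L)
    stop("narrowPeak requires 10 columns, found ", ncol(x))
  x <- x[, 1:10]
  names(x) <- c("chrom", "start", "end", "name", "score", "strand",
                "signal", "pvalue", "qvalue", "peak")
  if (normalize_chrom) x$chrom <- norm_chrom(x$chrom)
  if (any(!is.finite(x$signal))) stop("non-finite signalValue in column 7")
  .check_intervals(x, "peak")
}

#' Read BED files (3 to 6 columns)
#'
#' @inheritParams read_narrowpeak
#' @return Data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand` (defaults filled otherwise).
#' @export
read_bed <- function(path, normalize_chrom = FALSE) {
  x <- data.table::fread(path, sep = "\t", header = FALSE, data.table = FALSE)
  if (ncol(x) < 3L) stop("BED requires at least 3 columns")
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  x <- x[, seq_len(min(6L, ncol(x))), drop = FALSE]
  names(x) <- cols[seq_len(ncol(x))]
  if (is.null(x$name)) x$name <- paste0("iv", seq_len(nrow(x)))
  if (is.null(x$score)) x$score <- 0
  if (is.null(x$strand)) x$strand <- "."
  if (normalize_chrom) x$chrom <- norm_chrom(x$chrom)
  .check_intervals(x, "BED interval")
}

#' Write intervals as BED6
#'
#' @param df Data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optional `name`, `score`, `strand`.
#' @param path Output path.
#' @export
write_bed <- function(df, path) {
  out <- data.frame(chrom = df$chrom, start = df$start, end = df$end,
                    name = if (is.null(df$name)) "." else df$name,
                    score = if (is.null(df$score)) 0 else df$score,
                    strand = if (is.null(df$strand)) "." else df$strand)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write motif hits as extended BED
#'
#' BED6 with the score column scaled to 0-1000 relative to `max_bits` and
#' the raw bit score in column 7.
#'
#' @param hits Hit data frame from [scan_sequence()].
#' @param path Output path.
#' @param max_bits Bit score mapped to 1000 (defaults to the maximum
#'   observed).
#' @export
write_hits_bed <- function(hits, path, max_bits = max(hits$score)) {
  scaled <- if (nrow(hits)) pmax(0L, pmin(1000L,
    as.integer(round(1000 * hits$score / max_bits)))) else integer(0)
  out <- data.frame(chrom = hits$chrom, start = hits$start, end = hits$end,
                    name = hits$motif_id, score = scaled,
                    strand = hits$strand, bits = round(hits$score, 4))
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Convert between 0-based half-open and GRanges coordinates
#'
#' Internal coordinates are 0-based half-open throughout the package;
#' `as_granges0` converts such a data frame to a `GRanges` (1-based closed)
#' and `granges_to_df0` converts back.
#'
#' @param df Data frame with `chrom`, `start`, `end` and optional `strand`.
#' @return A `GRanges` / data frame.
#' @export
as_granges0 <- function(df) {
  strand <- if (is.null(df$strand)) "*" else ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand)
}

#' @param gr A `GRanges`.
#' @rdname as_granges0
#' @export
granges_to_df0 <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' 1-based / 0-based coordinate converters
#'
#' SNP and VCF positions are 1-based; internal coordinates are 0-based
#' half-open. `pos1_to_0` converts a 1-based position to its 0-based offset;
#' `pos0_to_1` converts back.
#'
#' @param pos Position(s).
#' @return Converted position(s).
#' @export
pos1_to_0 <- function(pos) as.integer(pos) - 1L

#' @rdname pos1_to_0
#' @export
pos0_to_1 <- function(pos) as.integer(pos) + 1L

#' Normalize chromosome names
#'
#' Adds (or strips) the "chr" prefix so that inputs from mixed sources
#' intersect correctly.
#'
#' @param x Character vector of chromosome names.
#' @param prefix If TRUE (default) ensure a "chr" prefix, else strip it.
#' @return Normalized names.
#' @export
norm_chrom <- function(x, prefix = TRUE) {
  has <- startsWith(x, "chr")
  if (prefix) ifelse(has, x, paste0("chr", x))
  else ifelse(has, substring(x, 4L), x)
}

#' Pair intervals by overlap or windowed proximity
#'
#' Returns the index pairs of intervals in `a` and `b` that intersect
#' (strict half-open overlap, `mode = "intersect"`) or that lie within
#' `window` bp of each other (`mode = "window"`; the gap boundary is
#' inclusive, so a pair separated by exactly `window` bp is reported).
#' Backed by the interval-tree overlap engine of GenomicRanges.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (0-based half-open).
#' @param mode `"intersect"` or `"window"`.
#' @param window Maximum gap in bp for window mode.
#' @return Data frame with columns `a_idx`, `b_idx`.
#' @export
interval_pairs <- function(a, b, mode = c("intersect", "window"), window = 0L) {
  mode <- match.arg(mode)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a_idx = integer(0), b_idx = integer(0)))
  ga <- as_granges0(a); gb <- as_granges0(b)
  maxgap <- if (mode == "intersect") -1L else as.integer(window)
  ## disjoint chromosome sets are a legitimate no-pair case, not a problem
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(ga, gb, maxgap = maxgap,
                                ignore.strand = TRUE))
  data.frame(a_idx = S4Vectors::queryHits(ov),
             b_idx = S4Vectors::subjectHits(ov))
}

#' Resolved run configuration
#'
#' Validates a set of analysis parameters against the registry of known
#' keys, fills defaults, and records them so every run can be reproduced
#' from its logged configuration. Unknown keys are rejected.
#'
#' @param ... Named parameters overriding the defaults.
#' @return A list of class `run_config`.
#' @export
run_config <- function(...) {
  defaults <- list(
    window = 100L,            # bp, windowed peak/motif intersection
    sensitivity = 0.8,        # scan threshold calibration target
    statistical_factor = 4,   # omega estimator convention
    open_threshold = "q85",   # ATAC open/closed threshold (absolute or qNN)
    pseudocount = 1,          # accessibility-ratio pseudocount
    noise_sd = 0.02,          # titration fraction noise
    seed = 1L)
  override <- list(...)
  if (length(override) == 1L && is.list(override[[1]]) && is.null(names(override)))
    override <- override[[1]]
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  structure(defaults, class = "run_config")
}

#' @param path YAML file of configuration overrides.
#' @rdname run_config
#' @export
load_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' One-line structured log of a pipeline stage
#'
#' @param stage Stage name.
#' @param config A [run_config()].
#' @param inputs Named character vector of input file paths (hashed by
#'   content into the log line).
#' @return The log line, invisibly (also emitted via `message`).
#' @export
log_stage <- function(stage, config, inputs = character(0)) {
  hash <- vapply(inputs, function(p) {
    if (file.exists(p)) sprintf("%s:%d", basename(p), file.size(p)) else "missing"
  }, character(1))
  line <- sprintf("[%s] stage=%s %s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage,
                  paste(sprintf("%s=%s", names(config),
                                vapply(config, function(v) paste(format(v), collapse = ","),
                                       character(1))), collapse = " "),
                  paste(sprintf("input.%s=%s", names(hash), hash), collapse = " "))
  message(line)
  invisible(line)
}
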