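#' Read SNP tables
#'
#' `read_snp_tsv` reads a TSV with columns `chrom`, `pos` (1-based), `id`,
#' `major`, `minor`. `read_snp_vcf` reads a minimal VCF (CHROM POS ID REF
#' ALT, first ALT only, SNVs only) into the same shape with REF as major
#' and ALT as minor allele.
#'
#' @param path File path.
#' @return Data frame with columns `chrom`, `pos`, `id`, `major`, `minor`.
#' @export
read_snp_tsv <- function(path) {
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  need <- c("chrom", "pos", "id", "major", "minor")
  if (!all(need %in% names(x)))
    stop("SNP table lacks columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  validate_snps(x[, need])
}

#' @rdname read_snp_tsv
#' @export
read_snp_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(0), pos = integer(0), id = character(0),
                      major = character(0), minor = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5L)
  if (length(bad)) stop("malformed VCF record at data line ", bad[1])
  x <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                  pos = suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L))),
                  id = vapply(fields, `[[`, "", 3L),
                  major = toupper(vapply(fields, `[[`, "", 4L)),
                  minor = toupper(vapply(fields, function(f)
                    strsplit(f[[5L]], ",", fixed = TRUE)[[1]][1], "")),
                  stringsAsFactors = FALSE)
  if (anyNA(x$pos)) stop("non-numeric POS at data line ", which(is.na(x$pos))[1])
  x <- x[nchar(x$major) == 1L & nchar(x$minor) == 1L, , drop = FALSE]  # SNVs only
  validate_snps(x)
}

validate_snps <- function(x) {
  ok_base <- function(b) b %in% c("A", "C", "G", "T")
  bad <- which(!ok_base(x$major) | !ok_base(x$minor) | x$major == x$minor |
                 !is.finite(x$pos) | x$pos < 1)
  if (length(bad))
    stop("malformed SNP record at line ", bad[1],
         " (id '", x$id[bad[1]], "'): alleles must be distinct single bases",
         " and pos a positive 1-based coordinate")
  x$pos <- as.integer(x$pos)
  x
}

#' Keep SNPs falling on the shared central TA of a dimer motif match
#'
#' Retains the SNPs whose (1-based) position lies on the central
#' dinucleotide of a DIV motif hit: positions 4-5 of the 8-bp match in the
#' hit's forward-coordinate frame (the TA shared by the juxtaposed
#' half-sites of the AAATATTT element). The central frame is symmetric
#' under strand reflection, so the hit strand does not affect retention.
#'
#' @param snps SNP data frame (`chrom`, `pos` 1-based, `id`, `major`,
#'   `minor`).
#' @param div_hits DIV hit data frame (0-based half-open intervals).
#' @param motif_length Motif match length in bp (default 8).
#' @return The retained subset of `snps`.
#' @export
filter_central_ta <- function(snps, div_hits, motif_length = 8L) {
  if (nrow(snps) == 0L || nrow(div_hits) == 0L)
    return(snps[integer(0), , drop = FALSE])
  central <- unique(c((motif_length + 1L) %/% 2L, (motif_length + 2L) %/% 2L))
  pos0 <- pos1_to_0(snps$pos)  # 0-based base coordinate of the SNP
  keep <- logical(nrow(snps))
  for (ci in central) {
    ## 0-based offsets of central position ci (1-based within the match)
    want_start <- pos0 - (ci - 1L)
    hitkey <- paste(div_hits$chrom, div_hits$start)
    keep <- keep | paste(snps$chrom, want_start) %in% hitkey
  }
  snps[keep, , drop = FALSE]
}

#' Score the allelic impact of a SNP on composite-motif match strength
#'
#' Substitutes each allele into the reference sequence, rescans the window
#' of +/- (motif length - 1) bp around the SNP on both strands, and takes
#' the best-scoring window per allele. `delta = score_major - score_minor`;
#' `perturbs_dimer` flags SNPs whose major allele supports a match at the
#' scan threshold while the minor allele does not. If the reference base
#' matches neither allele a warning is emitted and the substitution
#' proceeds.
#'
#' @param snps SNP data frame (`chrom`, `pos` 1-based, `id`, `major`,
#'   `minor`).
#' @param genome Named character vector of chromosome sequences.
#' @param motif A `composite_motif` (or [pwm()]).
#' @param threshold Scan threshold in bits (typically the calibrated
#'   genome-scan threshold).
#' @return Data frame with `snp_id`, `chrom`, `pos`, `score_major`,
#'   `score_minor`, `delta`, `perturbs_dimer`.
#' @export
allelic_score_delta <- function(snps, genome, motif, threshold) {
  W <- ncol(.motif_pwm(motif)$mat)
  out <- lapply(seq_len(nrow(snps)), function(i) {
    s <- snps[i, ]
    if (!s$chrom %in% names(genome))
      stop("SNP '", s$id, "' references unknown sequence '", s$chrom, "'")
    seq <- genome[[s$chrom]]
    pos0 <- pos1_to_0(s$pos)
    if (pos0 < 0L || pos0 >= nchar(seq))
      stop("SNP '", s$id, "' position outside sequence bounds")
    ref <- substr(seq, pos0 + 1L, pos0 + 1L)
    if (!ref %in% c(s$major, s$minor))
      warning("SNP '", s$id, "': reference base ", ref,
              " matches neither allele (", s$major, "/", s$minor,
              "); substituting anyway")
    lo <- max(0L, pos0 - (W - 1L))
    hi <- min(nchar(seq), pos0 + W)  # 0-based half-open window span
    ctx <- substr(seq, lo + 1L, hi)
    at <- pos0 - lo + 1L
    score_allele <- function(allele) {
      substr(ctx, at, at) <- allele
      hits <- scan_sequence(ctx, motif, threshold = -1e9, chrom = s$chrom)
      if (nrow(hits) == 0L) return(-Inf)
      max(hits$score)
    }
    sm <- score_allele(s$major)
    sn <- score_allele(s$minor)
    data.frame(snp_id = s$id, chrom = s$chrom, pos = s$pos,
               score_major = sm, score_minor = sn, delta = sm - sn,
               perturbs_dimer = (sm >= threshold) && (sn < threshold),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assemble the SNP screen report
#'
#' Joins the in-silico allelic deltas with externally supplied experimental
#' dimer calls and eQTL annotations (both consumed as input tables, never
#' computed here) and sorts by absolute delta, largest first. Rows of the
#' optional tables whose `snp_id` does not match any scored SNP are
#' appended and flagged rather than dropped.
#'
#' @param results Data frame from [allelic_score_delta()].
#' @param emsa_calls Optional data frame with `snp_id` plus experimental
#'   columns (e.g. a dimer-perturbation call).
#' @param eqtl_flags Optional data frame with `snp_id` plus annotation
#'   columns.
#' @return Report data frame with an `unmatched` logical column.
#' @export
screen_report <- function(results, emsa_calls = NULL, eqtl_flags = NULL) {
  rep <- results
  for (extra in list(emsa_calls, eqtl_flags)) {
    if (is.null(extra)) next
    stopifnot("snp_id" %in% names(extra))
    rep <- merge(rep, extra, by = "snp_id", all = TRUE, sort = FALSE)
  }
  rep$unmatched <- is.na(rep$delta)  # annotation rows with no scored SNP
  rep[order(-abs(rep$delta), rep$snp_id, na.last = TRUE), , drop = FALSE]
}
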