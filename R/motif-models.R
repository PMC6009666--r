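BASES <- c("A", "C", "G", "T")

IUPAC_BASES <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Position weight matrix
#'
#' @param id Motif identifier.
#' @param mat 4 x L numeric matrix of per-position base probabilities, rows
#'   A, C, G, T; each column must sum to 1.
#' @param background Base probability vector of length 4 (A, C, G, T),
#'   summing to 1.
#' @return An object of class `pwm`.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4L, ncol(mat) >= 1L)
  dimnames(mat) <- list(BASES, NULL)
  if (any(mat < 0)) stop("PWM probabilities must be >= 0")
  if (any(abs(colSums(mat) - 1) > 1e-9))
    stop("every PWM column must sum to 1")
  background <- as.numeric(background)
  stopifnot(length(background) == 4L)
  if (abs(sum(background) - 1) > 1e-9) stop("background must sum to 1")
  names(background) <- BASES
  structure(list(id = id, mat = mat, background = background), class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%d bp), consensus %s\n",
              x$id, ncol(x$mat), consensus_string(x)))
  invisible(x)
}

#' @export
length.pwm <- function(x) ncol(x$mat)

#' Build a PWM from a (possibly degenerate) consensus string
#'
#' Each position gives total probability `prob` to the consensus base(s)
#' (split equally among the bases of a degenerate IUPAC code) and spreads
#' the remainder over the other bases.
#'
#' @param consensus Consensus string in IUPAC code.
#' @param prob Total probability assigned to the consensus base(s), default
#'   0.7.
#' @param id Motif identifier.
#' @param background Background base probabilities.
#' @return A [pwm()].
#' @export
pwm_from_consensus <- function(consensus, prob = 0.7, id = consensus,
                               background = rep(0.25, 4)) {
  letters <- strsplit(toupper(consensus), "")[[1]]
  bad <- setdiff(letters, names(IUPAC_BASES))
  if (length(bad)) stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  mat <- vapply(letters, function(l) {
    hit <- IUPAC_BASES[[l]]
    p <- numeric(4); names(p) <- BASES
    if (length(hit) == 4L) p[] <- 0.25
    else {
      p[hit] <- prob / length(hit)
      p[setdiff(BASES, hit)] <- (1 - prob) / (4 - length(hit))
    }
    p
  }, numeric(4))
  pwm(id, mat, background)
}

#' Default forkhead monomer PWMs
#'
#' Self-contained monomer models built from published consensus sequences:
#' `"core"` is the 5-bp AT-rich core (TATTT) of the forkhead site whose
#' overlap defines the compact dimer element; `"homer"` is the 10-bp
#' AAAGTAAACA FOXA1 consensus from the HOMER database; `"full"` is the
#' degenerate 11-bp AWTRTTKRYTY monomer consensus. Consensus bases carry
#' probability 0.7 per position.
#'
#' @param source One of `"core"`, `"homer"`, `"full"`.
#' @param prob Consensus-base probability.
#' @return A [pwm()].
#' @export
foxa1_monomer_pwm <- function(source = c("core", "homer", "full"), prob = 0.7) {
  source <- match.arg(source)
  cons <- switch(source,
                 core = "TATTT",
                 homer = "AAAGTAAACA",
                 full = "AWTRTTKRYTY")
  pwm_from_consensus(cons, prob = prob, id = paste0("foxa1_", source))
}

#' Reverse complement of a PWM
#'
#' Reverses the column order and swaps the complementary base rows
#' (A with T, C with G). Applying it twice returns the input.
#'
#' @param x A [pwm()].
#' @return The reverse-complemented [pwm()].
#' @export
reverse_complement_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  mat <- x$mat[c("T", "G", "C", "A"), rev(seq_len(ncol(x$mat))), drop = FALSE]
  rownames(mat) <- BASES
  bg <- x$background[c("T", "G", "C", "A")]
  names(bg) <- BASES
  pwm(paste0(x$id, "_rc"), mat, bg)
}

#' Build a composite dimer motif from two monomer half-sites
#'
#' Merges two monomer PWMs into one composite matrix at a signed spacer.
#' In the diverging (`DIV`) orientation the reverse-complemented half sits
#' on the 5' side and the forward half on the 3' side, so the AT-rich cores
#' point away from each other; in the converging (`CON`) orientation the
#' forward half is 5' and the reverse-complemented half 3'. A positive
#' spacer inserts that many background columns between the halves; a
#' negative spacer overlaps them, merging overlapping columns by the
#' position-wise normalized product of probabilities (with pseudocount
#' 1e-4), which is equivalent to summing log-odds contributions.
#'
#' With the 5-bp TATTT core half, `DIV` at spacer -2 yields the 8-bp
#' AAATATTT element whose central TA dinucleotide is shared by the
#' juxtaposed half-sites; see [div_motif()] for the D0/Dn/C0 anchor
#' conventions.
#'
#' @param half1,half2 Monomer [pwm()]s (default: `half2 = half1`).
#' @param orientation `"DIV"` or `"CON"`.
#' @param spacer Signed spacer in bp (negative = overlap, 0 = abutting,
#'   positive = inserted background columns).
#' @param pseudocount Pseudocount used when merging overlapping columns.
#' @param id Identifier for the composite.
#' @return An object of class `composite_motif` with elements `pwm`,
#'   `half1_id`, `half2_id`, `orientation`, `spacer`.
#' @export
build_composite <- function(half1, half2 = half1,
                            orientation = c("DIV", "CON"),
                            spacer = 0L, pseudocount = 1e-4,
                            id = NULL) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(half1, "pwm"), inherits(half2, "pwm"))
  l1 <- ncol(half1$mat); l2 <- ncol(half2$mat)
  if (spacer < -min(l1, l2))
    stop("overlap deeper than a half-site: spacer ", spacer,
         " < -", min(l1, l2))

  left  <- if (orientation == "DIV") reverse_complement_pwm(half1) else half1
  right <- if (orientation == "DIV") half2 else reverse_complement_pwm(half2)
  bg <- (left$background + right$background[BASES]) / 2
  bg <- bg / sum(bg)

  if (spacer >= 0L) {
    mid <- matrix(rep(bg, spacer), nrow = 4L)
    mat <- cbind(left$mat, mid, right$mat)
  } else {
    k <- -spacer
    la <- left$mat[, seq_len(l1 - k), drop = FALSE]
    lo <- left$mat[, l1 - k + seq_len(k), drop = FALSE]
    ro <- right$mat[, seq_len(k), drop = FALSE]
    rb <- right$mat[, k + seq_len(l2 - k), drop = FALSE]
    merged <- (lo + pseudocount) * (ro + pseudocount)
    merged <- sweep(merged, 2L, colSums(merged), "/")
    mat <- cbind(la, merged, rb)
  }
  if (ncol(mat) != l1 + l2 + spacer)
    stop("internal error: merged length mismatch")

  if (is.null(id))
    id <- sprintf("%s_%s_%s_sp%+d", orientation, half1$id, half2$id, spacer)
  structure(list(pwm = pwm(id, mat, bg),
                 half1_id = half1$id, half2_id = half2$id,
                 orientation = orientation, spacer = as.integer(spacer)),
            class = "composite_motif")
}

#' @export
print.composite_motif <- function(x, ...) {
  cat(sprintf("composite_motif %s (%s, spacer %+d, %d bp), consensus %s\n",
              x$pwm$id, x$orientation, x$spacer, ncol(x$pwm$mat),
              consensus_string(x)))
  invisible(x)
}

#' @export
length.composite_motif <- function(x) ncol(x$pwm$mat)

#' Anchored DIV / CON composite series
#'
#' `div_motif(half, n)` returns the n-th member of the diverging series:
#' D0 is the compact element with 2 bp of half-site overlap (shared central
#' TA; spacer -2) and Dn (n = 1..10) inserts n bp between the overlapped
#' half-sites, i.e. DIV at spacer n - 2 (so D2 has abutting half-sites).
#' `con_motif(half, offset)` returns C0 (converging, spacer 0) or its
#' +/-1 bp spacer variants C1 / C-1.
#'
#' @param half Monomer half-site [pwm()].
#' @param n Spacer insertion in bp relative to the compact D0 element
#'   (0 = D0).
#' @param offset Spacer of the converging element (0 = C0).
#' @return A `composite_motif`.
#' @export
div_motif <- function(half = foxa1_monomer_pwm("core"), n = 0L) {
  stopifnot(n >= 0L)
  build_composite(half, half, "DIV", spacer = n - 2L,
                  id = paste0("D", n))
}

#' @rdname div_motif
#' @export
con_motif <- function(half = foxa1_monomer_pwm("core"), offset = 0L) {
  build_composite(half, half, "CON", spacer = as.integer(offset),
                  id = paste0("C", offset))
}

.motif_pwm <- function(motif) {
  if (inherits(motif, "composite_motif")) motif$pwm
  else if (inherits(motif, "pwm")) motif
  else stop("`motif` must be a pwm or composite_motif")
}

## log2-odds score matrix with an all-zero fifth row so that N contributes
## 0 bits (background-neutral)
.score_matrix <- function(motif) {
  p <- .motif_pwm(motif)
  s <- log2(p$mat / p$background)
  rbind(s, N = 0)
}

.encode_seq <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  code <- match(v, c(BASES, "N"))
  if (anyNA(code))
    stop("sequence contains bases outside {A,C,G,T,N} at position ",
         which(is.na(code))[1])
  code
}

#' Log-odds score of a window against a motif
#'
#' Sum over positions of `log2(p_base / background_base)`; an N base
#' contributes 0 bits. The consensus string attains the maximum achievable
#' score.
#'
#' @param window DNA string whose length equals the motif length.
#' @param motif A [pwm()] or `composite_motif`.
#' @return Score in bits.
#' @export
log_odds_score <- function(window, motif) {
  S <- .score_matrix(motif)
  code <- .encode_seq(window)
  if (length(code) != ncol(S))
    stop("window length ", length(code), " != motif length ", ncol(S))
  sum(S[cbind(code, seq_along(code))])
}

#' Maximum achievable score and consensus of a motif
#'
#' @param motif A [pwm()] or `composite_motif`.
#' @return `max_score`: maximum log-odds score in bits;
#'   `consensus_string`: the highest-probability base per position (ties
#'   broken in A,C,G,T order).
#' @export
max_score <- function(motif) {
  S <- .score_matrix(motif)[1:4, , drop = FALSE]
  sum(apply(S, 2L, max))
}

#' @rdname max_score
#' @export
consensus_string <- function(motif) {
  p <- .motif_pwm(motif)
  paste(BASES[apply(p$mat, 2L, which.max)], collapse = "")
}

## score every window start on the forward reading of `code` against score
## matrix S (vectorized over starts)
.window_scores <- function(code, S) {
  W <- ncol(S); L <- length(code)
  n <- L - W + 1L
  if (n < 1L) return(numeric(0))
  acc <- numeric(n)
  for (j in seq_len(W)) acc <- acc + S[code[j:(j + n - 1L)], j]
  acc
}

#' Scan a sequence with a motif on both strands
#'
#' Reports every window on either strand whose log-odds score meets the
#' threshold, in forward-strand 0-based half-open coordinates, sorted by
#' (start, strand). Minus-strand windows are scored with the
#' reverse-complemented matrix, so a palindromic composite produces equal
#' +/- scores at the same start.
#'
#' @param seq DNA string (bases A,C,G,T,N; case-insensitive).
#' @param motif A [pwm()] or `composite_motif`.
#' @param threshold Minimum score in bits (finite).
#' @param chrom Chromosome/sequence name recorded in the hits.
#' @return Data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `score`, `motif_id`. A sequence shorter than the motif yields zero
#'   rows.
#' @export
scan_sequence <- function(seq, motif, threshold, chrom = "seq") {
  if (!is.finite(threshold)) stop("`threshold` must be finite")
  p <- .motif_pwm(motif)
  S_fwd <- .score_matrix(motif)
  rc <- if (inherits(motif, "composite_motif"))
    reverse_complement_pwm(p) else reverse_complement_pwm(motif)
  S_rev <- .score_matrix(rc)

  code <- .encode_seq(seq)
  W <- ncol(S_fwd)
  fwd <- .window_scores(code, S_fwd)
  rev_ <- .window_scores(code, S_rev)

  hit_f <- which(fwd >= threshold)
  hit_r <- which(rev_ >= threshold)
  n <- length(hit_f) + length(hit_r)
  out <- data.frame(
    chrom = rep(chrom, n),
    start = c(hit_f, hit_r) - 1L,
    end = c(hit_f, hit_r) - 1L + W,
    strand = rep(c("+", "-"), c(length(hit_f), length(hit_r))),
    score = c(fwd[hit_f], rev_[hit_r]),
    motif_id = rep(p$id, n),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Scan a set of named sequences (a genome)
#'
#' @param seqs Named character vector of sequences (e.g. from
#'   [read_fasta()]).
#' @inheritParams scan_sequence
#' @return Combined hit data frame across sequences.
#' @export
scan_genome <- function(seqs, motif, threshold) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  hits <- lapply(names(seqs), function(nm)
    scan_sequence(seqs[[nm]], motif, threshold, chrom = nm))
  do.call(rbind, hits)
}

#' Best motif score of each sequence
#'
#' Maximum window score over both strands, per sequence; `-Inf` for
#' sequences shorter than the motif.
#'
#' @inheritParams scan_genome
#' @return Numeric vector of per-sequence maxima.
#' @export
best_scores <- function(seqs, motif) {
  S_fwd <- .score_matrix(motif)
  p <- .motif_pwm(motif)
  rc <- if (inherits(motif, "composite_motif"))
    reverse_complement_pwm(p) else reverse_complement_pwm(motif)
  S_rev <- .score_matrix(rc)
  vapply(seqs, function(s) {
    code <- .encode_seq(s)
    m <- suppressWarnings(max(.window_scores(code, S_fwd),
                              .window_scores(code, S_rev)))
    m
  }, numeric(1))
}

#' Calibrate a scan threshold to a target sensitivity
#'
#' Returns the largest threshold at which at least the requested fraction of
#' positive sequences (e.g. ChIP-seq peak sequences) contain a motif hit.
#' Candidate thresholds are the distinct per-sequence maximum scores, so the
#' achieved sensitivity at the returned threshold is >= the request while
#' any larger candidate would fall below it.
#'
#' @param motif A [pwm()] or `composite_motif`.
#' @param positive_sequences Character vector of positive sequences.
#' @param sensitivity Target sensitivity in (0, 1], default 0.8.
#' @return Threshold in bits, with the achieved sensitivity attached as
#'   attribute `sensitivity`.
#' @export
calibrate_threshold <- function(motif, positive_sequences, sensitivity = 0.8) {
  if (length(positive_sequences) < 1L)
    stop("need at least one positive sequence")
  if (sensitivity <= 0 || sensitivity > 1)
    stop("`sensitivity` must lie in (0, 1]")
  m <- best_scores(positive_sequences, motif)
  n <- length(m)
  k <- ceiling(sensitivity * n)
  thr <- sort(m, decreasing = TRUE)[k]
  structure(thr, sensitivity = mean(m >= thr))
}
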