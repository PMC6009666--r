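# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the package's own code paths: plain bisection,
# exhaustive loops and closed forms only.

# bisection solve of the two-site mass balance, independent of uniroot
oracle_equilibrium <- function(k, omega, p_total, d_total, sites = 2L,
                               tol = 1e-12) {
  frac_at <- function(p) {
    x <- p / k
    w <- if (sites == 1L) c(1, x, 0) else c(1, 2 * x, omega * x^2)
    w / sum(w)
  }
  bal <- function(p) {
    f <- frac_at(p)
    p + d_total * (f[2] + 2 * f[3]) - p_total
  }
  lo <- 0; hi <- p_total
  if (p_total == 0) return(c(1, 0, 0))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (bal(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * max(1, p_total)) break
  }
  frac_at((lo + hi) / 2)
}

# naive per-window double-strand rescan; scores computed from raw
# probabilities with string reverse-complementation
oracle_scan <- function(seq, mat, bg, threshold) {
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  W <- ncol(mat); L <- nchar(seq)
  score_str <- function(s) {
    b <- strsplit(s, "")[[1]]
    tot <- 0
    for (i in seq_len(W)) {
      if (b[i] == "N") next
      tot <- tot + log2(mat[b[i], i] / bg[b[i]])
    }
    tot
  }
  out <- NULL
  if (L >= W) for (s in 0:(L - W)) {
    win <- substr(seq, s + 1, s + W)
    fs <- score_str(win)
    rs <- score_str(revcomp(win))
    if (fs >= threshold)
      out <- rbind(out, data.frame(start = s, strand = "+", score = fs))
    if (rs >= threshold)
      out <- rbind(out, data.frame(start = s, strand = "-", score = rs))
  }
  if (is.null(out)) data.frame(start = integer(0), strand = character(0),
                               score = numeric(0))
  else out[order(out$start, out$strand), , drop = FALSE]
}

# all-pairs quadratic interval pairing (0-based half-open; window = -1 for
# strict intersection)
oracle_pairs <- function(a, b, window = -1L) {
  res <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] != b$chrom[j]) next
    overlap <- a$start[i] < b$end[j] && b$start[j] < a$end[i]
    if (window < 0) {
      if (overlap) res <- rbind(res, c(i, j))
    } else {
      gap <- if (overlap) 0L else max(b$start[j] - a$end[i], a$start[i] - b$end[j])
      if (gap <= window) res <- rbind(res, c(i, j))
    }
  }
  if (is.null(res)) data.frame(a_idx = integer(0), b_idx = integer(0))
  else data.frame(a_idx = res[, 1], b_idx = res[, 2])
}

# two-sided Fisher p by exhaustive hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  x <- tab[1, 1]
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(ks, r1, r2, c1)
  sum(probs[probs <= dhyper(x, r1, r2, c1) * (1 + 1e-7)])
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), span = 1e5,
                             max_len = 500L) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample.int(max_len, n, replace = TRUE))
}

random_seq <- function(n, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}

random_pwm <- function(len, id = "rand") {
  m <- matrix(rexp(4 * len), nrow = 4)
  m <- sweep(m, 2, colSums(m), "/")
  pwm(id, m)
}
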