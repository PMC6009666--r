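test_that("PWM reverse complementation swaps bases and is an involution", {
  one <- pwm("a_col", matrix(c(1, 0, 0, 0), nrow = 4))
  rc <- reverse_complement_pwm(one)
  expect_equal(unname(rc$mat[, 1]), c(0, 0, 0, 1))  # A column becomes T

  set.seed(3)
  p <- random_pwm(7)
  back <- reverse_complement_pwm(reverse_complement_pwm(p))
  expect_equal(back$mat, p$mat)

  core <- foxa1_monomer_pwm("core")  # consensus TATTT
  expect_equal(consensus_string(reverse_complement_pwm(core)), "AAATA")
})

test_that("composite construction reproduces the compact dimer geometry", {
  half <- foxa1_monomer_pwm("core")
  d0 <- div_motif(half, 0)
  expect_equal(length(d0), 8L)
  expect_equal(d0$spacer, -2L)
  # shared central TA of the juxtaposed half-sites
  expect_equal(consensus_string(d0), "AAATATTT")

  c0 <- con_motif(half, 0)
  expect_equal(c0$spacer, 0L)
  expect_equal(length(c0), 10L)
  expect_equal(consensus_string(c0), "TATTTAAATA")

  # spacer arithmetic of the control series: inserting n bp into the
  # overlapped element grows it by n
  for (n in 1:10)
    expect_equal(length(div_motif(half, n)) - length(d0), n)
  expect_equal(div_motif(half, 3)$spacer, 1L)

  expect_error(build_composite(half, half, "DIV", spacer = -6L), "deeper")
})

test_that("abutting composition with a uniform half alters no column", {
  set.seed(8)
  h1 <- random_pwm(5, "h1")
  uni <- pwm("uni", matrix(0.25, nrow = 4, ncol = 5))
  comp <- build_composite(h1, uni, "CON", spacer = 0L)
  # CON keeps half1 forward on the 5' side; uniform reverse-complements to
  # itself, so the result is plain concatenation
  expect_equal(unname(comp$pwm$mat[, 1:5]), unname(h1$mat))
  expect_equal(unname(comp$pwm$mat[, 6:10]), matrix(0.25, 4, 5))
})

test_that("composite assembly matches brute-force column assembly (D3)", {
  half <- foxa1_monomer_pwm("core")
  d3 <- div_motif(half, 3)  # spacer +1: one inserted background column
  left <- reverse_complement_pwm(half)$mat
  bg <- matrix(rep(0.25, 4), nrow = 4)
  manual <- cbind(left, bg, half$mat)
  expect_equal(unname(d3$pwm$mat), unname(manual))
})

test_that("overlap merge columns are normalized and uniform-neutral", {
  set.seed(12)
  h <- random_pwm(5, "h")
  for (sp in c(-1L, -2L, -3L)) {
    comp <- build_composite(h, h, "DIV", spacer = sp)
    expect_equal(colSums(comp$pwm$mat), rep(1, ncol(comp$pwm$mat)),
                 tolerance = 1e-9)
  }
  # merging against a uniform column returns the original (up to pseudocount)
  uni <- pwm("uni", matrix(0.25, nrow = 4, ncol = 5))
  comp <- build_composite(h, uni, "CON", spacer = -2L)
  # CON at -2: last 2 columns of h merged with uniform columns of revcomp(uni)
  expect_equal(unname(comp$pwm$mat[, 4:5]), unname(h$mat[, 4:5]),
               tolerance = 1e-3)
})

test_that("log-odds scoring matches closed forms and is N-neutral", {
  uni <- pwm("uni", matrix(0.25, nrow = 4, ncol = 6))
  expect_equal(log_odds_score("ACGTAC", uni), 0)

  half <- foxa1_monomer_pwm("core")
  d0 <- div_motif(half, 0)
  # consensus achieves the maximum over the full 4^8 enumeration
  S <- log2(d0$pwm$mat / d0$pwm$background)
  combos <- as.matrix(expand.grid(rep(list(1:4), 8)))
  all_scores <- S[cbind(c(t(combos)), rep(1:8, nrow(combos)))]
  all_scores <- rowSums(matrix(all_scores, ncol = 8, byrow = TRUE))
  expect_equal(log_odds_score(consensus_string(d0), d0), max(all_scores),
               tolerance = 1e-12)
  expect_equal(max_score(d0), max(all_scores), tolerance = 1e-12)

  # an N contributes exactly 0 bits
  win <- consensus_string(d0)
  win_n <- win; substr(win_n, 3, 3) <- "N"
  col3 <- log2(d0$pwm$mat["A", 3] / d0$pwm$background["A"])
  expect_equal(log_odds_score(win_n, d0),
               log_odds_score(win, d0) - unname(col3))

  expect_error(log_odds_score("ACGT", d0), "length")
  expect_error(log_odds_score("ACGTXACG", d0), "position 5")
})

test_that("scanning finds planted sites and matches the brute-force rescan", {
  half <- foxa1_monomer_pwm("core")
  d0 <- div_motif(half, 0)

  # threshold above the max yields nothing
  set.seed(21)
  expect_equal(nrow(scan_sequence(random_seq(500), d0, max_score(d0) + 1)), 0L)

  # planted consensus at a known offset in a GC-rich background: exactly one
  # +/- pair at that offset (the element is palindromic)
  set.seed(22)
  bg <- random_seq(400, prob = c(0.1, 0.4, 0.4, 0.1))
  planted <- paste0(substr(bg, 1, 150), consensus_string(d0),
                    substr(bg, 159, 400))
  hits <- scan_sequence(planted, d0, max_score(d0) - 1e-9)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(150L, 150L))
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(hits$end - hits$start, c(8L, 8L))

  # full equivalence with the naive double-strand rescan on random inputs
  set.seed(23)
  for (i in 1:50) {
    s <- random_seq(sample(30:120, 1))
    thr <- runif(1, -5, 8)
    got <- scan_sequence(s, d0, thr)
    want <- oracle_scan(s, d0$pwm$mat, d0$pwm$background, thr)
    expect_equal(got$start, want$start)
    expect_equal(got$strand, want$strand)
    expect_equal(got$score, want$score, tolerance = 1e-10)
  }
})

test_that("palindromic hit sets are symmetric under reverse complementation", {
  half <- foxa1_monomer_pwm("core")
  d0 <- div_motif(half, 0)
  set.seed(31)
  s <- paste0(random_seq(80), consensus_string(d0), random_seq(60))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  h1 <- scan_sequence(s, d0, 5)
  h2 <- scan_sequence(rc, d0, 5)
  # reflect h2 coordinates back onto the forward sequence
  L <- nchar(s)
  expect_setequal(h1$start, L - h2$end)
})

test_that("hit count is non-increasing in the threshold", {
  half <- foxa1_monomer_pwm("core")
  d0 <- div_motif(half, 0)
  set.seed(41)
  s <- random_seq(3000, prob = c(0.3, 0.2, 0.2, 0.3))
  ths <- seq(-6, 13, by = 1)
  counts <- vapply(ths, function(t) nrow(scan_sequence(s, d0, t)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("threshold calibration hits the requested sensitivity exactly", {
  half <- foxa1_monomer_pwm("core")
  d0 <- div_motif(half, 0)
  cons <- consensus_string(d0)

  # every positive contains the consensus: threshold equals the consensus
  # score at sensitivity 1
  set.seed(51)
  pos <- replicate(20, paste0(random_seq(40, prob = c(0.1, 0.4, 0.4, 0.1)),
                              cons,
                              random_seq(40, prob = c(0.1, 0.4, 0.4, 0.1))))
  t1 <- calibrate_threshold(d0, pos, sensitivity = 1)
  expect_equal(as.numeric(t1), max_score(d0), tolerance = 1e-9)
  expect_equal(attr(t1, "sensitivity"), 1)

  # 80 of 100 carry a strong site, 20 are weak background: the calibrated
  # threshold separates them at sensitivity exactly 0.80
  set.seed(52)
  strong <- replicate(80, paste0(random_seq(30, prob = c(0.1, 0.4, 0.4, 0.1)),
                                 cons,
                                 random_seq(30, prob = c(0.1, 0.4, 0.4, 0.1))))
  weak <- replicate(20, random_seq(68, prob = c(0.05, 0.45, 0.45, 0.05)))
  t80 <- calibrate_threshold(d0, c(strong, weak), sensitivity = 0.8)
  expect_equal(attr(t80, "sensitivity"), 0.8)
  expect_true(all(best_scores(strong, d0) >= as.numeric(t80)))
  expect_true(all(best_scores(weak, d0) < as.numeric(t80)))

  # sensitivity 1 on a mixed set returns the minimum per-sequence maximum
  mix <- c(strong[1:5], weak[1:5])
  tmin <- calibrate_threshold(d0, mix, sensitivity = 1)
  expect_equal(as.numeric(tmin), min(best_scores(mix, d0)))

  expect_error(calibrate_threshold(d0, character(0)), "at least one")
  expect_error(calibrate_threshold(d0, "ACGT", sensitivity = 0), "\\(0, 1\\]")
})

test_that("degenerate consensus codes spread probability over their bases", {
  full <- foxa1_monomer_pwm("full")  # AWTRTTKRYTY
  expect_equal(length(full), 11L)
  # W position: A and T share 0.7
  expect_equal(unname(full$mat[c("A", "T"), 2]), c(0.35, 0.35))
  expect_equal(unname(full$mat[c("C", "G"), 2]), c(0.15, 0.15))
  expect_equal(unname(colSums(full$mat)), rep(1, 11), tolerance = 1e-12)

  homer <- foxa1_monomer_pwm("homer")
  expect_equal(consensus_string(homer), "AAAGTAAACA")
})
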