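mk_snp <- function(pos, id = sprintf("rs%03d", seq_along(pos)),
                   major = "T", minor = "G", chrom = "chr1") {
  data.frame(chrom = chrom, pos = as.integer(pos), id = id,
             major = major, minor = minor, stringsAsFactors = FALSE)
}

test_that("central-TA filtering keeps exactly match positions 4-5 of 8", {
  hit <- data.frame(chrom = "chr1", start = 1000L, end = 1008L, strand = "+")
  # 0-based offsets 3 and 4 are the central TA; 1-based SNP positions
  # 1004 and 1005
  for (off in 0:7) {
    snp <- mk_snp(1000L + off + 1L)
    kept <- filter_central_ta(snp, hit)
    expect_equal(nrow(kept), if (off %in% c(3L, 4L)) 1L else 0L,
                 info = paste("offset", off))
  }
  # a SNP outside every hit is dropped
  expect_equal(nrow(filter_central_ta(mk_snp(5000L), hit)), 0L)
  # strand of the hit does not matter for the symmetric central frame
  hit_m <- within(hit, strand <- "-")
  expect_equal(nrow(filter_central_ta(mk_snp(1004L), hit_m)), 1L)
})

test_that("central-TA filtering commutes with coordinate translation", {
  set.seed(101)
  hits <- data.frame(chrom = "chr1",
                     start = sample.int(1e5, 20), strand = "+")
  hits$end <- hits$start + 8L
  snps <- mk_snp(sample.int(1e5, 50))
  k <- 137L
  shifted_first <- filter_central_ta(
    within(snps, pos <- pos + k),
    within(hits, { start <- start + k; end <- end + k }))
  filtered_first <- filter_central_ta(snps, hits)
  expect_equal(shifted_first$pos, filtered_first$pos + k)
})

test_that("allelic rescoring quantifies central-TA disruption", {
  half <- foxa1_monomer_pwm("core")
  d0 <- div_motif(half, 0)
  set.seed(102)
  bg <- random_seq(200, prob = c(0.1, 0.4, 0.4, 0.1))
  genome <- c(chr1 = paste0(substr(bg, 1, 100), consensus_string(d0),
                            substr(bg, 109, 200)))
  # SNP on the central T (0-based 103, 1-based 104): major = reference T,
  # minor G destroys the shared TA
  snp <- mk_snp(104L, id = "rs_central")
  thr <- max_score(d0) - 3
  res <- allelic_score_delta(snp, genome, d0, thr)
  expect_equal(res$score_major, max_score(d0), tolerance = 1e-9)
  expect_gt(res$delta, 0)
  expect_true(res$perturbs_dimer)
  expect_equal(res$delta, res$score_major - res$score_minor)

  # per-allele scores equal the exhaustive best-window enumeration
  W <- 8L
  enumerate_best <- function(allele) {
    s <- genome[["chr1"]]
    substr(s, 104L, 104L) <- allele
    lo <- 103L - (W - 1L); hi <- 103L + W
    ctx <- substr(s, lo + 1L, hi)
    max(oracle_scan(ctx, d0$pwm$mat, d0$pwm$background, -1e9)$score)
  }
  expect_equal(res$score_major, enumerate_best("T"), tolerance = 1e-10)
  expect_equal(res$score_minor, enumerate_best("G"), tolerance = 1e-10)

  # a position whose column weights both alleles equally gives delta 0:
  # the inserted-background column of the D3 control motif
  d3 <- div_motif(half, 3)
  plant <- consensus_string(d3)  # AAATA + background col + TATTT
  genome3 <- c(chr1 = paste0(substr(bg, 1, 100), plant, substr(bg, 112, 200)))
  snp_bg <- mk_snp(106L, id = "rs_spacer", major = "A", minor = "C")
  res3 <- allelic_score_delta(snp_bg, genome3, d3, max_score(d3) - 1)
  expect_equal(res3$delta, 0)

  # reference mismatch warns but proceeds
  snp_bad <- mk_snp(104L, id = "rs_bad", major = "C", minor = "G")
  expect_warning(allelic_score_delta(snp_bad, genome, d0, thr),
                 "matches neither allele")
})

test_that("allelic delta is invariant to the strand the hit was reported on", {
  half <- foxa1_monomer_pwm("core")
  d0 <- div_motif(half, 0)
  set.seed(103)
  bg <- random_seq(120, prob = c(0.15, 0.35, 0.35, 0.15))
  genome <- c(chr1 = paste0(substr(bg, 1, 60), consensus_string(d0),
                            substr(bg, 69, 120)))
  snp <- mk_snp(64L, id = "rs_x")   # central T, 0-based 63 = 60 + 3
  hits <- scan_sequence(genome[["chr1"]], d0, max_score(d0) - 1e-9)
  expect_setequal(hits$strand, c("+", "-"))
  # the scoring window scans both strands regardless of the reporting
  # strand, so both hits imply the same delta
  res <- allelic_score_delta(snp, genome, d0, max_score(d0) - 3)
  expect_equal(nrow(res), 1L)
  expect_gt(res$delta, 0)
})

test_that("SNP table and VCF readers validate records", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tid\tmajor\tminor",
               "chr1\t100\trs1\tA\tG",
               "chr2\t50\trs2\tT\tC"), tsv)
  snps <- read_snp_tsv(tsv)
  expect_equal(snps$id, c("rs1", "rs2"))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tid\tmajor\tminor",
               "chr1\t100\trs1\tA\tA"), bad)
  expect_error(read_snp_tsv(bad), "line 1")

  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT",
               "chr1\t100\trs1\tA\tG,T",
               "chr1\t200\trs2\tAT\tA",     # indel, dropped
               "chr1\t300\trs3\tC\tT"), vcf)
  got <- read_snp_vcf(vcf)
  expect_equal(got$id, c("rs1", "rs3"))
  expect_equal(got$minor, c("G", "T"))  # first ALT only
})

test_that("screen report joins annotations without dropping unmatched rows", {
  res <- data.frame(snp_id = c("rs1", "rs2"), chrom = "chr1", pos = c(1L, 2L),
                    score_major = c(10, 9), score_minor = c(4, 8.5),
                    delta = c(6, 0.5), perturbs_dimer = c(TRUE, FALSE))
  plain <- screen_report(res)
  expect_equal(plain$snp_id, c("rs1", "rs2"))  # sorted by |delta|
  expect_false(any(plain$unmatched))

  emsa <- data.frame(snp_id = c("rs1", "rs9"), dimer_call = c("lost", "kept"))
  rep <- screen_report(res, emsa_calls = emsa)
  expect_equal(nrow(rep), 3L)
  expect_true(rep$unmatched[rep$snp_id == "rs9"])
  expect_false(any(rep$unmatched[rep$snp_id != "rs9"]))
})

test_that("the synthetic funnel flags exactly the planted dimer-destroying SNPs", {
  cfg <- synth_config(seed = 13)
  g <- make_genome(cfg)
  snps <- make_snps(cfg, g$genome, g$truth)
  expect_equal(nrow(snps), 15L + 8L + 5L + 5L)

  # candidate dimer coordinates: intact and broken planted D0 frames
  cand <- g$truth[g$truth$name %in% c("D0", "D0broken"), ]
  kept <- filter_central_ta(snps, cand)
  expect_setequal(unique(kept$truth_label),
                  c("central_destructive", "central_tolerated"))
  expect_equal(nrow(kept), 23L)

  d0 <- div_motif()
  res <- allelic_score_delta(kept, g$genome, d0, threshold = max_score(d0) - 3)
  rep <- screen_report(res)
  flagged <- rep$snp_id[rep$perturbs_dimer]
  expect_setequal(flagged,
                  kept$id[kept$truth_label == "central_destructive"])
  expect_equal(length(flagged), 15L)
})
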