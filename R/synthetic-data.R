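#' Configuration of the synthetic-data generator
#'
#' Bundles every tunable of the generators with defaults that reproduce the
#' statistical structure the pipeline assumes: a ~2 Mb i.i.d. background
#' genome with planted compact-dimer (D0), spacer-perturbed control
#' (D1-D10) and monomer motif instances; ChIP-seq-like peaks whose
#' signalValue distribution depends on the motif category (D strongest);
#' two-condition accessibility counts in which D-category loci carry an
#' elevated closed-to-open probability; SNP tables mirroring the
#' central-TA screening funnel; and named titration presets for the
#' equilibrium model. All generators are byte-deterministic under a fixed
#' seed.
#'
#' @param seed Integer seed.
#' @param genome_length Genome length in bp.
#' @param gc_content Background GC fraction.
#' @param n_div,n_control,n_mono Planted counts of D0, control (cycling
#'   D1-D10) and monomer instances.
#' @param n_broken_div D0 instances planted with the central T mutated to G
#'   (weak sites used by the SNP funnel).
#' @param n_unbound_peaks Background peaks without any planted motif.
#' @param min_plant_gap Minimum distance between planted instances, bp.
#' @param peak_halfwidth,peak_jitter Peak half-width and center jitter, bp.
#' @param signal_meanlog,signal_sdlog Lognormal signalValue parameters per
#'   category.
#' @param class_base Base probabilities of the accessibility classes.
#' @param co_enrichment Additive boost of the CO-class probability for
#'   D-category loci.
#' @param atac_mu_open,atac_mu_closed,atac_size Negative-binomial count
#'   model (mean when open / closed, common dispersion size).
#' @param noise_sd Titration fraction noise SD.
#' @param n_snp_destructive,n_snp_tolerated,n_snp_flank,n_snp_offmotif SNP
#'   funnel composition (see [make_snps()]).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         genome_length = 2e6,
                         gc_content = 0.41,
                         n_div = 150L, n_control = 150L, n_mono = 150L,
                         n_broken_div = 8L,
                         n_unbound_peaks = 150L,
                         min_plant_gap = 500L,
                         peak_halfwidth = 150L, peak_jitter = 30L,
                         signal_meanlog = c(D = 2.2, C = 1.2, M = 1.1, N = 0.6),
                         signal_sdlog = 0.4,
                         class_base = c(PO = 0.05, CO = 0.10, OC = 0.10, CC = 0.75),
                         co_enrichment = 0.35,
                         atac_mu_open = 60, atac_mu_closed = 4, atac_size = 8,
                         noise_sd = 0.02,
                         n_snp_destructive = 15L, n_snp_tolerated = 8L,
                         n_snp_flank = 5L, n_snp_offmotif = 5L) {
  cfg <- as.list(environment())
  stopifnot(cfg$gc_content > 0, cfg$gc_content < 1,
            abs(sum(cfg$class_base) - 1) < 1e-9,
            cfg$co_enrichment >= 0,
            cfg$class_base["CO"] + cfg$co_enrichment <= 1)
  structure(cfg, class = "synth_config")
}

SYNTH_CHROM <- "chrS"

## greedy non-overlapping placement of n plant starts with pairwise distance
## >= gap, away from the sequence edges
.place_plants <- function(n, genome_length, gap, margin = 1000L) {
  lo <- margin; hi <- genome_length - margin
  starts <- integer(0)
  tries <- 0L
  while (length(starts) < n && tries < 50L) {
    cand <- sort(sample.int(hi - lo, n * 3L) + lo)
    for (s in cand) {
      if (length(starts) == n) break
      if (!length(starts) || all(abs(starts - s) >= gap)) starts <- c(starts, s)
    }
    tries <- tries + 1L
  }
  if (length(starts) < n)
    stop("could not place ", n, " plants with gap ", gap,
         " in ", genome_length, " bp")
  sort(starts)
}

.revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Generate a synthetic genome with planted motif instances
#'
#' Draws an i.i.d. background sequence at the configured GC content and
#' plants exact-consensus instances of the compact dimer element D0, the
#' spacer-perturbed controls D1-D10 (cycled), the monomer motif, and
#' "broken" D0 instances with the central T mutated to G. Plants are
#' non-overlapping, at least `min_plant_gap` apart, on random strands
#' (forward-only for the strand-asymmetric broken plants), and every plant
#' is recorded in a truth table sufficient to score recall of the scanning
#' stage.
#'
#' @param config A [synth_config()].
#' @return List with `genome` (named character vector of one chromosome)
#'   and `truth` (data frame `chrom`, `start`, `end`, `name`, `strand` in
#'   0-based half-open coordinates).
#' @export
make_genome <- function(config = synth_config()) {
  set.seed(config$seed)
  gc <- config$gc_content
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  L <- as.integer(config$genome_length)
  bases <- sample(names(base_prob), L, replace = TRUE, prob = base_prob)

  half <- foxa1_monomer_pwm("core")
  div_cons <- consensus_string(div_motif(half, 0))            # AAATATTT
  ## planted control instances use a GC-alternating inserted spacer so that
  ## no spacer choice can recreate the all-A/T compact element by chance;
  ## spacer columns are uniform in the control PWMs, so the plant still
  ## attains the control motif's maximum score
  ctrl_cons <- vapply(1:10, function(n) {
    if (n <= 2L) consensus_string(div_motif(half, n))
    else paste0("AAATA", substring(strrep("GC", 4L), 1L, n - 2L), "TATTT")
  }, character(1))
  mono_cons <- consensus_string(foxa1_monomer_pwm("homer"))   # AAAGTAAACA
  broken_cons <- div_cons
  substr(broken_cons, 4L, 4L) <- "G"                          # AAAGATTT

  ctrl_idx <- rep(1:10, length.out = config$n_control)
  plan <- data.frame(
    name = c(rep("D0", config$n_div),
             paste0("D", 1:10)[ctrl_idx],
             rep("M", config$n_mono),
             rep("D0broken", config$n_broken_div)),
    seq = c(rep(div_cons, config$n_div),
            ctrl_cons[ctrl_idx],
            rep(mono_cons, config$n_mono),
            rep(broken_cons, config$n_broken_div)),
    stringsAsFactors = FALSE)
  plan$strand <- sample(c("+", "-"), nrow(plan), replace = TRUE)
  plan$strand[plan$name == "D0broken"] <- "+"

  starts <- .place_plants(nrow(plan), L, config$min_plant_gap)
  plan <- plan[sample.int(nrow(plan)), , drop = FALSE]  # shuffle before placing
  plan$start <- starts
  for (i in seq_len(nrow(plan))) {
    s <- if (plan$strand[i] == "+") plan$seq[i] else .revcomp_chr(plan$seq[i])
    bases[plan$start[i] + seq_len(nchar(s))] <- strsplit(s, "")[[1]]
  }

  genome <- stats::setNames(paste(bases, collapse = ""), SYNTH_CHROM)
  truth <- data.frame(chrom = rep(SYNTH_CHROM, nrow(plan)),
                      start = plan$start,
                      end = plan$start + nchar(plan$seq),
                      name = plan$name,
                      strand = plan$strand,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  list(genome = genome, truth = truth)
}

.truth_category <- function(name) {
  ifelse(name == "D0", "D",
  ifelse(grepl("^D(10|[1-9])$", name), "C",
  ifelse(name == "M", "M", NA_character_)))
}

#' Generate ChIP-seq-like peaks over planted sites
#'
#' Centers one peak (with jitter) on every planted D0, control and monomer
#' instance, adds background peaks away from any plant, and draws
#' signalValue from a category-dependent lognormal (D strongest under the
#' defaults). Returns a narrowPeak-shaped table plus the truth category of
#' every peak.
#'
#' @param config A [synth_config()].
#' @param truth Truth table from [make_genome()].
#' @return List with `peaks` (narrowPeak columns plus nothing extra) and
#'   `truth_category` (factor parallel to the peaks).
#' @export
make_peaks <- function(config, truth) {
  set.seed(config$seed + 1L)
  motif_truth <- truth[!is.na(.truth_category(truth$name)), , drop = FALSE]
  category <- .truth_category(motif_truth$name)
  centers <- (motif_truth$start + motif_truth$end) %/% 2L

  ## background peaks: keep clear of every plant by window + half-width
  clear <- config$peak_halfwidth + config$peak_jitter + 200L
  n_bg <- config$n_unbound_peaks
  bg_centers <- integer(0)
  while (length(bg_centers) < n_bg) {
    cand <- sample.int(config$genome_length - 2L * clear, n_bg) + clear
    ok <- vapply(cand, function(x) all(abs(x - centers) > config$min_plant_gap %/% 2L +
                                         clear), logical(1))
    bg_centers <- unique(c(bg_centers, cand[ok]))
  }
  bg_centers <- bg_centers[seq_len(n_bg)]

  all_centers <- c(centers, bg_centers)
  all_cat <- c(category, rep("N", n_bg))
  jitter <- sample(seq(-config$peak_jitter, config$peak_jitter),
                   length(all_centers), replace = TRUE)
  start <- pmax(0L, all_centers + jitter - config$peak_halfwidth)
  end <- pmin(as.integer(config$genome_length),
              all_centers + jitter + config$peak_halfwidth)
  signal <- stats::rlnorm(length(all_centers),
                          meanlog = config$signal_meanlog[all_cat],
                          sdlog = config$signal_sdlog)
  peaks <- data.frame(chrom = SYNTH_CHROM, start = start, end = end,
                      name = sprintf("peak%04d", seq_along(all_centers)),
                      score = pmin(1000L, as.integer(round(10 * signal))),
                      strand = ".",
                      signal = signal, pvalue = -1, qvalue = -1,
                      peak = config$peak_halfwidth,
                      stringsAsFactors = FALSE)
  ord <- order(peaks$start)
  list(peaks = peaks[ord, , drop = FALSE],
       truth_category = factor(all_cat[ord], levels = CATEGORY_LEVELS))
}

#' Generate two-condition accessibility counts for labeled intervals
#'
#' Assigns every interval a true dynamics class (D-category intervals get
#' their CO probability boosted by `co_enrichment`, with the other classes
#' scaled down proportionally) and draws negative-binomial read counts per
#' condition: the open mean when the class is open in that condition, the
#' closed mean otherwise.
#'
#' @param config A [synth_config()].
#' @param intervals Data frame with `chrom`, `start`, `end`.
#' @param categories Category labels parallel to `intervals` (levels D, C,
#'   M, N and optionally "Unbound").
#' @return Data frame: the intervals plus `category`, `count_ctrl`,
#'   `count_trt` and `truth_class`.
#' @export
make_atac <- function(config, intervals, categories) {
  stopifnot(nrow(intervals) == length(categories))
  set.seed(config$seed + 2L)
  base <- config$class_base
  boosted <- base
  boosted["CO"] <- base["CO"] + config$co_enrichment
  others <- setdiff(names(base), "CO")
  boosted[others] <- base[others] * (1 - boosted["CO"]) / sum(base[others])

  cls <- vapply(as.character(categories), function(cat) {
    p <- if (identical(cat, "D")) boosted else base
    sample(names(p), 1L, prob = p)
  }, character(1))

  open_in <- cbind(ctrl = cls %in% c("PO", "OC"),
                   trt = cls %in% c("PO", "CO"))
  draw <- function(open) stats::rnbinom(length(open), size = config$atac_size,
                                        mu = ifelse(open, config$atac_mu_open,
                                                    config$atac_mu_closed))
  out <- intervals[, c("chrom", "start", "end")]
  out$category <- as.character(categories)
  out$count_ctrl <- draw(open_in[, "ctrl"])
  out$count_trt <- draw(open_in[, "trt"])
  out$truth_class <- factor(cls, levels = DYNAMICS_LEVELS)
  out
}

#' Named titration presets of the equilibrium model
#'
#' Operating points mirroring the quantitative gel experiments: `div` and
#' `con` are single-lane cooperativity measurements at 100 nM probe (400
#' and 320 nM protein respectively) with ground-truth omega 56.3 and 1.8;
#' `monomer` and `kd_apparent` are 14-lane two-fold dilution series (2500
#' nM down to 0.61 nM plus a no-protein lane) at 1 nM probe with
#' ground-truth dissociation constants 2.4 and 4.5 nM on a single-site
#' bound fraction; `rs2941742_major` / `rs2941742_minor` form an allele
#' pair whose minor-allele cooperativity is planted 20-fold below the
#' major allele (major omega 20, minor omega 1, i.e. the minor allele
#' abolishes cooperativity while half-site affinity is unchanged). The half-site affinity of each single-lane preset is set
#' so that free, monomer and dimer bands are all populated at the stated
#' lane (the omega estimator is invariant to this choice); the minor
#' allele is measured at a higher lane concentration for the same reason.
#'
#' @return Named list of presets; each has `params` ([binding_params()]),
#'   `p_series`, `d_total`, `sites` and `n_replicates`.
#' @export
titration_presets <- function() {
  grid14 <- c(2500 / 2^(0:12), 0)
  list(
    div = list(params = binding_params(2250, 56.3),
               p_series = 400, d_total = 100, sites = 2L, n_replicates = 5L),
    con = list(params = binding_params(300, 1.8),
               p_series = 320, d_total = 100, sites = 2L, n_replicates = 5L),
    monomer = list(params = binding_params(2.4, 1),
                   p_series = grid14, d_total = 1, sites = 1L,
                   n_replicates = 3L),
    kd_apparent = list(params = binding_params(4.5, 1),
                       p_series = grid14, d_total = 1, sites = 1L,
                       n_replicates = 3L),
    rs2941742_major = list(params = binding_params(1340, 20),
                           p_series = 400, d_total = 100, sites = 2L,
                           n_replicates = 5L),
    rs2941742_minor = list(params = binding_params(1340, 1),
                           p_series = 1440, d_total = 100, sites = 2L,
                           n_replicates = 5L))
}

#' Simulate replicate titration series from a named preset
#'
#' @param preset_name One of `names(titration_presets())`.
#' @param seed Integer seed (replicate sub-seeds are derived from it).
#' @param n_replicates Override of the preset replicate count.
#' @param noise_sd Fraction noise SD (default from [synth_config()]).
#' @return A titration data frame with one block per replicate.
#' @export
make_titrations <- function(preset_name, seed = 1L, n_replicates = NULL,
                            noise_sd = 0.02) {
  presets <- titration_presets()
  if (!preset_name %in% names(presets))
    stop("unknown preset '", preset_name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[preset_name]]
  n <- if (is.null(n_replicates)) p$n_replicates else as.integer(n_replicates)
  set.seed(seed)
  rep_seeds <- sample.int(2^30, n)
  do.call(rbind, lapply(seq_len(n), function(r)
    simulate_titration(p$params, p$p_series, p$d_total,
                       noise_sd = noise_sd, seed = rep_seeds[r],
                       sites = p$sites, probe_id = preset_name,
                       replicate_id = r)))
}

#' Generate the SNP screening funnel fixture
#'
#' Places single-nucleotide variants over the planted genome:
#' `n_snp_destructive` SNPs on the central T of intact D0 plants whose
#' minor allele (G) destroys the central TA; `n_snp_tolerated` SNPs on the
#' central position of the "broken" D0 plants, where neither allele
#' supports a dimer match (major G, minor C); `n_snp_flank` SNPs on the
#' first base of intact D0 plants (outside the central dinucleotide);
#' `n_snp_offmotif` SNPs in plain background. Truth labels are recorded
#' for recall scoring of the central-TA filter and of the allelic screen.
#'
#' @param config A [synth_config()].
#' @param genome,truth Output of [make_genome()].
#' @return Data frame with `chrom`, `pos` (1-based), `id`, `major`,
#'   `minor`, `truth_label`.
#' @export
make_snps <- function(config, genome, truth) {
  set.seed(config$seed + 3L)
  seq <- genome[[SYNTH_CHROM]]
  ref_at <- function(pos0) substr(seq, pos0 + 1L, pos0 + 1L)

  d0 <- truth[truth$name == "D0", , drop = FALSE]
  broken <- truth[truth$name == "D0broken", , drop = FALSE]
  if (nrow(d0) < config$n_snp_destructive + config$n_snp_flank)
    stop("not enough planted D0 instances for the requested SNP counts")
  if (nrow(broken) < config$n_snp_tolerated)
    stop("not enough broken D0 plants for the requested tolerated SNPs")

  pick <- sample.int(nrow(d0), config$n_snp_destructive + config$n_snp_flank)
  d0_destr <- d0[pick[seq_len(config$n_snp_destructive)], , drop = FALSE]
  d0_flank <- d0[pick[config$n_snp_destructive + seq_len(config$n_snp_flank)], ,
                 drop = FALSE]
  brk <- broken[seq_len(config$n_snp_tolerated), , drop = FALSE]

  other_base <- function(ref) vapply(ref, function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))

  ## central T of the 8-bp element: offset 3 (0-based) on either strand
  ## (the element is its own reverse complement)
  destr_pos0 <- d0_destr$start + 3L
  destr <- data.frame(chrom = SYNTH_CHROM, pos = pos0_to_1(destr_pos0),
                      major = ref_at(destr_pos0), minor = "G",
                      truth_label = "central_destructive")
  destr$minor[destr$major == "G"] <- "C"

  tol_pos0 <- brk$start + 3L
  tol <- data.frame(chrom = SYNTH_CHROM, pos = pos0_to_1(tol_pos0),
                    major = ref_at(tol_pos0), minor = "C",
                    truth_label = "central_tolerated")

  flank_pos0 <- d0_flank$start
  flank <- data.frame(chrom = SYNTH_CHROM, pos = pos0_to_1(flank_pos0),
                      major = ref_at(flank_pos0), minor = "G",
                      truth_label = "flank")
  flank$minor[flank$major == "G"] <- "C"

  clear <- 100L
  off_pos0 <- integer(0)
  while (length(off_pos0) < config$n_snp_offmotif) {
    cand <- sample.int(as.integer(config$genome_length) - 2000L,
                       config$n_snp_offmotif) + 1000L
    ok <- vapply(cand, function(x)
      all(x < truth$start - clear | x > truth$end + clear), logical(1))
    off_pos0 <- unique(c(off_pos0, cand[ok]))
  }
  off_pos0 <- off_pos0[seq_len(config$n_snp_offmotif)]
  off <- data.frame(chrom = SYNTH_CHROM, pos = pos0_to_1(off_pos0),
                    major = ref_at(off_pos0), minor = NA_character_,
                    truth_label = "off_motif")
  off$minor <- other_base(off$major)

  snps <- rbind(destr, tol, flank, off)
  snps$id <- sprintf("snp%03d", seq_len(nrow(snps)))
  snps[, c("chrom", "pos", "id", "major", "minor", "truth_label")]
}
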