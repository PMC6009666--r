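CATEGORY_LEVELS <- c("D", "C", "M", "N")

#' Remove control-dimer hits that overlap a correctly spaced dimer site
#'
#' Control loci (spacer-perturbed dimer motifs) that overlap a correctly
#' spaced DIV dimer locus by at least 1 bp are excluded before peak
#' categorization, so the control set does not double-count true dimer
#' sites.
#'
#' @param control_hits,div_hits Hit data frames (`chrom`, `start`, `end`).
#' @return `control_hits` restricted to rows with zero overlap against
#'   every DIV hit.
#' @export
exclude_div_overlapping_controls <- function(control_hits, div_hits) {
  if (nrow(control_hits) == 0L || nrow(div_hits) == 0L) return(control_hits)
  pairs <- interval_pairs(control_hits, div_hits, mode = "intersect")
  drop <- unique(pairs$a_idx)
  if (length(drop)) control_hits[-drop, , drop = FALSE] else control_hits
}

#' Categorize peaks by motif content
#'
#' Assigns each peak one of four binding-site categories with precedence
#' D > C > M > N: a peak within `window` bp of at least one DIV dimer hit
#' is `D`; otherwise within `window` bp of a (DIV-overlap-filtered)
#' control-dimer hit is `C`; otherwise within `window` bp of a monomer hit
#' is `M`; otherwise `N` ("no motif"). Proximity uses symmetric windowed
#' intersection with the gap boundary inclusive (a peak exactly `window` bp
#' from a hit still counts).
#'
#' @param peaks Peak data frame (`chrom`, `start`, `end`, ...).
#' @param div_hits,control_hits,mono_hits Motif hit data frames (possibly
#'   empty).
#' @param window Window in bp, >= 0 (default 100).
#' @return Factor of labels (levels D, C, M, N), one per peak.
#' @export
assign_categories <- function(peaks, div_hits, control_hits, mono_hits,
                              window = 100L) {
  stopifnot(window >= 0)
  empty <- function() data.frame(chrom = character(0), start = integer(0),
                                 end = integer(0))
  if (is.null(div_hits)) div_hits <- empty()
  if (is.null(control_hits)) control_hits <- empty()
  if (is.null(mono_hits)) mono_hits <- empty()

  control_hits <- exclude_div_overlapping_controls(control_hits, div_hits)

  near <- function(hits) {
    if (nrow(hits) == 0L) return(logical(nrow(peaks)))
    idx <- interval_pairs(peaks, hits, mode = "window", window = window)$a_idx
    seq_len(nrow(peaks)) %in% idx
  }
  lab <- rep("N", nrow(peaks))
  lab[near(mono_hits)] <- "M"
  lab[near(control_hits)] <- "C"
  lab[near(div_hits)] <- "D"
  factor(lab, levels = CATEGORY_LEVELS)
}

#' Peak signal summaries and pairwise tests by category
#'
#' Per-category count, median and quartiles of the peak signal, plus all
#' pairwise two-sided unpaired Wilcoxon rank-sum tests with Holm-adjusted
#' p-values (the adjustment spanning all pairwise comparisons within the
#' dataset). Categories with fewer than 2 peaks are summarized but excluded
#' from testing with a warning.
#'
#' @param peaks Peak data frame with a `signal` column.
#' @param labels Category factor from [assign_categories()].
#' @return List with `summary` (per-category data frame) and `tests`
#'   (pairwise comparisons with raw and Holm-adjusted p-values; `NULL` if
#'   fewer than two testable categories).
#' @export
signal_by_category <- function(peaks, labels) {
  stopifnot(nrow(peaks) == length(labels))
  labels <- factor(labels, levels = CATEGORY_LEVELS)
  sig <- peaks$signal
  summary <- do.call(rbind, lapply(levels(labels), function(l) {
    x <- sig[labels == l]
    data.frame(category = l, n = length(x),
               q1 = if (length(x)) unname(stats::quantile(x, 0.25)) else NA_real_,
               median = if (length(x)) stats::median(x) else NA_real_,
               q3 = if (length(x)) unname(stats::quantile(x, 0.75)) else NA_real_)
  }))

  counts <- table(labels)
  testable <- names(counts)[counts >= 2L]
  small <- names(counts)[counts >= 1L & counts < 2L]
  if (length(small))
    warning("category(ies) with n < 2 excluded from testing: ",
            paste(small, collapse = ", "))
  tests <- NULL
  if (length(testable) >= 2L) {
    keep <- labels %in% testable
    pw <- stats::pairwise.wilcox.test(sig[keep], droplevels(labels[keep]),
                                      p.adjust.method = "holm", exact = FALSE)
    m <- pw$p.value
    idx <- which(!is.na(m), arr.ind = TRUE)
    raw <- stats::pairwise.wilcox.test(sig[keep], droplevels(labels[keep]),
                                       p.adjust.method = "none", exact = FALSE)$p.value
    tests <- data.frame(group1 = rownames(m)[idx[, 1]],
                        group2 = colnames(m)[idx[, 2]],
                        p = raw[idx], p_adj = m[idx])
    tests <- tests[order(tests$p_adj), , drop = FALSE]
  }
  list(summary = summary, tests = tests)
}

#' Fractional category composition per signal decile
#'
#' Peaks are ranked by signal descending (stable on `name` for ties), split
#' into 10 near-equal deciles (decile 1 = strongest; when the count is not
#' divisible by 10 the remainder peaks go to the top deciles), and the
#' fractional count of each category is computed per decile.
#'
#' @param peaks Peak data frame with `signal` and `name` columns.
#' @param labels Category factor from [assign_categories()].
#' @return Data frame with `decile`, `n`, and one fraction column per
#'   category; fractions sum to 1 within each decile.
#' @export
decile_fractions <- function(peaks, labels) {
  n <- nrow(peaks)
  if (n < 10L) stop("need at least 10 peaks to form deciles")
  labels <- factor(labels, levels = CATEGORY_LEVELS)
  nm <- if (is.null(peaks$name)) as.character(seq_len(n)) else as.character(peaks$name)
  ord <- order(-peaks$signal, nm)
  sizes <- rep(n %/% 10L, 10L)
  r <- n %% 10L
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  decile <- rep(seq_len(10L), sizes)
  lab_sorted <- labels[ord]
  out <- do.call(rbind, lapply(1:10, function(d) {
    tab <- table(lab_sorted[decile == d])
    frac <- as.numeric(tab) / sum(tab)
    df <- data.frame(decile = d, n = sum(tab))
    for (i in seq_along(frac)) df[[names(tab)[i]]] <- frac[i]
    df
  }))
  rownames(out) <- NULL
  out
}

#' DIV versus control-dimer enrichment relative to the genome
#'
#' Ratio of the DIV/control category counts among peaks to the genome-wide
#' DIV/control motif counts: `(peaks_D / peaks_C) / (genome_D / genome_C)`.
#' A value of 1 means no enrichment of the correctly spaced dimer element
#' among bound peaks.
#'
#' @param peak_counts,genome_counts Named vectors (or lists) with positive
#'   elements `D` and `C`.
#' @return The enrichment ratio.
#' @export
div_control_enrichment <- function(peak_counts, genome_counts) {
  pk <- unlist(peak_counts)[c("D", "C")]
  gn <- unlist(genome_counts)[c("D", "C")]
  if (any(is.na(pk)) || any(is.na(gn)))
    stop("counts must provide elements 'D' and 'C'")
  if (any(c(pk, gn) <= 0))
    stop("all counts must be > 0; for zero categories add a pseudocount ",
         "to the counts before calling (e.g. + 0.5)")
  (pk[["D"]] / pk[["C"]]) / (gn[["D"]] / gn[["C"]])
}
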