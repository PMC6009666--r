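DYNAMICS_LEVELS <- c("PO", "CO", "OC", "CC")

#' Resolve an open/closed accessibility threshold
#'
#' Accepts either an absolute normalized count or a quantile specification
#' of the form `"q85"` (the 85th percentile of the pooled per-interval
#' counts across both conditions, the default used throughout).
#'
#' @param records Data frame with `count_ctrl` and `count_trt` columns.
#' @param spec Numeric threshold or `"qNN"` string.
#' @return Absolute threshold (normalized counts).
#' @export
resolve_open_threshold <- function(records, spec = "q85") {
  if (is.numeric(spec)) {
    if (spec <= 0) stop("`open_threshold` must be > 0")
    return(spec)
  }
  if (!grepl("^q[0-9]{1,2}(\\.[0-9]+)?$", spec))
    stop("threshold spec must be numeric or 'qNN' (e.g. 'q85')")
  q <- as.numeric(substring(spec, 2L)) / 100
  pooled <- c(records$count_ctrl, records$count_trt)
  thr <- unname(stats::quantile(pooled, q))
  if (thr <= 0) stop("quantile threshold resolved to ", thr, "; supply an absolute value")
  thr
}

#' Classify two-condition accessibility dynamics
#'
#' An interval is "open" in a condition when its normalized count is at
#' least the threshold (inclusive boundary). Classes across
#' control -> treatment: `PO` open/open (permanently open), `CO`
#' closed/open (gains accessibility), `OC` open/closed (loses
#' accessibility), `CC` closed/closed. `CC` completes the partition and is
#' excluded from three-class summaries via `drop_cc`.
#'
#' @param records Data frame with `count_ctrl` and `count_trt` (normalized
#'   counts, >= 0).
#' @param open_threshold Absolute threshold or `"qNN"` quantile spec (see
#'   [resolve_open_threshold()]).
#' @param drop_cc Return `NA` for closed/closed intervals instead of `CC`.
#' @return Factor of classes (levels PO, CO, OC, CC), one per record, with
#'   the resolved threshold attached as attribute `open_threshold`.
#' @export
classify_dynamics <- function(records, open_threshold = "q85", drop_cc = FALSE) {
  if (any(records$count_ctrl < 0) || any(records$count_trt < 0))
    stop("counts must be >= 0")
  thr <- resolve_open_threshold(records, open_threshold)
  open_ctrl <- records$count_ctrl >= thr
  open_trt <- records$count_trt >= thr
  cls <- ifelse(open_ctrl & open_trt, "PO",
         ifelse(!open_ctrl & open_trt, "CO",
         ifelse(open_ctrl & !open_trt, "OC", "CC")))
  if (drop_cc) cls[cls == "CC"] <- NA
  structure(factor(cls, levels = DYNAMICS_LEVELS), open_threshold = thr)
}

#' Treatment / control accessibility ratio
#'
#' `(count_trt + pseudocount) / (count_ctrl + pseudocount)`; the pseudocount
#' regularizes intervals with zero reads in one condition.
#'
#' @param records Data frame with `count_ctrl` and `count_trt`.
#' @param pseudocount Positive pseudocount in normalized-count units
#'   (default 1).
#' @return Numeric vector of ratios.
#' @export
accessibility_ratio <- function(records, pseudocount = 1) {
  if (pseudocount <= 0) stop("`pseudocount` must be > 0")
  (records$count_trt + pseudocount) / (records$count_ctrl + pseudocount)
}

#' Test association between a binding category and a dynamics class
#'
#' Builds the 2x2 table of peaks in the two focus categories (default DIV
#' `D` versus control dimer `C`) against membership in the focus dynamics
#' class (default closed-to-open `CO` versus any other class) and returns
#' the two-sided Fisher's exact test.
#'
#' @param labels Category factor (see [assign_categories()]).
#' @param classes Dynamics factor (see [classify_dynamics()]), parallel to
#'   `labels`.
#' @param focus Character pair of categories to compare.
#' @param focus_class The dynamics class of interest.
#' @return List with `table` (2x2 counts), `p_value` (two-sided Fisher) and
#'   `odds_ratio` (conditional MLE).
#' @export
category_class_association <- function(labels, classes,
                                       focus = c("D", "C"),
                                       focus_class = "CO") {
  stopifnot(length(labels) == length(classes), length(focus) == 2L)
  keep <- labels %in% focus & !is.na(classes)
  lab <- factor(as.character(labels[keep]), levels = focus)
  if (any(table(lab) == 0L))
    stop("degenerate table: category '",
         focus[which(table(lab) == 0L)[1]], "' is empty")
  in_class <- factor(ifelse(classes[keep] == focus_class, focus_class, "other"),
                     levels = c(focus_class, "other"))
  tab <- table(category = lab, class = in_class)
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab, p_value = ft$p.value,
       odds_ratio = unname(ft$estimate))
}

#' Fractional dynamics-class composition per binding stratum
#'
#' For each stratum (binding categories plus, typically, an `Unbound`
#' stratum), the fractions of intervals in the three paper-style classes
#' PO, CO, OC. Closed/closed (`CC`) intervals are excluded; strata with no
#' interval in any of the three classes are flagged and dropped.
#'
#' @param strata Factor or character vector of stratum labels.
#' @param classes Dynamics factor parallel to `strata`.
#' @return Data frame with `stratum`, `n` and fraction columns `PO`, `CO`,
#'   `OC` summing to 1 per row.
#' @export
fractional_class_composition <- function(strata, classes) {
  stopifnot(length(strata) == length(classes))
  keep_classes <- c("PO", "CO", "OC")
  out <- do.call(rbind, lapply(unique(as.character(strata)), function(s) {
    cls <- classes[strata == s]
    cls <- cls[!is.na(cls) & cls %in% keep_classes]
    if (length(cls) == 0L) {
      warning("stratum '", s, "' has no PO/CO/OC interval; dropped")
      return(NULL)
    }
    tab <- table(factor(as.character(cls), levels = keep_classes))
    data.frame(stratum = s, n = length(cls),
               PO = unname(tab["PO"]) / length(cls),
               CO = unname(tab["CO"]) / length(cls),
               OC = unname(tab["OC"]) / length(cls))
  }))
  rownames(out) <- NULL
  out
}
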