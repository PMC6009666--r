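#' Parameters of the two-site cooperative binding equilibrium
#'
#' A DNA probe carrying two identical half-sites binds up to two protein
#' monomers. `k_half` is the dissociation constant of one monomer for one
#' half-site (nM); `omega` is the dimensionless cooperativity factor, the
#' ratio K_d_monomer / K_d_dimer. `omega > 1` means the second molecule binds
#' more tightly to the pre-formed monomer complex (positive cooperativity),
#' `omega = 1` independent binding, `omega < 1` competition.
#'
#' @param k_half Half-site dissociation constant in nM, > 0.
#' @param omega Cooperativity factor, dimensionless, > 0.
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(k_half, omega) {
  stopifnot(is.numeric(k_half), length(k_half) == 1L,
            is.numeric(omega), length(omega) == 1L)
  if (!is.finite(k_half) || k_half <= 0)
    stop("`k_half` must be a finite positive dissociation constant (nM)")
  if (!is.finite(omega) || omega <= 0)
    stop("`omega` must be a finite positive cooperativity factor")
  structure(list(k_half = k_half, omega = omega), class = "binding_params")
}

#' @export
print.binding_params <- function(x, ...) {
  cat(sprintf("binding_params: k_half = %g nM, omega = %g (K_d_dimer = %g nM)\n",
              x$k_half, x$omega, x$k_half / x$omega))
  invisible(x)
}

#' Fractions of free, monomer-bound and dimer-bound DNA
#'
#' The three species resolved as distinct EMSA bands: free probe (F),
#' probe bound by one monomer (M) and probe bound by two monomers (D).
#'
#' @param f_free,f_mono,f_dim Fractions in \[0, 1\] summing to 1.
#' @return Named numeric vector of class `species_fractions`.
#' @export
species_fractions <- function(f_free, f_mono, f_dim) {
  f <- c(f_free = f_free, f_mono = f_mono, f_dim = f_dim)
  if (any(!is.finite(f)) || any(f < -1e-9) || any(f > 1 + 1e-9))
    stop("species fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-9)
    stop("species fractions must sum to 1 (got ", format(sum(f)), ")")
  structure(pmin(pmax(f, 0), 1), class = c("species_fractions", "numeric"))
}

## Statistical weights of the three DNA species at free-protein
## concentration p: 1 : 2 x : omega x^2 with x = p / k_half (the factor 2
## counts the two equivalent singly-bound configurations). For a one-site
## probe the weights are 1 : x and no dimer species exists.
.species_given_free <- function(p_free, k_half, omega, sites = 2L) {
  x <- p_free / k_half
  if (sites == 1L) {
    w <- c(1, x, 0)
  } else {
    w <- c(1, 2 * x, omega * x^2)
  }
  w / sum(w)
}

#' Solve the binding equilibrium under ligand depletion
#'
#' Computes the equilibrium species fractions of a two-site (or one-site)
#' probe given total protein and total DNA concentration, solving the full
#' mass balance `p_total = p + d_total * (f_mono + 2 f_dim)` for the free
#' protein concentration `p`. The balance is strictly monotone in `p`, so the
#' root is bracketed on `[0, p_total]` and found by bisection-safeguarded
#' root finding. Depletion is material in the gel regime used for
#' cooperativity measurements (100 nM probe, hundreds of nM protein), so no
#' free-ligand approximation is made.
#'
#' @param params A [binding_params()] object.
#' @param p_total Total protein concentration, nM, >= 0.
#' @param d_total Total DNA probe concentration, nM, > 0.
#' @param sites Number of protein binding sites on the probe (2 for
#'   composite dimer probes, 1 for monomer probes).
#' @return A [species_fractions()] vector. The free protein concentration is
#'   attached as attribute `p_free`.
#' @export
solve_equilibrium <- function(params, p_total, d_total, sites = 2L) {
  if (!inherits(params, "binding_params")) params <- do.call(binding_params, as.list(params))
  stopifnot(length(p_total) == 1L, length(d_total) == 1L)
  if (!is.finite(p_total) || p_total < 0) stop("`p_total` must be >= 0 nM")
  if (!is.finite(d_total) || d_total <= 0) stop("`d_total` must be > 0 nM")
  sites <- match.arg(as.character(sites), c("2", "1"))
  sites <- as.integer(sites)

  if (p_total == 0) {
    out <- species_fractions(1, 0, 0)
    attr(out, "p_free") <- 0
    return(out)
  }

  bound_per_dna <- function(p) {
    f <- .species_given_free(p, params$k_half, params$omega, sites)
    f[2] + 2 * f[3]
  }
  balance <- function(p) p + d_total * bound_per_dna(p) - p_total

  ## balance(0) = -p_total < 0, balance(p_total) >= 0: root always bracketed
  root <- stats::uniroot(balance, c(0, p_total),
                         tol = .Machine$double.eps^0.75, maxiter = 2000L)
  p_free <- root$root
  f <- .species_given_free(p_free, params$k_half, params$omega, sites)

  resid <- abs(p_free + d_total * (f[2] + 2 * f[3]) - p_total)
  if (resid > 1e-8 * max(p_total, 1))
    stop("mass-balance residual ", format(resid), " exceeds tolerance")

  out <- species_fractions(f[1], f[2], f[3])
  attr(out, "p_free") <- p_free
  out
}

#' Estimate the cooperativity factor from band fractions
#'
#' Given the free, monomer and dimer band fractions quantified from a single
#' lane at equilibrium, returns the cooperativity factor estimate. With two
#' identical half-sites the species weights are `1 : 2x : omega x^2`, so
#' `omega = 4 f_dim f_free / f_mono^2`; the statistical factor 4 makes
#' independent binding score exactly `omega = 1`. Set
#' `statistical_factor = 1` to drop the factor (alternative convention used
#' by some protocols). The estimator is independent of protein and DNA
#' concentration for noiseless model fractions.
#'
#' @param fractions A [species_fractions()] vector (or any length-3 numeric
#'   `c(f_free, f_mono, f_dim)`).
#' @param statistical_factor 4 (default, identical half-sites) or 1.
#' @return The cooperativity factor estimate (dimensionless).
#' @export
estimate_omega <- function(fractions, statistical_factor = 4) {
  f <- as.numeric(fractions)
  stopifnot(length(f) == 3L)
  if (!statistical_factor %in% c(4, 1))
    stop("`statistical_factor` must be 4 or 1")
  if (f[2] <= 0) {
    if (f[3] >= f[1])
      stop("omega estimator undefined: no monomer band (probe fully dimer-bound; titrate down)")
    stop("omega estimator undefined: no monomer band (probe essentially free; titrate up)")
  }
  statistical_factor * f[3] * f[1] / f[2]^2
}

#' Per-lane cooperativity estimates averaged over usable lanes
#'
#' Applies [estimate_omega()] to every lane of a titration series in which
#' all three band fractions are at least `min_fraction` (mirroring
#' quantification of gels where all three bands are visible) and returns the
#' mean over usable lanes.
#'
#' @param series A titration data frame as produced by [simulate_titration()]
#'   or read by [read_titrations()].
#' @param statistical_factor Passed to [estimate_omega()].
#' @param min_fraction Minimum band fraction for a lane to be usable.
#' @return Mean omega estimate over usable lanes.
#' @export
estimate_omega_series <- function(series, statistical_factor = 4, min_fraction = 0.02) {
  f <- as.matrix(series[, c("f_free", "f_mono", "f_dim")])
  usable <- rowSums(f >= min_fraction) == 3L
  if (!any(usable))
    stop("no lane has all three band fractions >= ", min_fraction)
  est <- apply(f[usable, , drop = FALSE], 1L,
               estimate_omega, statistical_factor = statistical_factor)
  mean(est)
}

#' Simulate a noisy EMSA titration series
#'
#' Forward-simulates band fractions for a protein dilution series from the
#' equilibrium model, perturbs each fraction with additive Gaussian noise
#' (emulating densitometry error), clips to \[0, 1\] and renormalizes the
#' lane to sum 1.
#'
#' @param params A [binding_params()] object.
#' @param p_series Vector of total protein concentrations, nM.
#' @param d_total Probe concentration, nM (shared by all lanes).
#' @param noise_sd Standard deviation of the additive fraction noise (0 for
#'   exact model fractions).
#' @param seed Optional integer seed for reproducibility.
#' @param sites 2 (dimer probe) or 1 (monomer probe).
#' @param probe_id,replicate_id Identifiers stored in the output.
#' @return A data frame with columns `probe_id`, `replicate`, `p_total_nM`,
#'   `d_total_nM`, `f_free`, `f_mono`, `f_dim`.
#' @export
simulate_titration <- function(params, p_series, d_total, noise_sd = 0,
                               seed = NULL, sites = 2L,
                               probe_id = "probe", replicate_id = 1L) {
  if (length(p_series) < 1L) stop("`p_series` must be non-empty")
  if (any(!is.finite(p_series)) || any(p_series < 0))
    stop("protein concentrations must be non-negative")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  f <- t(vapply(p_series, function(p)
    as.numeric(solve_equilibrium(params, p, d_total, sites = sites)),
    numeric(3)))
  if (noise_sd > 0) {
    f <- f + matrix(stats::rnorm(length(f), 0, noise_sd), nrow = nrow(f))
    f <- pmin(pmax(f, 0), 1)
    f <- f / rowSums(f)
  }
  data.frame(probe_id = probe_id, replicate = as.integer(replicate_id),
             p_total_nM = p_series, d_total_nM = d_total,
             f_free = f[, 1], f_mono = f[, 2], f_dim = f[, 3],
             stringsAsFactors = FALSE)
}

#' Quadratic ligand-depletion binding isotherm
#'
#' Bound DNA fraction of a single-site probe at total protein `P`, total DNA
#' `D` and dissociation constant `K`, with the DNA treated as a fixed, known
#' parameter: `((P + D + K) - sqrt((P + D + K)^2 - 4 P D)) / (2 D)`.
#'
#' @param P Total protein concentration(s), nM.
#' @param D Total DNA concentration, nM.
#' @param K Dissociation constant, nM.
#' @return Bound fraction(s) in \[0, 1\].
#' @export
depletion_isotherm <- function(P, D, K) {
  s <- P + D + K
  (s - sqrt(pmax(s^2 - 4 * P * D, 0))) / (2 * D)
}

#' Fit a dissociation constant by non-linear least squares
#'
#' Fits the quadratic ligand-depletion isotherm to a titration series by
#' Levenberg-Marquardt least squares, with the probe concentration fixed at
#' its known value. The bound fraction is either the monomer band alone
#' (monomer probes) or the monomer plus dimer bands regarded as one overall
#' bound fraction (the apparent-affinity fit for dimer probes).
#'
#' @param series Titration data frame (see [simulate_titration()]).
#' @param bound_definition `"monomer-band"` or `"monomer-plus-dimer"`.
#' @return A list with `estimate` (K_d in nM), `residuals`, and the
#'   underlying `nls` fit.
#' @export
fit_kd_single_site <- function(series,
                               bound_definition = c("monomer-band", "monomer-plus-dimer")) {
  bound_definition <- match.arg(bound_definition)
  if (nrow(series) < 4L)
    stop("need at least 4 titration points spanning the transition")
  d_total <- unique(series$d_total_nM)
  if (length(d_total) != 1L)
    stop("all points of one series must share d_total")
  bound <- if (bound_definition == "monomer-band") series$f_mono
           else series$f_mono + series$f_dim
  P <- series$p_total_nM

  if (max(bound) < 0.05 || min(bound) > 0.95 || diff(range(bound)) < 0.2)
    stop("series is non-identifiable: bound fraction does not span the transition (range ",
         format(min(bound), digits = 3), "-", format(max(bound), digits = 3), ")")

  ## initial K: protein concentration at half-maximal bound fraction
  half <- max(bound) / 2
  above <- which(bound >= half)
  k0 <- max(P[above][which.min(P[above])], d_total / 2, 1e-3)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      bound ~ depletion_isotherm(P, d_total, K),
      start = list(K = k0), lower = 1e-9,
      control = minpack.lm::nls.lm.control(ftol = 1e-10, maxiter = 200L)),
    error = function(e)
      stop("isotherm fit failed to converge: ", conditionMessage(e),
           "; residual range at start value ",
           paste(format(range(bound - depletion_isotherm(P, d_total, k0)), digits = 3),
                 collapse = " to ")))
  list(estimate = unname(stats::coef(fit)[["K"]]),
       residuals = stats::resid(fit),
       bound_definition = bound_definition,
       fit = fit)
}

#' Dissociation constant of the second binding event
#'
#' `K_d_dimer = K_d_monomer / omega`: the dissociation constant for the
#' binding of a second molecule to a pre-formed protein/DNA complex. A
#' cooperativity factor below 1 increases the dimer dissociation constant
#' (negative cooperativity).
#'
#' @param k_d_monomer Monomer dissociation constant, nM, > 0.
#' @param omega Cooperativity factor, > 0.
#' @return K_d_dimer in nM.
#' @export
derive_kd_dimer <- function(k_d_monomer, omega) {
  if (any(k_d_monomer <= 0) || any(omega <= 0))
    stop("`k_d_monomer` and `omega` must be positive")
  k_d_monomer / omega
}

#' Mean and standard deviation over replicate measurements
#'
#' @param values Numeric vector of replicate estimates (n >= 1).
#' @param convention Optional tag recording the omega statistical-factor
#'   convention the values were computed under.
#' @return A list of class `fit_result` with `estimate` (mean), `sd`
#'   (sample SD, n - 1 denominator; 0 when n = 1) and `n`.
#' @export
summarize_replicates <- function(values, convention = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("`values` must contain at least one finite replicate")
  structure(list(estimate = mean(values),
                 sd = if (length(values) > 1L) stats::sd(values) else 0,
                 n = length(values),
                 convention = convention),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%g +/- %g (n = %d)\n", x$estimate, x$sd, x$n))
  invisible(x)
}

#' Reporter expression score
#'
#' Total reporter expression scored from flow cytometry as the median signal
#' of all cells multiplied by the fraction of positive cells.
#'
#' @param median_signal Median reporter signal, arbitrary units.
#' @param fraction_positive Fraction of reporter-positive cells in \[0, 1\].
#' @return The expression score (arbitrary units).
#' @export
reporter_score <- function(median_signal, fraction_positive) {
  if (any(fraction_positive < 0) || any(fraction_positive > 1))
    stop("`fraction_positive` must lie in [0, 1]")
  median_signal * fraction_positive
}

#' Fraction of a protein covered by a residue span
#'
#' Percentage of the full-length protein covered by an inclusive residue
#' range (e.g. the purified DNA-binding domain construct).
#'
#' @param start_res,end_res First and last residue of the span (inclusive).
#' @param total_length Length of the full-length protein in residues.
#' @return Percentage of the protein covered.
#' @export
residue_span_fraction <- function(start_res, end_res, total_length) {
  stopifnot(start_res >= 1, end_res >= start_res, total_length >= end_res)
  100 * (end_res - start_res + 1) / total_length
}

#' Read / write titration tables
#'
#' TSV with columns `probe_id`, `replicate`, `p_total_nM`, `d_total_nM`,
#' `f_free`, `f_mono`, `f_dim`.
#'
#' @param path File path.
#' @return `read_titrations`: a data frame of titration points.
#' @export
read_titrations <- function(path) {
  need <- c("probe_id", "replicate", "p_total_nM", "d_total_nM",
            "f_free", "f_mono", "f_dim")
  x <- data.table::fread(path, sep = "\t", data.table = FALSE)
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("titration table lacks columns: ", paste(missing_cols, collapse = ", "))
  x[, need]
}

#' @param series Titration data frame.
#' @rdname read_titrations
#' @export
write_titrations <- function(series, path) {
  data.table::fwrite(series, path, sep = "\t")
  invisible(path)
}
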