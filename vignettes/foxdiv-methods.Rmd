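---
title: "Quantifying cooperative forkhead homodimerization on the compact DIV element"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cooperative forkhead homodimerization on the compact DIV element}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foxdiv)
```

## The binding model

FOXA1 can occupy a compact palindromic DNA element — called DIV for its
diverging half-sites — as a homodimer. The two 5-bp AT-rich half-site cores
overlap so that a central TA dinucleotide is shared, giving the 8-bp
consensus AAATATTT. `foxdiv` models a probe carrying two identical
half-sites as a three-state equilibrium. At free protein concentration $p$,
the relative statistical weights of free, singly bound and doubly bound
probe are

$$1 \;:\; 2\,\frac{p}{K} \;:\; \omega\left(\frac{p}{K}\right)^2,$$

where $K$ (`k_half`, nM) is the dissociation constant of one monomer for
one half-site and $\omega$ is the cooperativity factor, the ratio
$K_\mathrm{d,monomer}/K_\mathrm{d,dimer}$. $\omega > 1$ means the second
molecule binds more tightly to the pre-formed monomer complex; $\omega = 1$
is independent binding; $\omega < 1$ is competition. The factor 2 counts
the two equivalent singly-bound configurations, which co-migrate as one
monomer band on a gel.

`solve_equilibrium()` computes the species fractions under the full mass
balance $p_\mathrm{total} = p + d_\mathrm{total}(f_\mathrm{mono} +
2f_\mathrm{dim})$, found by bracketed root solving — no free-ligand
approximation. This matters: cooperativity gels run at 100 nM probe with a
few hundred nM protein, where depletion is material (at the DIV preset
operating point roughly a quarter of the protein is DNA-bound).

### Estimating the cooperativity factor

Inverting the weights gives the single-lane estimator used on quantified
band fractions:

$$\hat\omega = 4\,\frac{f_\mathrm{dim}\, f_\mathrm{free}}{f_\mathrm{mono}^2}.$$

The statistical factor 4 makes independent binding score exactly
$\hat\omega = 1$; `estimate_omega(..., statistical_factor = 1)` drops it
for comparison with conventions that fold the factor into $K$. The
estimator is exactly invariant to protein and DNA concentration on
noiseless model fractions (a property the test suite checks over random
parameter draws), so the choice of lane only affects noise robustness.
`estimate_omega_series()` averages per-lane estimates over lanes in which
all three bands are at least 2% of the probe, mirroring quantification of
gels where all three bands are visible.

### Dissociation constants

For 1 nM-probe titrations, `fit_kd_single_site()` fits the quadratic
ligand-depletion isotherm

$$f_\mathrm{bound}(P) = \frac{(P + D + K) - \sqrt{(P + D + K)^2 - 4 P D}}{2 D}$$

by Levenberg–Marquardt least squares with the probe concentration $D$
fixed at its known value, the initial $K$ taken at the half-maximal lane
and an objective tolerance of 1e-10. The bound fraction is either the
monomer band alone (monomer probes) or monomer plus dimer regarded as one
overall bound fraction — the apparent-affinity convention for dimer
probes. The quadratic depletion form is used rather than a hyperbolic
approximation: "DNA as a fixed parameter" is read as *fixed known
constant*, which is the safer reading at 1 nM probe and low-nM affinities
where depletion near the transition is not negligible.

## Titration presets and their operating points

`titration_presets()` encodes the study conditions: ground-truth
$\omega$ of 56.3 (DIV probe) and 1.8 (CON probe); dissociation constants
2.4 nM (monomer probe) and 4.5 nM (apparent affinity); and a single-lane
cooperativity measurement at 100 nM probe with 400 nM (DIV) or 320 nM
(CON) protein. Dissociation-constant presets use the 14-lane two-fold
dilution grid from 2500 nM down to 0.61 nM plus a no-protein lane, at 1 nM
probe.

Two preset choices deserve explanation:

* **Half-site affinity of the single-lane presets.** Because
  $\hat\omega$ is invariant to `k_half`, the preset affinity only sets
  which bands are populated at the stated lane. It is chosen (2250 nM for
  the DIV preset, 300 nM for CON) so that free, monomer and dimer bands
  are all well populated, as they must be on any gel from which all three
  fractions are quantified. At $\omega = 56.3$ the monomer band can never
  exceed $1/(\sqrt{\omega} + 1) \approx 11.8\%$ of the
  probe at any operating point, which bounds the precision of the
  single-lane estimator from below: with the default 2% band-fraction
  noise the per-lane coefficient of variation is about 30%, so the
  5-replicate mean carries roughly 14% standard error and a small upward
  convexity bias. This scatter is inherent to the protocol, and is of the
  same order as the published spread (±11.9 on 56.3).
* **The rs2941742 allele pair.** Only the 20-fold cooperativity reduction
  of the minor allele is published. The preset realizes it as major
  $\omega = 20$, minor $\omega = 1$: the minor allele abolishes
  cooperativity down to the independent-binding baseline while the
  half-site affinity is unchanged, matching the observation that
  monomeric binding is unaffected. The minor allele is measured at a
  higher lane concentration (1440 nM) so that its dimer band is populated
  despite the lost cooperativity.

`simulate_titration()` perturbs model fractions with additive Gaussian
noise (default sd 0.02 fraction units, a plausible densitometry error;
none is published), clips to [0, 1] and renormalizes each lane to sum 1.

## Composite motifs and scanning

`build_composite()` merges two monomer half-site PWMs at a signed spacer.
DIV places the reverse-complemented half 5′ of the forward half (cores
diverging); CON is the converse. Negative spacers overlap the halves and
merge overlapping columns by the position-wise normalized product of
probabilities with pseudocount 1e-4 — equivalent to summing the two
log-odds contributions. Anchors follow the experimental element series:
`div_motif(half, n)` inserts `n` bp between the *overlapped* half-sites,
so D0 is the compact element (spacer −2, shared TA), D2 has abutting
half-sites and Dn is DIV at spacer `n − 2`; C0 is CON at spacer 0 and
C±1 shift by one. The shipped default half-sites are consensus-built
(consensus base probability 0.7): the 5-bp TATTT core used for composite
construction, the 10-bp AAAGTAAACA monomer consensus, and the degenerate
11-bp AWTRTTKRYTY monomer site. The displacement arithmetic of the
original matrix pair cannot be verified without those matrices, so the
anchor convention above is the package's documented stand-in, and user
PWMs are accepted everywhere (JASPAR-style text, a TSV matrix dialect and
YAML composite definitions are supported by `read_jaspar_pwm()`,
`read_pwm_tsv()` and `composite_from_yaml()`).

Scoring is log2 odds against a base-frequency background; an N scores 0
bits (background-neutral) rather than −Inf, so assembly gaps do not veto
windows. `scan_sequence()` reports both strands in forward 0-based
half-open coordinates; `calibrate_threshold()` returns the largest
threshold at which the requested fraction (default 80%) of positive
sequences contains a hit, taking candidates from the finite set of
per-sequence maxima so the achieved sensitivity is exact. In the synthetic
workflow the calibration positives are the dimer-bound peak set; because
synthetic plants are exact consensus, the calibrated threshold lands at
the consensus score with sensitivity 1 — degenerate plants would lower it.

## Peak categorization and signal statistics

`assign_categories()` labels peaks `D`, `C`, `M` or `N` ("no motif") by
windowed intersection (default 100 bp, gap boundary inclusive) with
precedence D > C > M > N — a peak near both a DIV and a control hit is a
DIV peak, and `M` means *exclusively* monomer. Control hits overlapping a
correctly spaced DIV locus are excluded first
(`exclude_div_overlapping_controls()`). Categorization uses full peak
intervals; summit-anchored intersection was considered and not
implemented, as the synthetic peaks are summit-centered by construction
and the windowed full-interval rule subsumes it at these peak widths.
Signal comparisons use the unpaired two-sided Wilcoxon rank-sum test on
narrowPeak signalValue with Holm adjustment across all pairwise
comparisons; deciles are formed by descending-signal stable sort (ties on
name) with remainder peaks assigned to the top bins.

## Accessibility dynamics

`classify_dynamics()` calls an interval open in a condition when its
normalized count reaches the threshold, giving the classes PO (open →
open), CO (closed → open), OC (open → closed) and CC (closed → closed; CC
completes the partition and is excluded from three-class summaries). No
absolute threshold is published; the default is the 85th percentile of
the pooled per-interval counts (`"q85"`), which under the default count
model reproduces the observation that most loci are closed in at least
one condition, and an absolute override is accepted. Thresholding is an
approximation of whatever differential-accessibility caller produced the
original classes; with well-separated open/closed count distributions the
two agree almost everywhere, which is what the class-recovery test
checks. Category–class association is Fisher's exact test on the 2×2
table of {D, C} × {CO, not CO}; accessibility ratios are
`(trt + 1)/(ctrl + 1)` by default.

## The SNP screen

`filter_central_ta()` keeps variants whose 1-based position falls on match
positions 4–5 of an 8-bp dimer hit — the TA shared by the juxtaposed
half-sites. The central frame is symmetric under strand reflection, so hit
strand is irrelevant. `allelic_score_delta()` substitutes each allele,
rescans ±7 bp around the variant on both strands, takes the best window
per allele and reports the score difference; `perturbs_dimer` flags
variants whose major allele supports a match at the scan threshold while
the minor allele does not. LD expansion and eQTL annotations are consumed
as input tables (`screen_report()` joins them without dropping unmatched
rows); they are never computed.

## What the synthetic generator does and does not emulate

`make_genome()` plants exact-consensus motif instances on random strands
in an i.i.d. background (default 2 Mb at 41% GC — large enough for stable
category counts, small enough for seconds-scale scans), with a
GC-alternating inserted spacer in the control plants so that no spacer
content can recreate the all-A/T compact element. `make_peaks()` draws
lognormal signalValues whose meanlog depends on the planted category
(D strongest). `make_atac()` draws negative-binomial counts per condition
from a planted dynamics class, with the CO probability of D loci boosted
by `co_enrichment` (default +0.35 over a 0.10 base rate). `make_snps()`
builds the screening funnel: 15 variants that destroy the central TA of
intact plants, 8 on weakened plants that neither allele rescues, plus
flank and off-motif decoys. All generators are byte-deterministic under a
fixed seed and write truth tables sufficient to score recall.

These choices reproduce the *statistical shape* of the study data — not
real genomes. Background is i.i.d. (no repeats, no CpG structure, no
chromatin), plants are exact consensus (real sites are degenerate, so
real calibrated thresholds sit below the consensus score), peak signal is
lognormal by fiat, and count noise is negative-binomial with a single
dispersion. Passing tests therefore demonstrate that the estimators and
classifiers recover what was planted under the assumed noise — they do
not validate the biological claims on real data.

## Numerical choices and degenerate inputs

* Equilibrium root solving brackets [0, p_total]; the balance is strictly
  monotone, so failure to bracket cannot occur for valid inputs. The
  conservation residual is checked at 1e-8 relative.
* `estimate_omega` refuses lanes with no monomer band, distinguishing
  all-dimer from all-free input in the error message.
* Isotherm fits refuse series whose bound fraction does not span the
  transition (non-identifiable) and report residual ranges on
  non-convergence.
* Coordinates are 0-based half-open everywhere inside the package;
  1-based positions appear only at the SNP/VCF boundary with explicit
  converters. Windowed intersection is inclusive at the gap boundary.
* Ties: decile ranking is stabilized on peak name; threshold calibration
  scans the finite candidate set of per-sequence maxima; consensus
  strings resolve ties in A,C,G,T order.
* Problem sizes in the shipped tests and workflow (2 Mb genome, 600
  peaks, 150 sites per category, 200-replicate recovery simulations) were
  chosen to give stable statistics at seconds-scale runtimes.

## Known limitations

Single-chromosome synthetic genomes; order-0 background for scanning; no
methylation-aware scoring; two binding sites per probe at most; SNVs only
in the screen; thresholding (not a count model) for dynamics classes; the
single-lane cooperativity protocol carries irreducible ~14% standard
error on 5-replicate means at high omega, as derived above.
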