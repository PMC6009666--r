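# foxdiv

Quantitative analysis of DNA-mediated FOXA1 homodimerization on the
compact palindromic **DIV** element, and of its genomic footprint.

The forkhead pioneer factor FOXA1 was long thought to bind chromatin as a
monomer or as a heterodimer with nuclear receptors. On the DIV element —
two forkhead half-site cores in diverging orientation whose overlap shares
a central TA dinucleotide (consensus `AAATATTT`) — it instead forms a
highly cooperative homodimer. This package implements the computational
side of that analysis for anyone who wants to quantify cooperative
dimerization from gel-shift data or trace a composite element through
genomic datasets:

* **Equilibrium binding model.** A two-site probe at free protein
  concentration *p* populates free / monomer / dimer states with weights
  `1 : 2p/K : ω(p/K)²`, solved under full ligand depletion
  (`solve_equilibrium`). The cooperativity factor
  ω = K<sub>d,monomer</sub>/K<sub>d,dimer</sub> is estimated from
  quantified band fractions as `ω̂ = 4·f_dim·f_free/f_mono²`
  (`estimate_omega`), and dissociation constants are fitted with the
  quadratic ligand-depletion isotherm by Levenberg–Marquardt least squares
  (`fit_kd_single_site`).
* **Composite motifs.** Construction of DIV/CON dimer PWMs from monomer
  half-sites at signed spacers, including the D1–D10 spacer-control
  series; log-odds genome scanning with sensitivity-calibrated thresholds
  (`build_composite`, `div_motif`, `scan_genome`, `calibrate_threshold`).
* **Peak categorization.** ChIP-seq peaks labeled D / C / M / N by
  windowed motif intersection with precedence, Wilcoxon + Holm signal
  comparisons, signal-decile composition and genome-relative DIV/control
  enrichment (`assign_categories`, `signal_by_category`,
  `decile_fractions`).
* **Accessibility dynamics.** Two-condition ATAC counts classified into
  PO / CO / OC (/CC) classes and tested for category–class association by
  Fisher's exact test (`classify_dynamics`,
  `category_class_association`).
* **SNP screen.** Variants intersected with the shared central TA of
  dimer-motif hits and rescored per allele (`filter_central_ta`,
  `allelic_score_delta`, `screen_report`).
* **Synthetic data.** Deterministic generators for every input the
  pipeline consumes — planted genomes, peaks, counts, SNP funnels and
  noisy titrations with named presets encoding the published operating
  points (`synth_config`, `make_genome`, `make_titrations`, ...).

## Worked example

Five replicate single-lane EMSAs at the DIV operating point (100 nM
probe, 400 nM protein), and a 14-lane dilution-grid affinity fit:

```r
library(foxdiv)

params <- binding_params(k_half = 2250, omega = 56.3)
f <- solve_equilibrium(params, p_total = 400, d_total = 100)
round(as.numeric(f), 3)
#> [1] 0.441 0.118 0.441            # free, monomer, dimer fractions
estimate_omega(f)
#> [1] 56.3                         # noiseless round trip

tt <- make_titrations("div", seed = 1)        # 5 replicates, 2% band noise
est <- sapply(split(tt, tt$replicate), estimate_omega_series)
round(est, 1)
#>    1    2    3    4    5
#> 48.6 44.6 63.3 48.2 41.1
summarize_replicates(est)
#> 49.1479 +/- 8.44703 (n = 5)      # published: 56.3 +/- 11.9

kd <- make_titrations("monomer", seed = 2)    # 2500 -> 0.61 nM grid, 1 nM probe
ks <- sapply(split(kd, kd$replicate), function(s)
  fit_kd_single_site(s, "monomer-band")$estimate)
summarize_replicates(ks)
#> 2.41523 +/- 0.039435 (n = 3)     # published: 2.4 +/- 1.06 nM
```

The replicate means sit inside the published uncertainty; the scatter of
the single-lane ω estimates is intrinsic to the protocol (at ω ≈ 56 the
monomer band never exceeds ~12% of the probe, see the methods vignette).

## The analysis workflow

The numbered scripts under `analysis/` run the full study on synthetic
data, writing generated inputs to `scratch/synthetic/` and result tables
to `results/`:

```sh
Rscript analysis/01_simulate_data.R      # genome + peaks + SNPs + titrations
Rscript analysis/02_emsa_cooperativity.R # omega and K_d fits vs published values
Rscript analysis/03_motif_scan.R         # composite motifs, calibrated genome scan
Rscript analysis/04_peak_categories.R    # D/C/M/N labels, signal stats, deciles
Rscript analysis/05_atac_dynamics.R      # PO/CO/OC classes, Fisher association
Rscript analysis/06_snp_screen.R         # central-TA funnel, allelic deltas
```

On the default study seed this recovers the planted structure: 96% peak
category agreement with truth, a strong DIV-versus-control association
with the closed-to-open class (odds ratio 4.2, Fisher p = 6.9e-07), and a
23-candidate SNP funnel of which exactly the 15 planted dimer-destroying
variants are flagged.

## Documentation

The methods vignette (`vignettes/foxdiv-methods.Rmd`) documents the model
and its assumptions, the preset operating points, the composite-motif
anchor conventions, numerical choices, what the synthetic generator does
and does not emulate, and known limitations.
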