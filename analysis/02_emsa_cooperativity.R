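#!/usr/bin/env Rscript
# Stage 2: quantify cooperativity and affinity from the simulated EMSAs.
#
# Re-estimates, from the titration tables written by stage 1: the
# cooperativity factor omega on the DIV and CON probes (factor-4
# convention), the monomer and apparent dissociation constants by
# quadratic ligand-depletion isotherm fitting, the derived K_d_dimer, and
# the rs2941742 allelic fold change. Writes results/02_emsa_fits.tsv.

suppressPackageStartupMessages(library(foxdiv))

data_dir <- "scratch/synthetic"
log_stage("fit-emsa", run_config(),
          inputs = c(div = file.path(data_dir, "titration_div.tsv")))

omega_fit <- function(preset) {
  tt <- read_titrations(file.path(data_dir, paste0("titration_", preset, ".tsv")))
  est <- vapply(split(tt, tt$replicate), estimate_omega_series, numeric(1))
  summarize_replicates(est, convention = "statistical-factor-4")
}
kd_fit <- function(preset, bound) {
  tt <- read_titrations(file.path(data_dir, paste0("titration_", preset, ".tsv")))
  est <- vapply(split(tt, tt$replicate), function(s)
    fit_kd_single_site(s, bound)$estimate, numeric(1))
  summarize_replicates(est, convention = bound)
}

fits <- list(
  omega_div = omega_fit("div"),
  omega_con = omega_fit("con"),
  kd_monomer = kd_fit("monomer", "monomer-band"),
  kd_apparent = kd_fit("kd_apparent", "monomer-plus-dimer"),
  omega_rs2941742_major = omega_fit("rs2941742_major"),
  omega_rs2941742_minor = omega_fit("rs2941742_minor"))

tab <- data.frame(
  quantity = names(fits),
  estimate = vapply(fits, `[[`, numeric(1), "estimate"),
  sd = vapply(fits, `[[`, numeric(1), "sd"),
  n = vapply(fits, `[[`, integer(1), "n"),
  published = c(56.3, 1.8, 2.4, 4.5, NA, NA))
tab <- rbind(tab, data.frame(
  quantity = c("kd_dimer_div", "rs2941742_fold_change"),
  estimate = c(derive_kd_dimer(tab$estimate[tab$quantity == "kd_monomer"],
                               tab$estimate[tab$quantity == "omega_div"]),
               fits$omega_rs2941742_major$estimate /
                 fits$omega_rs2941742_minor$estimate),
  sd = NA, n = NA, published = c(NA, 20)))
data.table::fwrite(tab, "results/02_emsa_fits.tsv", sep = "\t")

message(paste(sprintf("%-22s %8.3f (published %s)", tab$quantity,
                      tab$estimate, format(tab$published)), collapse = "\n"))
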