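#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a 12-trait exposure manifest with
# three planted causal exposures against one shared binary-outcome GWAS,
# and an exposure/mediator/outcome triple with a planted mediation chain
# whose true mediated proportion is 7.125% (0.2 * 0.0285 / 0.08).
# Everything is written as the TSV dialect the readers consume, so the
# downstream scripts exercise the full file-based pipeline.

library(mrmediate)

seed <- 20240815
dir.create("results/sim_data", showWarnings = FALSE, recursive = TRUE)

man <- simulate_screen_manifest(12, causal = c(2, 5, 9), theta = 0.25,
                                seed = seed)
for (id in names(man$exposures))
  write_summary_stats(man$exposures[[id]],
                      file.path("results/sim_data", paste0(id, ".tsv")))
write_summary_stats(man$outcome, "results/sim_data/outcome.tsv")
write.table(man$truth, "results/sim_data/truth_exposures.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

tri <- simulate_mediation_triple(sim_config(
  m_snps = 100, seed = seed + 1,
  mediation = list(theta_xm = c(0.2, 0), theta_my = c(0.0285, 0),
                   theta_direct = 0.0743, m_mediator_snps = 60)))
write_summary_stats(tri$exposure, "results/sim_data/med_exposure.tsv")
write_summary_stats(tri$outcome, "results/sim_data/med_outcome.tsv")
for (id in names(tri$mediators))
  write_summary_stats(tri$mediators[[id]],
                      file.path("results/sim_data", paste0(id, ".tsv")))

# A lipid-like trait observed at the disease trait's own seven
# instrument variants (null reverse effect), so the reverse-direction
# screen in 03_screen.R has a target whose GWAS covers the disease
# instruments.
set.seed(seed + 2)
lipid_v <- table1_fixture()$variants
lipid_v$beta <- rnorm(7, 0, 0.02)
lipid_v$se <- 0.02
lipid_v$pval <- 2 * pnorm(-abs(lipid_v$beta / lipid_v$se))
lipid_v$n <- 7174
write_summary_stats(summary_stats(lipid_v, "lipid_trait"),
                    "results/sim_data/lipid_trait.tsv")

cat("Simulated screening manifest: 12 exposures (causal:",
    paste(man$truth$trait[man$truth$theta != 0], collapse = ", "),
    ")\n")
cat("Simulated mediation triple: true proportion mediated =",
    sprintf("%.3f%%", 100 * tri$truth$proportion[1]), "\n")
cat("wrote results/sim_data/\n")
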