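#!/usr/bin/env Rscript
# Stage 1: generate a synthetic FAERS-style universe with known ground
# truth. Three associations are injected at the odds strengths of the
# strongest pregnancy-related signals the pipeline is designed to surface
# (remdesivir-abortion 5.2, remdesivir-foetal death 6.3,
# tocilizumab-neonatal death 4.1); everything else is independent
# background reporting. Emits FAERS ASCII quarters plus a truth manifest.
#
# Run from the repository root: Rscript analysis/01_simulate.R

suppressPackageStartupMessages(library(faersror))

out_dir <- "results/sim_quarters"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

pairs <- data.frame(
  drug = c("REMDESIVIR", "REMDESIVIR", "TOCILIZUMAB"),
  pt = c("Abortion", "Foetal death", "Death neonatal"),
  lambda = c(5.2, 6.3, 4.1)
)
cfg <- sim_config(n_reports = 20000, injected_pairs = pairs, seed = 20260928)

sim <- simulate_faers(cfg, source_label = "2021Q1")
stopifnot(validate_bundle(sim$bundle)$clean)
write_quarter(sim$bundle, out_dir)
write_truth_manifest(sim$truth, file.path("results", "ground_truth.tsv"))

message(sprintf(
  "simulated %d cases (%d in window, %d re-filed at version 2); wrote %s",
  sim$truth$n_cases, sim$truth$n_in_window, sim$truth$n_duplicates, out_dir))
message("injected pairs and their expected contingency cells:")
print(sim$truth$pairs, row.names = FALSE)
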