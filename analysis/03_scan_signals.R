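#!/usr/bin/env Rscript
# Stage 3: disproportionality scan. For each study drug, every event term
# reported at least 3 times with the drug as primary suspect gets its 2x2
# table, ROR and Wald 95% CI; pairs with lower CI bound > 1 (or the c = 0
# sentinel) are flagged as potential safety signals and grouped by System
# Organ Class. Writes the full machine-readable dump (a, b, c, d included)
# and the rendered signal table per drug.
#
# Run from the repository root after 02_ingest.R.

suppressPackageStartupMessages(library(faersror))

bundle <- read_quarter("results/curated", source_label = "CURATED")
ds <- build_dataset(bundle, c("2020-01-01", "2022-12-31"))
map <- read_soc_map(system.file("extdata", "soc_map_synthetic.tsv",
                                package = "faersror"))

queries <- list(
  remdesivir = drug_query(c("REMDESIVIR", "VEKLURY"), label = "remdesivir"),
  tocilizumab = drug_query(c("TOCILIZUMAB", "ACTEMRA"), label = "tocilizumab")
)

for (q in queries) {
  res <- scan_signals(ds, q, min_frequency = 3, soc_map = map)
  res_soc <- aggregate_soc(res, map)
  full_path <- sprintf("results/pairs_full_%s.tsv", q$label)
  utils::write.table(res_soc, full_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  sig_path <- sprintf("results/signals_%s.tsv", q$label)
  utils::write.table(format_signal_table(res_soc), sig_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s: %d pairs at frequency >= 3 (%d with a >= 5), %d potential signals -> %s",
    q$label, nrow(res), sum(res$a_ge_5), sum(res$is_signal), sig_path))
  print(format_signal_table(res_soc), row.names = FALSE)
}
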