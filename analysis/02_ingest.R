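#!/usr/bin/env Rscript
# Stage 2: ingest the FAERS ASCII quarters, curate the case universe
# (version dedup, 2020-2022 event-date window), and cache it for the later
# stages. The provenance tallies printed here are the desk-scale analogue
# of the flowchart counts a full-archive run would be compared against.
#
# Run from the repository root after 01_simulate.R.

suppressPackageStartupMessages(library(faersror))

bundle <- read_quarter("results/sim_quarters", source_label = "2021Q1")
if (nrow(bundle$rejects)) {
  utils::write.table(bundle$rejects, "results/rejects.tsv", sep = "\t",
                     quote = FALSE, row.names = FALSE)
  message(nrow(bundle$rejects), " unparseable lines -> results/rejects.tsv")
}
stopifnot(validate_bundle(bundle)$clean)

ds <- build_dataset(bundle, c("2020-01-01", "2022-12-31"))
print(ds)

# cache the curated universe in the same ASCII dialect (re-read by stage 3)
cache <- quarter_bundle(ds$demo[, 1:9], ds$drug, ds$reac, ds$outc, ds$indi,
                        source_label = "CURATED")
write_quarter(cache, "results/curated")

prov <- data.frame(step = c("reports_read", "duplicates_removed",
                            "window_excluded", "reports_kept"),
                   n = unlist(ds$provenance[c("reports_read",
                                              "duplicates_removed",
                                              "window_excluded",
                                              "reports_kept")]))
utils::write.table(prov, "results/provenance.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
message("curated universe cached under results/curated")
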