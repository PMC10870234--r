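#!/usr/bin/env Rscript
# Stage 4: descriptive tables and the pregnancy-signal drilldown. Reporter
# occupations and outcome records per study drug, the indication rollup
# (COVID-19 treatment vs other vs unknown), and the case-level drilldown —
# age, sex, indications, concomitant-medication count, co-reported
# exposure terms, and per-field missingness — for the reports behind the
# injected pregnancy signals.
#
# Run from the repository root after 02_ingest.R.

suppressPackageStartupMessages(library(faersror))

bundle <- read_quarter("results/curated", source_label = "CURATED")
ds <- build_dataset(bundle, c("2020-01-01", "2022-12-31"))

queries <- list(
  remdesivir = drug_query(c("REMDESIVIR", "VEKLURY"), label = "remdesivir"),
  tocilizumab = drug_query(c("TOCILIZUMAB", "ACTEMRA"), label = "tocilizumab")
)
dump <- function(df, name) {
  utils::write.table(as.data.frame(df), file.path("results", name),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

for (q in queries) {
  rep_tab <- reporter_table(ds, q)
  out_tab <- outcome_table(ds, q)
  ind <- indication_breakdown(ds, q)
  dump(rep_tab, sprintf("reporters_%s.tsv", q$label))
  dump(out_tab, sprintf("outcomes_%s.tsv", q$label))
  dump(ind$rollup, sprintf("indications_%s.tsv", q$label))
  message("== ", q$label, ": notifier categories ==")
  print(rep_tab, row.names = FALSE)
  message("outcome records: ", attr(out_tab, "total"),
          "; COVID-19 indication share: ",
          ind$rollup$percent[ind$rollup$category == "COVID-19 treatment"],
          "%")
}

preg <- list(
  remdesivir = c("Abortion", "Foetal death"),
  tocilizumab = c("Death neonatal")
)
for (nm in names(preg)) {
  d <- drilldown(ds, queries[[nm]], preg[[nm]])
  if (is.null(d$cases)) next
  dump(d$cases, sprintf("drilldown_cases_%s.tsv", nm))
  dump(d$missingness, sprintf("drilldown_missingness_%s.tsv", nm))
  message(sprintf("== %s drilldown (%s): %d contributing reports ==",
                  nm, paste(preg[[nm]], collapse = ", "), nrow(d$cases)))
  print(d$missingness, row.names = FALSE)
  if (length(d$ages)) {
    message("age range of contributing reports: ",
            min(d$ages), "-", max(d$ages), " years")
  }
}
message("tables written under results/")
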