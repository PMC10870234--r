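# Published reference values from the full-scale 2020-2022 FAERS
# disproportionality analysis of remdesivir and tocilizumab that this
# pipeline reproduces. The full FDA quarterly archives are multi-gigabyte
# downloads, so the printed tables travel with the package as inputs for
# desk-scale arithmetic checks: recomputing the percentage columns and
# re-classifying the printed signal rows under the signal rule.

#' Published notifier-category counts (2020-2022 FAERS, primary suspect)
#'
#' Report counts by reporter occupation for remdesivir (7,147 reports) and
#' tocilizumab (19,602 reports), as printed in the full-scale analysis.
#' Percentages are *not* stored; they are recomputed with
#' [category_table()].
#'
#' @param drug `"remdesivir"` or `"tocilizumab"`.
#' @return named integer vector of counts.
#' @export
published_reporter_counts <- function(drug = c("remdesivir", "tocilizumab")) {
  drug <- match.arg(drug)
  labels <- c(OCCP_LABELS, Missing = "Missing")
  counts <- switch(drug,
    remdesivir  = c(1272, 4569, 679, 2, 401, 224),
    tocilizumab = c(4169, 1437, 5433, 2, 8112, 449)
  )
  setNames(counts, unname(labels))
}

#' Published outcome-record counts (2020-2022 FAERS, primary suspect)
#'
#' Outcome records by code for the two study drugs; the denominator is the
#' outcome-record total (7,453 for remdesivir, 14,454 for tocilizumab), not
#' the report count, since a report can carry several outcomes.
#'
#' @inheritParams published_reporter_counts
#' @return named integer vector of counts.
#' @export
published_outcome_counts <- function(drug = c("remdesivir", "tocilizumab")) {
  drug <- match.arg(drug)
  counts <- switch(drug,
    remdesivir  = c(DE = 1840, CA = 10, LT = 420, DS = 95, RI = 124,
                    HO = 1203, OT = 3761),
    tocilizumab = c(DE = 1740, CA = 19, LT = 429, DS = 459, RI = 21,
                    HO = 3545, OT = 8241)
  )
  setNames(as.integer(counts), unname(OUTCOME_LABELS[names(counts)]))
}

#' Published pregnancy-related signal rows (2020-2022 FAERS)
#'
#' The pregnancy-, foetus- and neonate-related rows of the full-scale signal
#' tables: six for remdesivir, three for tocilizumab, each with the printed
#' pair frequency, ROR and 95% CI bounds. Used to re-apply the signal rule
#' (frequency >= 3 and lower CI bound > 1) to the printed values.
#'
#' @param drug `"remdesivir"`, `"tocilizumab"` or `"both"`.
#' @return data frame with columns `drug`, `soc`, `pt`, `a`, `ror`,
#'   `ci_low`, `ci_high`.
#' @export
published_pregnancy_signals <- function(drug = c("both", "remdesivir",
                                                 "tocilizumab")) {
  drug <- match.arg(drug)
  preg <- "Pregnancy, Puerperium and Perinatal Conditions"
  inj <- "Injury, Poisoning and Procedural Complications"
  gen <- "General disorders and administration site conditions"
  rem <- data.frame(
    drug = "remdesivir",
    soc = c(preg, preg, preg, preg, inj, inj),
    pt = c("Abortion", "Foetal death", "Premature delivery",
           "Premature labor", "Maternal drugs affecting foetus",
           "Maternal exposure during pregnancy"),
    a = c(3L, 7L, 11L, 4L, 3L, 70L),
    ror = c(5.2, 6.3, 2.0, 4.2, 10.8, 2.3),
    ci_low = c(1.7, 3.0, 1.1, 1.6, 3.4, 1.8),
    ci_high = c(16.1, 13.3, 3.6, 11.1, 33.7, 2.9),
    stringsAsFactors = FALSE
  )
  toc <- data.frame(
    drug = "tocilizumab",
    soc = c(gen, inj, inj),
    pt = c("Death neonatal", "Maternal exposure timing unspecified",
           "Maternal exposure during pregnancy"),
    a = c(8L, 26L, 506L),
    ror = c(4.1, 6.7, 2.6),
    ci_low = c(2.0, 4.5, 2.4),
    ci_high = c(8.2, 9.9, 2.9),
    stringsAsFactors = FALSE
  )
  switch(drug, both = rbind(rem, toc), remdesivir = rem, tocilizumab = toc)
}

#' Re-classify published signal rows under the signal rule
#'
#' Applies [classify_signal()]'s rule to printed (frequency, CI) rows: a row
#' is a signal when `a >= min_frequency` and `ci_low > 1`.
#'
#' @param rows a data frame as returned by [published_pregnancy_signals()].
#' @param min_frequency minimum pair frequency.
#' @return logical vector, one flag per row.
#' @export
classify_published_rows <- function(rows, min_frequency = 3) {
  rows$a >= min_frequency & rows$ci_low > 1
}
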