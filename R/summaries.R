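# Descriptive outputs over the curated dataset: reporter and outcome
# breakdowns, indication rollups, SOC aggregation of signals, and per-signal
# case drilldowns with missingness rates.

OCCP_LABELS <- c(MD = "Physician", PH = "Pharmacist",
                 OT = "Other health professional", LW = "Lawyer",
                 CN = "Consumer")

OUTCOME_LABELS <- c(
  DE = "Death", CA = "Congenital Anomaly", LT = "Life-Threatening",
  DS = "Disability",
  RI = "Required Intervention to Prevent Permanent Impairment/Harm",
  HO = "Hospitalization - Initial or Prolonged",
  OT = "Other Serious Ones (Important Medical Events)"
)

#' Category table with half-up percentages
#'
#' @param counts named integer vector (category -> count).
#' @param total denominator; defaults to `sum(counts)`.
#' @return a `category_table` data frame with `category`, `count`, `percent`.
#' @export
category_table <- function(counts, total = sum(counts)) {
  stopifnot(total > 0)
  out <- data.frame(category = names(counts),
                    count = as.integer(counts),
                    percent = round_half_up(100 * as.numeric(counts) / total, 1),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- as.integer(total)
  class(out) <- c("category_table", "data.frame")
  out
}

study_report_ids <- function(dataset, query) {
  ids <- match_drug_reports(dataset$drug, query)
  if (length(ids) == 0L) {
    stop("no reports match the drug query '", query$label,
         "' under roles {", paste(query$role_filter, collapse = ","), "}",
         call. = FALSE)
  }
  ids
}

#' Reporter-category table for a study drug
#'
#' One row per notifier occupation over the study drug's reports (physician,
#' pharmacist, other health professional, lawyer, consumer, missing), with
#' percentages of the report total.
#'
#' @inheritParams build_contingency
#' @return a `category_table`.
#' @export
reporter_table <- function(dataset, query) {
  stopifnot(inherits(dataset, "case_dataset"))
  ids <- study_report_ids(dataset, query)
  demo <- dataset$demo[dataset$demo$primaryid %in% ids, , drop = FALSE]
  occ <- factor(demo$occp_cod, levels = names(OCCP_LABELS))
  counts <- table(occ)
  names(counts) <- OCCP_LABELS[names(counts)]
  counts <- c(counts, Missing = sum(is.na(demo$occp_cod)))
  category_table(counts)
}

#' Outcome table for a study drug
#'
#' One row per outcome code over the outcome *records* of the study drug's
#' reports. A report can carry zero, one or several outcomes, so the
#' denominator is the record count, not the report count.
#'
#' @inheritParams build_contingency
#' @return a `category_table`.
#' @export
outcome_table <- function(dataset, query) {
  stopifnot(inherits(dataset, "case_dataset"))
  ids <- study_report_ids(dataset, query)
  outc <- dataset$outc[dataset$outc$primaryid %in% ids, , drop = FALSE]
  if (nrow(outc) == 0L) {
    stop("no outcome records among reports for '", query$label, "'",
         call. = FALSE)
  }
  counts <- table(factor(outc$outc_cod, levels = names(OUTCOME_LABELS)))
  names(counts) <- OUTCOME_LABELS[names(counts)]
  category_table(counts)
}

DEFAULT_COVID_TERMS <- c("COVID-19", "COVID-19 pneumonia",
                         "Coronavirus infection",
                         "SARS-CoV-2 infection")

#' Indication breakdown for a study drug
#'
#' Indication records are joined to the study drug's own `drug_seq` only —
#' indications of concomitant medicines never count. Returns both the
#' per-term table (over indication records) and a report-level rollup into
#' COVID-19 treatment vs other indications vs unknown (no indication
#' record). The COVID term list is explicit and user-editable rather than a
#' guess at any fixed grouping.
#'
#' @inheritParams build_contingency
#' @param covid_terms Preferred Terms counted as COVID-19 treatment
#'   (case-insensitive).
#' @return list with `per_term` and `rollup` category tables.
#' @export
indication_breakdown <- function(dataset, query,
                                 covid_terms = DEFAULT_COVID_TERMS) {
  stopifnot(inherits(dataset, "case_dataset"))
  ids <- study_report_ids(dataset, query)
  drug <- dataset$drug
  in_role <- drug$role_cod %in% query$role_filter
  hit <- (match_name_token(drug$drugname, query$names) |
            match_name_token(drug$prod_ai, query$names)) & in_role
  study_drug_rows <- drug[hit & drug$primaryid %in% ids,
                          c("primaryid", "drug_seq"), drop = FALSE]
  indi <- merge(dataset$indi, study_drug_rows,
                by.x = c("primaryid", "indi_drug_seq"),
                by.y = c("primaryid", "drug_seq"))
  per_term <- if (nrow(indi)) {
    tab <- sort(table(indi$indi_pt), decreasing = TRUE)
    category_table(c(tab))
  } else {
    NULL
  }
  is_covid <- tolower(trimws(indi$indi_pt)) %in% tolower(trimws(covid_terms))
  covid_ids <- unique(indi$primaryid[is_covid])
  other_ids <- setdiff(unique(indi$primaryid), covid_ids)
  unknown <- length(ids) - length(covid_ids) - length(other_ids)
  rollup <- category_table(c(
    "COVID-19 treatment" = length(covid_ids),
    "Other indication" = length(other_ids),
    "Unknown" = unknown
  ))
  list(per_term = per_term, rollup = rollup)
}

#' Read a flat PT-to-SOC mapping
#'
#' MedDRA is licensed, so the System Organ Class mapping is supplied by the
#' user as a two-column delimited file (PT, SOC). Lookup is case-insensitive
#' on the PT; unmapped PTs yield `NA`, never a guess.
#'
#' @param path path to a tab- (or `sep`-) delimited two-column file, no
#'   header by default.
#' @param sep field separator.
#' @param header logical.
#' @return a `soc_map` (named character vector keyed by upper-cased PT).
#' @export
read_soc_map <- function(path, sep = "\t", header = FALSE) {
  df <- utils::read.table(path, sep = sep, header = header, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = c("pt", "soc"), fill = FALSE,
                          encoding = "UTF-8")
  soc_map(df$pt, df$soc)
}

#' @rdname read_soc_map
#' @param pt,soc character vectors defining the mapping directly.
#' @export
soc_map <- function(pt, soc) {
  stopifnot(length(pt) == length(soc))
  structure(setNames(as.character(soc), toupper(trimws(pt))),
            class = "soc_map")
}

#' @rdname read_soc_map
#' @param map a `soc_map`.
#' @param pts PTs to look up.
#' @export
soc_lookup <- function(map, pts) {
  stopifnot(inherits(map, "soc_map"))
  out <- unname(unclass(map)[toupper(trimws(pts))])
  as.character(out)
}

#' Group signal results by System Organ Class
#'
#' Annotates each signal with its SOC and orders the table by SOC name (then
#' descending ROR). PTs absent from the map land in an `"Unmapped"` group
#' with a warning; no signal is ever dropped, so group sizes sum to the
#' input count.
#'
#' @param signals a `signal_results` data frame.
#' @param soc_map a [soc_map()].
#' @return the signals with `soc` filled, sorted by SOC.
#' @export
aggregate_soc <- function(signals, soc_map) {
  df <- as.data.frame(signals)
  df$soc <- soc_lookup(soc_map, df$pt)
  n_un <- sum(is.na(df$soc))
  if (n_un > 0) {
    warning(n_un, " PT(s) missing from the SOC map; grouped as 'Unmapped'",
            call. = FALSE)
    df$soc[is.na(df$soc)] <- "Unmapped"
  }
  ord <- order(df$soc, -xtfrm(df$ror), df$pt, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("signal_results", "data.frame"))
}

DEFAULT_EXPOSURE_TERMS <- c(
  "Maternal exposure during pregnancy",
  "Foetal exposure during pregnancy",
  "Maternal condition affecting foetus",
  "Exposure during pregnancy",
  "Maternal exposure timing unspecified"
)

#' Case drilldown for named signal events
#'
#' Pulls the union of the study drug's reports contributing to the a-cells
#' of the named PTs and summarises per-case age, sex, indications for the
#' study drug, count of other medication records on the report, and which
#' pregnancy-exposure terms are co-reported; plus a per-field missingness
#' summary. The age vector is returned ready for histogramming.
#'
#' @inheritParams indication_breakdown
#' @param pts Preferred Terms whose contributing cases to pull.
#' @param exposure_terms co-reported exposure PTs to flag per case.
#' @return a `drilldown` list: `cases` data frame, `missingness` data frame,
#'   `ages` numeric vector, `pts_not_found` character vector.
#' @export
drilldown <- function(dataset, query, pts,
                      exposure_terms = DEFAULT_EXPOSURE_TERMS) {
  stopifnot(inherits(dataset, "case_dataset"))
  if (length(pts) == 0L) {
    return(structure(list(cases = NULL, missingness = NULL,
                          ages = numeric(0), pts_not_found = character(0)),
                     class = "drilldown"))
  }
  ids <- match_drug_reports(dataset$drug, query)
  reac <- dataset$reac
  reac$pt_norm <- tolower(trimws(reac$pt))
  wanted <- tolower(trimws(pts))
  found <- vapply(wanted, function(p) {
    any(reac$pt_norm == p & reac$primaryid %in% ids)
  }, logical(1))
  pts_not_found <- pts[!found]
  if (length(pts_not_found)) {
    message("no contributing study-drug reports for PT(s): ",
            paste(pts_not_found, collapse = ", "))
  }
  case_ids <- sort(unique(reac$primaryid[reac$pt_norm %in% wanted &
                                           reac$primaryid %in% ids]))
  if (length(case_ids) == 0L) {
    return(structure(list(cases = NULL, missingness = NULL,
                          ages = numeric(0), pts_not_found = pts_not_found),
                     class = "drilldown"))
  }
  demo <- dataset$demo[match(case_ids, dataset$demo$primaryid), ,
                       drop = FALSE]
  drug <- dataset$drug[dataset$drug$primaryid %in% case_ids, , drop = FALSE]
  in_role <- drug$role_cod %in% query$role_filter
  is_study <- (match_name_token(drug$drugname, query$names) |
                 match_name_token(drug$prod_ai, query$names)) & in_role
  other_counts <- table(factor(drug$primaryid[!is_study],
                               levels = case_ids))
  study_rows <- drug[is_study, c("primaryid", "drug_seq"), drop = FALSE]
  indi <- merge(dataset$indi, study_rows,
                by.x = c("primaryid", "indi_drug_seq"),
                by.y = c("primaryid", "drug_seq"))
  indi_by_case <- vapply(case_ids, function(id) {
    v <- sort(unique(indi$indi_pt[indi$primaryid == id]))
    if (length(v)) paste(v, collapse = "; ") else NA_character_
  }, character(1))
  expo_norm <- tolower(trimws(exposure_terms))
  expo_by_case <- vapply(case_ids, function(id) {
    v <- unique(reac$pt[reac$primaryid == id & reac$pt_norm %in% expo_norm])
    if (length(v)) paste(sort(v), collapse = "; ") else NA_character_
  }, character(1))
  cases <- data.frame(
    primaryid = case_ids,
    age = demo$age, age_cod = demo$age_cod, sex = demo$sex,
    indications = unname(indi_by_case),
    n_other_drug_records = as.integer(other_counts[case_ids]),
    exposure_pts = unname(expo_by_case),
    stringsAsFactors = FALSE
  )
  miss <- function(x) sum(is.na(x))
  n <- nrow(cases)
  missingness <- data.frame(
    field = c("age", "sex", "indications"),
    n_missing = c(miss(cases$age), miss(cases$sex), miss(cases$indications)),
    stringsAsFactors = FALSE
  )
  missingness$pct_missing <- round_half_up(100 * missingness$n_missing / n, 1)
  structure(list(cases = cases, missingness = missingness,
                 ages = cases$age[!is.na(cases$age)],
                 pts_not_found = pts_not_found),
            class = "drilldown")
}

#' @export
print.drilldown <- function(x, ...) {
  if (is.null(x$cases)) {
    cat("Drilldown: no contributing cases\n")
    return(invisible(x))
  }
  cat("Drilldown over", nrow(x$cases), "contributing case report(s)\n")
  print(x$missingness, row.names = FALSE)
  invisible(x)
}
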