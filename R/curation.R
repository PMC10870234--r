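# Curation: from raw quarter bundles to the analysis-ready case universe.
# FAERS re-files updated cases in later quarters under the same caseid with a
# higher caseversion, so deduplication runs on the union of all quarters
# before anything else; the event-date window is applied afterwards.

#' Drug query: names and role filter
#'
#' A report is selected when one of its drug records carries a role in
#' `role_filter` and its `drugname` or `prod_ai` matches one of `names`
#' case-insensitively as a whole-word token (or the whole field). The default
#' role filter keeps only primary-suspect drugs, which is the restriction
#' used for signal generation to increase specificity.
#'
#' @param names character vector of search names (INN plus brand names).
#' @param role_filter subset of `c("PS", "SS", "C", "I")`.
#' @param label display label for outputs (defaults to the first name,
#'   lower-cased).
#' @return a `drug_query`.
#' @export
drug_query <- function(names, role_filter = "PS", label = NULL) {
  names <- trimws(as.character(names))
  names <- names[nzchar(names)]
  if (length(names) == 0L) stop("drug query needs at least one name",
                                call. = FALSE)
  stopifnot(all(role_filter %in% ROLE_CODES))
  structure(
    list(names = names, role_filter = role_filter,
         label = label %||% tolower(names[[1]])),
    class = "drug_query"
  )
}

#' Deduplicate case reports to the most recent version
#'
#' FAERS cases updated over time recur under the same `caseid`; only the most
#' recent version is analysis-worthy. "Most recent" is the maximum of
#' (`caseversion`, `fda_dt`, `primaryid`) compared lexicographically — the
#' higher case version supersedes, ties broken by the later FDA receipt date,
#' then the larger report identifier, so the result is deterministic.
#'
#' @param demo data frame of DEMO records.
#' @return list with `kept` (one row per `caseid`) and `removed_count`.
#' @export
deduplicate <- function(demo) {
  if (nrow(demo) == 0L) return(list(kept = demo, removed_count = 0L))
  fda <- demo$fda_dt
  fda[is.na(fda)] <- ""  # absent receipt date sorts lowest
  ord <- order(demo$caseid, -xtfrm(demo$caseversion), -xtfrm(fda),
               -xtfrm(demo$primaryid), method = "radix")
  sorted <- demo[ord, , drop = FALSE]
  kept <- sorted[!duplicated(sorted$caseid), , drop = FALSE]
  kept <- kept[order(kept$primaryid, method = "radix"), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed_count = nrow(demo) - nrow(kept))
}

#' Apply the event-date window
#'
#' Excludes reports whose event date lies wholly outside the inclusive
#' window. Reports with no event date are kept (the exclusion rule
#' presupposes a date). A partial date (year or year-month precision) is
#' excluded only when no completion of it can fall inside the window, so a
#' year-only date drops out only if its whole year is outside.
#'
#' @param demo data frame of DEMO records.
#' @param window length-2 vector of inclusive ISO dates (start, end).
#' @return list with `kept` and `excluded_count`.
#' @export
apply_event_window <- function(demo, window) {
  w <- as_window(window)
  if (nrow(demo) == 0L) return(list(kept = demo, excluded_count = 0L))
  lo <- date_min_completion(demo$event_dt)
  hi <- date_max_completion(demo$event_dt)
  outside <- !is.na(lo) & (hi < w[1] | lo > w[2])
  kept <- demo[!outside, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded_count = sum(outside))
}

# Whole-word, case-insensitive match of `patterns` in `fields`: a pattern
# matches when it appears delimited by non-alphanumerics (or the field
# boundary), so "REMDESIVIR" matches "REMDESIVIR/XYZ COMBO" but not
# "NOTREMDESIVIRX".
match_name_token <- function(fields, patterns) {
  hit <- rep(FALSE, length(fields))
  for (p in patterns) {
    rx <- paste0("(?<![A-Za-z0-9])", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", p),
                 "(?![A-Za-z0-9])")
    hit <- hit | (!is.na(fields) &
                    grepl(rx, fields, ignore.case = TRUE, perl = TRUE))
  }
  hit
}

#' Select report ids matching a drug query
#'
#' @param drug data frame of DRUG records.
#' @param query a [drug_query()].
#' @return sorted character vector of matching `primaryid`s.
#' @export
match_drug_reports <- function(drug, query) {
  stopifnot(inherits(query, "drug_query"))
  if (nrow(drug) == 0L) return(character(0))
  in_role <- drug$role_cod %in% query$role_filter
  name_hit <- match_name_token(drug$drugname, query$names) |
    match_name_token(drug$prod_ai, query$names)
  sort(unique(drug$primaryid[in_role & name_hit]))
}

#' Build the analysis-ready case dataset
#'
#' Concatenates quarters, deduplicates cases across quarters to the most
#' recent version, applies the event-date window, and restricts the child
#' tables (drug, reaction, outcome, indication) to the kept reports. Exact
#' duplicate child rows (the same record re-extracted in several quarters)
#' are collapsed. Exclusion tallies are recorded as provenance so a run can
#' be compared against the flowchart-style counts of a full-scale extract.
#'
#' @param bundles a `quarter_bundle` or list of them.
#' @param window inclusive event-date window (two ISO dates).
#' @return a `case_dataset`: `demo`, `drug`, `reac`, `outc`, `indi`,
#'   `window`, `provenance`.
#' @export
build_dataset <- function(bundles, window) {
  if (inherits(bundles, "quarter_bundle")) bundles <- list(bundles)
  if (length(bundles) == 0L) stop("no quarter bundles supplied",
                                  call. = FALSE)
  stopifnot(all(vapply(bundles, inherits, logical(1), "quarter_bundle")))
  w <- as_window(window)
  cat_tab <- function(tb) {
    out <- do.call(rbind, c(lapply(bundles, `[[`, tb),
                            list(make.row.names = FALSE)))
    unique(out)
  }
  demo <- cat_tab("demo")
  n_input <- nrow(demo)
  dd <- deduplicate(demo)
  ww <- apply_event_window(dd$kept, w)
  kept_ids <- ww$kept$primaryid
  restrict <- function(df) {
    out <- df[df$primaryid %in% kept_ids, , drop = FALSE]
    # canonical row order so output is invariant to bundle supply order
    out <- out[do.call(order, c(unname(out), list(method = "radix"))), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(
    list(
      demo = ww$kept,
      drug = restrict(cat_tab("drug")),
      reac = restrict(cat_tab("reac")),
      outc = restrict(cat_tab("outc")),
      indi = restrict(cat_tab("indi")),
      window = w,
      provenance = list(
        source_labels = vapply(bundles, `[[`, character(1), "source_label"),
        reports_read = n_input,
        duplicates_removed = dd$removed_count,
        window_excluded = ww$excluded_count,
        reports_kept = nrow(ww$kept)
      )
    ),
    class = "case_dataset"
  )
}

#' @export
print.case_dataset <- function(x, ...) {
  p <- x$provenance
  cat("FAERS case dataset\n")
  cat("  quarters:", paste(p$source_labels, collapse = ", "), "\n")
  cat(sprintf("  window: %s .. %s\n", x$window[1], x$window[2]))
  cat(sprintf("  reports read %d | duplicate versions removed %d | outside window %d | kept %d\n",
              p$reports_read, p$duplicates_removed, p$window_excluded,
              p$reports_kept))
  cat(sprintf("  distinct reaction PTs: %d\n", length(unique(x$reac$pt))))
  invisible(x)
}
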