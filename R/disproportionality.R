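# Reporting Odds Ratio disproportionality over the curated case universe.
#
# For a study drug P and event term R the 2x2 contingency table over reports
# is
#           event R   other events
#   drug P     a           b
#   others     c           d
#
# and ROR = (a/b) / (c/d) with the Wald 95% CI
# exp(log ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d)). When no other
# medicine shares the event (c = 0) the ratio is incomputable and the
# conventional sentinel 99.9 is assigned to mark a possible signal; a pair is
# a potential safety signal when a >= 3 and the lower CI bound exceeds 1.

ROR_SENTINEL <- 99.9
ROR_Z <- 1.96

#' 2x2 contingency table for one drug-event pair
#'
#' Counts are at report level: a report contributes once to its cell however
#' many times the event term recurs inside it. With the default comparator,
#' every report not selected by the drug query forms the comparator rows, so
#' the four cells partition the dataset. With `comparator =
#' "exclude_any_role"`, reports that carry the study drug in a role outside
#' the query's filter (e.g. as a concomitant) are removed from the universe
#' altogether rather than counted among the comparators.
#'
#' @param dataset a [build_dataset()] result.
#' @param query a [drug_query()].
#' @param pt event Preferred Term (matched exactly after trimming).
#' @param comparator `"other_reports"` (default) or `"exclude_any_role"`.
#' @return a `contingency_table` with fields `a`, `b`, `c`, `d`.
#' @export
build_contingency <- function(dataset, query, pt,
                              comparator = c("other_reports",
                                             "exclude_any_role")) {
  stopifnot(inherits(dataset, "case_dataset"))
  comparator <- match.arg(comparator)
  if (nrow(dataset$demo) == 0L) stop("dataset holds no reports",
                                     call. = FALSE)
  universe <- dataset$demo$primaryid
  drug_ids <- match_drug_reports(dataset$drug, query)
  if (comparator == "exclude_any_role") {
    any_role <- drug_query(query$names, role_filter = ROLE_CODES)
    shadow <- setdiff(match_drug_reports(dataset$drug, any_role), drug_ids)
    universe <- setdiff(universe, shadow)
  }
  pt <- trimws(pt)
  event_ids <- unique(dataset$reac$primaryid[
    !is.na(dataset$reac$pt) & trimws(dataset$reac$pt) == pt])
  event_ids <- intersect(event_ids, universe)
  drug_ids <- intersect(drug_ids, universe)
  a <- length(intersect(drug_ids, event_ids))
  b <- length(drug_ids) - a
  c_ <- length(event_ids) - a
  d <- length(universe) - a - b - c_
  structure(list(a = a, b = b, c = c_, d = d,
                 drug_label = query$label, pt = pt,
                 n = length(universe), comparator = comparator),
            class = "contingency_table")
}

#' @rdname build_contingency
#' @param a,b,c,d cell counts (for constructing a table directly).
#' @export
contingency_table <- function(a, b, c, d, drug_label = NA_character_,
                              pt = NA_character_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("contingency counts must be non-negative", call. = FALSE)
  }
  structure(list(a = a, b = b, c = c, d = d, drug_label = drug_label,
                 pt = pt, n = a + b + c + d, comparator = "other_reports"),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("2x2 table%s%s\n",
              if (is.na(x$drug_label)) "" else paste0(" for ", x$drug_label),
              if (is.na(x$pt)) "" else paste0(" x '", x$pt, "'")))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other"), c("event", "no event")))
  print(m)
  invisible(x)
}

# Vectorized core shared by compute_ror() and scan_signals().
ror_fields <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) {
    stop("contingency counts must be non-negative", call. = FALSE)
  }
  sentinel <- c == 0
  computable <- !sentinel & a > 0 & b > 0 & d > 0
  ror <- rep(NA_real_, length(a))
  lo <- rep(NA_real_, length(a))
  hi <- rep(NA_real_, length(a))
  ror[sentinel] <- ROR_SENTINEL
  i <- computable
  if (any(i)) {
    est <- (a[i] / b[i]) / (c[i] / d[i])
    se <- sqrt(1 / a[i] + 1 / b[i] + 1 / c[i] + 1 / d[i])
    ror[i] <- est
    lo[i] <- exp(log(est) - ROR_Z * se)
    hi[i] <- exp(log(est) + ROR_Z * se)
  }
  list(ror = ror, ci_low = lo, ci_high = hi,
       sentinel = sentinel, computable = computable)
}

#' Reporting odds ratio with Wald 95% CI
#'
#' `c = 0` (the event reported for no other medicine) yields the sentinel
#' estimate: `ror = 99.9` exactly, no CI, `sentinel = TRUE` — a marker for a
#' possible signal, not a numeric estimate. `a = 0`, `b = 0` or `d = 0` with
#' `c > 0` yields a non-computable estimate (`computable = FALSE`), which is
#' distinct from the sentinel and never a signal; no continuity correction is
#' applied.
#'
#' @param table a `contingency_table`.
#' @return a `ror_estimate` with `ror`, `ci_low`, `ci_high`, `sentinel`,
#'   `computable`.
#' @export
compute_ror <- function(table) {
  stopifnot(inherits(table, "contingency_table"))
  f <- ror_fields(table$a, table$b, table$c, table$d)
  structure(list(ror = f$ror, ci_low = f$ci_low, ci_high = f$ci_high,
                 sentinel = f$sentinel, computable = f$computable),
            class = "ror_estimate")
}

#' @export
print.ror_estimate <- function(x, ...) {
  if (x$sentinel) {
    cat(sprintf("ROR = %.1f (sentinel: event unique to the study drug)\n",
                x$ror))
  } else if (!x$computable) {
    cat("ROR not computable (zero cell outside the sentinel case)\n")
  } else {
    cat(sprintf("ROR = %.2f (95%% CI %.2f-%.2f)\n",
                x$ror, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Potential-safety-signal rule
#'
#' A pair is flagged when the drug-event frequency `a` reaches
#' `min_frequency` and either the estimate is the `c = 0` sentinel or the
#' lower 95% CI bound strictly exceeds 1. Non-computable estimates are never
#' signals.
#'
#' @param a drug-event report count.
#' @param estimate a `ror_estimate`.
#' @param min_frequency minimum pair frequency (default 3).
#' @return logical flag.
#' @export
classify_signal <- function(a, estimate, min_frequency = 3) {
  stopifnot(inherits(estimate, "ror_estimate"))
  a >= min_frequency &&
    (estimate$sentinel ||
       (estimate$computable && estimate$ci_low > 1))
}

#' Scan all event terms reported with a study drug
#'
#' Builds the 2x2 table for every Preferred Term occurring in at least
#' `min_frequency` of the study drug's reports, computes ROR and CI, and
#' applies the signal rule. Rows are sorted by descending ROR then PT so
#' output is deterministic; pairs with `a >= 5` carry a separate flag.
#'
#' @inheritParams build_contingency
#' @param min_frequency minimum a-cell count for a pair to be evaluated.
#' @param soc_map optional [read_soc_map()] result used to annotate each PT
#'   with its System Organ Class.
#' @return a `signal_results` data frame with columns `drug`, `pt`, `soc`,
#'   `a`, `b`, `c`, `d`, `a_ge_5`, `ror`, `ci_low`, `ci_high`, `sentinel`,
#'   `computable`, `is_signal`.
#' @export
scan_signals <- function(dataset, query, min_frequency = 3, soc_map = NULL,
                         comparator = c("other_reports",
                                        "exclude_any_role")) {
  stopifnot(inherits(dataset, "case_dataset"))
  comparator <- match.arg(comparator)
  universe <- dataset$demo$primaryid
  drug_ids <- match_drug_reports(dataset$drug, query)
  if (comparator == "exclude_any_role") {
    any_role <- drug_query(query$names, role_filter = ROLE_CODES)
    shadow <- setdiff(match_drug_reports(dataset$drug, any_role), drug_ids)
    universe <- setdiff(universe, shadow)
  }
  drug_ids <- intersect(drug_ids, universe)
  reac <- dataset$reac[dataset$reac$primaryid %in% universe &
                         !is.na(dataset$reac$pt), , drop = FALSE]
  reac$pt <- trimws(reac$pt)
  pairs <- unique(reac[, c("primaryid", "pt")])
  in_drug <- pairs$primaryid %in% drug_ids
  a_tab <- table(pairs$pt[in_drug])
  pts <- names(a_tab)[a_tab >= min_frequency]
  empty <- data.frame(
    drug = character(0), pt = character(0), soc = character(0),
    a = integer(0), b = integer(0), c = integer(0), d = integer(0),
    a_ge_5 = logical(0), ror = numeric(0), ci_low = numeric(0),
    ci_high = numeric(0), sentinel = logical(0), computable = logical(0),
    is_signal = logical(0), stringsAsFactors = FALSE
  )
  if (length(drug_ids) == 0L || length(pts) == 0L) {
    return(structure(empty, class = c("signal_results", "data.frame")))
  }
  a <- as.integer(a_tab[pts])
  any_tab <- table(factor(pairs$pt, levels = pts))
  c_ <- as.integer(any_tab) - a
  b <- length(drug_ids) - a
  d <- length(universe) - length(drug_ids) - c_
  f <- ror_fields(a, b, c_, d)
  is_signal <- a >= min_frequency &
    (f$sentinel | (f$computable & !is.na(f$ci_low) & f$ci_low > 1))
  soc <- if (is.null(soc_map)) rep(NA_character_, length(pts)) else
    soc_lookup(soc_map, pts)
  out <- data.frame(
    drug = query$label, pt = pts, soc = soc,
    a = a, b = b, c = c_, d = d, a_ge_5 = a >= 5,
    ror = f$ror, ci_low = f$ci_low, ci_high = f$ci_high,
    sentinel = f$sentinel, computable = f$computable,
    is_signal = is_signal, stringsAsFactors = FALSE
  )
  ord <- order(-xtfrm(out$ror), out$pt, method = "radix", na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("signal_results", "data.frame"))
}

#' Render a signal table with 1-decimal ROR and CI
#'
#' Full precision is kept internally; rendered tables round ROR and CI to one
#' decimal, the convention of published signal tables.
#'
#' @param signals a `signal_results` data frame.
#' @param signals_only keep only rows with `is_signal`.
#' @return data frame with formatted `ror_ci` column.
#' @export
format_signal_table <- function(signals, signals_only = TRUE) {
  df <- as.data.frame(signals)
  if (signals_only) df <- df[df$is_signal, , drop = FALSE]
  df$ror_ci <- ifelse(
    df$sentinel, sprintf("%.1f (-)", df$ror),
    ifelse(df$computable,
           sprintf("%.1f (%.1f-%.1f)", round_half_up(df$ror, 1),
                   round_half_up(df$ci_low, 1), round_half_up(df$ci_high, 1)),
           "n.c.")
  )
  df[, c("drug", "soc", "pt", "a", "a_ge_5", "ror_ci")]
}
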