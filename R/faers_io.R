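# FAERS quarterly ASCII dialect: one header line, fields separated by "$"
# with no quoting (the FDA files never embed "$" in a value). Column order is
# taken from the header at read time, so trailing columns added in later
# quarters are tolerated; unknown columns are ignored with a logged note.
# Absent values are empty strings on disk and NA in memory.

ROLE_CODES <- c("PS", "SS", "C", "I")
OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")
AGE_CODES <- c("DEC", "YR", "MON", "WK", "DY", "HR")
SEX_CODES <- c("F", "M", "UNK")
OCCP_CODES <- c("MD", "PH", "OT", "LW", "CN")

FAERS_TABLES <- c("demo", "drug", "reac", "outc", "indi")

faers_schema <- function(table) {
  switch(table,
    demo = c("primaryid", "caseid", "caseversion", "event_dt", "fda_dt",
             "age", "age_cod", "sex", "occp_cod"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
    reac = c("primaryid", "pt"),
    outc = c("primaryid", "outc_cod"),
    indi = c("primaryid", "indi_drug_seq", "indi_pt"),
    stop("unknown FAERS table: ", table, call. = FALSE)
  )
}

# Columns that may be absent from the header without failing the read
# (prod_ai was added to DRUG in later FAERS revisions).
faers_optional_columns <- function(table) {
  switch(table, drug = "prod_ai", character(0))
}

empty_rejects <- function() {
  data.frame(file = character(0), line = integer(0), reason = character(0),
             stringsAsFactors = FALSE)
}

blank_to_na <- function(x) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  x
}

# Validate one parsed table; returns list(records = df of good rows,
# rejects = data.frame(file, line, reason)). Every input row lands in
# exactly one of the two, so parsing is total.
check_faers_rows <- function(df, table, file, lines) {
  reasons <- rep(NA_character_, nrow(df))
  note <- function(bad, why) {
    new <- bad & is.na(reasons)
    reasons[new] <<- why
  }
  note(is.na(df$primaryid), "missing primaryid")
  if (table == "demo") {
    note(is.na(df$caseid), "missing caseid")
    cv <- suppressWarnings(as.integer(df$caseversion))
    note(is.na(df$caseversion) | is.na(cv) | cv < 1L,
         "caseversion not an integer >= 1")
    note(!is.na(df$event_dt) & !is_partial_date(df$event_dt),
         "event_dt not a 4/6/8-digit date")
    note(!is.na(df$fda_dt) & !grepl("^\\d{8}$", df$fda_dt),
         "fda_dt not an 8-digit date")
    age <- suppressWarnings(as.numeric(df$age))
    note(!is.na(df$age) & (is.na(age) | age < 0),
         "age not a non-negative number")
    note(!is.na(df$age_cod) & !(df$age_cod %in% AGE_CODES),
         "age_cod outside {DEC, YR, MON, WK, DY, HR}")
    note(!is.na(df$sex) & !(df$sex %in% SEX_CODES),
         "sex outside {F, M, UNK}")
    note(!is.na(df$occp_cod) & !(df$occp_cod %in% OCCP_CODES),
         "occp_cod outside {MD, PH, OT, LW, CN}")
  } else if (table == "drug") {
    ds <- suppressWarnings(as.integer(df$drug_seq))
    note(is.na(df$drug_seq) | is.na(ds) | ds < 1L,
         "drug_seq not an integer >= 1")
    note(is.na(df$role_cod) | !(df$role_cod %in% ROLE_CODES),
         "role_cod outside {PS, SS, C, I}")
    note(is.na(df$drugname), "empty drugname")
  } else if (table == "reac") {
    note(is.na(df$pt), "empty pt")
  } else if (table == "outc") {
    note(is.na(df$outc_cod) | !(df$outc_cod %in% OUTCOME_CODES),
         "outc_cod outside {DE, LT, HO, DS, CA, RI, OT}")
  } else if (table == "indi") {
    is_ <- suppressWarnings(as.integer(df$indi_drug_seq))
    note(is.na(df$indi_drug_seq) | is.na(is_) | is_ < 1L,
         "indi_drug_seq not an integer >= 1")
    note(is.na(df$indi_pt), "empty indi_pt")
  }
  bad <- !is.na(reasons)
  rejects <- data.frame(file = rep(file, sum(bad)), line = lines[bad],
                        reason = reasons[bad], stringsAsFactors = FALSE)
  good <- df[!bad, , drop = FALSE]
  # typed columns
  if (table == "demo") {
    good$caseversion <- as.integer(good$caseversion)
    good$age <- suppressWarnings(as.numeric(good$age))
    good$event_precision <- date_precision(good$event_dt)
  } else if (table == "drug") {
    good$drug_seq <- as.integer(good$drug_seq)
  } else if (table == "indi") {
    good$indi_drug_seq <- as.integer(good$indi_drug_seq)
  }
  rownames(good) <- NULL
  list(records = good, rejects = rejects)
}

#' Read one FAERS ASCII table
#'
#' @param path path to a `$`-delimited FAERS file with a header line.
#' @param table one of `"demo"`, `"drug"`, `"reac"`, `"outc"`, `"indi"`.
#' @return list with `records` (typed data frame), `rejects` (file, line,
#'   reason — one row per unparseable line), and `notes` (character).
#' @export
read_faers_table <- function(path, table) {
  table <- match.arg(tolower(table), FAERS_TABLES)
  if (!file.exists(path)) {
    stop("missing mandatory file for table '", toupper(table), "': ", path,
         call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    stop("malformed header in ", path, ": file is empty; expected columns ",
         paste(faers_schema(table), collapse = ", "), call. = FALSE)
  }
  header <- tolower(trimws(strsplit(lines[[1]], "$", fixed = TRUE)[[1]]))
  schema <- faers_schema(table)
  required <- setdiff(schema, faers_optional_columns(table))
  if (!all(required %in% header)) {
    stop("malformed header in ", path, ": expected columns ",
         paste(required, collapse = ", "), "; found ",
         paste(header, collapse = ", "), call. = FALSE)
  }
  notes <- character(0)
  extra <- setdiff(header, schema)
  if (length(extra)) {
    notes <- paste0(basename(path), ": ignoring unknown columns ",
                    paste(extra, collapse = ", "))
  }
  body <- lines[-1]
  line_no <- seq_along(body) + 1L
  keep <- nzchar(trimws(body))
  body <- body[keep]
  line_no <- line_no[keep]
  if (length(body) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(schema)),
                                 schema), stringsAsFactors = FALSE)
    return(c(check_faers_rows(df, table, basename(path), integer(0)),
             list(notes = notes)))
  }
  parts <- strsplit(body, "$", fixed = TRUE)
  nf <- lengths(parts)
  # a line ending in "$" drops its trailing empty field under strsplit
  short_ok <- nf == length(header) - 1L & endsWith(body, "$")
  parts[short_ok] <- lapply(parts[short_ok], function(p) c(p, ""))
  nf[short_ok] <- length(header)
  bad_count <- nf != length(header)
  count_rejects <- data.frame(
    file = rep(basename(path), sum(bad_count)), line = line_no[bad_count],
    reason = sprintf("field count %d does not match header (%d)",
                     nf[bad_count], length(header)),
    stringsAsFactors = FALSE
  )
  parts <- parts[!bad_count]
  line_no <- line_no[!bad_count]
  mat <- matrix(unlist(parts, use.names = FALSE),
                ncol = length(header), byrow = TRUE)
  df <- setNames(vector("list", length(schema)), schema)
  for (col in schema) {
    df[[col]] <- if (col %in% header) blank_to_na(mat[, match(col, header)])
                 else rep(NA_character_, nrow(mat))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  out <- check_faers_rows(df, table, basename(path), line_no)
  out$rejects <- rbind(count_rejects, out$rejects)
  out$rejects <- out$rejects[order(out$rejects$line), , drop = FALSE]
  rownames(out$rejects) <- NULL
  out$notes <- notes
  out
}

new_quarter_bundle <- function(demo, drug, reac, outc, indi, source_label,
                               rejects = empty_rejects(),
                               notes = character(0)) {
  structure(
    list(demo = demo, drug = drug, reac = reac, outc = outc, indi = indi,
         source_label = source_label, rejects = rejects, notes = notes),
    class = "quarter_bundle"
  )
}

#' Assemble a quarter bundle from in-memory tables
#'
#' Fills defaults for omitted optional columns and derives event-date
#' precision. Intended for tests and the synthetic generator; files are read
#' with [read_quarter()].
#'
#' @param demo,drug,reac,outc,indi data frames following the FAERS column
#'   layout (see [read_faers_table()]); `reac`, `outc`, `indi` may be omitted.
#' @param source_label quarter tag, e.g. `"2020Q1"`.
#' @return a `quarter_bundle`.
#' @export
quarter_bundle <- function(demo, drug, reac = NULL, outc = NULL, indi = NULL,
                           source_label = "unknown") {
  empty <- function(table) {
    schema <- faers_schema(table)
    as.data.frame(setNames(rep(list(character(0)), length(schema)), schema),
                  stringsAsFactors = FALSE)
  }
  fix <- function(df, table) {
    if (is.null(df)) df <- empty(table)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (col in setdiff(faers_schema(table), names(df))) {
      df[[col]] <- rep(NA_character_, nrow(df))
    }
    df <- df[, faers_schema(table), drop = FALSE]
    for (col in names(df)) {
      if (is.character(df[[col]])) df[[col]] <- blank_to_na(df[[col]])
    }
    df
  }
  demo <- fix(demo, "demo")
  demo$caseversion <- as.integer(demo$caseversion)
  demo$age <- suppressWarnings(as.numeric(demo$age))
  demo$event_precision <- date_precision(demo$event_dt)
  drug <- fix(drug, "drug")
  drug$drug_seq <- as.integer(drug$drug_seq)
  indi <- fix(indi, "indi")
  indi$indi_drug_seq <- as.integer(indi$indi_drug_seq)
  new_quarter_bundle(demo, drug, fix(reac, "reac"), fix(outc, "outc"), indi,
                     source_label)
}

#' @export
print.quarter_bundle <- function(x, ...) {
  cat("FAERS quarter bundle [", x$source_label, "]\n", sep = "")
  for (tb in FAERS_TABLES) {
    cat(sprintf("  %-5s %6d rows\n", toupper(tb), nrow(x[[tb]])))
  }
  if (nrow(x$rejects)) {
    cat("  rejects:", nrow(x$rejects), "lines (see $rejects)\n")
  }
  invisible(x)
}

# File name tag: "2020Q1" -> "20Q1" (the FDA convention DEMO20Q1.txt).
quarter_file_tag <- function(source_label) {
  if (grepl("^\\d{4}Q[1-4]$", source_label)) {
    substr(source_label, 3, nchar(source_label))
  } else {
    source_label
  }
}

#' Read a FAERS quarter (DEMO/DRUG/REAC/OUTC/INDI)
#'
#' Locates the five mandatory tables either in a directory (matching the FDA
#' naming convention `DEMOyyQq.txt`, case-insensitively) or from a named list
#' of paths. Unparseable lines are collected into the bundle's rejects
#' report — with their source file and line number — never silently dropped.
#' Partial event dates (4-, 6- or 8-digit) are kept at their stated
#' precision.
#'
#' @param path a directory containing the quarter's files, or a named
#'   character vector/list with entries `demo`, `drug`, `reac`, `outc`,
#'   `indi`.
#' @param source_label quarter tag recorded as provenance (e.g. `"2020Q1"`).
#' @return a `quarter_bundle`: typed `demo`, `drug`, `reac`, `outc`, `indi`
#'   tables plus `source_label`, `rejects` and `notes`.
#' @seealso [write_quarter()], [validate_bundle()]
#' @export
read_quarter <- function(path, source_label = NULL) {
  if (length(path) == 1L && is.character(path) && dir.exists(path)) {
    files <- list.files(path, full.names = TRUE)
    locate <- function(table) {
      hit <- files[grepl(paste0("^", table), tolower(basename(files)))]
      if (length(hit) == 0L) {
        stop("missing mandatory file for table '", toupper(table),
             "' in ", path, call. = FALSE)
      }
      if (length(hit) > 1L) {
        stop("multiple candidate files for table '", toupper(table),
             "' in ", path, ": ", paste(basename(hit), collapse = ", "),
             call. = FALSE)
      }
      hit
    }
    paths <- setNames(vapply(FAERS_TABLES, locate, character(1)),
                      FAERS_TABLES)
    if (is.null(source_label)) source_label <- basename(normalizePath(path))
  } else {
    paths <- unlist(path)
    missing <- setdiff(FAERS_TABLES, names(paths))
    if (length(missing)) {
      stop("missing mandatory file for table(s): ",
           paste(toupper(missing), collapse = ", "), call. = FALSE)
    }
    if (is.null(source_label)) source_label <- "unknown"
  }
  parsed <- lapply(FAERS_TABLES, function(tb) {
    read_faers_table(paths[[tb]], tb)
  })
  names(parsed) <- FAERS_TABLES
  rejects <- do.call(rbind, c(lapply(parsed, `[[`, "rejects"),
                              list(make.row.names = FALSE)))
  notes <- unlist(lapply(parsed, `[[`, "notes"), use.names = FALSE)
  for (nt in notes) message(nt)
  new_quarter_bundle(
    parsed$demo$records, parsed$drug$records, parsed$reac$records,
    parsed$outc$records, parsed$indi$records,
    source_label = source_label, rejects = rejects, notes = notes
  )
}

na_to_blank <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x
}

format_faers_column <- function(x) {
  if (is.numeric(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else format(v, scientific = FALSE, trim = TRUE)
    }, character(1))
    out
  } else {
    na_to_blank(x)
  }
}

#' Write a quarter bundle in the FAERS ASCII dialect
#'
#' Emits `DEMOyyQq.txt` etc. ($-delimited, one header line) such that
#' [read_quarter()] reproduces the bundle field for field, including absent
#' values (written as empty fields).
#'
#' @param bundle a `quarter_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_quarter <- function(bundle, dir) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  if (file.access(dir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", dir, call. = FALSE)
  }
  tag <- quarter_file_tag(bundle$source_label)
  paths <- setNames(
    file.path(dir, paste0(toupper(FAERS_TABLES), tag, ".txt")),
    FAERS_TABLES
  )
  for (tb in FAERS_TABLES) {
    schema <- faers_schema(tb)
    df <- bundle[[tb]][, schema, drop = FALSE]
    cols <- lapply(df, format_faers_column)
    body <- if (nrow(df)) do.call(paste, c(cols, sep = "$")) else character(0)
    writeLines(c(paste(schema, collapse = "$"), body), paths[[tb]])
  }
  invisible(paths)
}

#' Structural validation of a quarter bundle
#'
#' Reports — never silently repairs — referential and enum problems: child
#' rows whose `primaryid` is absent from DEMO, code values outside their
#' enumerated sets, and duplicated `primaryid` rows in DEMO.
#'
#' @param bundle a `quarter_bundle`.
#' @return a `bundle_validation` list with per-table orphan counts,
#'   `enum_violations`, `duplicate_primaryids`, and a logical `clean`.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "quarter_bundle"))
  ids <- bundle$demo$primaryid
  orphans <- vapply(c("drug", "reac", "outc", "indi"), function(tb) {
    sum(!(bundle[[tb]]$primaryid %in% ids))
  }, integer(1))
  enum <- sum(
    !is.na(bundle$drug$role_cod) & !(bundle$drug$role_cod %in% ROLE_CODES),
    !is.na(bundle$outc$outc_cod) & !(bundle$outc$outc_cod %in% OUTCOME_CODES),
    !is.na(bundle$demo$sex) & !(bundle$demo$sex %in% SEX_CODES),
    !is.na(bundle$demo$occp_cod) & !(bundle$demo$occp_cod %in% OCCP_CODES),
    !is.na(bundle$demo$age_cod) & !(bundle$demo$age_cod %in% AGE_CODES)
  )
  dup <- sum(duplicated(ids))
  out <- list(orphans = orphans, enum_violations = enum,
              duplicate_primaryids = dup,
              clean = all(orphans == 0L) && enum == 0L && dup == 0L)
  class(out) <- "bundle_validation"
  out
}

#' @export
print.bundle_validation <- function(x, ...) {
  cat("Bundle validation:", if (x$clean) "clean" else "problems found", "\n")
  cat("  orphan primaryids:",
      paste(sprintf("%s=%d", toupper(names(x$orphans)), x$orphans),
            collapse = " "), "\n")
  cat("  enum violations:", x$enum_violations,
      " duplicate primaryids:", x$duplicate_primaryids, "\n")
  invisible(x)
}
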