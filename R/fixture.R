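# Deterministic hand-enumerable fixture: a tiny spontaneous-report universe
# whose curation tallies, contingency tables and summary tables were worked
# out by hand and frozen in fixture_manifest(). It exercises every boundary
# the pipeline cares about: duplicate case versions (including an
# equal-version tie broken on FDA receipt date), one out-of-window report,
# a year-precision event date, signal and non-signal pairs straddling the
# frequency-3 and lower-CI-1 boundaries, and missing demographic fields.

#' Hand-enumerated test fixture in FAERS form
#'
#' 44 DEMO rows; after curation over the window 2020-01-01..2022-12-31 the
#' dataset holds 40 reports (3 superseded case versions removed, 1 report
#' outside the window): 10 with remdesivir as primary suspect (half under
#' the brand name) and 30 comparator reports. See [fixture_manifest()] for
#' every expected count.
#'
#' @return a `quarter_bundle` with source label `"FIX2021Q1"`.
#' @export
make_demo_fixture <- function() {
  # --- study reports S1..S10 (caseids 1001..1010) -------------------------
  s_case <- as.character(1001:1010)
  s_id <- paste0(s_case, "1")
  s_id[1] <- "10012"  # S1 is the version-2 refile of caseid 1001
  demo_s <- data.frame(
    primaryid = s_id, caseid = s_case,
    caseversion = c("2", rep("1", 9)),
    event_dt = c("20200315", "20200710", "20201122", "20210205", "20210518",
                 "20210901", "20211214", "20220322", "20220630", "20221108"),
    fda_dt = c("20200402", "20200801", "20201210", "20210301", "20210602",
               "20210915", "20220105", "20220411", "20220715", "20221201"),
    age = c("25", "31", "28", "35", NA, NA, "22", "41", "33", "29"),
    age_cod = c("YR", "YR", "YR", "YR", NA, NA, "YR", "YR", "YR", "YR"),
    sex = c("F", "F", "F", "F", "F", "F", "F", "M", "F", "F"),
    occp_cod = c("PH", "PH", "PH", "PH", "PH", "PH", "MD", "MD", "CN", NA),
    stringsAsFactors = FALSE
  )
  # superseded version 1 of caseid 1001
  demo_s1v1 <- data.frame(
    primaryid = "10011", caseid = "1001", caseversion = "1",
    event_dt = "20200315", fda_dt = "20200320", age = "25", age_cod = "YR",
    sex = "F", occp_cod = "CN", stringsAsFactors = FALSE
  )

  # --- comparator reports C1..C30 (caseids 2001..2030) --------------------
  c_case <- as.character(2001:2030)
  c_id <- paste0(c_case, "1")
  c_id[3] <- "20032"  # C3 refiled at version 2
  ev_days <- sprintf("20%02d%02d%02d", rep(20:22, each = 10),
                     rep(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10), 3),
                     (seq_len(30) %% 27) + 1)
  demo_c <- data.frame(
    primaryid = c_id, caseid = c_case,
    caseversion = c("1", "1", "2", rep("1", 27)),
    event_dt = ev_days,
    fda_dt = sprintf("20%02d%02d15", rep(20:22, each = 10),
                     rep(c(2, 3, 4, 5, 6, 7, 8, 9, 10, 11), 3)),
    age = as.character(c(55, 61, 47, 38, 72, 29, 66, 51, 44, 58,
                         63, 35, 70, 49, 56, 42, 68, 53, 37, 60,
                         45, 74, 31, 57, 64, 40, 52, 69, 48, 36)),
    age_cod = "YR",
    sex = rep(c("F", "M"), 15),
    occp_cod = rep(c("MD", "OT", "CN", "PH", "MD", "CN"), 5),
    stringsAsFactors = FALSE
  )
  demo_c$event_dt[30] <- "2020"  # year-precision date: kept by window rule
  # superseded version 1 of caseid 2003
  demo_c3v1 <- data.frame(
    primaryid = "20031", caseid = "2003", caseversion = "1",
    event_dt = demo_c$event_dt[3], fda_dt = "20200601", age = "47",
    age_cod = "YR", sex = "F", occp_cod = "MD", stringsAsFactors = FALSE
  )
  # caseid 2004 filed twice at the same caseversion: the later FDA receipt
  # date wins even though its primaryid sorts lower
  demo_c4b <- demo_c[4, , drop = FALSE]
  demo_c4b$primaryid <- "20049"
  demo_c4b$fda_dt <- "20210101"
  demo_c$fda_dt[4] <- "20210301"
  # out-of-window report (event date before 2020)
  demo_oow <- data.frame(
    primaryid = "90011", caseid = "9001", caseversion = "1",
    event_dt = "20191215", fda_dt = "20200110", age = "50", age_cod = "YR",
    sex = "F", occp_cod = "MD", stringsAsFactors = FALSE
  )
  demo <- rbind(demo_s, demo_s1v1, demo_c, demo_c3v1, demo_c4b, demo_oow)

  # --- drug records --------------------------------------------------------
  # S1-S4 report the brand name, S5-S10 the INN; S1-S3 carry a concomitant.
  drug_s <- data.frame(
    primaryid = s_id, drug_seq = "1", role_cod = "PS",
    drugname = c(rep("VEKLURY", 4), rep("REMDESIVIR", 6)),
    prod_ai = c(rep("REMDESIVIR", 4), rep(NA, 6)),
    stringsAsFactors = FALSE
  )
  drug_s_con <- data.frame(
    primaryid = s_id[1:3], drug_seq = "2", role_cod = "C",
    drugname = "DEXAMETHASONE", prod_ai = "DEXAMETHASONE",
    stringsAsFactors = FALSE
  )
  comp_names <- rep(c("IBUPROFEN", "PARACETAMOL", "TOCILIZUMAB",
                      "METHOTREXATE", "HEPARIN", "AZITHROMYCIN"), 5)
  drug_c <- data.frame(
    primaryid = c_id, drug_seq = "1", role_cod = "PS",
    drugname = comp_names, prod_ai = comp_names, stringsAsFactors = FALSE
  )
  # C5 also carries remdesivir as a concomitant: must NOT match a PS query
  drug_c5 <- data.frame(
    primaryid = c_id[5], drug_seq = "2", role_cod = "C",
    drugname = "REMDESIVIR", prod_ai = "REMDESIVIR", stringsAsFactors = FALSE
  )
  drug_old <- data.frame(
    primaryid = c("10011", "20031", "20049", "90011"),
    drug_seq = "1", role_cod = "PS",
    drugname = c("VEKLURY", "TOCILIZUMAB", "METHOTREXATE", "REMDESIVIR"),
    prod_ai = c("REMDESIVIR", "TOCILIZUMAB", "METHOTREXATE", "REMDESIVIR"),
    stringsAsFactors = FALSE
  )
  drug <- rbind(drug_s, drug_s_con, drug_c, drug_c5, drug_old)

  # --- reactions -----------------------------------------------------------
  # study a-cells: Foetal death 5 (S1-S5), Abortion 3 (S5-S7),
  # Headache 3 (S3,S8,S9), Premature delivery 3 (S8-S10), Nausea 2 (S9,S10),
  # Maternal exposure during pregnancy 2 (S1,S7)
  reac_s <- data.frame(
    primaryid = c(s_id[1], s_id[1], s_id[2], s_id[3], s_id[3], s_id[4],
                  s_id[5], s_id[5], s_id[6], s_id[7], s_id[7],
                  s_id[8], s_id[8], s_id[9], s_id[9], s_id[9],
                  s_id[10], s_id[10]),
    pt = c("Foetal death", "Maternal exposure during pregnancy",
           "Foetal death", "Foetal death", "Headache", "Foetal death",
           "Foetal death", "Abortion", "Abortion", "Abortion",
           "Maternal exposure during pregnancy",
           "Headache", "Premature delivery",
           "Headache", "Nausea", "Premature delivery",
           "Premature delivery", "Nausea"),
    stringsAsFactors = FALSE
  )
  # comparator c-cells: Foetal death 2 (C1,C2), Headache 15 (C3..C17),
  # Premature delivery 3 (C18..C20), Nausea 10 (C21..C30); Abortion 0
  reac_c <- data.frame(
    primaryid = c_id,
    pt = c("Foetal death", "Foetal death", rep("Headache", 15),
           rep("Premature delivery", 3), rep("Nausea", 10)),
    stringsAsFactors = FALSE
  )
  reac_old <- data.frame(
    primaryid = c("10011", "20031", "20049", "90011"),
    pt = c("Foetal death", "Headache", "Headache", "Abortion"),
    stringsAsFactors = FALSE
  )
  reac <- rbind(reac_s, reac_c, reac_old)

  # --- outcomes: DE 2, HO 2, OT 1 among study reports ---------------------
  outc <- data.frame(
    primaryid = c(s_id[1], s_id[2], s_id[2], s_id[3], s_id[5],
                  c_id[1], c_id[21]),
    outc_cod = c("DE", "DE", "HO", "HO", "OT", "DE", "HO"),
    stringsAsFactors = FALSE
  )

  # --- indications: study PS drug gets COVID-19 (S1-S8), RA (S9), none
  # (S10); S1 also has an indication on its concomitant (never counted) ----
  indi <- data.frame(
    primaryid = c(s_id[1:9], s_id[1], c_id[5]),
    indi_drug_seq = c(rep("1", 9), "2", "2"),
    indi_pt = c(rep("COVID-19", 8), "Rheumatoid arthritis",
                "Corticosteroid therapy", "COVID-19"),
    stringsAsFactors = FALSE
  )

  quarter_bundle(demo, drug, reac, outc, indi, source_label = "FIX2021Q1")
}

#' Hand-enumerated expected values for [make_demo_fixture()]
#'
#' Every number here was enumerated by hand from the fixture's construction
#' and is independent of the pipeline code the fixture tests.
#'
#' @return a named list of expected tallies and tables.
#' @export
fixture_manifest <- function() {
  list(
    window = c("2020-01-01", "2022-12-31"),
    demo_rows = 44L,
    duplicates_removed = 3L,
    window_excluded = 1L,
    reports_kept = 40L,
    n_study_reports = 10L,
    query_names = c("remdesivir", "veklury"),
    # scan_signals at min_frequency 3 over the curated universe
    scan = data.frame(
      pt = c("Abortion", "Foetal death", "Headache", "Premature delivery"),
      a = c(3L, 5L, 3L, 3L),
      b = c(7L, 5L, 7L, 7L),
      c = c(0L, 2L, 15L, 3L),
      d = c(30L, 28L, 15L, 27L),
      sentinel = c(TRUE, FALSE, FALSE, FALSE),
      is_signal = c(TRUE, TRUE, FALSE, FALSE),
      a_ge_5 = c(FALSE, TRUE, FALSE, FALSE),
      stringsAsFactors = FALSE
    ),
    reporter = data.frame(
      category = c("Physician", "Pharmacist", "Other health professional",
                   "Lawyer", "Consumer", "Missing"),
      count = c(2L, 6L, 0L, 0L, 1L, 1L),
      percent = c(20.0, 60.0, 0.0, 0.0, 10.0, 10.0),
      stringsAsFactors = FALSE
    ),
    outcome = data.frame(
      code = c("Death", "Hospitalization - Initial or Prolonged",
               "Other Serious Ones (Important Medical Events)"),
      count = c(2L, 2L, 1L),
      percent = c(40.0, 40.0, 20.0),
      stringsAsFactors = FALSE
    ),
    outcome_total = 5L,
    indication_rollup = data.frame(
      category = c("COVID-19 treatment", "Other indication", "Unknown"),
      count = c(8L, 1L, 1L),
      percent = c(80.0, 10.0, 10.0),
      stringsAsFactors = FALSE
    ),
    drilldown_pts = c("Abortion", "Foetal death"),
    drilldown_cases = 7L,
    drilldown_age_missing = 2L,
    drilldown_age_missing_pct = 28.6
  )
}
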