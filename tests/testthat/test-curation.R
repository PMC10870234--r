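# Case-universe curation: version dedup, event-date window, drug matching.

demo_row <- function(primaryid, caseid, caseversion = 1, event_dt = "20210601",
                     fda_dt = "20210701") {
  data.frame(primaryid = primaryid, caseid = caseid,
             caseversion = as.integer(caseversion), event_dt = event_dt,
             fda_dt = fda_dt, age = NA_character_, age_cod = NA_character_,
             sex = NA_character_, occp_cod = NA_character_,
             event_precision = date_precision(event_dt),
             stringsAsFactors = FALSE)
}

test_that("deduplication keeps the most recent case version", {
  demo <- rbind(demo_row("1001", "100", 1), demo_row("1002", "100", 2),
                demo_row("2001", "200"), demo_row("3001", "300"))
  out <- deduplicate(demo)
  expect_equal(out$removed_count, 1L)
  expect_setequal(out$kept$primaryid, c("1002", "2001", "3001"))
})

test_that("equal versions tie-break on FDA date then primaryid", {
  demo <- rbind(demo_row("71", "7", 3, fda_dt = "20210101"),
                demo_row("72", "7", 3, fda_dt = "20210301"))
  expect_equal(deduplicate(demo)$kept$primaryid, "72")
  demo2 <- rbind(demo_row("71", "7", 3), demo_row("79", "7", 3))
  expect_equal(deduplicate(demo2)$kept$primaryid, "79")
})

test_that("deduplication is idempotent and conserves counts", {
  set.seed(3)
  demo <- do.call(rbind, lapply(1:40, function(i) {
    nv <- sample(1:3, 1)
    do.call(rbind, lapply(1:nv, function(v) {
      demo_row(paste0(i, v), as.character(i), v)
    }))
  }))
  once <- deduplicate(demo)
  twice <- deduplicate(once$kept)
  expect_equal(twice$kept, once$kept)
  expect_equal(twice$removed_count, 0L)
  expect_equal(nrow(once$kept) + once$removed_count, nrow(demo))
})

test_that("event-date window excludes outside dates, keeps absent dates", {
  w <- c("2020-01-01", "2022-12-31")
  demo <- rbind(demo_row("1", "1", event_dt = "20191231"),
                demo_row("2", "2", event_dt = "20200101"),
                demo_row("3", "3", event_dt = NA),
                demo_row("4", "4", event_dt = "20230101"))
  out <- apply_event_window(demo, w)
  expect_setequal(out$kept$primaryid, c("2", "3"))
  expect_equal(out$excluded_count, 2L)
  expect_error(apply_event_window(demo, rev(w)), "inverted")
})

test_that("partial dates are excluded only when no completion fits", {
  w <- c("2020-01-01", "2022-12-31")
  demo <- rbind(demo_row("1", "1", event_dt = "2020"),
                demo_row("2", "2", event_dt = "2019"),
                demo_row("3", "3", event_dt = "201912"),
                demo_row("4", "4", event_dt = "202212"))
  out <- apply_event_window(demo, w)
  expect_setequal(out$kept$primaryid, c("1", "4"))
  # a year-only date is never strictly inside a narrower window unless its
  # whole year is: 2020 overlaps [2020-06-01, 2020-06-30], so it is kept
  out2 <- apply_event_window(demo_row("5", "5", event_dt = "2020"),
                             c("2020-06-01", "2020-06-30"))
  expect_equal(nrow(out2$kept), 1L)
  out3 <- apply_event_window(demo_row("6", "6", event_dt = "2020"),
                             c("2021-01-01", "2021-12-31"))
  expect_equal(nrow(out3$kept), 0L)
})

test_that("widening the window never shrinks the kept set", {
  set.seed(8)
  demo <- do.call(rbind, lapply(1:60, function(i) {
    demo_row(paste0(i, "1"), as.character(i),
             event_dt = sample(c(NA, "2019", "202006",
                                 format(as.Date("2018-01-01") +
                                          sample(0:2500, 1), "%Y%m%d")), 1))
  }))
  narrow <- apply_event_window(demo, c("2020-01-01", "2020-12-31"))
  wide <- apply_event_window(demo, c("2019-01-01", "2022-12-31"))
  expect_true(all(narrow$kept$primaryid %in% wide$kept$primaryid))
})

test_that("drug matching is whole-token, case-insensitive, either-field, role-filtered", {
  drug <- data.frame(
    primaryid = c("1", "2", "3", "4", "5", "6"),
    drug_seq = 1L,
    role_cod = c("PS", "PS", "C", "PS", "PS", "PS"),
    drugname = c("VEKLURY", "UNKNOWN PRODUCT", "REMDESIVIR",
                 "REMDESIVIR/XYZ COMBO", "NOTREMDESIVIRX", "remdesivir "),
    prod_ai = c(NA, "REMDESIVIR", NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  q <- drug_query(c("remdesivir", "veklury"))
  expect_setequal(match_drug_reports(drug, q), c("1", "2", "4", "6"))
  q_all <- drug_query("remdesivir", role_filter = c("PS", "SS", "C", "I"))
  expect_true("3" %in% match_drug_reports(drug, q_all))
  expect_error(drug_query(character(0)), "at least one name")
})

test_that("build_dataset deduplicates across quarters and tallies provenance", {
  b1 <- quarter_bundle(
    demo = demo_row("1001", "100", 1)[, 1:9],
    drug = data.frame(primaryid = "1001", drug_seq = "1", role_cod = "PS",
                      drugname = "ASPIRIN", prod_ai = NA),
    reac = data.frame(primaryid = "1001", pt = "Nausea"),
    source_label = "2020Q1"
  )
  b2 <- quarter_bundle(
    demo = demo_row("1002", "100", 2)[, 1:9],
    drug = data.frame(primaryid = "1002", drug_seq = "1", role_cod = "PS",
                      drugname = "ASPIRIN", prod_ai = NA),
    reac = data.frame(primaryid = "1002", pt = "Nausea"),
    source_label = "2020Q2"
  )
  ds <- build_dataset(list(b1, b2), c("2020-01-01", "2022-12-31"))
  expect_equal(ds$demo$primaryid, "1002")
  expect_equal(ds$reac$primaryid, "1002")
  expect_equal(ds$provenance$duplicates_removed, 1L)
  expect_error(build_dataset(list(), c("2020-01-01", "2022-12-31")),
               "no quarter bundles")
})

test_that("build_dataset output is invariant to bundle order and re-curation", {
  sim <- simulate_faers(sim_config(n_reports = 300, seed = 5))
  b <- sim$bundle
  half <- nrow(b$demo) %/% 2
  split_bundle <- function(rows) {
    ids <- b$demo$primaryid[rows]
    quarter_bundle(b$demo[rows, 1:9],
                   b$drug[b$drug$primaryid %in% ids, ],
                   b$reac[b$reac$primaryid %in% ids, ],
                   b$outc[b$outc$primaryid %in% ids, ],
                   b$indi[b$indi$primaryid %in% ids, ],
                   source_label = "S")
  }
  p1 <- split_bundle(seq_len(half))
  p2 <- split_bundle((half + 1):nrow(b$demo))
  w <- c("2020-01-01", "2022-12-31")
  d12 <- build_dataset(list(p1, p2), w)
  d21 <- build_dataset(list(p2, p1), w)
  for (tb in c("demo", "drug", "reac", "outc", "indi")) {
    expect_same_table(d12[[tb]], d21[[tb]])
  }
  # curating an already-clean universe changes nothing
  clean <- quarter_bundle(d12$demo[, 1:9], d12$drug, d12$reac, d12$outc,
                          d12$indi, source_label = "CLEAN")
  again <- build_dataset(clean, w)
  expect_equal(again$provenance$duplicates_removed, 0L)
  expect_equal(again$provenance$window_excluded, 0L)
  expect_same_table(again$demo, d12$demo)
})

test_that("curation conserves reports: kept + duplicates + excluded = read", {
  sim <- simulate_faers(sim_config(n_reports = 400, seed = 9))
  ds <- build_dataset(sim$bundle, c("2020-01-01", "2022-12-31"))
  p <- ds$provenance
  expect_equal(p$reports_kept + p$duplicates_removed + p$window_excluded,
               p$reports_read)
})
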