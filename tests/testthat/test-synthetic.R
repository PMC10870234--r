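# Synthetic generator: determinism, structural validity, ground truth,
# calibration of injected enrichment.

test_that("simulation is reproducible from its seed, down to the bytes", {
  cfg <- sim_config(n_reports = 120, seed = 77)
  s1 <- simulate_faers(cfg)
  s2 <- simulate_faers(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_quarter(s1$bundle, d1)
  write_quarter(s2$bundle, d2)
  for (f in basename(list.files(d1))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  s3 <- simulate_faers(sim_config(n_reports = 120, seed = 78))
  expect_false(identical(s1$bundle$demo$event_dt, s3$bundle$demo$event_dt))
})

test_that("emitted bundles are structurally valid with one event minimum", {
  sim <- simulate_faers(sim_config(n_reports = 500, seed = 4))
  expect_true(validate_bundle(sim$bundle)$clean)
  expect_true(all(sim$bundle$demo$primaryid %in% sim$bundle$reac$primaryid))
  # exactly one primary suspect per report
  ps <- table(sim$bundle$drug$primaryid[sim$bundle$drug$role_cod == "PS"])
  expect_true(all(ps == 1))
  expect_setequal(names(ps), sim$bundle$demo$primaryid)
})

test_that("duplicate construction: re-filed caseids disappear under dedup", {
  cfg <- sim_config(n_reports = 100, duplicate_fraction = 0.2, seed = 31)
  sim <- simulate_faers(cfg)
  expect_equal(sim$truth$n_duplicates, 20L)
  versions <- table(sim$bundle$demo$caseid)
  expect_equal(sum(versions == 2), 20L)
  dd <- deduplicate(sim$bundle$demo)
  expect_equal(dd$removed_count, 20L)
  # the kept version is always caseversion 2 for duplicated cases
  kept_v <- dd$kept$caseversion[dd$kept$caseid %in%
                                  names(versions[versions == 2])]
  expect_true(all(kept_v == 2L))
})

test_that("window-status ground truth matches the curation outcome", {
  cfg <- sim_config(n_reports = 400, out_of_window_fraction = 0.1, seed = 12)
  sim <- simulate_faers(cfg)
  ds <- build_dataset(sim$bundle, cfg$window)
  expect_equal(ds$provenance$window_excluded,
               sum(!sim$truth$report_status$in_window))
  kept_cases <- sub("[12]$", "", ds$demo$primaryid)
  expect_setequal(kept_cases,
                  sim$truth$report_status$caseid[
                    sim$truth$report_status$in_window])
})

test_that("expected_ror is lambda for injected pairs and 1 otherwise", {
  pairs <- data.frame(drug = c("REMDESIVIR", "TOCILIZUMAB"),
                      pt = c("Abortion", "Death neonatal"),
                      lambda = c(4.1, 2.5))
  cfg <- sim_config(injected_pairs = pairs)
  expect_equal(expected_ror(cfg, "REMDESIVIR", "Abortion"), 4.1)
  expect_equal(expected_ror(cfg, "TOCILIZUMAB", "Death neonatal"), 2.5)
  expect_equal(expected_ror(cfg, "REMDESIVIR", "Nausea"), 1.0)
  expect_equal(expected_ror(cfg, "HEPARIN", "Abortion"), 1.0)
  expect_error(expected_ror(cfg, "NOPE", "Nausea"), "unknown drug")
  expect_error(expected_ror(cfg, "HEPARIN", "Nope"), "unknown event")
})

test_that("config validation rejects infeasible parameterizations", {
  expect_error(sim_config(injected_pairs = data.frame(
    drug = "REMDESIVIR", pt = "Abortion", lambda = -1)), "lambda")
  expect_error(sim_config(injected_pairs = data.frame(
    drug = "REMDESIVIR", pt = "Unknown PT", lambda = 2)), "unknown label")
  expect_error(sim_config(duplicate_fraction = 1.2), "fractions")
  ev <- default_event_vocabulary()
  ev$prob[1] <- 1
  expect_error(sim_config(event_vocabulary = ev), "strictly in")
})

test_that("realized a-cell counts are calibrated to the model expectation", {
  pairs <- data.frame(drug = "REMDESIVIR", pt = "Headache", lambda = 2)
  a_seen <- vapply(1:20, function(s) {
    cfg <- sim_config(n_reports = 2000, injected_pairs = pairs, seed = 400 + s)
    sim <- simulate_faers(cfg)
    ds <- build_dataset(sim$bundle, cfg$window)
    tab <- build_contingency(ds, drug_query(c("REMDESIVIR", "VEKLURY")),
                             "Headache")
    tab$a
  }, numeric(1))
  cfg <- sim_config(n_reports = 2000, injected_pairs = pairs)
  sim <- simulate_faers(cfg)
  e_a <- sim$truth$pairs$expected_a
  se_mean <- stats::sd(a_seen) / sqrt(length(a_seen))
  expect_lt(abs(mean(a_seen) - e_a), 3 * se_mean + 1e-9)
})

test_that("pipeline ROR bias for an injected pair shrinks with sample size", {
  pairs <- data.frame(drug = "REMDESIVIR", pt = "Headache", lambda = 4)
  est_at <- function(n, seeds) {
    vapply(seeds, function(s) {
      cfg <- sim_config(n_reports = n, injected_pairs = pairs, seed = s)
      sim <- simulate_faers(cfg)
      ds <- build_dataset(sim$bundle, cfg$window)
      tab <- build_contingency(ds, drug_query(c("REMDESIVIR", "VEKLURY")),
                               "Headache")
      compute_ror(tab)$ror
    }, numeric(1))
  }
  small <- est_at(2000, 101:110)
  large <- est_at(20000, 111:115)
  expect_lt(abs(mean(large) - 4), abs(mean(small) - 4) + 0.35)
  expect_lt(abs(mean(large) - 4), 0.35)
})

test_that("the truth manifest round-trips key tallies to disk", {
  cfg <- sim_config(n_reports = 100, seed = 2,
                    injected_pairs = data.frame(drug = "HEPARIN",
                                                pt = "Rash", lambda = 3))
  sim <- simulate_faers(cfg)
  path <- file.path(withr::local_tempdir(), "truth.tsv")
  write_truth_manifest(sim$truth, path)
  lines <- readLines(path)
  expect_match(lines[1], "cases=100")
  tab <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1)
  expect_equal(tab$expected_ror, 3)
})
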