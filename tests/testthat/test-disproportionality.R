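# ROR, Wald CI, sentinel and signal rule; oracle equivalence.

test_that("ROR and Wald CI match the closed form and the regression oracle", {
  est <- compute_ror(contingency_table(10, 10, 10, 10))
  expect_equal(est$ror, 1.0)
  expect_equal(est$ci_low, exp(-1.96 * sqrt(0.4)), tolerance = 1e-10)
  expect_equal(est$ci_high, exp(1.96 * sqrt(0.4)), tolerance = 1e-10)
  expect_equal(est$ci_low, 0.2895, tolerance = 1e-3)
  expect_equal(est$ci_high, 3.4542, tolerance = 1e-3)

  est2 <- compute_ror(contingency_table(3, 7, 30, 700))
  expect_equal(est2$ror, 10.0)
  expect_equal(est2$ci_low, 2.463, tolerance = 1e-3)
  expect_equal(est2$ci_high, 40.594, tolerance = 1e-3)

  for (cells in list(c(10, 10, 10, 10), c(3, 7, 30, 700), c(5, 120, 33, 4000),
                     c(70, 7077, 12000, 4500000))) {
    est <- compute_ror(do.call(contingency_table, as.list(cells)))
    oracle <- glm_odds_ratio(cells[1], cells[2], cells[3], cells[4])
    expect_equal(est$ror, unname(oracle["or"]), tolerance = 1e-4)
    expect_equal(est$ci_low, unname(oracle["lo"]), tolerance = 1e-4)
    expect_equal(est$ci_high, unname(oracle["hi"]), tolerance = 1e-4)
  }
})

test_that("c = 0 yields the 99.9 sentinel; other zero cells are non-computable", {
  s <- compute_ror(contingency_table(5, 95, 0, 900))
  expect_true(s$sentinel)
  expect_identical(s$ror, 99.9)
  expect_true(is.na(s$ci_low) && is.na(s$ci_high))

  nc <- compute_ror(contingency_table(0, 100, 10, 900))
  expect_false(nc$sentinel)
  expect_false(nc$computable)
  expect_true(is.na(nc$ror))
  nc2 <- compute_ror(contingency_table(5, 0, 10, 900))
  expect_false(nc2$sentinel || nc2$computable)
  expect_error(contingency_table(-1, 2, 3, 4), "non-negative")
})

test_that("signal rule: frequency >= 3 and strictly ci_low > 1, sentinel included", {
  sig <- compute_ror(contingency_table(3, 100, 20, 6000))
  expect_true(sig$ci_low > 1)
  expect_true(classify_signal(3, sig))
  expect_false(classify_signal(2, sig))
  # an estimate whose lower bound is exactly 1 is not a signal
  at_one <- structure(list(ror = 2, ci_low = 1, ci_high = 4,
                           sentinel = FALSE, computable = TRUE),
                      class = "ror_estimate")
  expect_false(classify_signal(10, at_one))
  expect_true(classify_signal(3, compute_ror(contingency_table(3, 7, 0, 90))))
  expect_false(classify_signal(3, compute_ror(contingency_table(3, 0, 5, 90))))
})

test_that("2x2 symmetry: transpose preserves ROR, row swap inverts it", {
  est <- compute_ror(contingency_table(8, 40, 15, 300))
  transposed <- compute_ror(contingency_table(8, 15, 40, 300))
  swapped <- compute_ror(contingency_table(15, 300, 8, 40))
  expect_equal(est$ror, transposed$ror)
  expect_equal(est$ror, 1 / swapped$ror)
})

test_that("ROR increases strictly in a with the other cells fixed", {
  rors <- vapply(1:10, function(a) {
    compute_ror(contingency_table(a, 50, 20, 400))$ror
  }, numeric(1))
  expect_true(all(diff(rors) > 0))
})

test_that("contingency cells partition the dataset and match brute force", {
  ds <- random_tiny_dataset(n = 80, seed = 21)
  q <- drug_query(c("remdesivir", "veklury"))
  n <- nrow(ds$demo)
  for (pt in c("Abortion", "Nausea", "Headache", "Unseen term")) {
    tab <- build_contingency(ds, q, pt)
    expect_equal(tab$a + tab$b + tab$c + tab$d, n)
    oracle <- brute_force_contingency(ds, q$names, q$role_filter, pt)
    expect_equal(c(a = tab$a, b = tab$b, c = tab$c, d = tab$d), oracle)
  }
  tab0 <- build_contingency(ds, q, "Unseen term")
  expect_equal(tab0$a, 0L)
  expect_equal(tab0$c, 0L)
})

test_that("every report having drug and event gives the degenerate partition", {
  demo <- data.frame(primaryid = c("11", "21"), caseid = c("1", "2"),
                     caseversion = "1", event_dt = "20210101",
                     fda_dt = "20210201")
  drug <- data.frame(primaryid = c("11", "21"), drug_seq = "1",
                     role_cod = "PS", drugname = "REMDESIVIR", prod_ai = NA)
  reac <- data.frame(primaryid = c("11", "21"), pt = "Nausea")
  ds <- build_dataset(quarter_bundle(demo, drug, reac, source_label = "X"),
                      c("2020-01-01", "2022-12-31"))
  tab <- build_contingency(ds, drug_query("remdesivir"), "Nausea")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(2L, 0L, 0L, 0L))
})

test_that("scan_signals equals the brute-force scan on small universes", {
  for (seed in c(2, 13)) {
    ds <- random_tiny_dataset(n = 120, seed = seed)
    q <- drug_query(c("remdesivir", "veklury"))
    got <- scan_signals(ds, q)
    oracle <- brute_force_scan(ds, q$names, q$role_filter)
    got <- got[order(got$pt), ]
    expect_equal(got$pt, oracle$pt)
    expect_equal(got$a, unname(oracle$a))
    expect_equal(got$b, unname(oracle$b))
    expect_equal(got$c, unname(oracle$c))
    expect_equal(got$d, unname(oracle$d))
  }
})

test_that("scan respects frequency thresholds and flags a >= 5", {
  m <- fixture_manifest()
  ds <- build_dataset(make_demo_fixture(), m$window)
  q <- drug_query(m$query_names)
  got <- scan_signals(ds, q)
  got <- got[order(got$pt), ]
  expect_same_table(got, m$scan,
                    cols = c("pt", "a", "b", "c", "d", "sentinel",
                             "is_signal", "a_ge_5"))
  # raising the threshold can only shrink the pair list
  got5 <- scan_signals(ds, q, min_frequency = 5)
  expect_true(all(got5$pt %in% got$pt))
  expect_equal(got5$pt, "Foetal death")
  # no study-drug reports -> empty result
  empty <- scan_signals(ds, drug_query("nonexistentdrug"))
  expect_equal(nrow(empty), 0L)
})

test_that("comparator switch removes non-PS study-drug reports from the universe", {
  ds <- build_dataset(make_demo_fixture(), fixture_manifest()$window)
  q <- drug_query(c("remdesivir", "veklury"))
  default <- build_contingency(ds, q, "Headache")
  strict <- build_contingency(ds, q, "Headache",
                              comparator = "exclude_any_role")
  # the fixture has exactly one report carrying remdesivir as a concomitant
  expect_equal(default$n - strict$n, 1L)
  expect_equal(default$a, strict$a)
})
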