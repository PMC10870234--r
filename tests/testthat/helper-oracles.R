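# Independent oracles used by the unit and acceptance suites. These are
# deliberately naive: the brute-force contingency classifier loops over
# reports and re-implements name matching by token splitting, and the 2x2
# odds-ratio oracle goes through logistic regression rather than the
# pipeline's closed form.

# Per-report brute-force classification into the 2x2 cells.
brute_force_contingency <- function(dataset, names, roles, pt) {
  names <- tolower(names)
  ids <- dataset$demo$primaryid
  drug_pos <- vapply(ids, function(id) {
    rows <- dataset$drug[dataset$drug$primaryid == id, , drop = FALSE]
    any(vapply(seq_len(nrow(rows)), function(i) {
      if (!(rows$role_cod[i] %in% roles)) return(FALSE)
      toks <- tolower(unlist(strsplit(
        c(rows$drugname[i], rows$prod_ai[i]), "[^A-Za-z0-9]+")))
      any(toks %in% names)
    }, logical(1)))
  }, logical(1))
  event_pos <- vapply(ids, function(id) {
    any(trimws(dataset$reac$pt[dataset$reac$primaryid == id]) == pt,
        na.rm = TRUE)
  }, logical(1))
  c(a = sum(drug_pos & event_pos), b = sum(drug_pos & !event_pos),
    c = sum(!drug_pos & event_pos), d = sum(!drug_pos & !event_pos))
}

# Brute-force signal scan: enumerate every PT seen in the drug's reports.
brute_force_scan <- function(dataset, names, roles, min_frequency = 3) {
  all_pts <- sort(unique(trimws(dataset$reac$pt)))
  rows <- lapply(all_pts, function(pt) {
    cells <- brute_force_contingency(dataset, names, roles, pt)
    if (cells["a"] < min_frequency) return(NULL)
    data.frame(pt = pt, a = cells["a"], b = cells["b"], c = cells["c"],
               d = cells["d"], stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out[order(out$pt), , drop = FALSE]
}

# Wald odds ratio and 95% CI via logistic regression: an independent route
# to the same estimand (coefficient = log OR, Wald SE = sqrt(sum 1/cell)).
glm_odds_ratio <- function(a, b, c, d) {
  fit <- stats::glm(cbind(c(a, c), c(b, d)) ~ c(1, 0), family = binomial())
  beta <- unname(stats::coef(fit)[2])
  se <- unname(sqrt(diag(stats::vcov(fit)))[2])
  c(or = exp(beta), lo = exp(beta - 1.96 * se), hi = exp(beta + 1.96 * se))
}

# Small random dataset builder for property tests (independent of the
# synthetic generator's model).
random_tiny_dataset <- function(n = 60, seed = 1) {
  set.seed(seed)
  drugs <- c("REMDESIVIR", "VEKLURY", "IBUPROFEN", "HEPARIN", "INSULIN")
  pts <- c("Nausea", "Headache", "Abortion", "Rash", "Pyrexia")
  id <- as.character(5000 + seq_len(n))
  demo <- data.frame(
    primaryid = paste0(id, "1"), caseid = id, caseversion = "1",
    event_dt = format(as.Date("2020-01-01") + sample(0:1000, n, TRUE),
                      "%Y%m%d"),
    fda_dt = "20230101", age = "50", age_cod = "YR", sex = "F",
    occp_cod = "MD", stringsAsFactors = FALSE
  )
  drug <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    data.frame(primaryid = demo$primaryid[i], drug_seq = as.character(1:k),
               role_cod = c("PS", sample(c("SS", "C", "I"), k - 1, TRUE)),
               drugname = sample(drugs, k), prod_ai = NA,
               stringsAsFactors = FALSE)
  }))
  reac <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:3, 1)
    data.frame(primaryid = demo$primaryid[i], pt = sample(pts, k),
               stringsAsFactors = FALSE)
  }))
  b <- quarter_bundle(demo, drug, reac, source_label = "RND")
  build_dataset(b, c("2019-01-01", "2023-12-31"))
}

expect_same_table <- function(df1, df2, cols = names(df1)) {
  df1 <- as.data.frame(df1)[, cols, drop = FALSE]
  df2 <- as.data.frame(df2)[, cols, drop = FALSE]
  rownames(df1) <- rownames(df2) <- NULL
  expect_equal(df1, df2)
}
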