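# Synthetic FAERS-format generator with analytically known ground truth.
#
# Each report draws one primary-suspect (PS) drug from the drug vocabulary's
# marginal probabilities; other drugs join the report independently as
# secondary suspect / concomitant / interacting records. Event terms enter a
# report independently with their background probability p, i.e. odds
# o = p/(1-p); an injected pair (drug g, event e, lambda) multiplies e's
# *odds* by lambda in reports where g is the PS drug. Because enrichment is
# multiplicative on the odds, the population reporting odds ratio of an
# injected pair equals lambda exactly and no probability can exceed 1.
# A report whose independent draws produce no event receives a dedicated
# filler term outside the analysis vocabulary, so the one-event-minimum
# holds without disturbing the vocabulary terms' independence.

FILLER_PT <- "Adverse event"

#' Default vocabularies of the synthetic generator
#'
#' Ten drugs with primary-suspect marginal probabilities summing to 1, and
#' two dozen event Preferred Terms with background report-level inclusion
#' probabilities between 0.8% and 12%.
#'
#' @return data frame `drug`/`prob` or `pt`/`prob`.
#' @export
default_drug_vocabulary <- function() {
  data.frame(
    drug = c("REMDESIVIR", "TOCILIZUMAB", "DEXAMETHASONE", "PARACETAMOL",
             "IBUPROFEN", "HEPARIN", "AZITHROMYCIN", "ENOXAPARIN",
             "METHOTREXATE", "INSULIN"),
    prob = c(0.12, 0.10, 0.10, 0.12, 0.11, 0.09, 0.10, 0.08, 0.08, 0.10),
    stringsAsFactors = FALSE
  )
}

#' @rdname default_drug_vocabulary
#' @export
default_event_vocabulary <- function() {
  data.frame(
    pt = c("Nausea", "Headache", "Pyrexia", "Fatigue", "Diarrhoea",
           "Vomiting", "Rash", "Dizziness", "Dyspnoea", "Pruritus",
           "Alanine aminotransferase increased", "Renal impairment",
           "Bradycardia", "Hepatotoxicity", "Anaemia", "Insomnia",
           "Hypotension", "Cough", "Abortion", "Foetal death",
           "Premature delivery", "Death neonatal",
           "Maternal exposure during pregnancy", "Drug ineffective"),
    prob = c(0.12, 0.10, 0.08, 0.09, 0.08,
             0.07, 0.06, 0.06, 0.05, 0.04,
             0.03, 0.03, 0.02, 0.02, 0.04, 0.03,
             0.04, 0.05, 0.01, 0.01, 0.012, 0.008, 0.015, 0.10),
    stringsAsFactors = FALSE
  )
}

default_brand_names <- function() {
  c(REMDESIVIR = "VEKLURY", TOCILIZUMAB = "ACTEMRA")
}

#' Configuration of the synthetic FAERS generator
#'
#' Defaults emulate a modest spontaneous-reporting universe: ten drugs, two
#' dozen event terms at background frequencies between 0.8% and 12%, about
#' 1.5 non-primary-suspect drug records per report, 5% of cases re-filed at
#' a higher case version, 2% of event dates falling outside the study
#' window, and missingness rates for age / sex / reporter occupation in the
#' range seen in spontaneous reports.
#'
#' @param n_reports number of base cases (before duplicate versions).
#' @param drug_vocabulary data frame `drug`, `prob` (PS marginal
#'   probabilities; must sum to 1).
#' @param event_vocabulary data frame `pt`, `prob` (background inclusion
#'   probabilities, each in (0,1)).
#' @param injected_pairs `NULL` or data frame `drug`, `pt`, `lambda`
#'   (odds multiplier > 0 applied when the drug is the PS).
#' @param concomitant_intensity expected number of extra (non-PS) drug
#'   records per report.
#' @param role_ratios probabilities of roles SS/C/I for extra drug records.
#' @param duplicate_fraction fraction of cases re-emitted at caseversion 2.
#' @param out_of_window_fraction fraction of cases dated outside `window`.
#' @param month_precision_fraction fraction of in-window event dates
#'   degraded to year-month precision.
#' @param missing_age_fraction,missing_sex_fraction,missing_occp_fraction
#'   per-field missingness.
#' @param occupation_distribution named probabilities over occupation codes.
#' @param outcome_mean Poisson mean of outcome records per report.
#' @param outcome_distribution named probabilities over outcome codes.
#' @param indication_rules named list of data frames `pt`, `prob` keyed by
#'   drug name, with a `default` entry; probabilities may sum to < 1, the
#'   remainder meaning "no indication recorded".
#' @param brand_names named map INN -> brand; a report's verbatim
#'   `drugname` uses the brand for roughly half the records of such drugs.
#' @param window inclusive event-date window (two ISO dates).
#' @param seed integer seed; the generator is fully reproducible from it.
#' @return a validated `sim_config`.
#' @export
sim_config <- function(n_reports = 2000,
                       drug_vocabulary = default_drug_vocabulary(),
                       event_vocabulary = default_event_vocabulary(),
                       injected_pairs = NULL,
                       concomitant_intensity = 1.5,
                       role_ratios = c(SS = 0.25, C = 0.65, I = 0.10),
                       duplicate_fraction = 0.05,
                       out_of_window_fraction = 0.02,
                       month_precision_fraction = 0.08,
                       missing_age_fraction = 0.15,
                       missing_sex_fraction = 0.08,
                       missing_occp_fraction = 0.03,
                       occupation_distribution =
                         c(MD = 0.20, PH = 0.30, OT = 0.22,
                           LW = 0.002, CN = 0.278),
                       outcome_mean = 0.9,
                       outcome_distribution =
                         c(DE = 0.17, CA = 0.002, LT = 0.04, DS = 0.03,
                           RI = 0.01, HO = 0.23, OT = 0.518),
                       indication_rules = list(
                         default = data.frame(
                           pt = c("COVID-19",
                                  "Product used for unknown indication"),
                           prob = c(0.60, 0.25), stringsAsFactors = FALSE)),
                       brand_names = default_brand_names(),
                       window = c("2020-01-01", "2022-12-31"),
                       seed = 1L) {
  stopifnot(n_reports >= 1)
  if (nrow(drug_vocabulary) == 0L || nrow(event_vocabulary) == 0L) {
    stop("vocabularies must be non-empty", call. = FALSE)
  }
  if (abs(sum(drug_vocabulary$prob) - 1) > 1e-8) {
    stop("drug vocabulary probabilities must sum to 1", call. = FALSE)
  }
  if (any(event_vocabulary$prob <= 0) || any(event_vocabulary$prob >= 1)) {
    stop("event probabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  if (anyDuplicated(drug_vocabulary$drug) || anyDuplicated(event_vocabulary$pt)) {
    stop("vocabulary labels must be unique", call. = FALSE)
  }
  if (!is.null(injected_pairs) && nrow(injected_pairs)) {
    stopifnot(all(c("drug", "pt", "lambda") %in% names(injected_pairs)))
    if (any(injected_pairs$lambda <= 0)) {
      stop("injected lambda must be > 0", call. = FALSE)
    }
    bad_d <- setdiff(injected_pairs$drug, drug_vocabulary$drug)
    bad_e <- setdiff(injected_pairs$pt, event_vocabulary$pt)
    if (length(bad_d) || length(bad_e)) {
      stop("injected pair references unknown label(s): ",
           paste(c(bad_d, bad_e), collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(injected_pairs[, c("drug", "pt")])) {
      stop("injected pairs must be unique", call. = FALSE)
    }
  }
  fr <- c(duplicate_fraction, out_of_window_fraction,
          month_precision_fraction, missing_age_fraction,
          missing_sex_fraction, missing_occp_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]",
                                 call. = FALSE)
  stopifnot(all(names(occupation_distribution) %in% OCCP_CODES),
            all(names(outcome_distribution) %in% names(OUTCOME_LABELS)),
            "default" %in% names(indication_rules))
  structure(
    list(n_reports = as.integer(n_reports),
         drug_vocabulary = drug_vocabulary,
         event_vocabulary = event_vocabulary,
         injected_pairs = injected_pairs,
         concomitant_intensity = concomitant_intensity,
         role_ratios = role_ratios / sum(role_ratios),
         duplicate_fraction = duplicate_fraction,
         out_of_window_fraction = out_of_window_fraction,
         month_precision_fraction = month_precision_fraction,
         missing_age_fraction = missing_age_fraction,
         missing_sex_fraction = missing_sex_fraction,
         missing_occp_fraction = missing_occp_fraction,
         occupation_distribution =
           occupation_distribution / sum(occupation_distribution),
         outcome_mean = outcome_mean,
         outcome_distribution =
           outcome_distribution / sum(outcome_distribution),
         indication_rules = indication_rules,
         brand_names = brand_names,
         window = as_window(window),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Expected reporting odds ratio under the generative model
#'
#' Under odds-multiplicative enrichment the population ROR of an injected
#' pair equals its lambda exactly; any other drug-event pair from the
#' vocabularies is independent and has expected ROR 1.
#'
#' @param config a [sim_config()].
#' @param drug,pt labels from the config's vocabularies.
#' @return positive scalar.
#' @export
expected_ror <- function(config, drug, pt) {
  stopifnot(inherits(config, "sim_config"))
  if (!(drug %in% config$drug_vocabulary$drug)) {
    stop("unknown drug label: ", drug, call. = FALSE)
  }
  if (!(pt %in% config$event_vocabulary$pt)) {
    stop("unknown event label: ", pt, call. = FALSE)
  }
  ip <- config$injected_pairs
  if (!is.null(ip) && nrow(ip)) {
    hit <- ip$drug == drug & ip$pt == pt
    if (any(hit)) return(ip$lambda[hit][1])
  }
  1.0
}

# Expected contingency cells for a pair over the in-window case universe.
expected_cells <- function(config, drug, pt, n_in_window) {
  p_g <- config$drug_vocabulary$prob[config$drug_vocabulary$drug == drug]
  p_e <- config$event_vocabulary$prob[config$event_vocabulary$pt == pt]
  lam <- expected_ror(config, drug, pt)
  o <- p_e / (1 - p_e)
  p_lam <- lam * o / (1 + lam * o)
  c(a = n_in_window * p_g * p_lam,
    b = n_in_window * p_g * (1 - p_lam),
    c = n_in_window * (1 - p_g) * p_e,
    d = n_in_window * (1 - p_g) * (1 - p_e))
}

#' Simulate a FAERS-format quarter with known ground truth
#'
#' Emits a `quarter_bundle` in the exact dialect [read_quarter()] consumes,
#' plus a ground-truth record: per injected pair the expected contingency
#' cells and expected ROR over the in-window universe, and per case its
#' window status and duplicate lineage. Fully reproducible from the config's
#' seed.
#'
#' @param config a [sim_config()].
#' @param source_label quarter tag for the emitted bundle.
#' @return list with `bundle` (a `quarter_bundle`) and `truth`.
#' @export
simulate_faers <- function(config, source_label = "SIMQ1") {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_faers_impl(config, source_label))
}

simulate_faers_impl <- function(config, source_label) {
  n <- config$n_reports
  dv <- config$drug_vocabulary
  ev <- config$event_vocabulary
  caseid <- as.character(1000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  # --- dates ---------------------------------------------------------------
  w <- config$window
  n_out <- round(config$out_of_window_fraction * n)
  out_idx <- if (n_out > 0) sample.int(n, n_out) else integer(0)
  days_in <- as.integer(w[2] - w[1])
  event_date <- w[1] + sample.int(days_in + 1L, n, replace = TRUE) - 1L
  if (n_out > 0) {
    before <- runif(n_out) < 0.5
    off <- sample.int(365L, n_out, replace = TRUE)
    event_date[out_idx] <- as.Date(ifelse(before, w[1] - off, w[2] + off),
                                   origin = "1970-01-01")
  }
  event_dt <- format(event_date, "%Y%m%d")
  in_window <- !(seq_len(n) %in% out_idx)
  n_month <- round(config$month_precision_fraction * sum(in_window))
  if (n_month > 0) {
    mi <- sample(which(in_window), n_month)
    event_dt[mi] <- substr(event_dt[mi], 1, 6)
  }
  fda_dt <- format(event_date + sample.int(120L, n, replace = TRUE),
                   "%Y%m%d")

  # --- demographics --------------------------------------------------------
  age <- pmin(pmax(round(rnorm(n, 52, 17)), 0), 100)
  age[runif(n) < config$missing_age_fraction] <- NA
  sex <- sample(c("F", "M"), n, replace = TRUE, prob = c(0.55, 0.45))
  sex[runif(n) < config$missing_sex_fraction] <- NA
  od <- config$occupation_distribution
  occp <- sample(names(od), n, replace = TRUE, prob = od)
  occp[runif(n) < config$missing_occp_fraction] <- NA
  demo <- data.frame(
    primaryid = primaryid, caseid = caseid, caseversion = "1",
    event_dt = event_dt, fda_dt = fda_dt,
    age = ifelse(is.na(age), NA_character_, as.character(age)),
    age_cod = ifelse(is.na(age), NA_character_, "YR"),
    sex = sex, occp_cod = occp, stringsAsFactors = FALSE
  )

  # --- drugs ---------------------------------------------------------------
  ps_drug <- sample(dv$drug, n, replace = TRUE, prob = dv$prob)
  brand <- config$brand_names
  verbatim <- function(inn) {
    has_brand <- inn %in% names(brand)
    use_brand <- has_brand & runif(length(inn)) < 0.5
    ifelse(use_brand, unname(brand[inn]), inn)
  }
  drug_rows <- list(data.frame(
    primaryid = primaryid, drug_seq = 1L, role_cod = "PS",
    drugname = verbatim(ps_drug), prod_ai = ps_drug,
    stringsAsFactors = FALSE
  ))
  q_extra <- pmin(1, config$concomitant_intensity * dv$prob)
  extra_mat <- matrix(runif(n * nrow(dv)) < rep(q_extra, each = n), n)
  extra_mat[cbind(seq_len(n), match(ps_drug, dv$drug))] <- FALSE
  hit <- which(extra_mat, arr.ind = TRUE)
  if (nrow(hit)) {
    ord <- order(hit[, 1], hit[, 2])
    hit <- hit[ord, , drop = FALSE]
    seq_within <- stats::ave(hit[, 1], hit[, 1], FUN = seq_along) + 1L
    inn <- dv$drug[hit[, 2]]
    drug_rows[[2]] <- data.frame(
      primaryid = primaryid[hit[, 1]], drug_seq = as.integer(seq_within),
      role_cod = sample(names(config$role_ratios), nrow(hit),
                        replace = TRUE, prob = config$role_ratios),
      drugname = verbatim(inn), prod_ai = inn, stringsAsFactors = FALSE
    )
  }
  drug <- do.call(rbind, drug_rows)

  # --- events --------------------------------------------------------------
  p_mat <- matrix(rep(ev$prob, each = n), n)
  ip <- config$injected_pairs
  if (!is.null(ip) && nrow(ip)) {
    for (k in seq_len(nrow(ip))) {
      rows <- ps_drug == ip$drug[k]
      col <- match(ip$pt[k], ev$pt)
      o <- ev$prob[col] / (1 - ev$prob[col])
      p_mat[rows, col] <- ip$lambda[k] * o / (1 + ip$lambda[k] * o)
    }
  }
  ev_mat <- matrix(runif(n * nrow(ev)) < p_mat, n)
  hit <- which(ev_mat, arr.ind = TRUE)
  reac <- data.frame(primaryid = primaryid[hit[, 1]], pt = ev$pt[hit[, 2]],
                     stringsAsFactors = FALSE)
  none <- which(rowSums(ev_mat) == 0L)
  if (length(none)) {
    reac <- rbind(reac, data.frame(primaryid = primaryid[none],
                                   pt = FILLER_PT, stringsAsFactors = FALSE))
  }

  # --- outcomes ------------------------------------------------------------
  k_out <- rpois(n, config$outcome_mean)
  outc <- data.frame(
    primaryid = rep(primaryid, k_out),
    outc_cod = sample(names(config$outcome_distribution), sum(k_out),
                      replace = TRUE, prob = config$outcome_distribution),
    stringsAsFactors = FALSE
  )
  outc <- unique(outc)

  # --- indications (attached to the PS drug record) ------------------------
  rules <- config$indication_rules
  rule_for <- function(d) rules[[d]] %||% rules$default
  indi_rows <- lapply(unique(ps_drug), function(d) {
    idx <- which(ps_drug == d)
    r <- rule_for(d)
    cut <- cumsum(r$prob)
    u <- runif(length(idx))
    pick <- findInterval(u, c(0, cut), left.open = TRUE)
    has <- pick >= 1 & pick <= nrow(r)
    data.frame(primaryid = primaryid[idx[has]], indi_drug_seq = 1L,
               indi_pt = r$pt[pick[has]], stringsAsFactors = FALSE)
  })
  indi <- do.call(rbind, indi_rows)

  # --- duplicate versions --------------------------------------------------
  n_dup <- round(config$duplicate_fraction * n)
  dup_idx <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  if (n_dup > 0) {
    v2_id <- paste0(caseid[dup_idx], "2")
    v2 <- demo[dup_idx, , drop = FALSE]
    v2$primaryid <- v2_id
    v2$caseversion <- "2"
    v2$fda_dt <- format(as.Date(v2$fda_dt, "%Y%m%d") + 30L, "%Y%m%d")
    demo <- rbind(demo, v2)
    clone <- function(df) {
      sub <- df[df$primaryid %in% primaryid[dup_idx], , drop = FALSE]
      sub$primaryid <- paste0(substr(sub$primaryid, 1,
                                     nchar(sub$primaryid) - 1L), "2")
      sub
    }
    drug <- rbind(drug, clone(drug))
    reac <- rbind(reac, clone(reac))
    outc <- rbind(outc, clone(outc))
    if (!is.null(indi) && nrow(indi)) indi <- rbind(indi, clone(indi))
  }

  sort_rows <- function(df, cols) {
    df[do.call(order, c(unname(df[cols]), list(method = "radix"))), ,
       drop = FALSE]
  }
  bundle <- quarter_bundle(
    demo = sort_rows(demo, "primaryid"),
    drug = sort_rows(drug, c("primaryid", "drug_seq")),
    reac = sort_rows(reac, c("primaryid", "pt")),
    outc = sort_rows(outc, c("primaryid", "outc_cod")),
    indi = if (is.null(indi)) NULL else
      sort_rows(indi, c("primaryid", "indi_drug_seq", "indi_pt")),
    source_label = source_label
  )

  n_in <- n - n_out
  pair_truth <- NULL
  if (!is.null(ip) && nrow(ip)) {
    cells <- t(vapply(seq_len(nrow(ip)), function(k) {
      expected_cells(config, ip$drug[k], ip$pt[k], n_in)
    }, numeric(4)))
    pair_truth <- data.frame(ip, expected_a = cells[, 1],
                             expected_b = cells[, 2],
                             expected_c = cells[, 3],
                             expected_d = cells[, 4],
                             expected_ror = ip$lambda,
                             stringsAsFactors = FALSE)
  }
  truth <- list(
    pairs = pair_truth,
    report_status = data.frame(
      caseid = caseid, primaryid = primaryid, in_window = in_window,
      has_duplicate = seq_len(n) %in% dup_idx, stringsAsFactors = FALSE
    ),
    n_cases = n, n_in_window = n_in, n_duplicates = n_dup,
    ps_drug = ps_drug
  )
  list(bundle = bundle, truth = truth)
}

#' Write a ground-truth manifest alongside simulated quarters
#'
#' @param truth the `truth` element of [simulate_faers()].
#' @param path output file (tab-delimited).
#' @return invisibly, `path`.
#' @export
write_truth_manifest <- function(truth, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# cases=%d in_window=%d duplicates=%d",
                     truth$n_cases, truth$n_in_window, truth$n_duplicates),
             con)
  if (!is.null(truth$pairs)) {
    utils::write.table(truth$pairs, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
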