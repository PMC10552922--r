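# Synthetic FAERS-like report corpora with known ground truth, and the
# constraint-satisfaction builder for the 43-case fixture.

# run code under a temporary, fully specified RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Configuration for the synthetic report generator
#'
#' Defaults describe a plausible spontaneous-report corpus in which HIT is a
#' rare event: one drug per report drawn from a mixed prescription pool
#' (three LMWHs plus common background drugs), a 1% background HIT reporting
#' probability, a designated target drug whose HIT odds are multiplied by
#' `target_or`, 5% of cases resubmitted as a higher version, and modest
#' demographic missingness.
#'
#' @param n_reports number of unique cases to draw (> 0).
#' @param drugs named numeric of per-report exposure probabilities, summing
#'   to 1 (exactly one drug per report, which keeps the ground-truth 2x2
#'   table unambiguous).
#' @param background_event_prob probability of the HIT preferred term for a
#'   report on a non-target drug, in (0, 1).
#' @param target_drug the drug carrying the injected association.
#' @param target_or odds ratio linking `target_drug` to the HIT preferred
#'   term (> 0): the event probability for exposed reports is
#'   `plogis(qlogis(p0) + log(target_or))`, so `target_or` is the exact
#'   conditional odds ratio, not an approximation.
#' @param duplicate_rate fraction of cases resubmitted with an incremented
#'   case version, in `[0, 1)`.
#' @param missingness per-field missing probabilities, a named list with
#'   elements `age`, `country` (sex falls back to `"unknown"` at rate
#'   `sex`).
#' @param seed integer seed driving all sampling.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_reports = 20000,
                       drugs = c(enoxaparin = 0.10, dalteparin = 0.03,
                                 tinzaparin = 0.02, warfarin = 0.20,
                                 aspirin = 0.30, metformin = 0.35),
                       background_event_prob = 0.01,
                       target_drug = "enoxaparin",
                       target_or = 1,
                       duplicate_rate = 0.05,
                       missingness = list(age = 0.10, sex = 0.05,
                                          country = 0.05),
                       seed = 1L) {
  stopifnot_scalar_number(n_reports, "n_reports", lower = 1)
  stopifnot_scalar_number(background_event_prob, "background_event_prob", 0)
  stopifnot_scalar_number(target_or, "target_or", 0)
  stopifnot_scalar_number(duplicate_rate, "duplicate_rate", 0)
  if (is.null(names(drugs)) || abs(sum(drugs) - 1) > 1e-8 || any(drugs < 0)) {
    stop("`drugs` must be named exposure probabilities summing to 1",
         call. = FALSE)
  }
  if (!target_drug %in% names(drugs)) {
    stop("`target_drug` must appear in `drugs`", call. = FALSE)
  }
  if (duplicate_rate >= 1) stop("`duplicate_rate` must be < 1", call. = FALSE)
  p_exposed <- plogis(qlogis(background_event_prob) + log(target_or))
  if (background_event_prob <= 0 || background_event_prob >= 1 ||
      p_exposed >= 1) {
    stop("implied event probability outside (0, 1); lower ",
         "`background_event_prob` or `target_or`", call. = FALSE)
  }
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 background_event_prob = background_event_prob,
                 target_drug = target_drug, target_or = target_or,
                 duplicate_rate = duplicate_rate, missingness = missingness,
                 seed = as.integer(seed)),
            class = "sim_config")
}

BACKGROUND_PTS <- c("Nausea", "Headache", "Dizziness", "Rash", "Fatigue",
                    "Diarrhoea", "Pyrexia", "Vomiting")
SIM_COUNTRIES <- c("US", "FR", "DE", "JP", "GB", "CN")

#' Generate a synthetic AE report corpus with known ground truth
#'
#' Draws `n_reports` unique cases: one drug per report (categorical over the
#' configured exposure probabilities), the HIT preferred term assigned with
#' probability `p0` off the target drug and `plogis(qlogis(p0) +
#' log(target_or))` on it, demographics with configured missingness, then a
#' `duplicate_rate` fraction of cases re-emitted as version 2 with a later
#' receipt date. The returned ground truth carries the realized 2x2 table
#' (computed on the unique cases before duplication), the injected odds
#' ratio and the duplicated case ids, so deduplication and screening can be
#' verified against truth.
#'
#' @param cfg a [sim_config()].
#' @return list with `reports` (AE report tibble, duplicates interleaved)
#'   and `truth` (list: `table` a [contingency_table()], `target_or`,
#'   `target_drug`, `duplicated_case_ids`, `config`).
#' @export
generate_reports <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_reports
    drug <- sample(names(cfg$drugs), n, replace = TRUE, prob = cfg$drugs)
    exposed <- drug == cfg$target_drug
    p0 <- cfg$background_event_prob
    p1 <- plogis(qlogis(p0) + log(cfg$target_or))
    event <- runif(n) < ifelse(exposed, p1, p0)
    reaction <- ifelse(event,
                       sample(hit_pt_keywords(), n, replace = TRUE,
                              prob = c(0.8, 0.1, 0.1)),
                       sample(BACKGROUND_PTS, n, replace = TRUE))
    age <- round(pmin(pmax(rnorm(n, 62, 18), 0), 100), 0)
    age[runif(n) < (cfg$missingness$age %||% 0)] <- NA_real_
    sex <- sample(c("female", "male"), n, replace = TRUE)
    sex[runif(n) < (cfg$missingness$sex %||% 0)] <- "unknown"
    outcome <- sample(c("death", "hospitalization", "life_threatening",
                        "disability", "other", NA_character_),
                      n, replace = TRUE,
                      prob = c(0.08, 0.35, 0.05, 0.04, 0.38, 0.10))
    country <- sample(SIM_COUNTRIES, n, replace = TRUE,
                      prob = c(0.40, 0.12, 0.12, 0.12, 0.12, 0.12))
    country[runif(n) < (cfg$missingness$country %||% 0)] <- NA_character_
    receipt <- as.Date("2020-01-01") + sample.int(900, n, replace = TRUE)
    case_id <- sprintf("SIM%07d", seq_len(n))

    reports <- tibble(
      case_id = case_id, case_version = 1L, receipt_date = receipt,
      age_years = age, sex = sex, outcome_code = outcome,
      reporter_country = country,
      drug_names = as.list(drug),
      drug_roles = rep(list("PS"), n),
      reactions = as.list(reaction)
    )

    n_dup <- floor(cfg$duplicate_rate * n)
    dup_ids <- character(0)
    if (n_dup > 0) {
      idx <- sample.int(n, n_dup)
      dup <- reports[idx, ]
      dup$case_version <- 2L
      dup$receipt_date <- dup$receipt_date + 30
      dup_ids <- dup$case_id
      reports <- dplyr::bind_rows(reports, dup)
      reports <- reports[sample.int(nrow(reports)), ]
    }

    truth_table <- contingency_table(
      a = sum(exposed & event), b = sum(exposed & !event),
      c = sum(!exposed & event), d = sum(!exposed & !event)
    )
    list(reports = reports,
         truth = list(table = truth_table, target_or = cfg$target_or,
                      target_drug = cfg$target_drug,
                      duplicated_case_ids = dup_ids, config = cfg))
  })
}

# deal `counts[type]` copies of each item type to distinct cases among
# `eligible` (logical), never twice the same type to one case, always to the
# currently least-loaded cases (seeded tie-break): keeps set-valued
# variables spread so every eligible case ends non-empty when the item total
# allows it
deal_items <- function(n_cases, eligible, counts, tiebreak) {
  load <- ifelse(eligible, 0L, NA_integer_)
  sets <- vector("list", n_cases)
  for (item in names(sort(counts, decreasing = TRUE))) {
    k <- counts[[item]]
    if (k == 0) next
    ord <- order(load, tiebreak, na.last = TRUE)
    pick <- ord[seq_len(k)]
    if (any(is.na(load[pick]))) {
      stop(sprintf("cannot place %d copies of '%s' among %d eligible cases",
                   k, item, sum(eligible)), call. = FALSE)
    }
    for (i in pick) sets[[i]] <- c(sets[[i]], item)
    load[pick] <- load[pick] + 1L
  }
  sets
}

# expand per-drug band counts (+ NA count) into a within-drug permuted vector
expand_bands <- function(drug_vec, per_drug) {
  out <- rep(NA_character_, length(drug_vec))
  for (dg in names(per_drug)) {
    rows <- which(drug_vec == dg)
    spec <- per_drug[[dg]]
    values <- c(rep(names(spec$bands), spec$bands),
                rep(NA_character_, spec$na))
    if (length(values) != length(rows)) {
      stop(sprintf("band counts for %s sum to %d but the drug has %d cases",
                   dg, length(values), length(rows)), call. = FALSE)
    }
    out[rows] <- sample(values)
  }
  out
}

#' Build the 43-case fixture by constraint satisfaction
#'
#' Fills the joint attribute assignment so that every published
#' drug-stratified marginal of the case series is satisfied simultaneously:
#' drug-stratified bands are dealt within each drug, set-valued variables
#' are dealt to the least-loaded eligible cases, and purely marginal
#' variables are seeded permutations of their published multisets.
#' Cross-variable correlations not constrained by the published tables are
#' arbitrary. Deterministic given `seed`; the result is verified with
#' [check_case_series()] and a violated marginal raises a diagnostic error.
#'
#' @param seed integer seed, default 101 (the packaged fixture's seed).
#' @return case tibble of 43 rows.
#' @export
build_case_fixture <- function(seed = 101L) {
  cases <- with_seed(seed, {
    drug <- rep(c("enoxaparin", "nadroparin", "dalteparin", "tinzaparin",
                  "bemiparin"), c(21, 14, 4, 2, 2))
    n <- length(drug)
    tiebreak <- sample.int(n)

    perm <- function(levels, counts) sample(rep(levels, counts))
    sex <- perm(c("male", "female"), c(12, 31))
    age_band <- perm(c("<18", "18-60", ">60"), c(1, 15, 27))
    # indication counts sum to 44: one patient carries two primary diseases
    indication <- deal_items(n, rep(TRUE, n), c(
      embolism = 10, joint_operation = 9, fracture = 5, surgery = 5,
      dialysis = 4, tumor = 3, heart_failure = 3, traffic_accident = 2,
      infection = 2, pregnancy = 1
    ), sample.int(n))
    outcome <- perm(c("recovery", "worse", "death"), c(41, 1, 1))
    d_dimer <- perm(c("TRUE", "FALSE", NA), c(5, 6, 32))
    liver_kidney <- perm(c("TRUE", "FALSE", NA), c(5, 3, 35))

    bands <- function(...) list(bands = c(...), na = 0L)
    bands_na <- function(na, ...) list(bands = c(...), na = na)
    onset <- expand_bands(drug, list(
      enoxaparin = bands("<5" = 3, "5-10" = 13, ">10" = 5),
      nadroparin = bands("<5" = 1, "5-10" = 10, ">10" = 3),
      dalteparin = bands(">10" = 4),
      tinzaparin = bands("<5" = 1, ">10" = 1),
      bemiparin = bands("5-10" = 1, ">10" = 1)
    ))
    nadir <- expand_bands(drug, list(
      enoxaparin = bands("10-19" = 1, "20-49" = 8, "50-100" = 7, ">100" = 5),
      nadroparin = bands_na(3, "<10" = 1, "10-19" = 1, "20-49" = 2,
                            "50-100" = 5, ">100" = 2),
      dalteparin = bands("10-19" = 1, "20-49" = 1, "50-100" = 1, ">100" = 1),
      tinzaparin = bands("20-49" = 1, ">100" = 1),
      bemiparin = bands("20-49" = 1, "50-100" = 1)
    ))
    decrease <- expand_bands(drug, list(
      enoxaparin = bands("30-50" = 2, ">50" = 19),
      nadroparin = bands_na(5, "30-50" = 1, ">50" = 8),
      dalteparin = bands_na(1, ">50" = 3),
      tinzaparin = bands("<30" = 1, ">50" = 1),
      bemiparin = bands(">50" = 2)
    ))
    pf4 <- expand_bands(drug, list(
      enoxaparin = bands_na(4, positive = 17),
      nadroparin = bands_na(2, positive = 12),
      dalteparin = bands(positive = 4),
      tinzaparin = bands_na(1, positive = 1),
      bemiparin = bands(positive = 2)
    ))
    fourt <- expand_bands(drug, list(
      enoxaparin = bands_na(14, "4-5" = 1, "6-8" = 6),
      nadroparin = bands_na(5, "6-8" = 9),
      dalteparin = bands_na(2, "4-5" = 2),
      tinzaparin = bands_na(1, "6-8" = 1),
      bemiparin = bands("6-8" = 2)
    ))
    recovery <- expand_bands(drug, list(
      enoxaparin = bands_na(5, "<5" = 3, "5-10" = 11, ">10" = 2),
      nadroparin = bands_na(1, "<5" = 4, "5-10" = 4, ">10" = 5),
      dalteparin = bands_na(2, "<5" = 2),
      tinzaparin = bands_na(1, "5-10" = 1),
      bemiparin = bands("5-10" = 1, ">10" = 1)
    ))

    hist_none <- seq_len(n) %in% sample.int(n, 9)
    history <- deal_items(n, !hist_none, c(
      diabetes = 10, surgery = 9, obesity = 6, hypertension = 6, tumor = 4,
      chronic_renal_insufficiency = 3, myocardial_disease = 3,
      cholecystectomy = 1, immune_related = 1, thrombus_history = 1
    ), tiebreak)
    history[hist_none] <- list("none")

    comb_pool <- sample.int(n, 7)   # 1 missing + 6 with combined medication
    comb_missing <- comb_pool[1]
    comb_with <- comb_pool[-1]
    combined <- deal_items(n, seq_len(n) %in% comb_with, c(
      antihypertensive = 4, antidiabetic = 2, antibiotics = 2,
      chemotherapeutic = 1, other_anticoagulant = 1
    ), tiebreak)
    combined[setdiff(seq_len(n), c(comb_missing, comb_with))] <- list("none")
    combined[comb_missing] <- list(NA_character_)

    symptoms <- deal_items(n, rep(TRUE, n), c(
      thrombus = 39, skin_lesions = 15, dyspnea = 13, hemorrhage = 9,
      limb_necrosis = 5, cerebral_infarction = 5, heart_failure = 5,
      acute_renal_failure = 2, shock = 1, fever = 1
    ), tiebreak)

    extra_treat <- deal_items(n, rep(TRUE, n), c(
      surgical_thrombectomy = 6, platelet_transfusion = 2, emergency = 1,
      thrombolytic = 1, glucocorticoid = 1
    ), tiebreak)
    treatments <- lapply(extra_treat, function(v) c("withdrawal", v))

    alt_none <- seq_len(n) %in% sample.int(n, 4)
    alt <- deal_items(n, !alt_none, c(
      fondaparinux = 17, lepirudin = 11, argatroban = 7, warfarin = 5,
      acenocoumarol = 5, rivaroxaban = 4, apixaban = 2, dabigatran = 1,
      clopidogrel = 1
    ), tiebreak)
    alt[alt_none] <- list("none")

    tibble(
      case_label = sprintf("case%02d", seq_len(n)),
      drug = drug, sex = sex, age_band = age_band, indication = indication,
      history = history, combined_drugs = combined, onset_band = onset,
      symptoms = symptoms, nadir_plt_band = nadir,
      plt_decrease_band = decrease, anti_pf4 = pf4, four_t_band = fourt,
      d_dimer_elevated = as.logical(d_dimer),
      liver_kidney_abnormal = as.logical(liver_kidney),
      treatments = treatments, alt_anticoagulants = alt,
      recovery_band = recovery, outcome = outcome
    )
  })
  chk <- check_case_series(cases)
  if (!chk$ok) {
    stop("fixture construction violated published marginal(s):\n",
         paste(utils::capture.output(print(chk$mismatches)), collapse = "\n"),
         call. = FALSE)
  }
  cases
}
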