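# The 43-patient literature case series of LMWH-induced HIT.
#
# One tibble row per patient. Banded variables store the band only (onset,
# platelet nadir, platelet-fall percentage, 4Ts band, recovery time), since
# per-patient raw values are not published; set-valued variables (history,
# symptoms, treatments, ...) are list-columns. Operations that would need
# raw values degrade explicitly rather than fabricate them.

CASE_SINGLE_LEVELS <- list(
  sex = c("male", "female"),
  age_band = c("<18", "18-60", ">60"),
  drug = c("enoxaparin", "nadroparin", "dalteparin", "tinzaparin", "bemiparin"),
  onset_band = c("<5", "5-10", ">10"),
  nadir_plt_band = c("<10", "10-19", "20-49", "50-100", ">100"),
  plt_decrease_band = c("<30", "30-50", ">50"),
  anti_pf4 = c("positive"),
  four_t_band = c("0-3", "4-5", "6-8"),
  recovery_band = c("<5", "5-10", ">10"),
  outcome = c("recovery", "worse", "death")
)

CASE_MULTI_LEVELS <- list(
  # the published indication counts sum to 44 over 43 patients (one patient
  # carries two primary diseases), so indication is set-valued
  indication = c("embolism", "joint_operation", "fracture", "surgery",
                 "dialysis", "tumor", "heart_failure", "traffic_accident",
                 "infection", "pregnancy"),
  history = c("diabetes", "surgery", "obesity", "hypertension", "tumor",
              "chronic_renal_insufficiency", "myocardial_disease",
              "cholecystectomy", "immune_related", "thrombus_history", "none"),
  combined_drugs = c("antihypertensive", "antidiabetic", "antibiotics",
                     "chemotherapeutic", "other_anticoagulant", "none"),
  symptoms = c("thrombus", "skin_lesions", "dyspnea", "hemorrhage",
               "limb_necrosis", "cerebral_infarction", "heart_failure",
               "acute_renal_failure", "shock", "fever"),
  treatments = c("withdrawal", "surgical_thrombectomy", "emergency",
                 "platelet_transfusion", "thrombolytic", "glucocorticoid"),
  alt_anticoagulants = c("fondaparinux", "lepirudin", "argatroban", "warfarin",
                         "acenocoumarol", "rivaroxaban", "apixaban",
                         "dabigatran", "clopidogrel", "none")
)

# how each block of the frequency tables is counted:
#   type: single-level factor, multi (set-valued) or logical
#   denom: "nonmissing" counts every case with an observed value;
#          "positive" counts only cases with at least one real item
#          (excludes "none"), as in the alternative-anticoagulant table
#   by_drug: the published tables stratify this block by drug
CASE_BLOCKS <- tibble::tribble(
  ~block,               ~type,     ~denom,       ~by_drug,
  "sex",                "single",  "nonmissing", FALSE,
  "age_band",           "single",  "nonmissing", FALSE,
  "drug",               "single",  "nonmissing", FALSE,
  "indication",         "multi",   "nonmissing", FALSE,
  "history",            "multi",   "nonmissing", FALSE,
  "combined_drugs",     "multi",   "nonmissing", FALSE,
  "onset_band",         "single",  "nonmissing", TRUE,
  "symptoms",           "multi",   "nonmissing", FALSE,
  "nadir_plt_band",     "single",  "nonmissing", TRUE,
  "plt_decrease_band",  "single",  "nonmissing", TRUE,
  "anti_pf4",           "single",  "nonmissing", TRUE,
  "four_t_band",        "single",  "nonmissing", TRUE,
  "d_dimer_elevated",   "logical", "nonmissing", FALSE,
  "liver_kidney_abnormal", "logical", "nonmissing", FALSE,
  "treatments",         "multi",   "nonmissing", FALSE,
  "alt_anticoagulants", "multi",   "positive",   FALSE,
  "recovery_band",      "single",  "nonmissing", TRUE,
  "outcome",            "single",  "nonmissing", FALSE
)

#' The packaged 43-case HIT series
#'
#' A structured reconstruction of a published literature case series of 43
#' patients with type II HIT under LMWH therapy, assembled from individual
#' case reports. Joint attributes are filled per drug so that every
#' published drug-stratified marginal is reproduced exactly (verified by
#' [check_case_series()]); cross-variable correlations that the published
#' tables do not constrain are arbitrary. Regenerate with
#' [build_case_fixture()].
#'
#' @return case tibble, one row per patient (43 rows).
#' @export
hit_case_series <- function() {
  read_case_series(system.file("extdata", "hit_cases_43.csv",
                               package = "hitsignal"))
}

#' Read a case-series CSV
#'
#' Set-valued fields are `;`-separated; empty fields are missing. Every row
#' is validated against the case schema; malformed rows produce a single
#' error listing each row-level problem.
#'
#' @param path CSV path with the documented case columns.
#' @return case tibble with set-valued columns as list-columns.
#' @export
read_case_series <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = "", progress = FALSE)
  problems <- character(0)
  note <- function(i, msg) problems <<- c(problems, sprintf("row %d: %s", i, msg))
  for (col in c("case_label", "drug", "sex", "age_band", "onset_band",
                "outcome")) {
    if (!col %in% names(raw)) {
      stop("case CSV is missing mandatory column: ", col, call. = FALSE)
    }
  }
  for (col in names(CASE_SINGLE_LEVELS)) {
    if (!col %in% names(raw)) next
    bad <- which(!is.na(raw[[col]]) & !raw[[col]] %in% CASE_SINGLE_LEVELS[[col]])
    for (i in bad) note(i, sprintf("invalid %s '%s'", col, raw[[col]][i]))
  }
  cases <- raw
  for (col in names(CASE_MULTI_LEVELS)) {
    if (!col %in% names(raw)) next
    parts <- strsplit(raw[[col]], ";", fixed = TRUE)
    parts[is.na(raw[[col]])] <- list(NA_character_)
    bad_rows <- which(vapply(seq_along(parts), function(i) {
      v <- parts[[i]]
      !all(is.na(v) | v %in% CASE_MULTI_LEVELS[[col]])
    }, logical(1)))
    for (i in bad_rows) note(i, sprintf("invalid %s '%s'", col, raw[[col]][i]))
    cases[[col]] <- parts
  }
  for (col in c("d_dimer_elevated", "liver_kidney_abnormal")) {
    if (!col %in% names(raw)) next
    ok <- is.na(raw[[col]]) | raw[[col]] %in% c("TRUE", "FALSE")
    for (i in which(!ok)) note(i, sprintf("invalid %s '%s'", col, raw[[col]][i]))
    cases[[col]] <- as.logical(raw[[col]])
  }
  if ("treatments" %in% names(cases)) {
    no_wd <- which(!vapply(cases$treatments, function(v) "withdrawal" %in% v,
                           logical(1)))
    for (i in no_wd) note(i, "treatments must include withdrawal")
  }
  if (length(problems)) {
    stop("case CSV failed validation:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cases
}

#' Write a case series to CSV
#'
#' Inverse of [read_case_series()]: set-valued columns are `;`-joined,
#' missing values written as empty fields.
#'
#' @param cases case tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_case_series <- function(cases, path) {
  out <- cases
  for (col in intersect(names(CASE_MULTI_LEVELS), names(out))) {
    out[[col]] <- vapply(out[[col]], function(v) {
      if (length(v) == 1 && is.na(v)) NA_character_ else paste(v, collapse = ";")
    }, character(1))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

multi_has <- function(column, level) {
  vapply(column, function(v) !all(is.na(v)) && level %in% v, logical(1))
}

multi_missing <- function(column) {
  vapply(column, function(v) length(v) == 1 && is.na(v), logical(1))
}

count_block <- function(cases, block, type, denom_rule) {
  col <- cases[[block]]
  if (type == "multi") {
    miss <- multi_missing(col)
    has_item <- !miss & !multi_has(col, "none")
    denom <- if (denom_rule == "positive") sum(has_item) else sum(!miss)
    levels <- CASE_MULTI_LEVELS[[block]]
    if (denom_rule == "positive") levels <- setdiff(levels, "none")
    n <- vapply(levels, function(lv) sum(multi_has(col, lv)), integer(1),
                USE.NAMES = FALSE)
    keep <- !miss
  } else if (type == "logical") {
    denom <- sum(!is.na(col))
    levels <- "yes"
    n <- sum(col, na.rm = TRUE)
    keep <- !is.na(col)
  } else {
    denom <- sum(!is.na(col))
    levels <- CASE_SINGLE_LEVELS[[block]] %||% sort(unique(col[!is.na(col)]))
    n <- vapply(levels, function(lv) sum(!is.na(col) & col == lv), integer(1),
                USE.NAMES = FALSE)
    keep <- !is.na(col)
  }
  list(levels = levels, n = n, denom = denom, keep = keep)
}

#' Frequency tables for a case series
#'
#' One table per variable block, with counts and percentages over the
#' block's non-missing denominator (for alternative anticoagulants, over the
#' cases that received at least one). Blocks that the published tables
#' stratify by drug additionally get per-drug rows whose percentages share
#' the block denominator. Percentages are rounded half-up to 2 decimals.
#'
#' @param cases case tibble (see [hit_case_series()]).
#' @param by_drug compute per-drug breakdown rows for the stratified blocks?
#'   Default `TRUE`.
#' @return tibble with columns `block`, `level`, `drug` (`NA` on overall
#'   rows), `n`, `denom`, `pct`.
#' @export
frequency_tables <- function(cases, by_drug = TRUE) {
  if (!nrow(cases)) {
    return(tibble(block = character(0), level = character(0),
                  drug = character(0), n = integer(0), denom = integer(0),
                  pct = numeric(0)))
  }
  blocks <- CASE_BLOCKS[CASE_BLOCKS$block %in% names(cases), ]
  rows <- lapply(seq_len(nrow(blocks)), function(i) {
    b <- blocks$block[i]
    cb <- count_block(cases, b, blocks$type[i], blocks$denom[i])
    if (cb$denom == 0 && !length(cb$levels)) {
      return(tibble(block = character(0), level = character(0),
                    drug = character(0), n = integer(0),
                    denom = integer(0), pct = numeric(0)))
    }
    overall <- tibble(
      block = b, level = cb$levels, drug = NA_character_,
      n = as.integer(cb$n), denom = as.integer(cb$denom),
      pct = if (cb$denom > 0) round_half_up(100 * cb$n / cb$denom, 2) else NA_real_
    )
    if (!by_drug || !blocks$by_drug[i] || !"drug" %in% names(cases)) {
      return(overall)
    }
    per_drug <- lapply(cb$levels, function(lv) {
      in_level <- if (blocks$type[i] == "multi") {
        multi_has(cases[[b]], lv)
      } else {
        !is.na(cases[[b]]) & cases[[b]] == lv
      }
      tab <- table(cases$drug[in_level & cb$keep])
      tab <- tab[tab > 0]
      if (!length(tab)) return(NULL)
      tibble(block = b, level = lv, drug = names(tab),
             n = as.integer(tab), denom = as.integer(cb$denom),
             pct = round_half_up(100 * as.integer(tab) / cb$denom, 2))
    })
    dplyr::bind_rows(overall, dplyr::bind_rows(per_drug))
  })
  dplyr::bind_rows(rows)
}

#' Narrative summary of a case series
#'
#' Reports the totals a clinical reader looks for first: cohort size, onset
#' distribution, symptom prevalence in `x/n` notation, anti-PF4 positivity,
#' the share of scored patients in the high 4Ts band, and outcomes. Onset is
#' recorded in bands only, so the modal band is reported with an explicit
#' `binned_only` marker instead of a median.
#'
#' @param cases case tibble.
#' @return a list with elements `n`, `onset` (tibble plus `modal_band`,
#'   `binned_only`), `symptoms` (tibble with `label` like `"39/43"`),
#'   `anti_pf4_positive`, `four_t` (scored, high count/share), `outcome`.
#' @export
summarize_series <- function(cases) {
  n <- nrow(cases)
  ft <- frequency_tables(cases, by_drug = FALSE)
  onset <- ft[ft$block == "onset_band", c("level", "n", "pct")]
  symptoms <- ft[ft$block == "symptoms", c("level", "n", "denom", "pct")]
  if (nrow(symptoms)) {
    symptoms <- symptoms[order(-symptoms$n), ]
    symptoms$label <- frac_label(symptoms$n, symptoms$denom)
  }
  pf4 <- if ("anti_pf4" %in% names(cases)) {
    sum(!is.na(cases$anti_pf4) & cases$anti_pf4 == "positive")
  } else NA_integer_
  scored <- if ("four_t_band" %in% names(cases)) sum(!is.na(cases$four_t_band)) else 0L
  high <- if (scored) sum(cases$four_t_band == "6-8", na.rm = TRUE) else 0L
  outcome <- ft[ft$block == "outcome", c("level", "n", "pct")]
  list(
    n = n,
    onset = list(
      table = onset,
      modal_band = if (nrow(onset) && any(onset$n > 0)) onset$level[which.max(onset$n)] else NA_character_,
      binned_only = TRUE
    ),
    symptoms = symptoms,
    anti_pf4_positive = pf4,
    four_t = list(scored = scored, high = high,
                  high_share = if (scored) round_half_up(100 * high / scored, 2) else NA_real_),
    outcome = outcome
  )
}

#' Published drug-stratified marginals of the 43-case series
#'
#' The counts and 2-decimal percentages printed in the source case-series
#' tables (patient characteristics, clinical manifestations, treatments and
#' outcomes), in the same layout as [frequency_tables()] output. Used by
#' [check_case_series()] as the reference for the exhaustive table diff.
#'
#' @return tibble with columns `block`, `level`, `drug`, `n`, `denom`, `pct`.
#' @export
case_series_reference <- function() {
  r <- function(block, level, drug, n, denom) {
    tibble(block = block, level = level, drug = drug, n = as.integer(n),
           denom = as.integer(denom), pct = round_half_up(100 * n / denom, 2))
  }
  ov <- function(block, levels, ns, denom) {
    r(block, levels, NA_character_, ns, denom)
  }
  dplyr::bind_rows(
    ov("sex", c("male", "female"), c(12, 31), 43),
    ov("age_band", c("<18", "18-60", ">60"), c(1, 15, 27), 43),
    ov("drug", c("enoxaparin", "nadroparin", "dalteparin", "tinzaparin",
                 "bemiparin"), c(21, 14, 4, 2, 2), 43),
    ov("indication", c("embolism", "joint_operation", "fracture", "surgery",
                       "dialysis", "tumor", "heart_failure",
                       "traffic_accident", "infection", "pregnancy"),
       c(10, 9, 5, 5, 4, 3, 3, 2, 2, 1), 43),
    ov("history", c("diabetes", "surgery", "obesity", "hypertension", "tumor",
                    "chronic_renal_insufficiency", "myocardial_disease",
                    "cholecystectomy", "immune_related", "thrombus_history",
                    "none"),
       c(10, 9, 6, 6, 4, 3, 3, 1, 1, 1, 9), 43),
    ov("combined_drugs", c("antihypertensive", "antidiabetic", "antibiotics",
                           "chemotherapeutic", "other_anticoagulant", "none"),
       c(4, 2, 2, 1, 1, 36), 42),
    # clinical manifestations
    ov("onset_band", c("<5", "5-10", ">10"), c(5, 24, 14), 43),
    r("onset_band", "<5", c("enoxaparin", "nadroparin", "tinzaparin"),
      c(3, 1, 1), 43),
    r("onset_band", "5-10", c("enoxaparin", "nadroparin", "bemiparin"),
      c(13, 10, 1), 43),
    r("onset_band", ">10", c("enoxaparin", "dalteparin", "nadroparin",
                             "bemiparin", "tinzaparin"), c(5, 4, 3, 1, 1), 43),
    ov("symptoms", c("thrombus", "skin_lesions", "dyspnea", "hemorrhage",
                     "limb_necrosis", "cerebral_infarction", "heart_failure",
                     "acute_renal_failure", "shock", "fever"),
       c(39, 15, 13, 9, 5, 5, 5, 2, 1, 1), 43),
    ov("nadir_plt_band", c("<10", "10-19", "20-49", "50-100", ">100"),
       c(1, 3, 13, 14, 9), 40),
    r("nadir_plt_band", "<10", "nadroparin", 1, 40),
    r("nadir_plt_band", "10-19", c("enoxaparin", "dalteparin", "nadroparin"),
      c(1, 1, 1), 40),
    r("nadir_plt_band", "20-49", c("enoxaparin", "nadroparin", "dalteparin",
                                   "bemiparin", "tinzaparin"),
      c(8, 2, 1, 1, 1), 40),
    r("nadir_plt_band", "50-100", c("enoxaparin", "nadroparin", "dalteparin",
                                    "bemiparin"), c(7, 5, 1, 1), 40),
    r("nadir_plt_band", ">100", c("enoxaparin", "nadroparin", "dalteparin",
                                  "tinzaparin"), c(5, 2, 1, 1), 40),
    ov("plt_decrease_band", c("<30", "30-50", ">50"), c(1, 3, 33), 37),
    r("plt_decrease_band", "<30", "tinzaparin", 1, 37),
    r("plt_decrease_band", "30-50", c("enoxaparin", "nadroparin"), c(2, 1), 37),
    r("plt_decrease_band", ">50", c("enoxaparin", "nadroparin", "dalteparin",
                                    "bemiparin", "tinzaparin"),
      c(19, 8, 3, 2, 1), 37),
    ov("anti_pf4", "positive", 36, 36),
    r("anti_pf4", "positive", c("enoxaparin", "nadroparin", "dalteparin",
                                "bemiparin", "tinzaparin"),
      c(17, 12, 4, 2, 1), 36),
    ov("four_t_band", c("0-3", "4-5", "6-8"), c(0, 3, 18), 21),
    r("four_t_band", "4-5", c("dalteparin", "enoxaparin"), c(2, 1), 21),
    r("four_t_band", "6-8", c("nadroparin", "enoxaparin", "bemiparin",
                              "tinzaparin"), c(9, 6, 2, 1), 21),
    ov("d_dimer_elevated", "yes", 5, 11),
    ov("liver_kidney_abnormal", "yes", 5, 8),
    # treatments and outcomes
    ov("treatments", c("withdrawal", "surgical_thrombectomy", "emergency",
                       "platelet_transfusion", "thrombolytic",
                       "glucocorticoid"), c(43, 6, 1, 2, 1, 1), 43),
    ov("alt_anticoagulants", c("fondaparinux", "lepirudin", "argatroban",
                               "warfarin", "acenocoumarol", "rivaroxaban",
                               "apixaban", "dabigatran", "clopidogrel"),
       c(17, 11, 7, 5, 5, 4, 2, 1, 1), 39),
    ov("recovery_band", c("<5", "5-10", ">10"), c(9, 17, 8), 34),
    r("recovery_band", "<5", c("nadroparin", "enoxaparin", "dalteparin"),
      c(4, 3, 2), 34),
    r("recovery_band", "5-10", c("enoxaparin", "nadroparin", "bemiparin",
                                 "tinzaparin"), c(11, 4, 1, 1), 34),
    r("recovery_band", ">10", c("nadroparin", "enoxaparin", "bemiparin"),
      c(5, 2, 1), 34),
    ov("outcome", c("recovery", "worse", "death"), c(41, 1, 1), 43)
  )
}

#' Exhaustive table diff of a case series against the published marginals
#'
#' Compares [frequency_tables()] output (counts and rounded percentages,
#' overall and per drug) against [case_series_reference()] in both
#' directions: every reference row must be reproduced exactly, and no extra
#' non-zero row may appear.
#'
#' @param cases case tibble.
#' @return a list with `ok` (logical) and `mismatches` (tibble of differing
#'   rows, empty when `ok`).
#' @export
check_case_series <- function(cases) {
  got <- frequency_tables(cases, by_drug = TRUE)
  ref <- case_series_reference()
  # police drug rows only where the reference stratifies by drug
  strat <- unique(ref$block[!is.na(ref$drug)])
  got <- got[is.na(got$drug) | got$block %in% strat, ]
  m <- dplyr::full_join(
    dplyr::rename(ref, n_ref = "n", denom_ref = "denom", pct_ref = "pct"),
    dplyr::rename(got, n_got = "n", denom_got = "denom", pct_got = "pct"),
    by = c("block", "level", "drug")
  )
  m$n_ref[is.na(m$n_ref) & !is.na(m$n_got)] <- 0L
  m$n_got[is.na(m$n_got) & !is.na(m$n_ref)] <- 0L
  bad <- m$n_ref != m$n_got |
    (!is.na(m$pct_ref) & !is.na(m$pct_got) & abs(m$pct_ref - m$pct_got) > 1e-9) |
    (!is.na(m$denom_ref) & !is.na(m$denom_got) & m$denom_ref != m$denom_got) |
    (m$n_ref > 0 & (is.na(m$pct_got) | is.na(m$denom_got)))
  list(ok = !any(bad), mismatches = m[bad, ])
}
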