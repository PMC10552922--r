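# End-to-end runs that regenerate publication-shaped outputs: a baseline
# stratification per drug, the drug-event signal table, and the case-series
# frequency tables. Thin enough to be driven from a shell wrapper.

#' Run the signal-detection pipeline
#'
#' Reads (or simulates) a report corpus, deduplicates it, matches the HIT
#' preferred terms, and writes the baseline stratification of HIT reports
#' per drug, the full signal table, and a JSON run log with every exclusion
#' count. With `simulate`, the corpus is generated, written in the FAERS
#' dialect, and read back through the regular ingestion path, so the run
#' exercises the whole pipeline.
#'
#' @param input named list/vector with paths `demo`, `drug`, `reac`, or
#'   `NULL` to simulate. Exactly one of `input`/`simulate` must be given.
#' @param simulate a [sim_config()], or `NULL`.
#' @param drugs generic drug names to screen; default the seven LMWHs.
#' @param dict_path optional path to a drug dictionary CSV.
#' @param pt_keywords event preferred terms, default [hit_pt_keywords()].
#' @param out_dir output directory.
#' @param yates Yates-correct the chi-square? Default `FALSE`.
#' @param roles drug role codes counted as exposure, default suspect-only.
#' @return (invisibly) list with `baseline`, `signals`, `log`, and the
#'   output file paths.
#' @export
run_signal <- function(input = NULL, simulate = NULL,
                       drugs = lmwh_generics(), dict_path = NULL,
                       pt_keywords = hit_pt_keywords(), out_dir,
                       yates = FALSE, roles = c("PS", "SS")) {
  if (is.null(input) == is.null(simulate)) {
    stop("exactly one of `input` or `simulate` must be given", call. = FALSE)
  }
  dict <- lmwh_dictionary(dict_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(simulate)) {
    sim <- generate_reports(simulate)
    paths <- write_faers_reports(sim$reports, file.path(out_dir, "corpus"))
    input <- as.list(paths)
  }
  reports <- read_faers_reports(input$demo, input$drug, input$reac)
  exclusions <- attr(reports, "exclusions")
  n_raw <- nrow(reports)
  reports <- deduplicate_reports(reports)
  n_dedup <- nrow(reports)

  matcher <- function(reactions) match_hit_pt(reactions, pt_keywords)
  signals <- screen_pairs(reports, drugs, event_matcher = matcher,
                          dict = dict, roles = roles, yates = yates)
  if (sum(signals$n_reports) == 0) {
    message("no qualifying reports: no screened drug has any event report")
  }
  is_event <- matcher(reports$reactions)
  baselines <- dplyr::bind_rows(lapply(drugs, function(dg) {
    sub <- reports[is_event & mentions_drug(reports, dg, dict, roles), ]
    if (!nrow(sub)) return(NULL)
    dplyr::bind_cols(tibble(drug = dg), baseline_table(sub))
  }))

  log <- list(
    n_reports_read = n_raw,
    n_after_dedup = n_dedup,
    n_duplicates_removed = n_raw - n_dedup,
    exclusions = exclusions,
    n_event_reports = sum(is_event),
    thresholds = list(prr = 2, chi2 = 4, n = 2, ror_ci_lower = 1),
    yates = yates, roles = roles
  )
  files <- c(signals = file.path(out_dir, "signal_table.csv"),
             baseline = file.path(out_dir, "baseline_table.csv"),
             log = file.path(out_dir, "run_log.json"))
  readr::write_csv(signals, files[["signals"]])
  readr::write_csv(baselines, files[["baseline"]])
  jsonlite::write_json(log, files[["log"]], auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(list(baseline = baselines, signals = signals, log = log,
                 files = files))
}

#' Run the case-series pipeline
#'
#' Loads the packaged 43-case fixture (or a user case CSV), verifies it
#' against the published marginals when it is the fixture, and writes the
#' three frequency-table files (patient characteristics; clinical
#' manifestations; treatments and outcomes) plus the narrative summary.
#'
#' @param csv path to a case CSV, or `NULL` for the packaged fixture.
#' @param out_dir output directory.
#' @param check verify the table diff against the published marginals and
#'   fail if it does not match (default `TRUE` for the packaged fixture,
#'   ignored for user CSVs).
#' @return (invisibly) list with `cases`, `tables`, `summary`, `files`.
#' @export
run_cases <- function(csv = NULL, out_dir, check = TRUE) {
  fixture <- is.null(csv)
  cases <- if (fixture) hit_case_series() else read_case_series(csv)
  if (fixture && check) {
    chk <- check_case_series(cases)
    if (!chk$ok) {
      stop("packaged fixture failed the published-marginal table diff",
           call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- frequency_tables(cases)
  groups <- list(
    characteristics = c("sex", "age_band", "drug", "indication", "history",
                        "combined_drugs"),
    manifestations = c("onset_band", "symptoms", "nadir_plt_band",
                       "plt_decrease_band", "anti_pf4", "four_t_band",
                       "d_dimer_elevated", "liver_kidney_abnormal"),
    treatments_outcomes = c("treatments", "alt_anticoagulants",
                            "recovery_band", "outcome")
  )
  files <- character(0)
  for (g in names(groups)) {
    f <- file.path(out_dir, paste0(g, ".csv"))
    readr::write_csv(tables[tables$block %in% groups[[g]], ], f)
    files[g] <- f
  }
  summ <- summarize_series(cases)
  files["summary"] <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, files[["summary"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")
  invisible(list(cases = cases, tables = tables, summary = summ,
                 files = files))
}
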