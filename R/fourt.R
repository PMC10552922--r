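# Warkentin 4Ts pretest probability score for HIT.
#
# Four criteria - Thrombocytopenia, Timing, Thrombosis, oTher causes - each
# scored 0/1/2; the sum (0-8) maps to pretest probability bands
# low (0-3), intermediate (4-5), high (6-8).

#' Assemble the observations feeding the 4Ts score
#'
#' @param platelet_fall_pct percentage fall from baseline platelet count,
#'   in `[0, 100]`.
#' @param nadir_plt platelet nadir, in 10^9/L.
#' @param onset_day days from first heparin exposure to the platelet fall
#'   (>= 0).
#' @param recent_heparin was there heparin exposure within the previous 30
#'   days (makes a fall at day <= 1 typical)? Default `FALSE`.
#' @param timing_unclear is the timing consistent with HIT but not clearly
#'   documented? Default `FALSE`.
#' @param thrombosis `"none"` (default), `"possible"` (progressive,
#'   recurrent or suspected thrombosis, erythematous skin lesions) or
#'   `"confirmed"` (proven new thrombosis, skin necrosis, or acute systemic
#'   reaction after a heparin bolus).
#' @param other_cause other explanation for the platelet fall: `"definite"`
#'   (default), `"possible"` or `"none"`.
#' @return a tibble of validated inputs (vectorized; one row per patient).
#' @export
four_t_inputs <- function(platelet_fall_pct, nadir_plt, onset_day,
                          recent_heparin = FALSE, timing_unclear = FALSE,
                          thrombosis = "none", other_cause = "definite") {
  match_values(thrombosis, c("none", "possible", "confirmed"), "thrombosis")
  match_values(other_cause, c("definite", "possible", "none"), "other_cause")
  if (any(platelet_fall_pct < 0 | platelet_fall_pct > 100, na.rm = TRUE)) {
    stop("`platelet_fall_pct` must lie in [0, 100]", call. = FALSE)
  }
  if (any(onset_day < 0, na.rm = TRUE)) {
    stop("`onset_day` must be non-negative", call. = FALSE)
  }
  tibble(platelet_fall_pct = platelet_fall_pct, nadir_plt = nadir_plt,
         onset_day = onset_day, recent_heparin = recent_heparin,
         timing_unclear = timing_unclear, thrombosis = thrombosis,
         other_cause = other_cause)
}

match_values <- function(x, choices, name) {
  if (!all(x %in% choices | is.na(x))) {
    stop(sprintf("`%s` must be one of: %s", name,
                 paste(choices, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Compute the Warkentin 4Ts score
#'
#' Per-criterion scoring (standard published rubric):
#' * thrombocytopenia: 2 if fall > 50% and nadir >= 20; 1 if fall 30-50%
#'   or nadir 10-19; else 0;
#' * timing: 2 if onset day 5-10, or <= 1 day with heparin exposure in the
#'   previous 30 days; 1 if onset after day 10 or timing unclear; else 0;
#' * thrombosis: 2 if confirmed new thrombosis, skin necrosis or acute
#'   systemic reaction; 1 if possible; 0 if none;
#' * other cause of the fall: 2 if none apparent; 1 if possible; 0 if
#'   definite.
#'
#' A missing criterion yields an explicitly missing score (`NA` total and
#' category, with the missing criteria named) - never an imputed one. The
#' total is monotone: worsening any single criterion never decreases it.
#'
#' @param x tibble from [four_t_inputs()] (one row per patient).
#' @return tibble with the four sub-scores (`t_thrombocytopenia`, `t_timing`,
#'   `t_thrombosis`, `t_other`), `score` (0-8) and `category`
#'   (`low`/`intermediate`/`high`), plus `missing_criteria` listing any
#'   unobserved criterion.
#' @export
#' @examples
#' four_t_score(four_t_inputs(60, 45, 7, thrombosis = "confirmed",
#'                            other_cause = "none"))
four_t_score <- function(x) {
  t_plt <- dplyr::case_when(
    is.na(x$platelet_fall_pct) | is.na(x$nadir_plt) ~ NA_integer_,
    x$platelet_fall_pct > 50 & x$nadir_plt >= 20 ~ 2L,
    (x$platelet_fall_pct >= 30 & x$platelet_fall_pct <= 50) |
      (x$nadir_plt >= 10 & x$nadir_plt < 20) ~ 1L,
    TRUE ~ 0L
  )
  t_time <- dplyr::case_when(
    is.na(x$onset_day) ~ NA_integer_,
    (x$onset_day >= 5 & x$onset_day <= 10) |
      (x$onset_day <= 1 & x$recent_heparin) ~ 2L,
    x$onset_day > 10 | x$timing_unclear ~ 1L,
    TRUE ~ 0L
  )
  t_thr <- c(none = 0L, possible = 1L, confirmed = 2L)[x$thrombosis]
  t_oth <- c(definite = 0L, possible = 1L, none = 2L)[x$other_cause]
  score <- t_plt + t_time + unname(t_thr) + unname(t_oth)
  category <- dplyr::case_when(
    is.na(score) ~ NA_character_,
    score <= 3 ~ "low",
    score <= 5 ~ "intermediate",
    TRUE ~ "high"
  )
  missing_criteria <- apply(
    cbind(thrombocytopenia = is.na(t_plt), timing = is.na(t_time),
          thrombosis = is.na(t_thr), other_cause = is.na(t_oth)),
    1, function(m) paste(names(m)[m], collapse = ","))
  tibble(t_thrombocytopenia = t_plt, t_timing = t_time,
         t_thrombosis = unname(t_thr), t_other = unname(t_oth),
         score = score, category = category,
         missing_criteria = missing_criteria)
}
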