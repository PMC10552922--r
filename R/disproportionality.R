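# Disproportionality statistics on drug-event 2x2 contingency tables.
#
# Cell layout for a given drug and event, counted over deduplicated reports:
#   a: reports of the event with the drug      b: other events with the drug
#   c: reports of the event with other drugs   d: other events with other drugs

#' Construct a drug-event contingency table
#'
#' @param a,b,c,d non-negative integer cell counts (see layout above);
#'   `a + b + c + d` must be positive. Non-integer values are accepted only
#'   for continuity-corrected cells.
#' @return an object of class `contingency_table`.
#' @export
#' @examples
#' contingency_table(10, 90, 10, 890)
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop("all cells must be finite and non-negative", call. = FALSE)
  }
  if (sum(cells) <= 0) stop("a + b + c + d must be positive", call. = FALSE)
  structure(as.list(cells), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(c("drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

# explicit not-a-value result: NA carrying the reason it is undefined
na_value <- function(reason) structure(NA_real_, reason = reason)

#' @export
#' @rdname compute_prr
value_reason <- function(x) attr(x, "reason")

#' Proportional reporting ratio
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`: the proportion of the drug's reports that
#' are the event, relative to the same proportion among all other drugs.
#' Undefined denominators yield an explicit `NA` whose reason is available
#' via `value_reason()`, never a silent zero.
#'
#' @param t a [contingency_table()].
#' @return the PRR (or reasoned `NA`).
#' @export
#' @examples
#' compute_prr(contingency_table(10, 90, 10, 890)) # 9
compute_prr <- function(t) {
  if (t$a + t$b <= 0) return(na_value("a + b = 0: drug has no reports"))
  if (t$c + t$d <= 0) return(na_value("c + d = 0: no comparator reports"))
  if (t$c <= 0) return(na_value("c = 0: event unseen with other drugs"))
  (t$a / (t$a + t$b)) / (t$c / (t$c + t$d))
}

#' Reporting odds ratio
#'
#' `ROR = (a/c)/(b/d) = ad/bc`: the odds of the event among the drug's
#' reports relative to the odds among all other drugs.
#'
#' @param t a [contingency_table()].
#' @return the ROR (or reasoned `NA`).
#' @export
#' @examples
#' compute_ror(contingency_table(10, 90, 10, 890)) # 9.889
compute_ror <- function(t) {
  if (t$b <= 0) return(na_value("b = 0: drug has no non-event reports"))
  if (t$c <= 0) return(na_value("c = 0: event unseen with other drugs"))
  (t$a * t$d) / (t$b * t$c)
}

#' Pearson chi-square for a 2x2 table
#'
#' `chi2 = N (|ad - bc| - yates * N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]` with
#' `N = a+b+c+d`; `yates = TRUE` applies the continuity correction (clamped
#' at zero). Invariant under simultaneous row and column swap.
#'
#' @param t a [contingency_table()].
#' @param yates apply the Yates continuity correction? Default `FALSE`.
#' @return the statistic (or reasoned `NA` when a margin is zero).
#' @export
compute_chi2 <- function(t, yates = FALSE) {
  n <- t$a + t$b + t$c + t$d
  margins <- c(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d)
  if (any(margins <= 0)) return(na_value("zero margin: chi-square undefined"))
  dev <- abs(t$a * t$d - t$b * t$c)
  if (yates) dev <- max(0, dev - n / 2)
  n * dev^2 / prod(margins)
}

#' Two-sided log-scale Wald confidence interval for PRR or ROR
#'
#' Bounds are `exp(log(point) -+ z * SE)` with
#' `SE(log ROR) = sqrt(1/a + 1/b + 1/c + 1/d)` and
#' `SE(log PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`, so the point estimate
#' is the geometric mean of the bounds.
#'
#' @param point the PRR or ROR point estimate.
#' @param t the [contingency_table()] it was computed from.
#' @param kind `"prr"` or `"ror"`.
#' @param conf_level confidence level, default 0.95 (z = 1.96).
#' @return named numeric `c(lower, upper)` (reasoned `NA`s on zero cells).
#' @export
wald_ci <- function(point, t, kind = c("ror", "prr"), conf_level = 0.95) {
  kind <- match.arg(kind)
  z <- if (identical(conf_level, 0.95)) 1.96 else stats::qnorm(1 - (1 - conf_level) / 2)
  if (is.na(point)) {
    return(c(lower = na_value("point estimate undefined"),
             upper = na_value("point estimate undefined")))
  }
  if (kind == "ror") {
    if (min(t$a, t$b, t$c, t$d) <= 0) {
      return(c(lower = na_value("zero cell: SE(log ROR) undefined"),
               upper = na_value("zero cell: SE(log ROR) undefined")))
    }
    se <- sqrt(1 / t$a + 1 / t$b + 1 / t$c + 1 / t$d)
  } else {
    if (t$a <= 0 || t$c <= 0) {
      return(c(lower = na_value("zero cell: SE(log PRR) undefined"),
               upper = na_value("zero cell: SE(log PRR) undefined")))
    }
    se <- sqrt(1 / t$a - 1 / (t$a + t$b) + 1 / t$c - 1 / (t$c + t$d))
  }
  c(lower = point * exp(-z * se), upper = point * exp(z * se))
}

#' Full signal statistics for one drug-event table
#'
#' Computes PRR, ROR, chi-square and both 95% CIs, applies the screening
#' rules via [apply_signal_criteria()], and records whether the
#' Haldane-Anscombe correction (+0.5 to every cell, used only when some cell
#' is zero) was applied. `n_reports` is cell `a`, the event-with-drug count
#' used as N in the screening rules.
#'
#' @param t a [contingency_table()].
#' @param yates Yates correction for the chi-square, default `FALSE`.
#' @param zero_cell `"correct"` (default) applies +0.5 to all four cells when
#'   any cell is zero; `"none"` leaves the table untouched (statistics may
#'   come back as reasoned `NA`s).
#' @return one-row tibble: `a,b,c,d, prr, prr_l95, prr_u95, ror, ror_l95,
#'   ror_u95, chi2, n_reports, prr_signal, ror_signal, corrected`.
#' @export
signal_stats <- function(t, yates = FALSE, zero_cell = c("correct", "none")) {
  zero_cell <- match.arg(zero_cell)
  corrected <- FALSE
  tc <- t
  if (zero_cell == "correct" && min(t$a, t$b, t$c, t$d) == 0) {
    tc <- contingency_table(t$a + 0.5, t$b + 0.5, t$c + 0.5, t$d + 0.5)
    corrected <- TRUE
  }
  prr <- compute_prr(tc)
  ror <- compute_ror(tc)
  chi2 <- compute_chi2(tc, yates = yates)
  prr_ci <- wald_ci(prr, tc, "prr")
  ror_ci <- wald_ci(ror, tc, "ror")
  out <- tibble(
    a = t$a, b = t$b, c = t$c, d = t$d,
    prr = as.numeric(prr), prr_l95 = as.numeric(prr_ci[["lower"]]),
    prr_u95 = as.numeric(prr_ci[["upper"]]),
    ror = as.numeric(ror), ror_l95 = as.numeric(ror_ci[["lower"]]),
    ror_u95 = as.numeric(ror_ci[["upper"]]),
    chi2 = as.numeric(chi2), n_reports = t$a,
    prr_signal = NA, ror_signal = NA, corrected = corrected
  )
  apply_signal_criteria(out)
}

#' Apply the dual screening rules to signal statistics
#'
#' A drug-event pair is a PRR signal when `PRR > 2`, `chi2 > 4` and `N > 2`;
#' it is a ROR signal when the lower 95% CI bound of the ROR exceeds 1 and
#' `N > 2`. All inequalities are strict; N is cell `a` (`n_reports`).
#'
#' @param stats tibble from [signal_stats()] (any number of rows).
#' @param prr_threshold,chi2_threshold,n_threshold,ror_ci_threshold rule
#'   thresholds; defaults 2, 4, 2 and 1.
#' @return `stats` with `prr_signal` and `ror_signal` filled in (`FALSE`
#'   where the underlying statistics are undefined).
#' @export
apply_signal_criteria <- function(stats, prr_threshold = 2, chi2_threshold = 4,
                                  n_threshold = 2, ror_ci_threshold = 1) {
  stopifnot(all(c(prr_threshold, chi2_threshold, n_threshold, ror_ci_threshold) > 0))
  prr_ok <- !is.na(stats$prr) & !is.na(stats$chi2) &
    stats$prr > prr_threshold & stats$chi2 > chi2_threshold &
    stats$n_reports > n_threshold
  ror_ok <- !is.na(stats$ror_l95) &
    stats$ror_l95 > ror_ci_threshold & stats$n_reports > n_threshold
  stats$prr_signal <- prr_ok
  stats$ror_signal <- ror_ok
  stats
}

#' Screen drug-event pairs over a deduplicated report corpus
#'
#' Builds, for each drug, the 2x2 table of the event against the rest of the
#' corpus (so `a+b+c+d` equals the total deduplicated report count on every
#' row) and returns the full signal statistics. A drug counts toward a report
#' when it appears with one of the given role codes (suspect-only by
#' default; add `"C"`/`"I"` to include concomitant/interacting).
#'
#' @param reports deduplicated AE report tibble (see [deduplicate_reports()]).
#' @param drugs character vector of generic drug names to screen.
#' @param event_matcher function mapping the `reactions` list-column to a
#'   logical event indicator per report; default [match_hit_pt()].
#' @param dict drug dictionary for name normalization.
#' @param roles drug role codes that count as exposure, default `c("PS","SS")`.
#' @param yates Yates correction for the chi-square, default `FALSE`.
#' @return tibble with one row per drug: `drug` plus the [signal_stats()]
#'   columns. Drugs with zero reports get `n_reports = 0` and no flags.
#' @export
screen_pairs <- function(reports, drugs, event_matcher = match_hit_pt,
                         dict = lmwh_dictionary(), roles = c("PS", "SS"),
                         yates = FALSE) {
  n_total <- nrow(reports)
  is_event <- if (n_total) event_matcher(reports$reactions) else logical(0)
  mentions <- if (n_total) drug_mentions(reports, dict, roles) else NULL
  rows <- lapply(drugs, function(dg) {
    exposed <- mentions_drug(reports, dg, mentions = mentions)
    a <- sum(exposed & is_event)
    b <- sum(exposed & !is_event)
    c <- sum(!exposed & is_event)
    d <- sum(!exposed & !is_event)
    if (a + b + c + d == 0) {
      return(tibble(drug = dg, a = 0, b = 0, c = 0, d = 0,
                    prr = NA_real_, prr_l95 = NA_real_, prr_u95 = NA_real_,
                    ror = NA_real_, ror_l95 = NA_real_, ror_u95 = NA_real_,
                    chi2 = NA_real_, n_reports = 0,
                    prr_signal = FALSE, ror_signal = FALSE, corrected = FALSE))
    }
    st <- signal_stats(contingency_table(a, b, c, d), yates = yates)
    if (a + b == 0) st$prr_signal <- st$ror_signal <- FALSE
    dplyr::bind_cols(tibble(drug = dg), st)
  })
  dplyr::bind_rows(rows)
}
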