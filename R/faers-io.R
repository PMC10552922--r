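# Reading, writing and normalising FAERS-style spontaneous report tables.
#
# In-memory representation: one tibble row per report (an "AE report"), with
# columns case_id, case_version, receipt_date, age_years, sex, outcome_code,
# reporter_country, plus list-columns drug_names, drug_roles, reactions.
# Reports are the unit of counting throughout the package.

AE_REPORT_COLS <- c("case_id", "case_version", "receipt_date", "age_years",
                    "sex", "outcome_code", "reporter_country",
                    "drug_names", "drug_roles", "reactions")

SEX_LEVELS <- c("female", "male", "unknown")
OUTCOME_LEVELS <- c("death", "life_threatening", "disability",
                    "hospitalization", "other")
ROLE_CODES <- c("PS", "SS", "C", "I")

# file <-> memory code maps (FAERS ASCII conventions)
SEX_CODES <- c(F = "female", M = "male", UNK = "unknown")
OUTC_CODES <- c(DE = "death", LT = "life_threatening", DS = "disability",
                HO = "hospitalization", OT = "other")

#' File dialect for FAERS-style quarterly tables
#'
#' FAERS quarters ship as `$`-delimited ASCII tables (demographics, drugs,
#' reactions) joined on a primary id. The dialect is configurable so that
#' differently named exports can be ingested; the default mimics the FAERS
#' ASCII layout. No network access is ever used.
#'
#' @param delim field delimiter, default `"$"`.
#' @param demo,drug,reac named character vectors mapping the canonical column
#'   roles to the column names found in each file. Canonical roles are:
#'   demo: `primaryid`, `caseid`, `caseversion`, `fda_dt`, `age`, `sex`,
#'   `outc_cod`, `occr_country`; drug: `primaryid`, `drugname`, `role_cod`;
#'   reac: `primaryid`, `pt`.
#' @return a list describing the dialect, for [read_faers_reports()].
#' @export
faers_dialect <- function(delim = "$",
                          demo = NULL, drug = NULL, reac = NULL) {
  default_demo <- c(primaryid = "primaryid", caseid = "caseid",
                    caseversion = "caseversion", fda_dt = "fda_dt",
                    age = "age", sex = "sex", outc_cod = "outc_cod",
                    occr_country = "occr_country")
  default_drug <- c(primaryid = "primaryid", drugname = "drugname",
                    role_cod = "role_cod")
  default_reac <- c(primaryid = "primaryid", pt = "pt")
  merge_map <- function(default, user) {
    if (is.null(user)) return(default)
    default[names(user)] <- user
    default
  }
  list(delim = delim,
       demo = merge_map(default_demo, demo),
       drug = merge_map(default_drug, drug),
       reac = merge_map(default_reac, reac))
}

read_delim_quiet <- function(path, delim) {
  readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                    na = c("", "NA"), progress = FALSE,
                    show_col_types = FALSE)
}

check_columns <- function(tbl, map, file) {
  missing <- setdiff(unname(map), names(tbl))
  if (length(missing)) {
    stop(sprintf("file '%s' is missing mandatory column(s): %s",
                 file, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read a FAERS-style quarter into AE reports
#'
#' Joins the demographics, drug and reaction tables on the primary id and
#' returns one row per raw case entry (all case versions retained; use
#' [deduplicate_reports()] before counting). Child rows whose primary id has
#' no demographics row are excluded with a warning; demographics rows without
#' any drug or any reaction are likewise excluded, so that every returned
#' report has non-empty drugs and reactions. All exclusions are counted in
#' the `exclusions` attribute, never silently dropped.
#'
#' @param demo,drug,reac file paths for the three tables.
#' @param dialect file dialect from [faers_dialect()].
#' @return a tibble of AE reports with attribute `exclusions`, a named list
#'   of counts (`orphan_drug_rows`, `orphan_reac_rows`, `no_drug_cases`,
#'   `no_reaction_cases`, `malformed_values`).
#' @export
read_faers_reports <- function(demo, drug, reac, dialect = faers_dialect()) {
  for (p in c(demo, drug, reac)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  d_demo <- read_delim_quiet(demo, dialect$delim)
  d_drug <- read_delim_quiet(drug, dialect$delim)
  d_reac <- read_delim_quiet(reac, dialect$delim)
  check_columns(d_demo, dialect$demo, demo)
  check_columns(d_drug, dialect$drug, drug)
  check_columns(d_reac, dialect$reac, reac)

  dm <- dialect$demo
  id <- d_demo[[dm[["primaryid"]]]]

  # orphan child rows: no matching demographics entry
  drug_ok <- d_drug[[dialect$drug[["primaryid"]]]] %in% id
  reac_ok <- d_reac[[dialect$reac[["primaryid"]]]] %in% id
  n_orphan_drug <- sum(!drug_ok)
  n_orphan_reac <- sum(!reac_ok)
  if (n_orphan_drug + n_orphan_reac > 0) {
    warning(sprintf("excluded %d drug and %d reaction row(s) with no matching demographics row",
                    n_orphan_drug, n_orphan_reac), call. = FALSE)
  }
  d_drug <- d_drug[drug_ok, ]
  d_reac <- d_reac[reac_ok, ]

  malformed <- 0L
  age_raw <- d_demo[[dm[["age"]]]]
  age <- suppressWarnings(as.numeric(age_raw))
  bad_age <- !is.na(age_raw) & is.na(age) | (!is.na(age) & age < 0)
  malformed <- malformed + sum(bad_age)
  age[bad_age | age < 0] <- NA_real_

  version_raw <- d_demo[[dm[["caseversion"]]]]
  version <- suppressWarnings(as.integer(version_raw))
  bad_version <- is.na(version) | version < 1L
  malformed <- malformed + sum(bad_version)
  version[bad_version] <- 1L

  date_raw <- d_demo[[dm[["fda_dt"]]]]
  receipt <- as.Date(date_raw, format = "%Y%m%d")
  malformed <- malformed + sum(!is.na(date_raw) & is.na(receipt))

  sex <- unname(SEX_CODES[d_demo[[dm[["sex"]]]]])
  sex[is.na(sex)] <- "unknown"

  outc <- vapply(d_demo[[dm[["outc_cod"]]]], parse_outcome, character(1),
                 USE.NAMES = FALSE)

  # group drugs and reactions per primary id
  split_chr <- function(values, ids) {
    out <- split(values, factor(ids, levels = unique(id)))
    unname(out)
  }
  drug_names <- split_chr(d_drug[[dialect$drug[["drugname"]]]],
                          d_drug[[dialect$drug[["primaryid"]]]])
  role_raw <- d_drug[[dialect$drug[["role_cod"]]]]
  role_raw[!role_raw %in% ROLE_CODES] <- "C"
  drug_roles <- split_chr(role_raw, d_drug[[dialect$drug[["primaryid"]]]])
  reactions <- split_chr(d_reac[[dialect$reac[["pt"]]]],
                         d_reac[[dialect$reac[["primaryid"]]]])

  reports <- tibble(
    case_id = d_demo[[dm[["caseid"]]]],
    case_version = version,
    receipt_date = receipt,
    age_years = age,
    sex = sex,
    outcome_code = outc,
    reporter_country = d_demo[[dm[["occr_country"]]]],
    drug_names = drug_names,
    drug_roles = drug_roles,
    reactions = reactions
  )

  no_drug <- lengths(reports$drug_names) == 0L
  no_reac <- lengths(reports$reactions) == 0L
  if (any(no_drug | no_reac)) {
    warning(sprintf("excluded %d case(s) without drug rows and %d without reaction rows",
                    sum(no_drug), sum(no_reac & !no_drug)), call. = FALSE)
  }
  out <- reports[!(no_drug | no_reac), ]
  attr(out, "exclusions") <- list(
    orphan_drug_rows = n_orphan_drug,
    orphan_reac_rows = n_orphan_reac,
    no_drug_cases = sum(no_drug),
    no_reaction_cases = sum(no_reac & !no_drug),
    malformed_values = malformed
  )
  out
}

# multiple outcome codes may arrive comma-joined; precedence keeps the most
# severe: death > life-threatening/disability/hospitalization > other
parse_outcome <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NA_character_)
  codes <- toupper(trimws(strsplit(x, ",", fixed = TRUE)[[1]]))
  mapped <- unname(OUTC_CODES[codes])
  mapped <- mapped[!is.na(mapped)]
  if (!length(mapped)) return(NA_character_)
  OUTCOME_LEVELS[min(match(mapped, OUTCOME_LEVELS))]
}

#' Write AE reports in the FAERS-style delimited dialect
#'
#' Inverse of [read_faers_reports()] on all modeled fields; used by the
#' synthetic generator so the whole pipeline can run from files.
#'
#' @param reports AE report tibble.
#' @param dir output directory (created if needed).
#' @param dialect file dialect from [faers_dialect()].
#' @return named character vector of the three file paths (demo, drug, reac).
#' @export
write_faers_reports <- function(reports, dir, dialect = faers_dialect()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(reports)
  primaryid <- sprintf("%s-%d", reports$case_id, reports$case_version)
  inv_sex <- setNames(names(SEX_CODES), SEX_CODES)
  inv_outc <- setNames(names(OUTC_CODES), OUTC_CODES)
  demo <- tibble(
    primaryid = primaryid,
    caseid = reports$case_id,
    caseversion = reports$case_version,
    fda_dt = format(reports$receipt_date, "%Y%m%d"),
    age = reports$age_years,
    sex = unname(inv_sex[reports$sex]),
    outc_cod = unname(inv_outc[reports$outcome_code]),
    occr_country = reports$reporter_country
  )
  reps <- lengths(reports$drug_names)
  drug <- tibble(
    primaryid = rep(primaryid, reps),
    drugname = unlist(reports$drug_names, use.names = FALSE),
    role_cod = unlist(reports$drug_roles, use.names = FALSE)
  )
  reac <- tibble(
    primaryid = rep(primaryid, lengths(reports$reactions)),
    pt = unlist(reports$reactions, use.names = FALSE)
  )
  paths <- c(demo = file.path(dir, "demo.txt"),
             drug = file.path(dir, "drug.txt"),
             reac = file.path(dir, "reac.txt"))
  readr::write_delim(demo, paths[["demo"]], delim = dialect$delim, na = "")
  readr::write_delim(drug, paths[["drug"]], delim = dialect$delim, na = "")
  readr::write_delim(reac, paths[["reac"]], delim = dialect$delim, na = "")
  paths
}

#' Deduplicate AE reports to one row per case
#'
#' Spontaneous-report databases carry resubmitted versions of the same case;
#' disproportionality must be computed over unique cases. Keeps, per
#' `case_id`, the highest `case_version`; ties are broken by latest
#' `receipt_date`, remaining ties by input order (later rows supersede
#' earlier ones). Idempotent and never increases the report count.
#'
#' @param reports AE report tibble.
#' @return deduplicated tibble, original relative order preserved.
#' @export
deduplicate_reports <- function(reports) {
  if (!nrow(reports)) return(reports)
  ord <- seq_len(nrow(reports))
  date_key <- as.numeric(reports$receipt_date)
  date_key[is.na(date_key)] <- -Inf
  o <- order(reports$case_id, reports$case_version, date_key, ord)
  keep_last <- !duplicated(reports$case_id[o], fromLast = TRUE)
  idx <- sort(ord[o][keep_last])
  reports[idx, ]
}

#' MedDRA preferred terms identifying HIT
#'
#' The three preferred terms under which heparin-induced thrombocytopenia is
#' coded: the event itself, the laboratory test, and a positive test result.
#'
#' @return character vector of three preferred terms.
#' @export
hit_pt_keywords <- function() {
  c("heparin-induced thrombocytopenia",
    "heparin-induced thrombocytopenia test",
    "heparin-induced thrombocytopenia test positive")
}

#' Match reaction preferred terms against the HIT keywords
#'
#' Exact string equality after case-folding and whitespace collapse, not
#' substring matching: the keyword list is closed, and e.g. plain
#' "Thrombocytopenia" must not match.
#'
#' @param reactions a character vector of preferred terms (one report), or a
#'   list of such vectors (many reports).
#' @param keywords keyword list, default [hit_pt_keywords()].
#' @return logical: for a list input, one value per report, `TRUE` if any of
#'   its reactions equals a keyword.
#' @export
#' @examples
#' match_hit_pt(c("Heparin-induced thrombocytopenia"))
#' match_hit_pt(list(c("Thrombocytopenia"), c("HEPARIN-INDUCED THROMBOCYTOPENIA")))
match_hit_pt <- function(reactions, keywords = hit_pt_keywords()) {
  keys <- norm_ws(keywords)
  if (!is.list(reactions)) {
    return(any(norm_ws(reactions) %in% keys))
  }
  if (!length(reactions)) return(logical(0))
  flat <- norm_ws(unlist(reactions, use.names = FALSE))
  row <- rep.int(seq_along(reactions), lengths(reactions))
  hit <- flat %in% keys
  out <- logical(length(reactions))
  if (any(hit)) out[unique(row[hit])] <- TRUE
  out
}

# flatten the drug list-columns once: per-mention row index, generic name
# (falling back to the cleaned verbatim name) and role-eligibility
drug_mentions <- function(reports, dict = lmwh_dictionary(),
                          roles = c("PS", "SS")) {
  flat_names <- unlist(reports$drug_names, use.names = FALSE)
  flat_roles <- unlist(reports$drug_roles, use.names = FALSE)
  generic <- normalize_drug(flat_names, dict)
  generic[is.na(generic)] <- norm_drug_key(flat_names[is.na(generic)])
  list(row = rep.int(seq_len(nrow(reports)), lengths(reports$drug_names)),
       generic = generic, role_ok = flat_roles %in% roles)
}

# reports mentioning a drug (normalized name) in one of the given roles
mentions_drug <- function(reports, drug, dict = lmwh_dictionary(),
                          roles = c("PS", "SS"), mentions = NULL) {
  if (!nrow(reports)) return(logical(0))
  m <- mentions %||% drug_mentions(reports, dict, roles)
  sel <- m$generic == drug & m$role_ok
  out <- logical(nrow(reports))
  if (any(sel)) out[unique(m$row[sel])] <- TRUE
  out
}

#' Baseline stratification of HIT reports for one drug
#'
#' Counts and percentages by age band (<18, 18-60, >60, unknown; band edges
#' 18 and 60 fall in the middle band), sex, grouped outcome (death;
#' hospitalization/disability/life-threatening; others) and reporter country
#' (US vs other). Percentages are computed over all supplied reports and sum
#' to 100 within each block up to rounding. The input is expected to be
#' deduplicated and already restricted to the HIT reports of one drug (see
#' [deduplicate_reports()], [match_hit_pt()], [mentions_drug] via
#' [screen_pairs()]); an empty input yields an all-zero table.
#'
#' @param reports AE report tibble.
#' @return tibble with columns `block`, `level`, `n`, `pct` (half-up, 2 dp).
#' @export
baseline_table <- function(reports) {
  total <- nrow(reports)
  age_band <- dplyr::case_when(
    is.na(reports$age_years) ~ "unknown",
    reports$age_years < 18 ~ "<18",
    reports$age_years <= 60 ~ "18-60",
    TRUE ~ ">60"
  )
  sex <- reports$sex
  outcome <- dplyr::case_when(
    is.na(reports$outcome_code) ~ "others",
    reports$outcome_code == "death" ~ "death",
    reports$outcome_code %in% c("hospitalization", "disability",
                                "life_threatening") ~
      "hospitalization/disability/life-threatening",
    TRUE ~ "others"
  )
  country <- ifelse(!is.na(reports$reporter_country) &
                      toupper(reports$reporter_country) == "US",
                    "US", "other_countries")
  blocks <- list(
    age = factor(age_band, levels = c("<18", "18-60", ">60", "unknown")),
    sex = factor(sex, levels = SEX_LEVELS),
    outcome = factor(outcome, levels = c(
      "death", "hospitalization/disability/life-threatening", "others")),
    country = factor(country, levels = c("US", "other_countries"))
  )
  out <- lapply(names(blocks), function(b) {
    tab <- table(blocks[[b]])
    tibble(block = b, level = names(tab), n = as.integer(tab),
           pct = if (total > 0) round_half_up(100 * as.integer(tab) / total, 2) else 0)
  })
  dplyr::bind_rows(out)
}
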