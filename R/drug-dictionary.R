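#' Synonym dictionary for the seven LMWHs
#'
#' Maps brand, trade and salt spellings to generic names for the seven
#' low-molecular-weight heparins (enoxaparin, nadroparin, dalteparin,
#' tinzaparin, bemiparin, reviparin, parnaparin). Lookup through
#' [normalize_drug()] is case-, whitespace- and punctuation-insensitive.
#'
#' @param path optional path to a CSV with columns `generic` and `synonym`;
#'   defaults to the dictionary shipped with the package.
#' @return a tibble with columns `generic` and `synonym`, one row per synonym.
#' @export
#' @examples
#' lmwh_dictionary()
lmwh_dictionary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "lmwh_synonyms.csv", package = "hitsignal")
  if (!file.exists(path)) {
    stop("drug dictionary file not found: ", path, call. = FALSE)
  }
  dict <- readr::read_csv(path, col_types = readr::cols(
    generic = readr::col_character(),
    synonym = readr::col_character()
  ))
  keys <- norm_drug_key(dict$synonym)
  dup <- duplicated(keys)
  if (any(dup)) {
    clash <- dict$synonym[dup]
    # disjointness across generics is an invariant of the dictionary
    stop("synonym(s) mapped to more than one generic: ",
         paste(unique(clash), collapse = ", "), call. = FALSE)
  }
  dict$key <- keys
  dict
}

#' Normalize a verbatim drug name to its LMWH generic
#'
#' Case, surrounding/internal whitespace and punctuation are ignored, so
#' `"ENOXAPARIN SODIUM."` and `"Lovenox"` both resolve to `"enoxaparin"`.
#' Names absent from the dictionary return `NA`.
#'
#' @param verbatim character vector of drug names as reported.
#' @param dict dictionary tibble from [lmwh_dictionary()].
#' @return character vector of generic names, `NA` where unmatched.
#' @export
#' @examples
#' normalize_drug(c("LOVENOX", "ENOXAPARIN SODIUM.", "warfarin"))
normalize_drug <- function(verbatim, dict = lmwh_dictionary()) {
  if (is.null(dict$key)) dict$key <- norm_drug_key(dict$synonym)
  dict$generic[match(norm_drug_key(verbatim), dict$key)]
}

#' The generic names of the seven LMWHs
#' @return character vector of generic names.
#' @export
lmwh_generics <- function() {
  c("enoxaparin", "nadroparin", "dalteparin", "tinzaparin",
    "bemiparin", "reviparin", "parnaparin")
}
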