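# shared internal helpers

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published frequency tables round
#' half up (2.335 -> 2.34). Used for every printed percentage.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @export
#' @examples
#' round_half_up(c(2.335, 2.345), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# lowercase, trim, collapse internal whitespace
norm_ws <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# normalisation for drug-name lookup: also strip punctuation
norm_drug_key <- function(x) {
  x <- norm_ws(x)
  x <- gsub("[[:punct:]]", " ", x)
  gsub("[[:space:]]+", " ", trimws(x))
}

# percentage string helper for x/n notation
frac_label <- function(x, n) sprintf("%d/%d", x, n)

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    stop(sprintf("`%s` must be a single number >= %s", name, lower), call. = FALSE)
  }
  invisible(x)
}
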