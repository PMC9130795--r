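# Small shared helpers. Dyads are always stored in canonical order
# (male1 < male2 lexicographically) so that joins and tallies agree.

dyad_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

canonical_dyad <- function(df, col1, col2) {
  a <- df[[col1]]
  b <- df[[col2]]
  df[[col1]] <- pmin(a, b)
  df[[col2]] <- pmax(a, b)
  df
}

#' Calendar year of a date or timestamp
#' @noRd
year_of <- function(x) as.integer(lubridate::year(x))

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# statistical mode with ties broken toward the larger value
mode_largest <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  max(vals[tab == max(tab)])
}
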