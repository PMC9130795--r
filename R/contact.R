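#' Dyadic contact hours for male-male dyads
#'
#' Observation effort for a dyad is the portion of the party's contact time
#' during which both males were present, at day granularity: the sum of the
#' party's session durations over the days on which the census marks both
#' males present in that party. Dyads that were never co-present get 0 hours.
#' Party contact time is used (rather than focal time) as the common exposure
#' denominator for all dyadic rates.
#'
#' @param ds a [study_dataset()].
#' @param party party id.
#' @param year calendar year (January-December).
#' @return tibble `male1`, `male2` (canonical order), `contact_h`, one row per
#'   unordered pair of males recorded present in the party that year.
#' @export
dyad_contact_hours <- function(ds, party, year) {
  stopifnot(inherits(ds, "study_dataset"))
  if (!party %in% ds$census$party) {
    abort(sprintf("dyad_contact_hours: unknown party '%s'", party))
  }
  # adult/subadult study males only: individuals born into the study
  # (known mother) are infants, not social partners
  males <- ds$individuals$id[ds$individuals$sex == "male" &
                               is.na(ds$individuals$mother_id)]
  cen <- ds$census %>%
    filter(.data$party == !!party, year_of(.data$date) == !!year,
           .data$present, .data$individual_id %in% males)
  ses <- ds$sessions %>%
    filter(.data$party == !!party, year_of(.data$date) == !!year) %>%
    group_by(.data$date) %>%
    summarise(hours = sum(.data$duration_h), .groups = "drop")
  ids <- sort(unique(cen$individual_id))
  if (length(ids) < 2) {
    return(tibble(male1 = character(), male2 = character(),
                  contact_h = double()))
  }
  # presence matrix restricted to session days, weighted by daily hours
  days <- ses$date
  P <- matrix(0, nrow = length(days), ncol = length(ids),
              dimnames = list(NULL, ids))
  cen_s <- cen %>% filter(.data$date %in% days)
  if (nrow(cen_s)) {
    P[cbind(match(cen_s$date, days), match(cen_s$individual_id, ids))] <- 1
  }
  C <- t(P) %*% (P * ses$hours)
  pairs <- t(utils::combn(ids, 2))
  tibble(male1 = pairs[, 1], male2 = pairs[, 2],
         contact_h = C[pairs])
}
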