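fm_affiliative_behaviours <- function() {
  c("groom", "contact_sit", "approach_1m", "greeting", "copulation")
}

#' Daily reproductive-unit assignment from female-male interactions
#'
#' Females in this society exchange far more affiliative and sexual
#' interactions with their primary male than with any other male, so daily
#' unit composition can be read off the interaction record. For each
#' female-day the candidate primary is the male with the most
#' affiliative/sexual interaction occurrences with her over the trailing
#' `window_days` window (any source, occurrences not durations). Assignment
#' is sticky (hysteresis): the incumbent keeps the female unless another male
#' strictly exceeds his windowed count. Before any interaction is observed --
#' or when candidates tie with no incumbent -- the female is unassigned. A
#' female is only assigned on days she is present, and an incumbent who
#' leaves the party loses his females.
#'
#' @param ds a [study_dataset()].
#' @param window_days trailing window length in days.
#' @return tibble `date`, `female_id`, `party`, `male_id` (`NA` =
#'   unassigned), one row per present female-day.
#' @export
assign_daily_units <- function(ds, window_days = 30) {
  males <- ds$individuals$id[ds$individuals$sex == "male" &
                               is.na(ds$individuals$mother_id)]
  females <- ds$individuals$id[ds$individuals$sex == "female" &
                                 is.na(ds$individuals$mother_id)]
  ev <- ds$events %>%
    filter(.data$behaviour %in% fm_affiliative_behaviours(),
           (.data$actor_id %in% males & .data$receiver_id %in% females) |
             (.data$actor_id %in% females & .data$receiver_id %in% males)) %>%
    mutate(female_id = if_else(.data$actor_id %in% females, .data$actor_id,
                               .data$receiver_id),
           male_id = if_else(.data$actor_id %in% males, .data$actor_id,
                             .data$receiver_id),
           date = as.Date(.data$timestamp)) %>%
    count(.data$female_id, .data$male_id, .data$date)

  cen <- ds$census %>% filter(.data$present, .data$individual_id %in% females)
  if (!nrow(cen)) {
    return(tibble(date = as.Date(character()), female_id = character(),
                  party = character(), male_id = character()))
  }
  days <- seq(min(cen$date), max(cen$date), by = "day")
  n_days <- length(days)
  male_cen <- ds$census %>%
    filter(.data$present, .data$individual_id %in% males)

  purrr::map_dfr(sort(unique(cen$individual_id)), function(f) {
    fc <- cen %>% filter(.data$individual_id == f)
    f_party <- fc$party[1]
    fe <- ev %>% filter(.data$female_id == f)
    cand <- sort(unique(fe$male_id))
    # males present in the female's party, by day index
    mc <- male_cen %>% filter(.data$party == f_party)
    pres_m <- matrix(FALSE, n_days, length(males),
                     dimnames = list(NULL, males))
    if (nrow(mc)) {
      pres_m[cbind(match(mc$date, days), match(mc$individual_id, males))] <- TRUE
    }
    if (length(cand)) {
      counts <- matrix(0, n_days, length(cand), dimnames = list(NULL, cand))
      counts[cbind(match(fe$date, days), match(fe$male_id, cand))] <- fe$n
      cum <- apply(counts, 2, cumsum)
      cum <- rbind(matrix(0, 1, length(cand)), cum)
    }
    f_days <- match(fc$date, days)
    incumbent <- NA_character_
    out <- character(n_days)
    out[] <- NA_character_
    for (d in sort(f_days)) {
      if (!is.na(incumbent) && !pres_m[d, incumbent]) incumbent <- NA_character_
      if (length(cand)) {
        win <- cum[d + 1L, ] - cum[max(1L, d + 1L - window_days), ]
        win[!pres_m[d, cand]] <- -Inf
        if (any(is.finite(win) & win > 0)) {
          if (is.na(incumbent)) {
            top <- max(win)
            best <- cand[win == top]
            if (length(best) == 1L && top > 0) incumbent <- best
          } else {
            inc_count <- if (incumbent %in% cand) win[incumbent] else 0
            challengers <- cand[win > max(inc_count, 0)]
            if (length(challengers) == 1L) {
              incumbent <- challengers
            } else if (length(challengers) > 1L) {
              top <- max(win[challengers])
              best <- challengers[win[challengers] == top]
              if (length(best) == 1L) incumbent <- best
              # tie among strict challengers: incumbent retained
            }
          }
        }
      }
      out[d] <- incumbent
    }
    tibble(date = days[sort(f_days)], female_id = f, party = f_party,
           male_id = out[sort(f_days)])
  })
}

#' Daily unit sizes and status per male
#'
#' @param assignments output of [assign_daily_units()].
#' @param ds the [study_dataset()] (for male presence).
#' @return tibble `date`, `male_id`, `party`, `n_females`, `status`
#'   ("primary" when >= 1 assigned female, else "bachelor"), one row per
#'   present male-day.
#' @export
daily_unit_sizes <- function(assignments, ds) {
  males <- ds$individuals$id[ds$individuals$sex == "male" &
                               is.na(ds$individuals$mother_id)]
  pres <- ds$census %>%
    filter(.data$present, .data$individual_id %in% males) %>%
    select(date = "date", male_id = "individual_id", party = "party")
  sizes <- assignments %>%
    filter(!is.na(.data$male_id)) %>%
    count(.data$date, .data$male_id, name = "n_females")
  pres %>%
    left_join(sizes, by = c("date", "male_id")) %>%
    mutate(n_females = if_else(is.na(.data$n_females), 0L,
                               as.integer(.data$n_females)),
           status = if_else(.data$n_females > 0, "primary", "bachelor"))
}

#' Yearly mode of a male's daily unit size
#'
#' The most frequent daily number of associated females over the male's
#' presence days in a calendar year; ties are broken toward the larger value.
#'
#' @param unit_sizes output of [daily_unit_sizes()].
#' @param male_id male id.
#' @param year calendar year.
#' @return integer mode.
#' @export
yearly_mode <- function(unit_sizes, male_id, year) {
  x <- unit_sizes %>%
    filter(.data$male_id == !!male_id, year_of(.data$date) == !!year)
  if (!nrow(x)) {
    abort(sprintf("yearly_mode: male %s has no presence days in %d",
                  male_id, year))
  }
  as.integer(mode_largest(x$n_females))
}

#' Model-ready male-year table
#'
#' Joins the per-male sociality profiles with unit-size statistics, presence
#' days, status summaries and (optionally) yearly sired-offspring counts into
#' the table the count models are fitted on.
#'
#' @param ds a [study_dataset()].
#' @param profiles output of [sociality_profile()].
#' @param unit_sizes output of [daily_unit_sizes()].
#' @param sired optional output of [yearly_sired_counts()].
#' @return tibble with one row per male-year: `male_id`, `party`, `year`,
#'   `bond_strength`, `n_strong_bonds`, `affiliation_proportion`,
#'   `unit_size_mode`, `presence_days`, `days_primary`, `n_sired` (0 when no
#'   paternity table is supplied).
#' @export
male_year_table <- function(ds, profiles, unit_sizes, sired = NULL) {
  usz <- unit_sizes %>%
    mutate(year = year_of(.data$date)) %>%
    group_by(.data$male_id, .data$year) %>%
    summarise(unit_size_mode = as.integer(mode_largest(.data$n_females)),
              presence_days = dplyr::n(),
              days_primary = sum(.data$status == "primary"),
              .groups = "drop")
  out <- profiles %>%
    left_join(usz, by = c("male_id", "year")) %>%
    mutate(unit_size_mode = if_else(is.na(.data$unit_size_mode), 0L,
                                    .data$unit_size_mode),
           presence_days = if_else(is.na(.data$presence_days), 0L,
                                   as.integer(.data$presence_days)),
           days_primary = if_else(is.na(.data$days_primary), 0L,
                                  as.integer(.data$days_primary)))
  if (!is.null(sired)) {
    out <- out %>%
      left_join(sired, by = c("male_id", "year"))
  } else {
    out$n_sired <- 0L
  }
  out %>%
    mutate(n_sired = if_else(is.na(.data$n_sired), 0L,
                             as.integer(.data$n_sired)))
}
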