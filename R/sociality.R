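dsi_behaviour_cols <- function() {
  c("groom_freq", "groom_dur", "contact_sit_freq", "contact_sit_dur",
    "approach_freq")
}

#' Filter redundant within-1-m approaches
#'
#' An approach is dropped when any other recorded social event between the
#' same (unordered) dyad starts within 10 s after it, because such approaches
#' merely announce the behaviour that follows. Events of any source count as
#' follow-ups.
#'
#' @param events event tibble (see [study_dataset()]).
#' @param window_s follow-up window in seconds.
#' @return the approach rows of `events` that survive the filter.
#' @keywords internal
filter_approaches <- function(events, window_s = 10) {
  app <- events %>% filter(.data$behaviour == "approach_1m")
  if (!nrow(app)) return(app)
  key <- dyad_key(events$actor_id, events$receiver_id)
  app_key <- dyad_key(app$actor_id, app$receiver_id)
  t_all <- as.numeric(events$timestamp)
  t_app <- as.numeric(app$timestamp)
  is_app <- events$behaviour == "approach_1m"
  keep <- vapply(seq_len(nrow(app)), function(i) {
    same <- key == app_key[i]
    dt <- t_all - t_app[i]
    follow <- same & dt > 0 & dt <= window_s
    # another event at the exact same instant also counts, except the
    # approach itself
    !any(follow)
  }, logical(1))
  app[keep, ]
}

#' Dyadic behavioural rates for the composite sociality index
#'
#' Computes, per male-male dyad within one party-year, the five rate
#' components of the index: grooming frequency and duration, contact-sit
#' frequency and duration, and frequency of within-1-m approaches.
#' Frequencies are focal events per dyad contact hour; durations are focal
#' seconds per dyad contact hour. Approaches followed by any other social
#' event between the same dyad within 10 s are excluded. Dyads with zero
#' contact hours are omitted.
#'
#' @param ds a [study_dataset()].
#' @param party party id.
#' @param year calendar year.
#' @return tibble `party`, `year`, `male1`, `male2`, `contact_h` and the five
#'   rate columns.
#' @export
compute_dyadic_rates <- function(ds, party, year) {
  n_ses <- sum(year_of(ds$sessions$date) == year & ds$sessions$party == party)
  if (n_ses == 0) {
    abort(sprintf("compute_dyadic_rates: no sessions for party %s in %d",
                  party, year))
  }
  ch <- dyad_contact_hours(ds, party, year)
  if (!nrow(ch)) {
    abort(sprintf("compute_dyadic_rates: no males in party %s, year %d",
                  party, year))
  }
  males <- unique(c(ch$male1, ch$male2))
  ev <- ds$events %>%
    filter(.data$actor_id %in% males, .data$receiver_id %in% males,
           year_of(.data$timestamp) == !!year)
  foc <- ev %>% filter(.data$source == "focal")
  app <- filter_approaches(ev) %>% filter(.data$source == "focal")

  tally <- function(df, beh, what = c("n", "dur")) {
    what <- match.arg(what)
    df %>%
      filter(.data$behaviour == beh) %>%
      canonical_dyad("actor_id", "receiver_id") %>%
      group_by(male1 = .data$actor_id, male2 = .data$receiver_id) %>%
      summarise(val = if (what == "n") dplyr::n() else sum(.data$duration_s),
                .groups = "drop")
  }
  add_rate <- function(tab, df, beh, col, what) {
    t <- tally(df, beh, what)
    tab %>%
      left_join(t, by = c("male1", "male2")) %>%
      mutate(!!col := if_else(is.na(.data$val), 0, .data$val) /
               .data$contact_h) %>%
      select(-"val")
  }
  out <- ch %>%
    filter(.data$contact_h > 0) %>%
    mutate(party = !!party, year = !!year, .before = 1) %>%
    add_rate(foc, "groom", "groom_freq", "n") %>%
    add_rate(foc, "groom", "groom_dur", "dur") %>%
    add_rate(foc, "contact_sit", "contact_sit_freq", "n") %>%
    add_rate(foc, "contact_sit", "contact_sit_dur", "dur") %>%
    add_rate(app, "approach_1m", "approach_freq", "n")
  out
}

#' Dyadic composite sociality index (DSI)
#'
#' For each party-year, the index of dyad xy is the mean over the d included
#' behaviours of that dyad's rate divided by the average rate across all
#' included dyads: `DSI_xy = (1/d) * sum_i f_ixy / fbar_i`. The index is
#' non-negative and averages exactly 1 across the included dyads of a
#' party-year; values above 1 mark dyads that affiliate more than the party
#' average. A behaviour whose party-year mean rate is zero is dropped from
#' the index (with a warning) and `d` reduced accordingly.
#'
#' @param rates output of [compute_dyadic_rates()] (several party-years may
#'   be stacked).
#' @return `rates` with a `dsi` column; attributes `behaviour_means` (tibble
#'   of the party-year mean rates) and `d` are attached.
#' @export
#' @examples
#' rates <- tibble::tibble(party = "p1", year = 2014,
#'                         male1 = c("a", "a", "b"), male2 = c("b", "c", "c"),
#'                         contact_h = 10,
#'                         groom_freq = c(2, 1, 0), groom_dur = c(60, 30, 0),
#'                         contact_sit_freq = c(1, 1, 1),
#'                         contact_sit_dur = c(10, 20, 30),
#'                         approach_freq = c(3, 2, 1))
#' compute_dsi(rates)$dsi
compute_dsi <- function(rates) {
  cols <- intersect(dsi_behaviour_cols(), names(rates))
  if (!length(cols)) abort("compute_dsi: no behaviour rate columns found")
  groups <- rates %>% distinct(.data$party, .data$year)
  out <- purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- rates %>%
      filter(.data$party == groups$party[i], .data$year == groups$year[i])
    if (nrow(g) < 2) {
      abort("compute_dsi: need at least two dyads per party-year")
    }
    means <- vapply(cols, function(cl) mean(g[[cl]]), double(1))
    keep <- means > 0
    if (!any(keep)) {
      abort(sprintf(
        "compute_dsi: all behaviour means are zero for party %s, year %s",
        groups$party[i], groups$year[i]))
    }
    if (any(!keep)) {
      warn(sprintf(
        "compute_dsi: dropping behaviour(s) with zero mean for party %s, year %s: %s",
        groups$party[i], groups$year[i],
        paste(cols[!keep], collapse = ", ")))
    }
    ratio <- as.matrix(g[, cols[keep], drop = FALSE])
    ratio <- sweep(ratio, 2, means[keep], "/")
    g$dsi <- rowMeans(ratio)
    attr(g, "d") <- sum(keep)
    g
  })
  attr(out, "behaviour_means") <- rates %>%
    group_by(.data$party, .data$year) %>%
    summarise(across(all_of(cols), mean), .groups = "drop")
  out
}

#' Per-male sociality profiles
#'
#' Summarises each male's position in the party-year index table:
#' `bond_strength` is the sum of his three largest DSI values (all of them if
#' he has fewer than three partners; with ties at the third place the three
#' summands are fixed by ordering on partner id), `n_strong_bonds` counts his
#' DSI values strictly greater than the party-year mean DSI, and
#' `affiliation_proportion` is the fraction of his focal observation time
#' spent grooming or contact-sitting with other males (as focal actor or
#' receiver). Males without focal time get `NA` with
#' `affiliation_defined = FALSE`.
#'
#' @param dsi output of [compute_dsi()].
#' @param ds the [study_dataset()] the index was computed from.
#' @return tibble `male_id`, `party`, `year`, `bond_strength`,
#'   `n_strong_bonds`, `affiliation_proportion`, `affiliation_defined`.
#' @export
sociality_profile <- function(dsi, ds) {
  long <- bind_rows(
    dsi %>% select("party", "year", male_id = "male1", partner = "male2",
                   "dsi"),
    dsi %>% select("party", "year", male_id = "male2", partner = "male1",
                   "dsi"))
  mean_dsi <- dsi %>%
    group_by(.data$party, .data$year) %>%
    summarise(mean_dsi = mean(.data$dsi), .groups = "drop")
  prof <- long %>%
    left_join(mean_dsi, by = c("party", "year")) %>%
    group_by(.data$party, .data$year, .data$male_id) %>%
    arrange(dplyr::desc(.data$dsi), .data$partner, .by_group = TRUE) %>%
    summarise(bond_strength = sum(head(.data$dsi, 3)),
              n_strong_bonds = sum(.data$dsi > first(.data$mean_dsi)),
              .groups = "drop")

  males <- ds$individuals$id[ds$individuals$sex == "male"]
  affil <- ds$events %>%
    filter(.data$source == "focal",
           .data$behaviour %in% c("groom", "contact_sit"),
           .data$actor_id %in% males, .data$receiver_id %in% males,
           !is.na(.data$focal_id),
           .data$focal_id == .data$actor_id |
             .data$focal_id == .data$receiver_id) %>%
    mutate(year = year_of(.data$timestamp)) %>%
    group_by(male_id = .data$focal_id, .data$year) %>%
    summarise(affil_s = sum(.data$duration_s), .groups = "drop")
  focal_time <- if (is.null(ds$focals)) {
    tibble(male_id = character(), year = integer(), focal_s = double())
  } else {
    ds$focals %>%
      mutate(year = year_of(.data$date)) %>%
      group_by(.data$male_id, .data$year) %>%
      summarise(focal_s = 3600 * sum(.data$duration_h), .groups = "drop")
  }
  prof %>%
    left_join(affil, by = c("male_id", "year")) %>%
    left_join(focal_time, by = c("male_id", "year")) %>%
    mutate(affil_s = if_else(is.na(.data$affil_s), 0, .data$affil_s),
           affiliation_defined = !is.na(.data$focal_s) & .data$focal_s > 0,
           affiliation_proportion = if_else(.data$affiliation_defined,
                                            .data$affil_s / .data$focal_s,
                                            NA_real_)) %>%
    select("male_id", "party", "year", "bond_strength", "n_strong_bonds",
           "affiliation_proportion", "affiliation_defined")
}

#' Dyadic coalitionary-support counts and rates
#'
#' Counts, per male-male dyad of a party-year, the coalition events (focal
#' and ad libitum) whose ally pair equals the dyad, and expresses them per
#' dyad contact hour. Every dyad of the party-year appears, with zero counts
#' where no coalition was seen.
#'
#' @param ds a [study_dataset()].
#' @param party party id.
#' @param year calendar year.
#' @return tibble `party`, `year`, `male1`, `male2`, `contact_h`,
#'   `n_coalitions`, `rate_per_h`.
#' @export
coalition_rate <- function(ds, party, year) {
  ch <- dyad_contact_hours(ds, party, year)
  males <- unique(c(ch$male1, ch$male2))
  co <- ds$coalitions %>%
    filter(year_of(.data$timestamp) == !!year,
           .data$ally1_id %in% males, .data$ally2_id %in% males) %>%
    canonical_dyad("ally1_id", "ally2_id") %>%
    count(male1 = .data$ally1_id, male2 = .data$ally2_id,
          name = "n_coalitions")
  ch %>%
    mutate(party = !!party, year = !!year, .before = 1) %>%
    left_join(co, by = c("male1", "male2")) %>%
    mutate(n_coalitions = if_else(is.na(.data$n_coalitions), 0L,
                                  .data$n_coalitions),
           rate_per_h = if_else(.data$contact_h > 0,
                                .data$n_coalitions / .data$contact_h, 0))
}
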