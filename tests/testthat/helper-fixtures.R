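# Hand-built minimal dataset: one party, configurable males/events.
# All tables are constructed explicitly so tests control every record.

toy_tables <- function() {
  individuals <- tibble::tibble(
    id = c("A", "B", "C", "F1"),
    sex = c("male", "male", "male", "female"),
    party = "p1",
    birth_date = as.Date(NA),
    mother_id = NA_character_)
  days <- seq(as.Date("2015-01-01"), as.Date("2015-01-10"), by = "day")
  census <- tidyr::crossing(date = days, individual_id = individuals$id) |>
    dplyr::mutate(party = "p1", present = TRUE, repro_state = NA_character_)
  sessions <- tibble::tibble(date = days, party = "p1", duration_h = 1)
  events <- tibble::tibble(
    timestamp = as.POSIXct("2015-01-02 10:00:00", tz = "UTC"),
    actor_id = "A", receiver_id = "B", behaviour = "groom",
    duration_s = 60, source = "focal", focal_id = "A")
  coalitions <- tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    ally1_id = character(), ally2_id = character(),
    target_id = character(), source = character())
  list(individuals = individuals, census = census, sessions = sessions,
       events = events, coalitions = coalitions)
}

toy_dataset <- function(...) {
  tabs <- toy_tables()
  repl <- list(...)
  for (nm in names(repl)) tabs[[nm]] <- repl[[nm]]
  study_dataset(individuals = tabs$individuals, census = tabs$census,
                sessions = tabs$sessions, events = tabs$events,
                coalitions = tabs$coalitions, genotypes = tabs$genotypes,
                focals = tabs$focals, ages = tabs$ages)
}

small_sim <- function(seed = 42, males = 10, years = 1, sessions = 40,
                      females_per_party = 6, ...) {
  simulate_study(sim_config(seed = seed, n_parties = 1,
                            males_per_party = males,
                            females_per_party = females_per_party,
                            years = years, sessions_per_year = sessions,
                            n_extra_males = 2, ...))
}

# ---- independent brute-force oracles ----------------------------------------

# day-by-day contact hours for one dyad
bf_contact_hours <- function(ds, party, year, m1, m2) {
  total <- 0
  ses <- ds$sessions[ds$sessions$party == party &
                       format(ds$sessions$date, "%Y") == as.character(year), ]
  for (i in seq_len(nrow(ses))) {
    d <- ses$date[i]
    ok1 <- any(ds$census$date == d & ds$census$individual_id == m1 &
                 ds$census$party == party & ds$census$present)
    ok2 <- any(ds$census$date == d & ds$census$individual_id == m2 &
                 ds$census$party == party & ds$census$present)
    if (ok1 && ok2) total <- total + ses$duration_h[i]
  }
  total
}

# event-loop recomputation of the five dyadic rates for one party-year
bf_dyadic_rates <- function(ds, party, year) {
  ch <- dyad_contact_hours(ds, party, year)
  ch <- ch[ch$contact_h > 0, ]
  ev <- ds$events[format(ev_ts <- ds$events$timestamp, "%Y") ==
                    as.character(year), ]
  out <- ch
  for (col in c("groom_freq", "groom_dur", "contact_sit_freq",
                "contact_sit_dur", "approach_freq")) out[[col]] <- 0
  for (i in seq_len(nrow(ch))) {
    m1 <- ch$male1[i]; m2 <- ch$male2[i]
    sub <- ev[(ev$actor_id == m1 & ev$receiver_id == m2) |
                (ev$actor_id == m2 & ev$receiver_id == m1), ]
    foc <- sub[sub$source == "focal", ]
    gro <- foc[foc$behaviour == "groom", ]
    cs <- foc[foc$behaviour == "contact_sit", ]
    app <- foc[foc$behaviour == "approach_1m", ]
    keep <- logical(nrow(app))
    for (j in seq_len(nrow(app))) {
      dt <- as.numeric(sub$timestamp) - as.numeric(app$timestamp[j])
      keep[j] <- !any(dt > 0 & dt <= 10)
    }
    h <- ch$contact_h[i]
    out$groom_freq[i] <- nrow(gro) / h
    out$groom_dur[i] <- sum(gro$duration_s) / h
    out$contact_sit_freq[i] <- nrow(cs) / h
    out$contact_sit_dur[i] <- sum(cs$duration_s) / h
    out$approach_freq[i] <- sum(keep) / h
  }
  out
}

# definitional DSI recomputation from a rate table (single party-year)
bf_dsi <- function(rates) {
  cols <- c("groom_freq", "groom_dur", "contact_sit_freq", "contact_sit_dur",
            "approach_freq")
  means <- sapply(cols, function(cl) mean(rates[[cl]]))
  cols <- cols[means > 0]
  means <- means[means > 0]
  sapply(seq_len(nrow(rates)), function(i) {
    mean(sapply(seq_along(cols),
                function(j) rates[[cols[j]]][i] / means[j]))
  })
}

# sort-and-sum profile oracle for one male from a dsi table (one party-year)
bf_profile <- function(dsi_tab, male) {
  vals <- c(dsi_tab$dsi[dsi_tab$male1 == male],
            dsi_tab$dsi[dsi_tab$male2 == male])
  vals <- sort(vals, decreasing = TRUE)
  list(bond_strength = sum(vals[seq_len(min(3, length(vals)))]),
       n_strong = sum(vals > mean(dsi_tab$dsi)))
}

# manual coalition tally for one party-year
bf_coalition_counts <- function(ds, party, year, m1, m2) {
  co <- ds$coalitions
  sum(format(co$timestamp, "%Y") == as.character(year) &
        ((co$ally1_id == m1 & co$ally2_id == m2) |
           (co$ally1_id == m2 & co$ally2_id == m1)))
}

# full-enumeration trio-likelihood oracle at one locus: enumerates parental
# transmissions and, separately, every possible observed offspring genotype
# under the per-allele error model, then reads off the requested probability
bf_locus_lr <- function(obs, mom, dad, p, eps) {
  k <- length(p)
  p_obs_allele <- function(a, t) (1 - eps) * (a == t) + eps * p[a]
  prob_obs_given_true <- function(o, tm, tc) {
    # o unordered pair; first observed slot matched to either true gamete
    if (o[1] == o[2]) {
      p_obs_allele(o[1], tm) * p_obs_allele(o[2], tc)
    } else {
      p_obs_allele(o[1], tm) * p_obs_allele(o[2], tc) +
        p_obs_allele(o[2], tm) * p_obs_allele(o[1], tc)
    }
  }
  num <- 0
  for (tm in mom) for (tc in dad) {
    num <- num + 0.25 * prob_obs_given_true(obs, tm, tc)
  }
  den <- 0
  for (tm in mom) for (tc in seq_len(k)) {
    den <- den + 0.5 * p[tc] * prob_obs_given_true(obs, tm, tc)
  }
  num / den
}

geno_tab <- function(loci, a1, a2) {
  tibble::tibble(locus = loci, allele1 = a1, allele2 = a2)
}

# pedigree-only dataset for parentage tests: n_m candidate males, n_f
# mothers, n_o offspring with known true fathers; genotypes via
# simulate_genotypes
pedigree_sim <- function(seed, n_m = 49, n_f = 33, n_o = 36, n_loci = 23,
                         genotyping_error = 0, null_loci = integer(0),
                         p_genotyped = 1, ...) {
  cfg <- sim_config(seed = seed, n_loci = n_loci,
                    genotyping_error = genotyping_error,
                    null_loci = null_loci, ...)
  withr::with_seed(seed, {
    males <- sprintf("M%02d", seq_len(n_m))
    fems <- sprintf("F%02d", seq_len(n_f))
    offs <- sprintf("O%02d", seq_len(n_o))
    mothers <- sample(fems, n_o, replace = TRUE)
    fathers <- sample(males, n_o, replace = TRUE)
    individuals <- tibble::tibble(
      id = c(males, fems, offs),
      sex = c(rep("male", n_m), rep("female", n_f),
              sample(c("male", "female"), n_o, TRUE)),
      party = "p1",
      birth_date = c(rep(as.Date(NA), n_m + n_f),
                     as.Date("2015-06-01") + seq_len(n_o)),
      mother_id = c(rep(NA_character_, n_m + n_f), mothers))
    truth <- tibble::tibble(offspring_id = offs, father_id = fathers)
    geno_ids <- c(males, fems,
                  offs[runif(n_o) < p_genotyped])
    gt <- simulate_genotypes(cfg, individuals, truth, subset_ids = geno_ids,
                             seed = seed + 1)
    days <- as.Date("2015-01-01")
    ds <- study_dataset(
      individuals = individuals,
      census = tibble::tibble(date = days, individual_id = individuals$id[1],
                              party = "p1", present = TRUE,
                              repro_state = NA_character_),
      sessions = tibble::tibble(date = days, party = "p1", duration_h = 1),
      events = toy_tables()$events[0, ],
      coalitions = toy_tables()$coalitions,
      genotypes = gt)
    list(ds = ds, truth = truth)
  })
}
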