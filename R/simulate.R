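#' Configuration for the synthetic study generator
#'
#' The generator emulates a multi-year field study of two baboon parties:
#' daily census with demographic change, party contact sessions, focal and
#' ad libitum social events among males, female-male interactions that encode
#' reproductive-unit membership, two-ally coalitions, births with a strong
#' primary-male paternity skew, and multi-locus microsatellite genotypes with
#' Mendelian inheritance, optional genotyping error and null alleles.
#'
#' Dyadic affiliation is driven by a latent log-normal affinity `a_xy`
#' (mean 1) that multiplies all affiliative event rates of a dyad, and by a
#' trade-off factor `exp(gamma * unit_size)` per male linking the number of
#' females he holds to his male-male affiliation time (`gamma <= 0`).
#' Observed focal records are a thinned view of the underlying event process:
#' an event involving males x and y is captured on a focal protocol with
#' probability `min(1, 2 * focal_fraction)`.
#'
#' @param seed integer RNG seed; a fixed seed makes the whole dataset
#'   reproducible. One master stream is split into per-component sub-streams
#'   so adding a component does not perturb the others.
#' @param n_parties,males_per_party,females_per_party study community layout.
#' @param n_extra_males genotyped males outside the study parties (candidate
#'   fathers for extra-party paternities).
#' @param years,start_year calendar years simulated (January-December).
#' @param sessions_per_year,mean_session_h,session_shape daily contact
#'   sessions per party-year; durations are Gamma with the given shape.
#' @param focal_fraction fraction of party contact time each male is the
#'   focal subject.
#' @param rates named baseline male-male event rates (events per dyad contact
#'   hour) for `groom`, `contact_sit`, `approach_1m`, `greeting`,
#'   `aggression`, `retreat`.
#' @param groom_duration,contact_sit_duration `c(meanlog, sdlog)` of
#'   log-normal bout durations in seconds.
#' @param adlib_groom_prob probability a non-focal grooming bout is still
#'   recorded ad libitum.
#' @param approach_before_prob probability a recorded affiliative bout is
#'   preceded (< 10 s) by a within-1-m approach, exercising the approach
#'   redundancy filter.
#' @param affinity_sdlog sdlog of the latent log-normal dyadic affinity
#'   (mean fixed at 1). The default 1.6 puts ~21% of dyads above the party
#'   average, matching the right-skewed index distribution of wild parties.
#' @param gamma trade-off coefficient (<= 0) on a male's unit size.
#' @param coalition_rate baseline coalitionary-support rate per dyad contact
#'   hour (multiplied by affinity).
#' @param fm_rate_primary,fm_rate_other female-male interaction occurrence
#'   rates per hour with the female's primary male vs. each other male.
#' @param fm_behaviour_probs sampling probabilities of female-male behaviours.
#' @param transfer_prob per-day probability a female transfers to another
#'   unit.
#' @param p_male_offstudy,p_female_offstudy probability an adult is not
#'   present the whole study (late arrival or early departure).
#' @param birth_rate_day per present-female-day birth probability.
#' @param gestation_days gestation length used to date conceptions.
#' @param paternity_skew probability an offspring is sired by the mother's
#'   primary male at conception.
#' @param p_extra_sire probability a non-primary sire is an extra-party male.
#' @param p_offspring_genotyped probability an infant could be sampled for
#'   genotyping.
#' @param n_loci,allele_count_probs,dirichlet_alpha microsatellite panel:
#'   number of loci, distribution of allele counts per locus, Dirichlet
#'   concentration of allele frequencies.
#' @param min_locus_het minimum expected heterozygosity per locus; frequency
#'   draws below it are rejected and redrawn. 0 disables the filter. Field
#'   panels are optimised marker sets, so a positive floor emulates that
#'   selection.
#' @param genotyping_error per-allele mistyping probability.
#' @param null_loci integer indices of loci carrying a null allele.
#' @param null_freq null-allele frequency at those loci.
#'
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_parties = 2L,
                       males_per_party = 15L,
                       females_per_party = 20L,
                       n_extra_males = 19L,
                       years = 4L,
                       start_year = 2014L,
                       sessions_per_year = 110L,
                       mean_session_h = 4.5,
                       session_shape = 20,
                       focal_fraction = 0.03,
                       rates = c(groom = 0.12, contact_sit = 0.15,
                                 approach_1m = 0.40, greeting = 0.10,
                                 aggression = 0.01, retreat = 0.03),
                       groom_duration = c(meanlog = log(150), sdlog = 0.5),
                       contact_sit_duration = c(meanlog = log(120), sdlog = 0.5),
                       adlib_groom_prob = 0.3,
                       approach_before_prob = 0.25,
                       affinity_sdlog = 1.6,
                       gamma = -0.2,
                       coalition_rate = 0.00075,
                       fm_rate_primary = 0.6,
                       fm_rate_other = 0.03,
                       fm_behaviour_probs = c(groom = 0.40, contact_sit = 0.25,
                                              greeting = 0.20,
                                              copulation = 0.15),
                       transfer_prob = 0.001,
                       p_male_offstudy = 0.15,
                       p_female_offstudy = 0.10,
                       birth_rate_day = 0.00115,
                       gestation_days = 184L,
                       paternity_skew = 0.917,
                       p_extra_sire = 0.02,
                       p_offspring_genotyped = 0.72,
                       n_loci = 24L,
                       allele_count_probs = c(`2` = 0.20, `3` = 0.25,
                                              `4` = 0.25, `5` = 0.15,
                                              `6` = 0.10, `7` = 0.05),
                       dirichlet_alpha = 1,
                       min_locus_het = 0,
                       genotyping_error = 0,
                       null_loci = integer(0),
                       null_freq = 0.2) {
  cfg <- as.list(environment())
  # YAML deserialisation hands named vectors back as lists; coerce
  for (nm in c("rates", "allele_count_probs", "fm_behaviour_probs",
               "groom_duration", "contact_sit_duration")) {
    if (is.list(cfg[[nm]])) cfg[[nm]] <- unlist(cfg[[nm]])
  }
  cfg$null_loci <- as.integer(unlist(cfg$null_loci))
  probs <- c(cfg$adlib_groom_prob, cfg$approach_before_prob, cfg$transfer_prob,
             cfg$p_male_offstudy, cfg$p_female_offstudy, cfg$birth_rate_day,
             cfg$paternity_skew, cfg$p_extra_sire, cfg$p_offspring_genotyped,
             cfg$genotyping_error, cfg$null_freq, cfg$focal_fraction)
  if (any(probs < 0 | probs > 1)) {
    abort("sim_config: probabilities must lie in [0, 1]")
  }
  if (any(cfg$rates < 0) || cfg$coalition_rate < 0 ||
      cfg$fm_rate_primary < 0 || cfg$fm_rate_other < 0) {
    abort("sim_config: behaviour rates must be >= 0")
  }
  if (cfg$gamma > 0) abort("sim_config: gamma must be <= 0")
  if (cfg$affinity_sdlog < 0) abort("sim_config: affinity_sdlog must be >= 0")
  structure(cfg, class = c("sim_config", "list"))
}

rdirichlet1 <- function(k, alpha) {
  g <- rgamma(k, shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a synthetic study dataset with ground truth
#'
#' Draws a complete [study_dataset()] from a [sim_config()] together with a
#' truth table: the latent dyadic affinities, the true daily unit membership,
#' the true father of every offspring and the trade-off coefficient used.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `dataset` (a [study_dataset()]) and `truth`
#'   (list: `affinities`, `units_daily`, `fathers`, `gamma`, `config`).
#' @export
#' @examples
#' sim <- simulate_study(sim_config(seed = 7, n_parties = 1,
#'                                  males_per_party = 5, females_per_party = 3,
#'                                  years = 1, sessions_per_year = 20))
#' sim$dataset
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- withr::with_seed(cfg$seed,
                            sample.int(.Machine$integer.max - 1L, 12L))

  start <- as.Date(sprintf("%d-01-01", cfg$start_year))
  end <- as.Date(sprintf("%d-12-31", cfg$start_year + cfg$years - 1L))
  all_days <- seq(start, end, by = "day")
  n_days <- length(all_days)
  parties <- sprintf("p%d", seq_len(cfg$n_parties))

  ## -- 1. demography ---------------------------------------------------------
  demo <- withr::with_seed(seeds[1], {
    make_adults <- function(party, sex, n, p_off) {
      pre <- if (sex == "male") "M" else "F"
      ids <- sprintf("%s_%s%02d", party, pre, seq_len(n))
      arr <- rep(1L, n)
      dep <- rep(n_days, n)
      off <- runif(n) < p_off
      late <- off & runif(n) < 0.5
      arr[late] <- sample.int(floor(n_days * 0.6), sum(late), replace = TRUE)
      early <- off & !late
      dep[early] <- n_days - sample.int(floor(n_days * 0.6), sum(early),
                                        replace = TRUE)
      tibble(id = ids, sex = sex, party = party,
             birth_date = as.Date(NA), mother_id = NA_character_,
             arr = arr, dep = dep)
    }
    purrr::map_dfr(parties, function(p) {
      bind_rows(make_adults(p, "male", cfg$males_per_party, cfg$p_male_offstudy),
                make_adults(p, "female", cfg$females_per_party,
                            cfg$p_female_offstudy))
    }) %>%
      bind_rows(if (cfg$n_extra_males > 0) {
        tibble(id = sprintf("ex_M%02d", seq_len(cfg$n_extra_males)),
               sex = "male", party = "extra", birth_date = as.Date(NA),
               mother_id = NA_character_, arr = NA_integer_,
               dep = NA_integer_)
      })
  })

  ## -- 2. contact sessions ---------------------------------------------------
  sessions <- withr::with_seed(seeds[2], {
    purrr::map_dfr(parties, function(p) {
      purrr::map_dfr(seq_len(cfg$years), function(yi) {
        yr <- cfg$start_year + yi - 1L
        ydays <- all_days[year_of(all_days) == yr]
        nses <- min(cfg$sessions_per_year, length(ydays))
        dates <- sort(sample(ydays, nses))
        tibble(date = dates, party = p,
               duration_h = rgamma(nses, shape = cfg$session_shape,
                                   rate = cfg$session_shape / cfg$mean_session_h))
      })
    })
  })

  ## -- 3. dyadic affinities --------------------------------------------------
  affinities <- withr::with_seed(seeds[3], {
    purrr::map_dfr(parties, function(p) {
      ids <- sort(demo$id[demo$party == p & demo$sex == "male"])
      pr <- t(utils::combn(ids, 2))
      s <- cfg$affinity_sdlog
      tibble(party = p, male1 = pr[, 1], male2 = pr[, 2],
             affinity = rlnorm(nrow(pr), meanlog = -s^2 / 2, sdlog = s))
    })
  })

  ## -- 4. daily unit membership ---------------------------------------------
  present_at <- function(ids, day_idx) {
    i <- match(ids, demo$id)
    !is.na(demo$arr[i]) & demo$arr[i] <= day_idx & demo$dep[i] >= day_idx
  }
  units <- withr::with_seed(seeds[4], {
    purrr::map(parties, function(p) {
      males <- demo$id[demo$party == p & demo$sex == "male"]
      fems <- demo$id[demo$party == p & demo$sex == "female"]
      w <- rgamma(length(males), shape = 0.4, rate = 1)
      names(w) <- males
      primary <- matrix(NA_character_, nrow = length(fems), ncol = n_days,
                        dimnames = list(fems, NULL))
      cur <- setNames(rep(NA_character_, length(fems)), fems)
      for (d in seq_len(n_days)) {
        pm <- males[present_at(males, d)]
        if (!length(pm)) { cur[] <- NA_character_; next }
        pf <- fems[present_at(fems, d)]
        for (f in pf) {
          if (is.na(cur[f]) || !(cur[f] %in% pm)) {
            cur[f] <- sample(pm, 1, prob = w[pm])
          } else if (runif(1) < cfg$transfer_prob && length(pm) > 1) {
            oth <- setdiff(pm, cur[f])
            cur[f] <- sample(oth, 1, prob = w[oth])
          }
        }
        cur[setdiff(fems, pf)] <- NA_character_
        primary[pf, d] <- cur[pf]
      }
      list(party = p, males = males, fems = fems, primary = primary)
    })
  })
  units_daily <- purrr::map_dfr(units, function(u) {
    idx <- which(!is.na(u$primary), arr.ind = TRUE)
    tibble(date = all_days[idx[, 2]], female_id = rownames(u$primary)[idx[, 1]],
           male_id = u$primary[idx], party = u$party)
  })
  # daily unit size per male (males with no female that day -> 0)
  unit_size <- purrr::map(units, function(u) {
    m <- matrix(0L, nrow = length(u$males), ncol = n_days,
                dimnames = list(u$males, NULL))
    if (nrow(u$primary)) {
      for (d in seq_len(n_days)) {
        tab <- table(u$primary[, d])
        if (length(tab)) m[names(tab), d] <- as.integer(tab)
      }
    }
    m
  })
  names(unit_size) <- parties

  ## -- 5. births and true paternity ------------------------------------------
  births <- withr::with_seed(seeds[5], {
    out <- list()
    k <- 0L
    for (u in units) {
      p <- u$party
      males <- u$males
      extra <- demo$id[demo$party == "extra"]
      for (f in u$fems) {
        pres <- which(present_at(f, seq_len(n_days)))
        if (!length(pres)) next
        hits <- pres[runif(length(pres)) < cfg$birth_rate_day]
        last <- -Inf
        for (d in hits) {
          if (d - last < 300) next
          last <- d
          k <- k + 1L
          conc <- max(1L, d - cfg$gestation_days)
          prim <- u$primary[f, conc]
          if (is.na(prim)) {
            first_ok <- which(!is.na(u$primary[f, ]))[1]
            prim <- if (is.na(first_ok)) NA_character_ else
              u$primary[f, first_ok]
          }
          pm <- males[present_at(males, conc)]
          if (!is.na(prim) && runif(1) < cfg$paternity_skew) {
            father <- prim
          } else if (length(extra) && runif(1) < cfg$p_extra_sire) {
            father <- sample(extra, 1)
          } else {
            pool <- setdiff(pm, prim)
            father <- if (length(pool)) sample(pool, 1) else
              if (!is.na(prim)) prim else sample(extra, 1)
          }
          out[[k]] <- tibble(
            id = sprintf("%s_I%03d", p, k), party = p,
            sex = sample(c("male", "female"), 1),
            birth_date = all_days[d], mother_id = f,
            father_id = father, conception_date = all_days[conc],
            sampled = runif(1) < cfg$p_offspring_genotyped)
        }
      }
    }
    if (k) bind_rows(out) else
      tibble(id = character(), party = character(), sex = character(),
             birth_date = as.Date(character()), mother_id = character(),
             father_id = character(), conception_date = as.Date(character()),
             sampled = logical())
  })

  individuals <- bind_rows(
    demo %>% select("id", "sex", "party", "birth_date", "mother_id"),
    births %>% select("id", "sex", "party", "birth_date", "mother_id"))

  ## -- census (study parties, adults + infants from birth) -------------------
  census <- purrr::map_dfr(parties, function(p) {
    ids <- demo$id[demo$party == p]
    purrr::map_dfr(ids, function(i) {
      j <- match(i, demo$id)
      d <- seq(demo$arr[j], demo$dep[j])
      tibble(date = all_days[d], individual_id = i, party = p, present = TRUE,
             repro_state = NA_character_)
    })
  })
  if (nrow(births)) {
    census <- bind_rows(census, purrr::map_dfr(seq_len(nrow(births)), function(i) {
      d <- seq(match(births$birth_date[i], all_days), n_days)
      tibble(date = all_days[d], individual_id = births$id[i],
             party = births$party[i], present = TRUE,
             repro_state = NA_character_)
    }))
  }

  day_hours <- sessions %>%
    group_by(.data$party, .data$date) %>%
    summarise(hours = sum(.data$duration_h), .groups = "drop")

  ## -- 6. male-male social events --------------------------------------------
  p_focal <- min(1, 2 * cfg$focal_fraction)
  mm_events <- withr::with_seed(seeds[6], {
    purrr::map_dfr(parties, function(p) {
      dy <- affinities %>% filter(.data$party == p)
      dh <- day_hours %>% filter(.data$party == p)
      if (!nrow(dy) || !nrow(dh)) return(NULL)
      grid <- tidyr::crossing(dy, dh %>% select("date", "hours"))
      didx <- match(grid$date, all_days)
      us <- unit_size[[p]]
      both <- present_at(grid$male1, didx) & present_at(grid$male2, didx)
      grid <- grid[both, ]
      didx <- didx[both]
      tf <- exp(cfg$gamma * (us[cbind(match(grid$male1, rownames(us)), didx)] +
                             us[cbind(match(grid$male2, rownames(us)), didx)]))
      lam0 <- grid$affinity * tf * grid$hours
      purrr::map_dfr(names(cfg$rates), function(b) {
        n <- rpois(nrow(grid), cfg$rates[[b]] * lam0)
        keep <- n > 0
        if (!any(keep)) return(NULL)
        g <- grid[rep(which(keep), n[keep]), ]
        ne <- nrow(g)
        focal <- runif(ne) < p_focal
        recorded <- focal |
          (b == "groom" & runif(ne) < cfg$adlib_groom_prob) |
          b == "aggression"
        g <- g[recorded, ]
        focal <- focal[recorded]
        ne <- nrow(g)
        if (!ne) return(NULL)
        dur <- if (b == "groom") {
          round(rlnorm(ne, cfg$groom_duration[["meanlog"]],
                       cfg$groom_duration[["sdlog"]]))
        } else if (b == "contact_sit") {
          round(rlnorm(ne, cfg$contact_sit_duration[["meanlog"]],
                       cfg$contact_sit_duration[["sdlog"]]))
        } else 0
        swap <- runif(ne) < 0.5
        tibble(
          timestamp = as.POSIXct(g$date, tz = "UTC") + 9 * 3600 +
            floor(runif(ne, 0, pmax(1, g$hours * 3600 - 600))),
          actor_id = if_else(swap, g$male2, g$male1),
          receiver_id = if_else(swap, g$male1, g$male2),
          behaviour = b, duration_s = as.double(dur),
          source = if_else(focal, "focal", "adlib"),
          focal_id = if_else(focal,
                             if_else(runif(ne) < 0.5, g$male1, g$male2),
                             NA_character_))
      })
    })
  })
  # approaches shortly before affiliative bouts (exercises the 10-s filter)
  pre_app <- withr::with_seed(seeds[7], {
    cand <- if (is.null(mm_events) || !nrow(mm_events)) NULL else
      mm_events %>%
        filter(.data$behaviour %in% c("groom", "contact_sit"),
               .data$source == "focal")
    if (is.null(cand)) cand <- mm_events[0, ]
    if (nrow(cand)) {
      cand <- cand[runif(nrow(cand)) < cfg$approach_before_prob, ]
    }
    if (!nrow(cand)) NULL else
      cand %>%
        mutate(timestamp = .data$timestamp -
                 sample(1:9, nrow(cand), replace = TRUE),
               behaviour = "approach_1m", duration_s = 0)
  })
  mm_events <- bind_rows(mm_events, pre_app)
  empty_events <- tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                         actor_id = character(), receiver_id = character(),
                         behaviour = character(), duration_s = double(),
                         source = character(), focal_id = character())
  if (is.null(mm_events) || !nrow(mm_events)) mm_events <- empty_events

  ## -- 7. female-male interaction events -------------------------------------
  fm_events <- withr::with_seed(seeds[8], {
    purrr::map_dfr(seq_along(parties), function(pi) {
      p <- parties[pi]
      u <- units[[pi]]
      dh <- day_hours %>% filter(.data$party == p)
      if (!nrow(dh) || !length(u$fems)) return(NULL)
      didx <- match(dh$date, all_days)
      grid <- tidyr::crossing(tibble(female = u$fems),
                              tibble(di = didx, hours = dh$hours))
      grid <- grid[present_at(grid$female, grid$di), ]
      grid$primary <- u$primary[cbind(match(grid$female, u$fems), grid$di)]
      # interactions with the primary male, plus a thinner stream with the
      # other party males (partner drawn uniformly, draws landing on an
      # absent male or the primary are discarded)
      n1 <- rpois(nrow(grid), cfg$fm_rate_primary * grid$hours *
                    as.integer(!is.na(grid$primary)))
      n2 <- rpois(nrow(grid), cfg$fm_rate_other *
                    max(0, length(u$males) - 1) * grid$hours)
      g1 <- grid[rep(seq_len(nrow(grid)), n1), ]
      g1$male <- g1$primary
      g2 <- grid[rep(seq_len(nrow(grid)), n2), ]
      if (nrow(g2)) {
        g2$male <- sample(u$males, nrow(g2), replace = TRUE)
        keep <- !is.na(g2$male) &
          (is.na(g2$primary) | g2$male != g2$primary) &
          present_at(g2$male, g2$di)
        g2 <- g2[keep, ]
      }
      g <- bind_rows(g1 %>% filter(!is.na(.data$male)), g2)
      ne <- nrow(g)
      if (!ne) return(NULL)
      beh <- sample(names(cfg$fm_behaviour_probs), ne, replace = TRUE,
                    prob = cfg$fm_behaviour_probs)
      dur <- if_else(beh %in% c("groom", "contact_sit"),
                     round(rlnorm(ne, cfg$groom_duration[["meanlog"]],
                                  cfg$groom_duration[["sdlog"]])), 0)
      swap <- runif(ne) < 0.5
      tibble(timestamp = as.POSIXct(all_days[g$di], tz = "UTC") + 9 * 3600 +
               floor(runif(ne, 0, 6 * 3600)),
             actor_id = if_else(swap, g$male, g$female),
             receiver_id = if_else(swap, g$female, g$male),
             behaviour = beh, duration_s = as.double(dur),
             source = "adlib", focal_id = NA_character_)
    })
  })

  events <- bind_rows(mm_events, fm_events)
  if (!nrow(events)) events <- empty_events
  events <- events %>%
    arrange(.data$timestamp, .data$actor_id, .data$behaviour)

  ## -- 8. coalitions ---------------------------------------------------------
  coalitions <- withr::with_seed(seeds[9], {
    purrr::map_dfr(parties, function(p) {
      dy <- affinities %>% filter(.data$party == p)
      dh <- day_hours %>% filter(.data$party == p)
      if (!nrow(dy) || !nrow(dh)) return(NULL)
      grid <- tidyr::crossing(dy, dh %>% select("date", "hours"))
      didx <- match(grid$date, all_days)
      both <- present_at(grid$male1, didx) & present_at(grid$male2, didx)
      grid <- grid[both, ]
      didx <- didx[both]
      n <- rpois(nrow(grid), cfg$coalition_rate * grid$affinity * grid$hours)
      keep <- which(n > 0)
      if (!length(keep)) return(NULL)
      g <- grid[rep(keep, n[keep]), ]
      gi <- didx[rep(keep, n[keep])]
      males <- sort(unique(c(dy$male1, dy$male2)))
      target <- vapply(seq_len(nrow(g)), function(i) {
        pool <- males[present_at(males, gi[i])]
        pool <- setdiff(pool, c(g$male1[i], g$male2[i]))
        if (length(pool)) sample(pool, 1) else NA_character_
      }, character(1))
      ok <- !is.na(target)
      g <- g[ok, ]
      target <- target[ok]
      ne <- nrow(g)
      tibble(timestamp = as.POSIXct(g$date, tz = "UTC") + 9 * 3600 +
               floor(runif(ne, 0, pmax(1, g$hours * 3600 - 600))),
             ally1_id = g$male1, ally2_id = g$male2, target_id = target,
             source = if_else(runif(ne) < p_focal, "focal", "adlib"))
    })
  })
  if (!nrow(coalitions)) {
    coalitions <- tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                         ally1_id = character(), ally2_id = character(),
                         target_id = character(), source = character())
  }

  ## -- focal observation time ------------------------------------------------
  focals <- purrr::map_dfr(parties, function(p) {
    dh <- day_hours %>% filter(.data$party == p)
    males <- demo$id[demo$party == p & demo$sex == "male"]
    grid <- tidyr::crossing(tibble(male_id = males),
                            dh %>% select("date", "hours"))
    grid <- grid[present_at(grid$male_id, match(grid$date, all_days)), ]
    grid %>%
      mutate(duration_h = cfg$focal_fraction * .data$hours) %>%
      select("date", "male_id", "duration_h")
  })

  ## -- ages (all study males enter as adults; a few as large subadults) ------
  ages <- withr::with_seed(seeds[10], {
    m <- demo %>% filter(.data$sex == "male", .data$party != "extra")
    sub <- runif(nrow(m)) < 0.2
    bind_rows(
      tibble(individual_id = m$id,
             date = all_days[m$arr],
             category = if_else(sub, "large_subadult", "adult")),
      tibble(individual_id = m$id[sub],
             date = pmin(all_days[m$arr[sub]] + 400, end),
             category = "adult"))
  })

  ## -- 9. genotypes -----------------------------------------------------------
  fathers <- births %>%
    select(offspring_id = "id", father_id = "father_id",
           conception_date = "conception_date")
  genotyped_ids <- c(demo$id, births$id[births$sampled])
  genotypes <- simulate_genotypes(cfg, individuals, fathers,
                                  subset_ids = genotyped_ids,
                                  seed = seeds[[11]])

  ds <- study_dataset(individuals = individuals, census = census,
                      sessions = sessions, events = events,
                      coalitions = coalitions, genotypes = genotypes,
                      focals = focals, ages = ages,
                      meta = list(config = unclass(cfg)))
  truth <- list(affinities = affinities, units_daily = units_daily,
                fathers = fathers, gamma = cfg$gamma, config = cfg)
  list(dataset = ds, truth = truth)
}

#' Simulate microsatellite genotypes down a pedigree
#'
#' Founders (individuals without a recorded mother) are drawn from
#' Dirichlet-distributed locus allele frequencies under Hardy-Weinberg;
#' offspring inherit one allele from each parent. Null alleles (frequency
#' `null_freq` at `null_loci`) segregate like normal alleles but do not
#' amplify: a null heterozygote appears homozygous for its visible allele and
#' a null homozygote appears as missing. Each visible allele is independently
#' mistyped with probability `genotyping_error`, being replaced by a random
#' allele drawn from the locus frequencies.
#'
#' @param cfg a [sim_config()] (locus panel and error model are read from it).
#' @param individuals individual table with `id`, `mother_id`, `birth_date`.
#' @param fathers tibble `offspring_id`, `father_id` (true sires).
#' @param subset_ids individuals to genotype (default: all).
#' @param seed RNG seed.
#' @return long genotype tibble `individual_id`, `locus`, `allele1`,
#'   `allele2` (`NA` = missing) with the per-locus visible allele frequencies
#'   attached as attribute `"freqs"`.
#' @export
simulate_genotypes <- function(cfg, individuals, fathers,
                               subset_ids = NULL, seed = cfg$seed) {
  withr::with_seed(seed, {
    loci <- sprintf("L%02d", seq_len(cfg$n_loci))
    sizes <- as.integer(names(cfg$allele_count_probs))
    karyo <- sizes[sample.int(length(sizes), cfg$n_loci, replace = TRUE,
                              prob = cfg$allele_count_probs)]
    freqs <- lapply(seq_len(cfg$n_loci), function(l) {
      f <- rdirichlet1(karyo[l], cfg$dirichlet_alpha)
      while (1 - sum(f^2) < cfg$min_locus_het && karyo[l] > 1) {
        f <- rdirichlet1(karyo[l], cfg$dirichlet_alpha)
      }
      if (l %in% cfg$null_loci) {
        # allele index 0 = null
        c(`0` = cfg$null_freq, setNames(f * (1 - cfg$null_freq),
                                        seq_along(f)))
      } else setNames(f, seq_along(f))
    })
    names(freqs) <- loci

    has_mother <- !is.na(individuals$mother_id)
    founders <- individuals$id[!has_mother]
    offspring <- individuals$id[has_mother]
    fa <- setNames(fathers$father_id, fathers$offspring_id)
    mo <- setNames(individuals$mother_id[has_mother], offspring)

    # order offspring so parents are always resolved first
    resolved <- founders
    pending <- offspring
    order_off <- character(0)
    while (length(pending)) {
      ready <- pending[mo[pending] %in% resolved &
                         (is.na(fa[pending]) | fa[pending] %in% resolved)]
      if (!length(ready)) abort("simulate_genotypes: pedigree loop detected")
      order_off <- c(order_off, ready)
      resolved <- c(resolved, ready)
      pending <- setdiff(pending, ready)
    }

    # true genotypes: matrix individuals x loci, for each of two gametes
    all_ids <- c(founders, order_off)
    g1 <- matrix(NA_integer_, length(all_ids), cfg$n_loci,
                 dimnames = list(all_ids, loci))
    g2 <- g1
    draw_allele <- function(fr, n) {
      as.integer(names(fr))[sample.int(length(fr), n, TRUE, fr)]
    }
    for (l in seq_len(cfg$n_loci)) {
      g1[founders, l] <- draw_allele(freqs[[l]], length(founders))
      g2[founders, l] <- draw_allele(freqs[[l]], length(founders))
    }
    for (id in order_off) {
      m <- mo[[id]]
      f <- fa[[id]]
      pick <- function(p, l) if (runif(1) < 0.5) g1[p, l] else g2[p, l]
      for (l in seq_len(cfg$n_loci)) {
        g1[id, l] <- pick(m, l)
        g2[id, l] <- if (is.na(f)) draw_allele(freqs[[l]], 1) else pick(f, l)
      }
    }

    ids <- if (is.null(subset_ids)) all_ids else
      intersect(all_ids, subset_ids)
    out <- purrr::map_dfr(seq_len(cfg$n_loci), function(l) {
      a1 <- g1[ids, l]
      a2 <- g2[ids, l]
      vis <- as.integer(names(freqs[[l]]))
      vis <- vis[vis != 0L]
      pvis <- freqs[[l]][as.character(vis)]
      pvis <- pvis / sum(pvis)
      err <- function(a) {
        hit <- runif(length(a)) < cfg$genotyping_error
        a[hit] <- vis[sample.int(length(vis), sum(hit), TRUE, pvis)]
        a
      }
      o1 <- err(a1)
      o2 <- err(a2)
      # null-allele masking (error applies to amplified alleles only)
      null1 <- a1 == 0L
      null2 <- a2 == 0L
      o1[null1 & !null2] <- o2[null1 & !null2]
      o2[null2 & !null1] <- o1[null2 & !null1]
      o1[null1 & null2] <- NA_integer_
      o2[null1 & null2] <- NA_integer_
      tibble(individual_id = ids, locus = loci[l],
             allele1 = pmin(o1, o2), allele2 = pmax(o1, o2))
    })
    attr(out, "freqs") <- freqs
    out
  })
}

#' Simulate a model-ready male-year table with a known trade-off effect
#'
#' Direct generator for validating the count models: per male-year rows with a
#' bond-strength covariate and a Poisson unit-size response whose log-mean
#' carries a known effect of z-scored bond strength, plus a male random
#' intercept and inert year/party controls.
#'
#' @param n_males,years table layout (default 23 x 4 ~ the study's 91
#'   male-years).
#' @param beta_bond true effect of z-scored bond strength on the log scale.
#' @param beta_strong true effect of z-scored number of strong bonds.
#' @param intercept log-scale intercept.
#' @param sigma_male SD of the male random intercept.
#' @param seed RNG seed.
#' @return tibble `male_id`, `party`, `year`, `bond_strength`,
#'   `n_strong_bonds`, `unit_size`.
#' @export
simulate_male_year_table <- function(n_males = 23, years = 4,
                                     beta_bond = -0.75, beta_strong = 0,
                                     intercept = log(1.2), sigma_male = 0.4,
                                     seed = 1) {
  withr::with_seed(seed, {
    male <- sprintf("M%02d", seq_len(n_males))
    tab <- tidyr::crossing(male_id = male, year = seq_len(years)) %>%
      mutate(party = if_else(match(.data$male_id, male) <= n_males / 2,
                             "p1", "p2"))
    mu_bond <- setNames(rnorm(n_males, 2, 0.5), male)
    u <- setNames(rnorm(n_males, 0, sigma_male), male)
    tab <- tab %>%
      mutate(bond_strength = rlnorm(n(), mu_bond[.data$male_id] - 1, 0.45),
             n_strong_bonds = rpois(n(), 2.2))
    zb <- as.numeric(scale(tab$bond_strength))
    zs <- as.numeric(scale(tab$n_strong_bonds))
    tab %>%
      mutate(unit_size = rpois(n(), exp(intercept + beta_bond * zb +
                                          beta_strong * zs +
                                          u[.data$male_id])))
  })
}
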