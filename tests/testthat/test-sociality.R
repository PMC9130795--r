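mk_event <- function(time, actor, receiver, behaviour, dur = 0,
                     source = "focal", focal = actor) {
  tibble::tibble(timestamp = as.POSIXct(time, tz = "UTC"), actor_id = actor,
                 receiver_id = receiver, behaviour = behaviour,
                 duration_s = dur, source = source, focal_id = focal)
}

test_that("single-event arithmetic: one 60 s groom in 10 dyad-hours", {
  ds <- toy_dataset()  # one groom A-B, 10 one-hour days, all present
  r <- compute_dyadic_rates(ds, "p1", 2015)
  ab <- r[r$male1 == "A" & r$male2 == "B", ]
  expect_equal(ab$contact_h, 10)
  expect_equal(ab$groom_dur, 6)      # 60 s / 10 h
  expect_equal(ab$groom_freq, 0.1)   # 1 event / 10 h
  expect_equal(ab$approach_freq, 0)
})

test_that("approaches followed within 10 s by dyadic behaviour are excluded", {
  ev <- dplyr::bind_rows(
    mk_event("2015-01-02 10:00:00", "A", "B", "approach_1m"),   # groom at +5 s
    mk_event("2015-01-02 10:00:05", "A", "B", "groom", dur = 30),
    mk_event("2015-01-03 10:00:00", "A", "B", "approach_1m"),   # groom at +15 s
    mk_event("2015-01-03 10:00:15", "A", "B", "groom", dur = 30),
    mk_event("2015-01-04 10:00:00", "A", "B", "approach_1m"),   # aggression +9 s
    mk_event("2015-01-04 10:00:09", "B", "A", "aggression"),
    mk_event("2015-01-05 10:00:00", "A", "B", "approach_1m"),   # other dyad +5 s
    mk_event("2015-01-05 10:00:05", "A", "C", "groom", dur = 30),
    mk_event("2015-01-06 10:00:00", "A", "B", "approach_1m"))   # isolated
  ds <- toy_dataset(events = ev)
  r <- compute_dyadic_rates(ds, "p1", 2015)
  ab <- r[r$male1 == "A" & r$male2 == "B", ]
  # kept: +15 s follow-up, other-dyad follow-up, isolated = 3 of 5
  expect_equal(ab$approach_freq, 3 / 10)
  # removing the filtered events can only increase the approach rate
  ev2 <- ev[ev$behaviour == "approach_1m", ]
  r2 <- compute_dyadic_rates(toy_dataset(events = ev2), "p1", 2015)
  expect_gte(r2$approach_freq[r2$male1 == "A" & r2$male2 == "B"],
             ab$approach_freq)
})

test_that("a year without sessions is an error", {
  expect_error(compute_dyadic_rates(toy_dataset(), "p1", 2016),
               "no sessions")
})

test_that("DSI matches its definition on hand-computed fixtures", {
  rates <- tibble::tibble(
    party = "p1", year = 2015,
    male1 = c("a", "a", "b"), male2 = c("b", "c", "c"),
    contact_h = 10,
    groom_freq = c(2, 1, 0), groom_dur = c(0, 0, 0),
    contact_sit_freq = c(0, 0, 0), contact_sit_dur = c(0, 0, 0),
    approach_freq = c(3, 2, 1))
  expect_warning(dsi <- compute_dsi(rates), "zero mean")
  # d = 2 surviving behaviours, means 1 and 2:
  # ab: (2/1 + 3/2)/2 = 1.75; ac: (1/1 + 2/2)/2 = 1; bc: (0/1 + 1/2)/2 = 0.25
  expect_equal(dsi$dsi, c(1.75, 1, 0.25))
  expect_equal(mean(dsi$dsi), 1, tolerance = 1e-12)

  # a dyad with every rate equal to the party mean scores exactly 1
  r2 <- tibble::tibble(
    party = "p1", year = 2015,
    male1 = c("a", "a"), male2 = c("b", "c"), contact_h = 5,
    groom_freq = c(1, 1), groom_dur = c(30, 30),
    contact_sit_freq = c(2, 2), contact_sit_dur = c(40, 40),
    approach_freq = c(0.5, 0.5))
  expect_equal(compute_dsi(r2)$dsi, c(1, 1))

  # an all-zero dyad scores 0; an all-zero party-year is an error
  r3 <- r2
  r3[2, c("groom_freq", "groom_dur", "contact_sit_freq", "contact_sit_dur",
          "approach_freq")] <- 0
  expect_equal(compute_dsi(r3)$dsi[2], 0)
  r4 <- r3
  r4[1, 6:10] <- 0
  expect_error(compute_dsi(r4), "all behaviour means are zero")
})

test_that("DSI is invariant to rescaling one behaviour's rates", {
  sim <- small_sim(seed = 17, males = 8, sessions = 30)
  yr <- as.integer(format(sim$dataset$sessions$date[1], "%Y"))
  r <- compute_dyadic_rates(sim$dataset, "p1", yr)
  d1 <- compute_dsi(r)
  r2 <- r
  r2$groom_dur <- r2$groom_dur * 7.3
  d2 <- compute_dsi(r2)
  expect_equal(d1$dsi, d2$dsi, tolerance = 1e-12)
})

test_that("dyadic rates equal a brute-force per-event recount", {
  sim <- small_sim(seed = 23, males = 6, sessions = 30)
  yr <- as.integer(format(sim$dataset$sessions$date[1], "%Y"))
  r <- compute_dyadic_rates(sim$dataset, "p1", yr)
  bf <- bf_dyadic_rates(sim$dataset, "p1", yr)
  key <- function(x) dplyr::arrange(x, male1, male2)
  r <- key(r); bf <- key(bf)
  for (col in c("groom_freq", "groom_dur", "contact_sit_freq",
                "contact_sit_dur", "approach_freq")) {
    expect_equal(r[[col]], bf[[col]], tolerance = 1e-12, label = col)
  }
  expect_equal(compute_dsi(r)$dsi, bf_dsi(bf), tolerance = 1e-12)
})

test_that("profiles follow the top-three and strictly-greater rules", {
  # 5 males; m's dyads carry 4, 3, 2, 1 and all other dyads 0
  prs <- t(combn(c("m", "v", "w", "x", "y"), 2))
  dsi <- tibble::tibble(party = "p1", year = 2015,
                        male1 = prs[, 1], male2 = prs[, 2], contact_h = 10,
                        dsi = 0)
  dsi$dsi[dsi$male1 == "m"] <- c(4, 3, 2, 1)
  expect_equal(mean(dsi$dsi), 1)
  prof <- sociality_profile(dsi, toy_dataset())
  m <- prof[prof$male_id == "m", ]
  expect_equal(m$bond_strength, 9)      # 4 + 3 + 2
  expect_equal(m$n_strong_bonds, 3L)    # strictly greater than the mean of 1
  v <- prof[prof$male_id == "v", ]      # partner of the 4-dyad only
  expect_equal(v$bond_strength, 4)
  expect_equal(v$n_strong_bonds, 1L)
})

test_that("a male with fewer than three partners sums what he has", {
  dsi <- tibble::tibble(party = "p1", year = 2015,
                        male1 = c("a", "b"), male2 = c("b", "c"),
                        contact_h = 10, dsi = c(0.5, 1.5))
  prof <- sociality_profile(dsi, toy_dataset())
  a <- prof[prof$male_id == "a", ]
  expect_equal(a$bond_strength, 0.5)
  expect_equal(a$n_strong_bonds, 0L)
})

test_that("profiles equal a brute-force sort-and-sum oracle on 10 males", {
  sim <- small_sim(seed = 29, males = 10, sessions = 40)
  ds <- sim$dataset
  yr <- as.integer(format(ds$sessions$date[1], "%Y"))
  dsi <- compute_dsi(compute_dyadic_rates(ds, "p1", yr))
  prof <- sociality_profile(dsi, ds)
  for (m in unique(prof$male_id)) {
    bf <- bf_profile(dsi, m)
    row <- prof[prof$male_id == m, ]
    expect_equal(row$bond_strength, bf$bond_strength, tolerance = 1e-12)
    expect_equal(row$n_strong_bonds, bf$n_strong)
  }
})

test_that("males with zero focal time are flagged, not silently dropped", {
  ds <- toy_dataset()   # no focals table at all
  dsi <- tibble::tibble(party = "p1", year = 2015,
                        male1 = c("A", "A"), male2 = c("B", "C"),
                        contact_h = 10, dsi = c(1.5, 0.5))
  prof <- sociality_profile(dsi, ds)
  expect_true(all(!prof$affiliation_defined))
  expect_true(all(is.na(prof$affiliation_proportion)))
})

test_that("coalition counts match a manual tally and default to zero", {
  co <- tibble::tibble(
    timestamp = as.POSIXct("2015-03-01 12:00:00", tz = "UTC") + 1:5,
    ally1_id = c("A", "B", "A", "A", "B"),
    ally2_id = c("B", "A", "C", "B", "C"),
    target_id = c("C", "C", "B", "C", "A"),
    source = c("focal", "adlib", "adlib", "focal", "adlib"))
  ds <- toy_dataset(coalitions = co)
  cr <- coalition_rate(ds, "p1", 2015)
  expect_equal(cr$n_coalitions[cr$male1 == "A" & cr$male2 == "B"], 3L)
  expect_equal(cr$n_coalitions[cr$male1 == "A" & cr$male2 == "C"], 1L)
  expect_equal(cr$n_coalitions[cr$male1 == "B" & cr$male2 == "C"], 1L)
  expect_equal(cr$rate_per_h, cr$n_coalitions / cr$contact_h)
  # manual tally oracle
  for (i in seq_len(nrow(cr))) {
    expect_equal(cr$n_coalitions[i],
                 bf_coalition_counts(ds, "p1", 2015, cr$male1[i],
                                     cr$male2[i]))
  }
  # and a party-year without coalitions is all zeros
  cr0 <- coalition_rate(toy_dataset(), "p1", 2015)
  expect_true(all(cr0$n_coalitions == 0))
  expect_true(all(cr0$rate_per_h == 0))
})

test_that("true affinity and measured DSI are positively rank-correlated", {
  sim <- small_sim(seed = 37, males = 10, sessions = 80)
  ds <- sim$dataset
  yr <- as.integer(format(ds$sessions$date[1], "%Y"))
  dsi <- compute_dsi(compute_dyadic_rates(ds, "p1", yr))
  j <- dplyr::inner_join(dsi, sim$truth$affinities,
                         by = c("party", "male1", "male2"))
  expect_gt(cor(j$dsi, j$affinity, method = "spearman"), 0.5)
})
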