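hw_genotypes <- function() {
  # 100 individuals at exact Hardy-Weinberg proportions for p = q = 0.5
  tibble::tibble(
    individual_id = sprintf("i%03d", 1:100), locus = "L1",
    allele1 = rep(c(1L, 1L, 2L), c(25, 50, 25)),
    allele2 = rep(c(1L, 2L, 2L), c(25, 50, 25)))
}

test_that("locus statistics are exact at Hardy-Weinberg equilibrium", {
  st <- locus_stats(hw_genotypes(), hwe_permutations = 500, seed = 1)
  expect_equal(st$n_alleles, 2L)
  expect_equal(st$h_obs, 0.5)
  expect_equal(st$h_exp, 0.5 * 200 / 199)     # gene-copy correction
  expect_lt(abs(st$f_is), 0.01)
  expect_gt(st$hwe_p, 0.3)
  expect_lt(abs(st$null_allele_estimate), 0.01)
  expect_equal(unname(st$freqs[[1]]), c(0.5, 0.5))
})

test_that("monomorphic and all-missing loci are flagged, not computed", {
  gt <- tibble::tibble(individual_id = sprintf("i%02d", 1:20),
                       locus = "L1", allele1 = 1L, allele2 = 1L)
  st <- locus_stats(gt, hwe_permutations = 100)
  expect_equal(st$h_obs, 0)
  expect_equal(st$h_exp, 0)
  expect_true(is.na(st$f_is))
  expect_true(is.na(st$hwe_p))
  gt2 <- gt
  gt2$allele1 <- NA_integer_
  st2 <- locus_stats(gt2, hwe_permutations = 100)
  expect_equal(st2$n_ind, 0L)
  expect_true(is.na(st2$h_obs))
})

test_that("frequency estimates and HWE rejection rates are calibrated", {
  # frequencies recovered within binomial error
  ped <- pedigree_sim(seed = 41, n_m = 50, n_f = 30, n_o = 20, n_loci = 6)
  st <- locus_stats(ped$ds$genotypes, hwe_permutations = 200, seed = 2)
  freqs <- attr(ped$ds$genotypes, "freqs")
  for (i in seq_len(nrow(st))) {
    est <- st$freqs[[i]]
    tru <- freqs[[st$locus[i]]]
    n <- 2 * st$n_ind[i]
    for (a in names(est)) {
      p <- tru[[a]]
      expect_lt(abs(est[[a]] - p), 4 * sqrt(p * (1 - p) / n) + 0.01)
    }
  }
  # type-I error of the Monte-Carlo exact test near the nominal level
  withr::with_seed(7, {
    rej <- vapply(1:200, function(i) {
      a <- sample(1:3, 100, TRUE, c(0.5, 0.3, 0.2))
      g <- matrix(a[1:100], 50, 2)
      gt <- tibble::tibble(individual_id = sprintf("x%02d", 1:50),
                           locus = "L1", allele1 = pmin(g[, 1], g[, 2]),
                           allele2 = pmax(g[, 1], g[, 2]))
      locus_stats(gt, hwe_permutations = 300, seed = i)$hwe_p < 0.05
    }, logical(1))
    expect_gt(mean(rej), 0.005)
    expect_lt(mean(rej), 0.12)
  })
})

test_that("locus exclusion removes only null-allele suspects", {
  st <- tibble::tibble(locus = sprintf("L%02d", 1:24),
                       null_allele_estimate = c(rep(0, 12), 0.12,
                                                rep(0.01, 11)))
  expect_message(keep <- exclude_loci(st), "retained 23 of 24")
  expect_equal(length(keep), 23)
  expect_false("L13" %in% keep)
  st$null_allele_estimate <- 0
  expect_message(keep2 <- exclude_loci(st), "retained 24 of 24")
  expect_equal(length(keep2), 24)
})

test_that("trio LOD equals the full-enumeration oracle on a 2-locus toy", {
  freqs <- list(La = c(`1` = 0.5, `2` = 0.5),
                Lb = c(`1` = 0.25, `2` = 0.25, `3` = 0.25, `4` = 0.25))
  off <- geno_tab(c("La", "Lb"), c(1L, 1L), c(2L, 3L))
  mom <- geno_tab(c("La", "Lb"), c(1L, 1L), c(1L, 2L))
  dad <- geno_tab(c("La", "Lb"), c(2L, 3L), c(2L, 4L))
  for (eps in c(0.001, 0.01, 0.1)) {
    lr1 <- bf_locus_lr(c(1, 2), c(1, 1), c(2, 2), unname(freqs$La), eps)
    lr2 <- bf_locus_lr(c(1, 3), c(1, 2), c(3, 4), unname(freqs$Lb), eps)
    expect_equal(trio_lod(off, mom, dad, freqs, error_rate = eps),
                 log(lr1) + log(lr2), tolerance = 1e-12)
  }
  # additivity: permuting loci leaves the total unchanged
  perm <- c(2, 1)
  expect_equal(trio_lod(off[perm, ], mom[perm, ], dad[perm, ], freqs,
                        error_rate = 0.01),
               trio_lod(off, mom, dad, freqs, error_rate = 0.01))
  # missing locus contributes zero
  off_na <- off
  off_na$allele1[2] <- NA_integer_
  expect_equal(trio_lod(off_na, mom, dad, freqs, error_rate = 0.01),
               log(bf_locus_lr(c(1, 2), c(1, 1), c(2, 2),
                               unname(freqs$La), 0.01)))
  expect_error(trio_lod(off, mom, dad, freqs, error_rate = 0),
               "error_rate")
  expect_error(trio_lod(off, mom, dad, freqs, error_rate = 0.7),
               "error_rate")
})

test_that("LOD limits behave: support grows and exclusions sink as error shrinks", {
  freqs <- list(La = c(`1` = 0.5, `2` = 0.5))
  off <- geno_tab("La", 1L, 2L)
  mom <- geno_tab("La", 1L, 1L)
  dad_match <- geno_tab("La", 2L, 2L)     # transmits the paternal allele
  dad_excl <- geno_tab("La", 1L, 1L)      # cannot transmit allele 2
  eps_grid <- c(0.2, 0.05, 0.01, 0.001)
  lod_match <- vapply(eps_grid, function(e) {
    trio_lod(off, mom, dad_match, freqs, e)
  }, double(1))
  lod_excl <- vapply(eps_grid, function(e) {
    trio_lod(off, mom, dad_excl, freqs, e)
  }, double(1))
  expect_true(all(diff(lod_match) > 0))   # monotone increase as eps -> 0
  expect_true(all(diff(lod_excl) < 0))    # exclusion term heads to -Inf
  expect_true(all(lod_excl < 0))
})

test_that("error-free data give perfect, zero-mismatch assignments", {
  ped <- pedigree_sim(seed = 51, n_m = 20, n_f = 10, n_o = 12, n_loci = 16)
  pat <- assign_paternity(ped$ds, error_rate = 0.01, sim_cycles = 1000,
                          seed = 3)
  m <- merge(pat, ped$truth, by = "offspring_id")
  expect_true(all(m$best_father_id == m$father_id.y))
  expect_true(all(m$mismatches == 0L))
  expect_true(all(m$accepted))
  expect_true(all(m$confidence == "strict"))
})

test_that("a mismatching genotyped mother halts the analysis", {
  ped <- pedigree_sim(seed = 53, n_m = 10, n_f = 5, n_o = 5, n_loci = 10)
  gt <- ped$ds$genotypes
  o <- ped$truth$offspring_id[1]
  # overwrite the offspring's genotypes with alleles foreign to the mother
  rows <- gt$individual_id == o
  gt$allele1[rows] <- 901L
  gt$allele2[rows] <- 902L
  ds2 <- ped$ds
  ds2$genotypes <- gt
  expect_error(assign_paternity(ds2, sim_cycles = 200, seed = 1),
               "maternity check failed")
  # flag mode warns, excludes the offspring and carries on
  expect_warning(
    pat <- assign_paternity(ds2, sim_cycles = 200, seed = 1,
                            maternity_action = "flag"),
    "maternity check failed")
  row <- pat[pat$offspring_id == o, ]
  expect_false(row$maternity_ok)
  expect_false(row$accepted)
  expect_true(is.na(row$father_id))
  expect_true(all(pat$maternity_ok[pat$offspring_id != o]))
})

test_that("ungenotyped offspring fall back to the mother's primary male", {
  ped <- pedigree_sim(seed = 57, n_m = 8, n_f = 4, n_o = 6, n_loci = 12,
                      p_genotyped = 0)
  conc <- ped$ds$individuals$birth_date - 184
  mo <- ped$ds$individuals$mother_id
  keep <- !is.na(mo)
  asg <- tibble::tibble(date = conc[keep], female_id = mo[keep],
                        party = "p1", male_id = "M01")
  pat <- assign_paternity(ped$ds, sim_cycles = 200, assignments = asg,
                          seed = 1)
  expect_true(all(pat$imputed))
  expect_true(all(pat$father_id == "M01"))
  expect_true(all(!pat$accepted))
})

test_that("yearly sired counts attribute offspring to fathers by birth year", {
  tabs <- toy_tables()
  infants <- tibble::tibble(
    id = c("I1", "I2", "I3"), sex = "female", party = "p1",
    birth_date = as.Date(c("2015-01-03", "2015-01-05", "2015-01-08")),
    mother_id = "F1")
  extra <- tibble::tibble(id = "X1", sex = "male", party = "extra",
                          birth_date = as.Date(NA),
                          mother_id = NA_character_)
  ds <- toy_dataset(individuals = dplyr::bind_rows(tabs$individuals,
                                                   infants, extra))
  pat <- tibble::tibble(offspring_id = infants$id,
                        mother_id = "F1", best_father_id = "A",
                        lod = 1, delta = 1, mismatches = 0L,
                        confidence = "strict", accepted = TRUE,
                        imputed = FALSE, father_id = "A")
  sired <- yearly_sired_counts(pat, ds)
  expect_equal(sired$n_sired[sired$male_id == "A" & sired$year == 2015], 3L)
  expect_true(all(sired$n_sired[sired$male_id != "A"] == 0L))
  # an extra-party father contributes to no study male
  pat$father_id <- "X1"
  sired2 <- yearly_sired_counts(pat, ds)
  expect_true(all(sired2$n_sired == 0L))
})

test_that("simulated pedigrees reproduce the truth table counts", {
  sim <- simulate_study(sim_config(seed = 67, years = 2,
                                   sessions_per_year = 60))
  ds <- sim$dataset
  asg <- assign_daily_units(ds)
  pat <- assign_paternity(ds, sim_cycles = 1000, assignments = asg, seed = 5)
  sired <- yearly_sired_counts(pat, ds)
  tru <- merge(sim$truth$fathers,
               ds$individuals[, c("id", "birth_date")],
               by.x = "offspring_id", by.y = "id")
  tru$year <- as.integer(format(tru$birth_date, "%Y"))
  tru_counts <- aggregate(offspring_id ~ father_id + year, tru, length)
  hits <- 0; tot <- 0
  for (i in seq_len(nrow(tru_counts))) {
    got <- sired$n_sired[sired$male_id == tru_counts$father_id[i] &
                           sired$year == tru_counts$year[i]]
    if (length(got)) {
      tot <- tot + 1
      hits <- hits + (got == tru_counts$offspring_id[i])
    }
  }
  expect_gt(hits / tot, 0.8)   # genotyped offspring exact; imputed may differ
})
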