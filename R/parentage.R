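#' Per-locus descriptive statistics and quality control
#'
#' For each microsatellite locus: allele frequencies by direct counting,
#' observed heterozygosity, expected heterozygosity under Hardy-Weinberg with
#' the small-sample correction n_g/(n_g - 1) on gene copies, the inbreeding
#' coefficient F_IS = 1 - H_obs/H_exp, a Monte-Carlo exact test of
#' Hardy-Weinberg proportions (alleles permuted among genotypes, conditional
#' table probability as test statistic), and the Brookfield (1996) estimator
#' 1 of null-allele frequency, r = (H_exp - H_obs)/(1 + H_exp) (computed with
#' the uncorrected H_exp).
#'
#' @param genotypes long tibble `individual_id`, `locus`, `allele1`,
#'   `allele2`.
#' @param hwe_permutations Monte-Carlo permutations for the exact test.
#' @param seed RNG seed for the permutation test.
#' @return tibble `locus`, `n_ind`, `n_alleles`, `h_obs`, `h_exp`, `f_is`,
#'   `hwe_p`, `null_allele_estimate`, `freqs` (list-column of named
#'   frequency vectors). Monomorphic or all-missing loci carry `NA` in the
#'   undefined statistics.
#' @export
locus_stats <- function(genotypes, hwe_permutations = 10000, seed = 1) {
  assert_cols(genotypes, c("individual_id", "locus", "allele1", "allele2"),
              "genotypes")
  if (dplyr::n_distinct(genotypes$individual_id) < 2) {
    abort("locus_stats: need genotypes for at least 2 individuals")
  }
  loci <- unique(genotypes$locus)
  withr::with_seed(seed, {
    purrr::map_dfr(loci, function(l) {
      g <- genotypes %>%
        filter(.data$locus == l, !is.na(.data$allele1), !is.na(.data$allele2))
      n <- nrow(g)
      if (n == 0) {
        return(tibble(locus = l, n_ind = 0L, n_alleles = 0L, h_obs = NA_real_,
                      h_exp = NA_real_, f_is = NA_real_, hwe_p = NA_real_,
                      null_allele_estimate = NA_real_, freqs = list(NULL)))
      }
      al <- c(g$allele1, g$allele2)
      tab <- table(al)
      p <- as.numeric(tab) / length(al)
      names(p) <- names(tab)
      k <- length(p)
      h_obs <- mean(g$allele1 != g$allele2)
      he_raw <- 1 - sum(p^2)
      ng <- length(al)
      h_exp <- he_raw * ng / (ng - 1)
      f_is <- if (h_exp > 0) 1 - h_obs / h_exp else NA_real_
      hwe_p <- if (k > 1) {
        hwe_exact_mc(g$allele1, g$allele2, n_perm = hwe_permutations)
      } else NA_real_
      null_est <- if (k > 1) (he_raw - h_obs) / (1 + he_raw) else NA_real_
      tibble(locus = l, n_ind = n, n_alleles = k, h_obs = h_obs,
             h_exp = h_exp, f_is = f_is, hwe_p = hwe_p,
             null_allele_estimate = null_est, freqs = list(p))
    })
  })
}

# Monte-Carlo exact test of Hardy-Weinberg proportions: the statistic is the
# conditional probability of the genotype table given the allele counts
# (up to constants: n_het * log 2 - sum(lfactorial(genotype counts)));
# alleles are shuffled among individuals and the p-value is the share of
# shuffles with probability <= the observed one.
hwe_exact_mc <- function(a1, a2, n_perm = 10000) {
  al <- c(a1, a2)
  codes <- as.integer(factor(al))
  k <- max(codes)
  n <- length(a1)
  stat <- function(x1, x2) {
    het <- sum(x1 != x2)
    gid <- pmin(x1, x2) * (k + 1L) + pmax(x1, x2)
    het * log(2) - sum(lfactorial(tabulate(match(gid, unique(gid)))))
  }
  obs <- stat(codes[seq_len(n)], codes[n + seq_len(n)])
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- codes[sample.int(2L * n)]
    if (stat(perm[seq_len(n)], perm[n + seq_len(n)]) <= obs + 1e-9) {
      hits <- hits + 1L
    }
  }
  (hits + 1) / (n_perm + 1)
}

#' Exclude loci showing signs of null alleles
#'
#' @param stats output of [locus_stats()].
#' @param null_threshold loci with a Brookfield estimate above this are
#'   removed.
#' @return character vector of retained locus names (message reports the
#'   exclusions).
#' @export
exclude_loci <- function(stats, null_threshold = 0.05) {
  drop <- stats$locus[!is.na(stats$null_allele_estimate) &
                        stats$null_allele_estimate > null_threshold]
  keep <- setdiff(stats$locus, drop)
  inform(sprintf("exclude_loci: retained %d of %d loci%s",
                 length(keep), nrow(stats),
                 if (length(drop)) paste0(" (excluded: ",
                                          paste(drop, collapse = ", "), ")")
                 else ""))
  keep
}

# -- trio-likelihood machinery -------------------------------------------------
# Error model: the offspring's two observed alleles are independently mistyped
# with probability eps, a mistyped allele being a random draw from the locus
# allele frequencies. P(obs a | true t) = (1 - eps) * [a == t] + eps * p_a.
# All vectorised over trios for one locus; alleles are indices into p.

p_obs_given_true <- function(obs, true, p, eps) {
  (1 - eps) * (obs == true) + eps * p[obs]
}

# P(observed unordered offspring genotype (o1, o2) | true unordered (t1, t2))
p_geno_obs <- function(o1, o2, t1, t2, p, eps) {
  both <- p_obs_given_true(o1, t1, p, eps) * p_obs_given_true(o2, t2, p, eps)
  cross <- p_obs_given_true(o2, t1, p, eps) * p_obs_given_true(o1, t2, p, eps)
  if_else(o1 == o2, both, both + cross)
}

# P(obs offspring | mother, candidate father): average over the four parental
# transmissions. Vectors of equal length (one locus, many trios).
lik_trio <- function(o1, o2, m1, m2, c1, c2, p, eps) {
  0.25 * (p_geno_obs(o1, o2, m1, c1, p, eps) +
            p_geno_obs(o1, o2, m1, c2, p, eps) +
            p_geno_obs(o1, o2, m2, c1, p, eps) +
            p_geno_obs(o1, o2, m2, c2, p, eps))
}

# P(obs offspring | mother, father unknown): paternal allele integrated over
# the population allele frequencies.
lik_mother_only <- function(o1, o2, m1, m2, p, eps) {
  acc <- 0
  for (k in seq_along(p)) {
    acc <- acc + p[k] * 0.5 * (p_geno_obs(o1, o2, m1, k, p, eps) +
                                 p_geno_obs(o1, o2, m2, k, p, eps))
  }
  acc
}

# locus-level Mendelian consistency of the trio: TRUE when no assignment of
# the offspring alleles to (maternal, paternal from candidate) exists
trio_mismatch <- function(o1, o2, m1, m2, c1, c2) {
  ok <- ((o1 == m1 | o1 == m2) & (o2 == c1 | o2 == c2)) |
    ((o2 == m1 | o2 == m2) & (o1 == c1 | o1 == c2))
  !ok
}

#' Trio-likelihood paternity LOD score
#'
#' The log-likelihood ratio, summed over loci, of the hypothesis that the
#' candidate is the father given the known mother, against the hypothesis
#' that the father is a random male from the population:
#' `LOD = sum_l ln P(g_o | g_m, g_c, eps) / P(g_o | g_m, eps)`. Loci with a
#' missing genotype in any trio member contribute 0.
#'
#' @param offspring,mother,candidate genotype tibbles (`locus`, `allele1`,
#'   `allele2`) for one individual each.
#' @param freqs named list (by locus) of named allele-frequency vectors, as
#'   attached by [locus_stats()] (`freqs` list-column, names = locus).
#' @param error_rate per-allele mistyping rate eps, in (0, 0.5).
#' @return LOD score (double scalar).
#' @export
trio_lod <- function(offspring, mother, candidate, freqs, error_rate = 0.01) {
  if (error_rate <= 0 || error_rate >= 0.5) {
    abort("trio_lod: error_rate must lie in (0, 0.5)")
  }
  loci <- intersect(names(freqs), offspring$locus)
  total <- 0
  for (l in loci) {
    o <- offspring[offspring$locus == l, ]
    m <- mother[mother$locus == l, ]
    cc <- candidate[candidate$locus == l, ]
    if (!nrow(o) || !nrow(m) || !nrow(cc)) next
    gl <- c(o$allele1[1], o$allele2[1], m$allele1[1], m$allele2[1],
            cc$allele1[1], cc$allele2[1])
    if (anyNA(gl)) next
    p <- freqs[[l]]
    idx <- match(as.character(gl), names(p))
    if (anyNA(idx)) {
      # allele unseen in the frequency table: give it a nominal tiny frequency
      p <- c(p, setNames(rep(1e-4, sum(is.na(idx))),
                         as.character(gl[is.na(idx)])))
      p <- p / sum(p)
      idx <- match(as.character(gl), names(p))
    }
    l1 <- lik_trio(idx[1], idx[2], idx[3], idx[4], idx[5], idx[6],
                   unname(p), error_rate)
    l2 <- lik_mother_only(idx[1], idx[2], idx[3], idx[4], unname(p),
                          error_rate)
    total <- total + log(l1) - log(l2)
  }
  total
}

# Internal vectorised LOD over many trios at integer-coded genotypes.
# geno_* are matrices [n, 2] of allele indices per locus list element.
lod_matrix <- function(off, mom, cand, freq_list, eps) {
  # off/mom: list per locus of n x 2; cand: list per locus of n x 2
  n <- nrow(off[[1]])
  lod <- numeric(n)
  mism <- integer(n)
  for (l in seq_along(freq_list)) {
    p <- freq_list[[l]]
    o <- off[[l]]; m <- mom[[l]]; cc <- cand[[l]]
    use <- !(is.na(o[, 1]) | is.na(m[, 1]) | is.na(cc[, 1]))
    if (!any(use)) next
    l1 <- lik_trio(o[use, 1], o[use, 2], m[use, 1], m[use, 2],
                   cc[use, 1], cc[use, 2], p, eps)
    l2 <- lik_mother_only(o[use, 1], o[use, 2], m[use, 1], m[use, 2], p, eps)
    lod[use] <- lod[use] + log(l1) - log(l2)
    mm <- trio_mismatch(o[use, 1], o[use, 2], m[use, 1], m[use, 2],
                        cc[use, 1], cc[use, 2])
    mism[use] <- mism[use] + mm
  }
  list(lod = lod, mismatches = mism)
}

# Critical Delta (gap between best and second-best LOD) at the requested
# confidence levels, from parametric simulation in the style of the standard
# likelihood parentage software: mothers and true fathers are drawn from the
# allele frequencies, offspring follow Mendelian inheritance plus the error
# model, unsampled fathers occur with probability 1 - prop_sampled, and the
# remaining candidates are unrelated males.
critical_delta <- function(freq_list, n_candidates, eps, sim_cycles = 10000,
                           prop_sampled = 0.9, levels = c(0.95, 0.80)) {
  L <- length(freq_list)
  draw_geno <- function(n) {
    lapply(freq_list, function(p) {
      k <- length(p)
      cbind(sample.int(k, n, TRUE, p), sample.int(k, n, TRUE, p))
    })
  }
  mendel <- function(mom, dad, n) {
    lapply(seq_len(L), function(l) {
      p <- freq_list[[l]]
      a1 <- ifelse(runif(n) < 0.5, mom[[l]][, 1], mom[[l]][, 2])
      a2 <- ifelse(runif(n) < 0.5, dad[[l]][, 1], dad[[l]][, 2])
      err <- runif(n) < eps
      a1[err] <- sample.int(length(p), sum(err), TRUE, p)
      err <- runif(n) < eps
      a2[err] <- sample.int(length(p), sum(err), TRUE, p)
      cbind(a1, a2)
    })
  }
  n <- sim_cycles
  mom <- draw_geno(n)
  dad <- draw_geno(n)
  off <- mendel(mom, dad, n)
  sampled <- runif(n) < prop_sampled

  best <- rep(-Inf, n)
  second <- rep(-Inf, n)
  best_is_true <- logical(n)
  for (j in seq_len(n_candidates)) {
    cand <- draw_geno(n)
    is_true <- sampled & (j == 1L)  # slot 1 holds the true father when sampled
    if (any(is_true)) {
      for (l in seq_len(L)) cand[[l]][is_true, ] <- dad[[l]][is_true, ]
    }
    lod <- lod_matrix(off, mom, cand, freq_list, eps)$lod
    better <- lod > best
    second <- if_else(better, best, pmax(second, lod))
    best_is_true <- if_else(better, is_true, best_is_true)
    best <- pmax(best, lod)
  }
  delta <- best - second
  # positive-LOD convention: assignments with non-positive best LOD resolve
  # nothing and are treated as incorrect
  ok <- best_is_true & best > 0
  ord <- order(delta, decreasing = TRUE)
  cum_ok <- cumsum(ok[ord])
  prec <- cum_ok / seq_along(ord)
  vapply(levels, function(cl) {
    pass <- which(prec >= cl)
    if (!length(pass)) return(Inf)
    delta[ord][max(pass)]
  }, double(1))
}

#' Trio-likelihood paternity assignment with simulated confidence
#'
#' Ranks every candidate male by trio LOD for each genotyped offspring whose
#' mother is known, and accepts the top candidate under the strict criterion:
#' the gap to the second-best LOD (Delta) exceeds the 95% critical value
#' obtained from `sim_cycles` simulated paternity tests, and the trio shows
#' at most one mismatched locus. An 80% (relaxed) confidence level is also
#' reported. Mothers are first verified: a genotyped mother-offspring pair
#' with any Mendelian mismatch is an error. Offspring without genotypes are
#' imputed to the mother's primary male at conception (birth date minus
#' `gestation_days`), flagged `imputed`.
#'
#' @param ds a [study_dataset()] with genotypes.
#' @param retained_loci loci to use (e.g. from [exclude_loci()]); default all.
#' @param error_rate per-allele mistyping rate used in the likelihoods.
#' @param sim_cycles simulation cycles for the critical Delta.
#' @param prop_sampled assumed proportion of true fathers among the
#'   candidates.
#' @param gestation_days gestation length for conception dating.
#' @param assignments daily unit table from [assign_daily_units()], needed
#'   for the primary-male imputation (optional; without it ungenotyped
#'   offspring stay unassigned).
#' @param max_maternity_mismatches mismatching loci tolerated in the
#'   mother-offspring verification. The default 0 is the strict field
#'   criterion.
#' @param maternity_action what to do with a pair exceeding the tolerance:
#'   `"error"` (default) halts the analysis; `"flag"` warns, marks the
#'   offspring (`maternity_ok = FALSE`) and excludes it from assignment --
#'   the practical choice for genotypes that carry typing error, where a
#'   hard stop on any single discordant pair is not workable.
#' @param seed RNG seed for the confidence simulation.
#' @return tibble `offspring_id`, `mother_id`, `best_father_id`, `lod`,
#'   `delta`, `mismatches`, `confidence` ("strict", "relaxed", "none"),
#'   `accepted`, `imputed`, `father_id` (accepted or imputed father, else
#'   `NA`).
#' @export
assign_paternity <- function(ds, retained_loci = NULL, error_rate = 0.01,
                             sim_cycles = 10000, prop_sampled = 0.9,
                             gestation_days = 184, assignments = NULL,
                             max_maternity_mismatches = 0,
                             maternity_action = c("error", "flag"),
                             seed = 1) {
  maternity_action <- match.arg(maternity_action)
  if (is.null(ds$genotypes)) abort("assign_paternity: dataset has no genotypes")
  gt <- ds$genotypes
  if (!is.null(retained_loci)) gt <- gt %>% filter(.data$locus %in% retained_loci)
  loci <- sort(unique(gt$locus))

  offspring <- ds$individuals %>% filter(!is.na(.data$mother_id))
  if (!nrow(offspring)) {
    abort("assign_paternity: no offspring (individuals with a mother) found")
  }
  geno_ids <- unique(gt$individual_id)
  candidates <- ds$individuals %>%
    filter(.data$sex == "male", is.na(.data$mother_id),
           .data$id %in% geno_ids) %>%
    pull("id")

  # frequencies from all genotyped individuals
  freq_tab <- gt %>%
    tidyr::pivot_longer(c("allele1", "allele2"), values_to = "allele") %>%
    filter(!is.na(.data$allele)) %>%
    count(.data$locus, .data$allele)
  freq_list <- lapply(loci, function(l) {
    f <- freq_tab %>% filter(.data$locus == l)
    setNames(f$n / sum(f$n), f$allele)
  })
  names(freq_list) <- loci

  # integer-coded genotype lookup: list per locus of [individual, 2]
  code <- function(ids) {
    lapply(loci, function(l) {
      g <- gt %>% filter(.data$locus == l, .data$individual_id %in% ids)
      m <- matrix(NA_integer_, length(ids), 2,
                  dimnames = list(ids, NULL))
      i <- match(g$individual_id, ids)
      m[i, 1] <- match(as.character(g$allele1), names(freq_list[[l]]))
      m[i, 2] <- match(as.character(g$allele2), names(freq_list[[l]]))
      # half-missing genotypes are treated as missing
      m[is.na(m[, 1]) | is.na(m[, 2]), ] <- NA_integer_
      m
    })
  }
  all_ids <- unique(c(offspring$id, offspring$mother_id, candidates))
  G <- code(all_ids)
  grow <- function(id) lapply(G, function(m) m[match(id, all_ids), , drop = FALSE])
  has_geno <- vapply(all_ids, function(id) {
    any(vapply(G, function(m) !is.na(m[match(id, all_ids), 1]), logical(1)))
  }, logical(1))
  names(has_geno) <- all_ids

  # maternity verification
  maternity_ok <- setNames(rep(TRUE, nrow(offspring)), offspring$id)
  for (i in seq_len(nrow(offspring))) {
    oid <- offspring$id[i]
    mid <- offspring$mother_id[i]
    if (!has_geno[oid] || !has_geno[mid]) next
    mm <- 0L
    for (l in seq_along(loci)) {
      o <- G[[l]][match(oid, all_ids), ]
      m <- G[[l]][match(mid, all_ids), ]
      if (anyNA(o) || anyNA(m)) next
      if (!(o[1] %in% m | o[2] %in% m)) mm <- mm + 1L
    }
    if (mm > max_maternity_mismatches) {
      if (maternity_action == "error") {
        abort(sprintf(
          "assign_paternity: maternity check failed for %s / mother %s (%d mismatching loci)",
          oid, mid, mm))
      }
      warn(sprintf(
        "assign_paternity: maternity check failed for %s / mother %s (%d mismatching loci); offspring excluded",
        oid, mid, mm))
      maternity_ok[oid] <- FALSE
    }
  }

  crit <- withr::with_seed(seed, {
    critical_delta(unname(lapply(freq_list, unname)),
                   n_candidates = length(candidates), eps = error_rate,
                   sim_cycles = sim_cycles, prop_sampled = prop_sampled)
  })

  res <- purrr::map_dfr(seq_len(nrow(offspring)), function(i) {
    oid <- offspring$id[i]
    mid <- offspring$mother_id[i]
    if (!maternity_ok[oid]) {
      return(tibble(offspring_id = oid, mother_id = mid,
                    best_father_id = NA_character_, lod = NA_real_,
                    delta = NA_real_, mismatches = NA_integer_,
                    confidence = "none", accepted = FALSE, imputed = FALSE,
                    maternity_ok = FALSE, father_id = NA_character_))
    }
    if (!has_geno[oid] || !has_geno[mid]) {
      father <- NA_character_
      if (!is.null(assignments) && !is.na(offspring$birth_date[i])) {
        conc <- offspring$birth_date[i] - gestation_days
        row <- assignments %>%
          filter(.data$female_id == mid, .data$date == conc)
        if (!nrow(row)) {
          row <- assignments %>%
            filter(.data$female_id == mid, .data$date >= conc) %>%
            arrange(.data$date) %>% slice(1)
        }
        if (nrow(row)) father <- row$male_id[1]
      }
      return(tibble(offspring_id = oid, mother_id = mid,
                    best_father_id = NA_character_, lod = NA_real_,
                    delta = NA_real_, mismatches = NA_integer_,
                    confidence = "none", accepted = FALSE, imputed = TRUE,
                    maternity_ok = TRUE, father_id = father))
    }
    cands <- setdiff(candidates, c(oid, mid))
    nc <- length(cands)
    off_g <- lapply(G, function(m) {
      m[rep(match(oid, all_ids), nc), , drop = FALSE]
    })
    mom_g <- lapply(G, function(m) {
      m[rep(match(mid, all_ids), nc), , drop = FALSE]
    })
    cand_g <- lapply(G, function(m) m[match(cands, all_ids), , drop = FALSE])
    sc <- lod_matrix(off_g, mom_g, cand_g,
                     unname(lapply(freq_list, unname)), error_rate)
    ord <- order(sc$lod, decreasing = TRUE)
    best <- ord[1]
    delta <- sc$lod[best] - if (nc > 1) sc$lod[ord[2]] else -Inf
    conf <- if (sc$lod[best] > 0 && delta >= crit[1]) "strict"
      else if (sc$lod[best] > 0 && delta >= crit[2]) "relaxed"
      else "none"
    accepted <- conf == "strict" && sc$mismatches[best] <= 1
    tibble(offspring_id = oid, mother_id = mid,
           best_father_id = cands[best], lod = sc$lod[best], delta = delta,
           mismatches = sc$mismatches[best], confidence = conf,
           accepted = accepted, imputed = FALSE, maternity_ok = TRUE,
           father_id = if (accepted) cands[best] else NA_character_)
  })
  attr(res, "critical_delta") <- setNames(crit, c("strict", "relaxed"))
  res
}

#' Yearly sired-offspring counts per male
#'
#' Attributes each offspring to its accepted or imputed father in the
#' offspring's birth year and tallies per male-year. Only males of the study
#' parties are counted (an extra-party father contributes to no study male);
#' males and years without offspring get 0.
#'
#' @param paternity output of [assign_paternity()].
#' @param ds the [study_dataset()].
#' @return tibble `male_id`, `year`, `n_sired`.
#' @export
yearly_sired_counts <- function(paternity, ds) {
  study_parties <- setdiff(unique(ds$census$party), "extra")
  males <- ds$individuals %>%
    filter(.data$sex == "male", is.na(.data$mother_id),
           .data$party %in% study_parties)
  years <- sort(unique(year_of(ds$census$date)))
  base <- tidyr::crossing(male_id = males$id, year = years)
  counts <- paternity %>%
    filter(!is.na(.data$father_id)) %>%
    left_join(ds$individuals %>% select(offspring_id = "id", "birth_date"),
              by = "offspring_id") %>%
    filter(!is.na(.data$birth_date)) %>%
    mutate(year = year_of(.data$birth_date)) %>%
    count(male_id = .data$father_id, .data$year, name = "n_sired")
  base %>%
    left_join(counts, by = c("male_id", "year")) %>%
    mutate(n_sired = if_else(is.na(.data$n_sired), 0L,
                             as.integer(.data$n_sired)))
}
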