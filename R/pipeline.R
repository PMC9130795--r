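#' Pipeline configuration
#'
#' Collects every tunable of the full analysis run in one nested, YAML-
#' serialisable list: the generator settings (or an input directory of CSV
#' tables), the DSI/unit/parentage parameters and the model/bootstrap sizes.
#' Every paper-gap default of the pipeline lives here so that it is visible
#' and overridable.
#'
#' @param simulate a [sim_config()], or `NULL` when `input_dir` is given.
#' @param input_dir directory of study CSV tables (see [load_study_csv()]).
#' @param window_days unit-assignment trailing window.
#' @param null_threshold locus-QC null-allele exclusion threshold.
#' @param error_rate,sim_cycles,prop_sampled,gestation_days parentage
#'   parameters (see [assign_paternity()]).
#' @param n_boot bootstrap draws for the male-year models.
#' @param n_boot_coalition bootstrap draws for the (slower) dyadic coalition
#'   model.
#' @param seed master seed for every stochastic stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = sim_config(), input_dir = NULL,
                            window_days = 30, null_threshold = 0.05,
                            error_rate = 0.01, sim_cycles = 10000,
                            prop_sampled = 0.9, gestation_days = 184,
                            n_boot = 25, n_boot_coalition = 25,
                            seed = 1L) {
  structure(as.list(environment()), class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  as_maps <- function(x) {
    if (is.list(x)) lapply(x, as_maps)
    else if (!is.null(names(x)) && length(x) > 1) as.list(x)
    else x
  }
  cfg <- as_maps(rapply(unclass(config), unclass, how = "replace"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- if (!is.null(raw$simulate)) do.call(sim_config, raw$simulate)
  raw$simulate <- NULL
  do.call(pipeline_config, c(list(simulate = sim), raw))
}

log_line <- function(log_path, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = log_path, append = TRUE)
  inform(msg)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> sociality -> units -> parentage -> models
#' -> report, writing every intermediate table, the model results and the
#' descriptive summary to `outdir` as CSV/text. Each stage is a pure function
#' of the dataset and the configuration, so rerunning with the same
#' configuration reproduces every table byte for byte. Individual stages can
#' be run via the `stages` argument.
#'
#' When the dataset has no genotypes the parentage stage runs in
#' imputation-only mode (fathers from the mother's primary male at
#' conception) and says so in the log.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param stages subset of stages to run (dependencies must already exist in
#'   `outdir` as this simply skips the others).
#' @return invisibly, a list with the run's tables and fitted models.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         stages = c("simulate", "dsi", "units", "parentage",
                                    "models", "report")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(outdir, "run.log")
  cat("baboonbonds pipeline run\n", file = log_path)
  cat(yaml::as.yaml(rapply(unclass(config), unclass, how = "replace")),
      file = log_path, append = TRUE)
  res <- list()

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    log_line(log_path, "stage %s: start", name)
    tryCatch(fun(), error = function(e) {
      log_line(log_path, "stage %s: FAILED: %s", name, conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    log_line(log_path, "stage %s: done", name)
  }

  ## simulate / load --------------------------------------------------------
  run_stage("simulate", function() {
    if (!is.null(config$input_dir)) {
      res$dataset <<- load_study_csv(config$input_dir)
      res$truth <<- NULL
    } else {
      sim <- simulate_study(config$simulate)
      res$dataset <<- sim$dataset
      res$truth <<- sim$truth
      write_study_csv(sim$dataset, file.path(outdir, "dataset"))
      readr::write_csv(sim$truth$fathers,
                       file.path(outdir, "truth_fathers.csv"))
    }
  })
  ds <- res$dataset
  parties <- setdiff(sort(unique(ds$census$party)), "extra")
  years <- sort(unique(year_of(ds$sessions$date)))
  py <- tidyr::crossing(party = parties, year = years)

  ## sociality --------------------------------------------------------------
  run_stage("dsi", function() {
    rates <- purrr::map_dfr(seq_len(nrow(py)), function(i) {
      compute_dyadic_rates(ds, py$party[i], py$year[i])
    })
    dsi <- compute_dsi(rates)
    res$dsi <<- dsi
    res$profiles <<- sociality_profile(dsi, ds)
    res$coalitions <<- purrr::map_dfr(seq_len(nrow(py)), function(i) {
      coalition_rate(ds, py$party[i], py$year[i])
    })
    readr::write_csv(dsi, file.path(outdir, "dsi.csv"))
    readr::write_csv(res$profiles, file.path(outdir, "profiles.csv"))
    readr::write_csv(res$coalitions,
                     file.path(outdir, "coalitions_summary.csv"))
  })

  ## units ------------------------------------------------------------------
  run_stage("units", function() {
    res$assignments <<- assign_daily_units(ds, config$window_days)
    res$unit_sizes <<- daily_unit_sizes(res$assignments, ds)
    readr::write_csv(res$assignments, file.path(outdir, "units_daily.csv"))
  })

  ## parentage --------------------------------------------------------------
  run_stage("parentage", function() {
    if (is.null(ds$genotypes) || !nrow(ds$genotypes)) {
      log_line(log_path,
               "parentage: no genotypes; imputation-only mode (flagged)")
      offspring <- ds$individuals %>% filter(!is.na(.data$mother_id))
      res$paternity <<- purrr::map_dfr(seq_len(nrow(offspring)), function(i) {
        conc <- offspring$birth_date[i] - config$gestation_days
        row <- res$assignments %>%
          filter(.data$female_id == offspring$mother_id[i],
                 .data$date == conc)
        tibble(offspring_id = offspring$id[i],
               mother_id = offspring$mother_id[i],
               best_father_id = NA_character_, lod = NA_real_,
               delta = NA_real_, mismatches = NA_integer_,
               confidence = "none", accepted = FALSE, imputed = TRUE,
               maternity_ok = NA,
               father_id = if (nrow(row)) row$male_id[1] else NA_character_)
      })
      res$locus_qc <<- NULL
    } else {
      stats <- locus_stats(ds$genotypes, seed = config$seed)
      retained <- exclude_loci(stats, config$null_threshold)
      res$locus_qc <<- stats %>% select(-"freqs")
      res$paternity <<- assign_paternity(
        ds, retained_loci = retained, error_rate = config$error_rate,
        sim_cycles = config$sim_cycles, prop_sampled = config$prop_sampled,
        gestation_days = config$gestation_days,
        assignments = res$assignments, seed = config$seed)
      readr::write_csv(res$locus_qc, file.path(outdir, "locus_stats.csv"))
    }
    res$sired <<- yearly_sired_counts(res$paternity, ds)
    readr::write_csv(res$paternity, file.path(outdir, "paternity.csv"))
    res$male_year <<- male_year_table(ds, res$profiles, res$unit_sizes,
                                      res$sired)
    readr::write_csv(res$male_year, file.path(outdir, "male_year.csv"))
  })

  ## models -----------------------------------------------------------------
  run_stage("models", function() {
    res$models <<- fit_study_models(ds, res$dsi, res$coalitions,
                                    res$male_year,
                                    n_boot = config$n_boot,
                                    n_boot_coalition = config$n_boot_coalition,
                                    seed = config$seed)
    readr::write_csv(model_results_table(res$models),
                     file.path(outdir, "model_results.csv"))
    purrr::iwalk(res$models, function(m, nm) {
      fd <- effect_plot_data(m)
      if (!is.null(fd)) {
        readr::write_csv(fd, file.path(outdir, sprintf("fig_%s.csv", nm)))
      }
    })
  })

  ## report -----------------------------------------------------------------
  run_stage("report", function() {
    rep <- summary_report(list(dsi = res$dsi, profiles = res$profiles,
                               coalitions = res$coalitions,
                               male_year = res$male_year))
    res$report <<- rep
    readr::write_csv(rep, file.path(outdir, "summary_report.csv"))
    writeLines(format_summary_report(rep),
               file.path(outdir, "summary_report.txt"))
  })

  invisible(res)
}

#' Fit the three main models plus the post hoc beta model
#'
#' 1. Dyadic coalition counts ~ log-z DSI, Poisson with log contact-hour
#'    offset, random intercepts for both males and the dyad with uncorrelated
#'    DSI slopes within the male identities.
#' 2./3. Male-year unit-size mode and sired-offspring counts ~ z bond
#'    strength + z number of strong bonds, Poisson, male random intercept and
#'    uncorrelated bond-strength slope; z-scored presence proportion as a
#'    fixed control.
#' 4. Post hoc: squeezed proportion of focal time affiliating with males ~ z
#'    unit size, beta with logit link and male random intercept; the
#'    coefficient table is additionally reported with overdispersion-adjusted
#'    standard errors.
#'
#' Year and party enter every model as centred dummy controls. Each model
#' carries the full inference suite (full-null LRT, drop1, bootstrap CIs).
#'
#' @param ds study dataset (unused directly at present; kept for interface
#'   stability).
#' @param dsi,coalitions,male_year stage tables.
#' @param n_boot,n_boot_coalition bootstrap sizes.
#' @param seed RNG seed.
#' @return named list of `bbn_glmm` objects: `coalition`, `females`,
#'   `offspring`, `affiliation`.
#' @export
fit_study_models <- function(ds, dsi, coalitions, male_year, n_boot = 200,
                             n_boot_coalition = 100, seed = 1) {
  ## -- coalition model (dyad-year) -----------------------------------------
  dy <- dsi %>%
    select("party", "year", "male1", "male2", "dsi") %>%
    inner_join(coalitions %>%
                 select("party", "year", "male1", "male2", "contact_h",
                        "n_coalitions"),
               by = c("party", "year", "male1", "male2")) %>%
    filter(.data$contact_h > 0) %>%
    mutate(dyad = dyad_key(.data$male1, .data$male2),
           dsi_logz = log_z_dsi(.data$dsi))
  dy <- bind_cols(dy, centred_dummies(dy$year) %>%
                    rlang::set_names(~ sub("^d_", "year_", .x)))
  if (length(unique(dy$party)) > 1) {
    dy <- bind_cols(dy, centred_dummies(dy$party) %>%
                      rlang::set_names(~ sub("^d_", "party_", .x)))
  }
  yr_terms <- grep("^year_", names(dy), value = TRUE)
  pt_terms <- grep("^party_", names(dy), value = TRUE)
  ctrl <- c(yr_terms, pt_terms)
  # random slopes of the index within both male identities; intercept-slope
  # correlations excluded by construction
  re <- c("(1 | male1)", "(1 | male2)", "(1 | dyad)",
          "(0 + dsi_logz | male1)", "(0 + dsi_logz | male2)")
  f_coal <- as.formula(paste("n_coalitions ~",
                             paste(c("dsi_logz", ctrl, re),
                                   collapse = " + ")))
  f_coal_null <- as.formula(paste("n_coalitions ~",
                                  paste(c(ctrl, "1", re),
                                        collapse = " + ")))
  m_coal <- fit_glmm(dy, f_coal, "poisson_log", offset_col = "contact_h")
  m_coal <- inference_suite(m_coal, f_coal_null, predictors = "dsi_logz",
                            n_boot = n_boot_coalition, seed = seed)
  m_coal$effect_term <- "dsi_logz"
  m_coal$effect_raw <- "dsi"

  ## -- male-year models ----------------------------------------------------
  my <- male_year %>%
    filter(.data$presence_days > 0) %>%
    mutate(bond_z = z_transform(.data$bond_strength),
           strong_z = z_transform(.data$n_strong_bonds),
           presence_z = z_transform(.data$presence_days))
  my <- bind_cols(my, centred_dummies(my$year) %>%
                    rlang::set_names(~ sub("^d_", "year_", .x)))
  if (length(unique(my$party)) > 1) {
    my <- bind_cols(my, centred_dummies(my$party) %>%
                      rlang::set_names(~ sub("^d_", "party_", .x)))
  }
  yr2 <- grep("^year_", names(my), value = TRUE)
  pt2 <- grep("^party_", names(my), value = TRUE)
  ctrl2 <- c(yr2, pt2, "presence_z")
  re2 <- c("(1 | male_id)", "(0 + bond_z | male_id)")
  fit_my <- function(resp) {
    f <- as.formula(paste(
      resp, "~", paste(c("bond_z", "strong_z", ctrl2, re2),
                       collapse = " + ")))
    f0 <- as.formula(paste(
      resp, "~", paste(c(ctrl2, re2), collapse = " + ")))
    m <- fit_glmm(my, f, "poisson_log")
    m <- inference_suite(m, f0, predictors = c("bond_z", "strong_z"),
                         n_boot = n_boot, seed = seed)
    m$effect_term <- "bond_z"
    m$effect_raw <- "bond_strength"
    m
  }
  m_fem <- fit_my("unit_size_mode")
  m_off <- fit_my("n_sired")

  ## -- post hoc beta model -------------------------------------------------
  pb <- my %>%
    filter(!is.na(.data$affiliation_proportion)) %>%
    mutate(affil_sq = squeeze_proportion(.data$affiliation_proportion),
           unit_z = z_transform(.data$unit_size_mode))
  f_b <- as.formula(paste("affil_sq ~",
                          paste(c("unit_z", yr2, pt2, "(1 | male_id)"),
                                collapse = " + ")))
  f_b0 <- as.formula(paste("affil_sq ~",
                           paste(c(yr2, pt2, "1", "(1 | male_id)"),
                                 collapse = " + ")))
  m_beta <- fit_glmm(pb, f_b, "beta_logit")
  m_beta <- inference_suite(m_beta, f_b0, predictors = "unit_z",
                            n_boot = n_boot, seed = seed)
  m_beta$effect_term <- "unit_z"
  m_beta$effect_raw <- "unit_size_mode"

  list(coalition = m_coal, females = m_fem, offspring = m_off,
       affiliation = m_beta)
}

#' Flat results table for a set of fitted models
#' @param models named list of `bbn_glmm` objects.
#' @return tibble with one row per model term plus dispersion, LRT and VIF
#'   summaries.
#' @export
model_results_table <- function(models) {
  purrr::imap_dfr(models, function(m, nm) {
    tab <- if (m$family == "beta_logit") dispersion_adjust(m) else tidy(m)
    fn <- m$inference$full_null
    tab %>%
      mutate(model = nm, .before = 1) %>%
      mutate(dispersion = overdispersion(m)$phi,
             full_null_chisq = if (!is.null(fn)) fn$chisq else NA_real_,
             full_null_p = if (!is.null(fn)) fn$p_value else NA_real_,
             converged = m$converged)
  })
}

# data behind the effect plots: observed scatter plus the fixed-effect
# fitted curve with bootstrap band over a grid of the predictor of interest
effect_plot_data <- function(m) {
  term <- m$effect_term
  if (is.null(term)) return(NULL)
  est <- fixef_of(m)
  if (!term %in% names(est)) return(NULL)
  grid <- tibble(x = seq(min(m$data[[term]]), max(m$data[[term]]),
                         length.out = 50))
  eta <- est["(Intercept)"] + est[term] * grid$x
  inv <- if (m$family == "poisson_log") exp else plogis
  ci <- m$inference$boot_ci
  lo <- hi <- rep(NA_real_, nrow(grid))
  if (!is.null(ci) && term %in% ci$term && "(Intercept)" %in% ci$term) {
    b_lo <- ci$conf_low[ci$term == term]
    b_hi <- ci$conf_high[ci$term == term]
    i_est <- est["(Intercept)"]
    lo <- inv(i_est + pmin(b_lo * grid$x, b_hi * grid$x))
    hi <- inv(i_est + pmax(b_lo * grid$x, b_hi * grid$x))
  }
  tibble(term = term, x = grid$x, fitted = inv(eta),
         conf_low = lo, conf_high = hi)
}

#' Descriptive summary report
#'
#' Count-ratio descriptive statistics of a pipeline run, each computed
#' directly from the stage tables: the percentage of dyads with at least one
#' coalition and the mean number of coalitions per dyad (dyads pooled over
#' the study period), the percentage of dyad-years with an above-average
#' index value and the mean index of those strong dyads, the mean bond
#' strength per male-year, and mean sired offspring per study male, per
#' ever-primary male and per male-year.
#'
#' @param tables list with elements `dsi`, `profiles`, `coalitions`,
#'   `male_year` (any may be `NULL`, with a warning for the affected rows).
#' @return tibble `statistic`, `value`, `numerator`, `denominator`.
#' @export
summary_report <- function(tables) {
  rows <- list()
  add <- function(statistic, num, den, scale = 1) {
    rows[[length(rows) + 1L]] <<- tibble(
      statistic = statistic,
      value = if (den > 0) scale * num / den else NA_real_,
      numerator = num, denominator = den)
  }
  co <- tables$coalitions
  if (!is.null(co) && nrow(co)) {
    per_dyad <- co %>%
      group_by(.data$party, .data$male1, .data$male2) %>%
      summarise(n = sum(.data$n_coalitions), .groups = "drop")
    add("pct_dyads_with_coalition", sum(per_dyad$n >= 1), nrow(per_dyad), 100)
    add("mean_coalitions_per_dyad", sum(per_dyad$n), nrow(per_dyad))
  } else {
    warn("summary_report: no coalition table; coalition section empty")
  }
  dsi <- tables$dsi
  if (!is.null(dsi) && nrow(dsi)) {
    strong <- dsi %>%
      group_by(.data$party, .data$year) %>%
      mutate(strong = .data$dsi > mean(.data$dsi)) %>%
      ungroup()
    add("pct_dyads_above_average_dsi", sum(strong$strong), nrow(strong), 100)
    add("mean_dsi_strong_dyads", sum(strong$dsi[strong$strong]),
        sum(strong$strong))
  } else {
    warn("summary_report: no DSI table; DSI section empty")
  }
  prof <- tables$profiles
  if (!is.null(prof) && nrow(prof)) {
    add("mean_bond_strength", sum(prof$bond_strength), nrow(prof))
  }
  my <- tables$male_year
  if (!is.null(my) && nrow(my)) {
    per_male <- my %>%
      group_by(.data$male_id) %>%
      summarise(n_sired = sum(.data$n_sired),
                ever_primary = any(.data$days_primary > 0),
                .groups = "drop")
    tot <- sum(per_male$n_sired)
    add("mean_sired_per_male", tot, nrow(per_male))
    add("mean_sired_per_primary_male", tot, sum(per_male$ever_primary))
    add("mean_sired_per_male_year", sum(my$n_sired), nrow(my))
  } else {
    warn("summary_report: no male-year table; reproduction section empty")
  }
  bind_rows(rows)
}

format_summary_report <- function(rep) {
  c("descriptive summary",
    "===================",
    sprintf("%-32s %10.4f  (%g / %g)", rep$statistic, rep$value,
            rep$numerator, rep$denominator))
}
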