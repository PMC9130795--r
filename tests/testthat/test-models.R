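test_that("covariate transforms follow the printed formulas exactly", {
  x <- c(0, rep(0.2, 99))
  sq <- squeeze_proportion(x)
  expect_equal(sq[1], 0.5 / 100)                  # 0 -> 0.5/N
  expect_equal(squeeze_proportion(rep(0.5, 7))[1], 0.5)   # fixed point
  expect_equal(squeeze_proportion(1, n = 50), (1 * 49 + 0.5) / 50)

  withr::with_seed(1, {
    z <- z_transform(rnorm(200, 5, 3))
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
  })
  expect_error(z_transform(rep(2, 10)), "zero variance")

  d <- c(0, 0.1, 0.4, 2)
  lz <- log_z_dsi(d)     # offset c = half the smallest positive value
  expect_equal(lz, z_transform(log(d + 0.05)))
  expect_lt(abs(mean(lz)), 1e-12)

  cd <- centred_dummies(c("a", "a", "b", "c"))
  expect_equal(ncol(cd), 2)
  expect_equal(unname(colSums(cd)), c(0, 0))
})

test_that("adjusted standard errors scale with the dispersion parameter", {
  tab <- tibble::tibble(term = "x", estimate = 0.2, std_error = 0.1,
                        statistic = 2, p_value = 0.0455)
  phi <- 1.283
  se_adj <- tab$std_error * sqrt(phi)
  expect_equal(se_adj, 0.1132696, tolerance = 1e-6)
  z <- tab$estimate / se_adj
  expect_equal(2 * pnorm(-abs(z)), 2 * pnorm(-abs(0.2 / 0.1132696)),
               tolerance = 1e-6)
  # phi = 1 leaves standard errors untouched
  expect_equal(tab$std_error * sqrt(1), tab$std_error)
})

test_that("dispersion_adjust applies SE * sqrt(phi) to a fitted model", {
  tab <- simulate_male_year_table(seed = 2)
  tab$bond_z <- z_transform(tab$bond_strength)
  m <- fit_glmm(tab, unit_size ~ bond_z + (1 | male_id), "poisson_log")
  phi <- overdispersion(m)$phi
  adj <- dispersion_adjust(m)
  base <- tidy(m)
  expect_equal(adj$std_error_adj, base$std_error * sqrt(phi))
  expect_equal(adj$p_value_adj,
               2 * pnorm(-abs(base$estimate / adj$std_error_adj)))
  adj2 <- dispersion_adjust(m, phi = 1)
  expect_equal(adj2$std_error_adj, base$std_error)
})

test_that("variance inflation factors match their closed form", {
  withr::with_seed(3, {
    n <- 400
    x1 <- rnorm(n)
    e <- rnorm(n)
    # construct x2 with an exact sample correlation of 0.9
    x1s <- as.numeric(scale(x1))
    es <- as.numeric(scale(lm(e ~ x1)$residuals))
    x2 <- 0.9 * x1s + sqrt(1 - 0.81) * es
    x3 <- as.numeric(scale(lm(rnorm(n) ~ x1 + x2)$residuals))
    d <- tibble::tibble(y = rnorm(n), x1 = x1s, x2 = x2, x3 = x3)
    v <- vif_table(d, y ~ x1 + x2 + x3)
    expect_equal(v$vif[v$term %in% c("x1", "x2")],
                 rep(1 / (1 - 0.81), 2), tolerance = 1e-9)
    expect_equal(v$vif[v$term == "x3"], 1, tolerance = 1e-9)
    # orthogonal predictors all score 1
    v2 <- vif_table(d, y ~ x1 + x3)
    expect_equal(v2$vif, c(1, 1), tolerance = 1e-9)
    # a duplicated predictor is flagged as infinite
    d$x4 <- d$x1
    v3 <- vif_table(d, y ~ x1 + x4)
    expect_true(all(v3$collinear))
    expect_true(all(!is.finite(v3$vif)))
  })
})

test_that("with no group variance the mixed model collapses onto the GLM", {
  withr::with_seed(5, {
    d <- tibble::tibble(x = rnorm(120),
                        g = rep(sprintf("g%02d", 1:12), each = 10))
    d$y <- rpois(120, exp(0.3 + 0.6 * d$x))     # no group effect at all
  })
  m <- fit_glmm(d, y ~ x + (1 | g), "poisson_log")
  expect_equal(unname(lme4::VarCorr(m$model)$g[1, 1]), 0, tolerance = 1e-6)
  g <- glm(y ~ x, poisson(), d)
  expect_equal(unname(lme4::fixef(m$model)), unname(coef(g)),
               tolerance = 1e-5)
})

test_that("an all-zero count response is flagged as a boundary case", {
  d <- tibble::tibble(x = rnorm(30), off = runif(30, 1, 5),
                      g = rep(c("a", "b", "c"), 10), y = 0)
  m <- fit_glmm(d, y ~ x + (1 | g), "poisson_log", offset_col = "off")
  expect_true(m$boundary)
  expect_match(paste(m$messages, collapse = " "), "all zeros")
})

test_that("the inference suite: identical models give chisq 0, p 1", {
  tab <- simulate_male_year_table(seed = 11)
  tab$bond_z <- z_transform(tab$bond_strength)
  f <- unit_size ~ bond_z + (1 | male_id)
  m <- fit_glmm(tab, f, "poisson_log")
  m0 <- inference_suite(m, f, predictors = "bond_z", n_boot = 0)
  expect_equal(m0$inference$full_null$chisq, 0, tolerance = 1e-6)
  expect_equal(m0$inference$full_null$p_value, 1)
  expect_error(
    inference_suite(m, unit_size ~ strong_z + (1 | male_id), n_boot = 0),
    "not nested")
})

test_that("bootstrap intervals are reproducible under a fixed seed", {
  tab <- simulate_male_year_table(seed = 13)
  tab$bond_z <- z_transform(tab$bond_strength)
  m <- fit_glmm(tab, unit_size ~ bond_z + (1 | male_id), "poisson_log")
  ci1 <- parametric_boot_ci(m, n_boot = 30, seed = 99)
  ci2 <- parametric_boot_ci(m, n_boot = 30, seed = 99)
  expect_equal(ci1, ci2)
  expect_true(all(ci1$conf_low < ci1$conf_high))
  est <- lme4::fixef(m$model)
  expect_true(all(ci1$conf_low <= est & est <= ci1$conf_high))
})

test_that("the full-null test keeps its nominal size under the null", {
  withr::with_seed(17, {
    rej <- vapply(1:40, function(i) {
      tab <- simulate_male_year_table(seed = 1000 + i, beta_bond = 0)
      tab$bond_z <- z_transform(tab$bond_strength)
      m <- fit_glmm(tab, unit_size ~ bond_z + (1 | male_id), "poisson_log")
      m <- inference_suite(m, unit_size ~ (1 | male_id),
                           predictors = "bond_z", n_boot = 0)
      m$inference$full_null$p_value < 0.05
    }, logical(1))
  })
  expect_lt(mean(rej), 0.15)
})

test_that("likelihood never decreases from null to full model", {
  tab <- simulate_male_year_table(seed = 19)
  tab$bond_z <- z_transform(tab$bond_strength)
  tab$strong_z <- z_transform(tab$n_strong_bonds)
  f <- unit_size ~ bond_z + strong_z + (1 | male_id)
  f0 <- unit_size ~ (1 | male_id)
  m <- inference_suite(fit_glmm(tab, f, "poisson_log"), f0, n_boot = 0)
  expect_gte(m$inference$full_null$chisq, 0)
  expect_equal(nrow(m$inference$drop1), 2)
  expect_true(all(m$inference$drop1$chisq >= 0))
})

test_that("model deviance is invariant to affine rescaling before the z-transform", {
  tab <- simulate_male_year_table(seed = 23)
  fit_with <- function(x) {
    tab$bz <- z_transform(x)
    fit_glmm(tab, unit_size ~ bz + (1 | male_id), "poisson_log")
  }
  m1 <- fit_with(tab$bond_strength)
  m2 <- fit_with(tab$bond_strength * 13 - 5)
  expect_equal(as.numeric(logLik(m1$model)), as.numeric(logLik(m2$model)),
               tolerance = 1e-6)
  expect_equal(unname(lme4::fixef(m1$model)["bz"]),
               unname(lme4::fixef(m2$model)["bz"]),
               tolerance = 1e-6)
})

test_that("equidispersed Poisson data show a dispersion parameter near 1", {
  withr::with_seed(29, {
    phis <- vapply(1:20, function(i) {
      d <- tibble::tibble(x = rnorm(200),
                          g = rep(sprintf("g%02d", 1:20), each = 10))
      u <- rnorm(20, 0, 0.3)
      d$y <- rpois(200, exp(0.5 + 0.4 * d$x + u[as.integer(factor(d$g))]))
      overdispersion(fit_glmm(d, y ~ x + (1 | g), "poisson_log"))$phi
    }, double(1))
  })
  expect_lt(abs(mean(phis) - 1), 0.1)
})

test_that("beta-family dispersion uses the full beta variance", {
  tab <- simulate_male_year_table(seed = 31)
  tab$prop <- withr::with_seed(31, squeeze_proportion(
    plogis(-1.5 + 0.3 * z_transform(tab$bond_strength) +
             rnorm(nrow(tab), 0, 0.3))))
  tab$bond_z <- z_transform(tab$bond_strength)
  m <- fit_glmm(tab, prop ~ bond_z + (1 | male_id), "beta_logit")
  phi <- overdispersion(m)$phi
  expect_gt(phi, 0.3)   # on the natural scale, not the raw pearson one
  expect_lt(phi, 3)
})

test_that("tidy and glance expose the broom-style summaries", {
  tab <- simulate_male_year_table(seed = 37)
  tab$bond_z <- z_transform(tab$bond_strength)
  m <- fit_glmm(tab, unit_size ~ bond_z + (1 | male_id), "poisson_log")
  m <- inference_suite(m, unit_size ~ (1 | male_id), predictors = "bond_z",
                       n_boot = 20, seed = 1)
  td <- tidy(m)
  expect_true(all(c("term", "estimate", "std_error", "conf_low",
                    "conf_high", "p_lrt") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$nobs, nrow(tab))
  expect_true(gl$dispersion > 0)
  expect_true(gl$r2_marginal >= 0 && gl$r2_marginal <= 1)
  p <- autoplot(m, term = "bond_z")
  expect_s3_class(p, "ggplot")
})
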