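#' Covariate transforms for the mixed models
#'
#' `z_transform()` centres and scales to mean 0, SD 1 (error on zero
#' variance). `log_z_dsi()` log-transforms an index with zeros by adding half
#' the smallest positive value before the log, then z-transforms.
#' `squeeze_proportion()` maps a proportion away from the boundary with
#' `x' = (x * (N - 1) + 0.5) / N`, so 0 becomes `0.5/N` and 0.5 is a fixed
#' point. `centred_dummies()` dummy-codes a factor and centres each dummy.
#'
#' @param x numeric vector (factor/character for `centred_dummies`).
#' @param n sample size used in the squeeze (defaults to `length(x)`).
#' @return transformed numeric vector (a tibble of columns for
#'   `centred_dummies`).
#' @name transforms
NULL

#' @rdname transforms
#' @export
z_transform <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("z_transform: covariate has zero variance")
  }
  (x - mean(x)) / s
}

#' @rdname transforms
#' @export
log_z_dsi <- function(x) {
  pos <- x[x > 0]
  if (!length(pos)) abort("log_z_dsi: all values are zero")
  c0 <- min(pos) * 0.5
  z_transform(log(x + c0))
}

#' @rdname transforms
#' @export
squeeze_proportion <- function(x, n = length(x)) {
  (x * (n - 1) + 0.5) / n
}

#' @rdname transforms
#' @export
centred_dummies <- function(x) {
  f <- factor(x)
  if (nlevels(f) < 2) {
    return(tibble(.rows = length(x)))
  }
  mm <- model.matrix(~ f)[, -1, drop = FALSE]
  colnames(mm) <- paste0("d_", levels(f)[-1])
  tibble::as_tibble(scale(mm, scale = FALSE))
}

#' Fit a generalized linear mixed model for the pipeline
#'
#' Thin, deterministic wrapper around the two model families the analyses
#' use: Poisson with log link (lme4, adaptive Laplace approximation, bobyqa
#' optimizer) optionally with a log-exposure offset, and beta with logit link
#' (glmmTMB). Random-effect terms are passed in the formula; by convention
#' random slopes are written as separate `(0 + x | g)` terms so that
#' intercept-slope correlations are excluded. Non-convergence and boundary
#' problems (e.g. an all-zero count response) are flagged on the returned
#' object, not silently ignored.
#'
#' @param data model-ready tibble.
#' @param formula mixed-model formula (response, fixed and random terms).
#' @param family `"poisson_log"` or `"beta_logit"`.
#' @param offset_col name of a column whose log is used as offset
#'   (`poisson_log` only).
#' @param nAGQ integration points for the Poisson family: 1 (default) is the
#'   adaptive Laplace approximation; 0 uses the faster penalized
#'   least-squares step only, useful in large simulation studies.
#' @return object of class `bbn_glmm`: list with the underlying `model`,
#'   `family`, `data`, `formula`, `offset_col`, `converged`, `boundary`,
#'   `messages`.
#' @export
fit_glmm <- function(data, formula, family = c("poisson_log", "beta_logit"),
                     offset_col = NULL, nAGQ = 1) {
  family <- match.arg(family)
  if (nrow(data) < 10) abort("fit_glmm: need at least 10 rows")
  msgs <- character(0)
  resp <- all.vars(formula)[1]
  boundary <- FALSE
  if (family == "poisson_log" && all(data[[resp]] == 0)) {
    boundary <- TRUE
    msgs <- c(msgs, "response is all zeros: intercept at the log-link boundary")
  }
  if (!is.null(offset_col) && family != "poisson_log") {
    abort("fit_glmm: offsets are only supported for poisson_log")
  }
  if (!is.null(offset_col)) data$.offset_log <- log(data[[offset_col]])
  if (boundary) {
    # a constant zero response has its ML intercept at -Inf on the log link;
    # return a flagged, unfitted object instead of silent output
    return(structure(list(model = NULL, family = family, data = data,
                          formula = formula, offset_col = offset_col,
                          converged = FALSE, boundary = TRUE,
                          messages = msgs),
                     class = "bbn_glmm"))
  }
  fit <- withCallingHandlers(
    {
      if (family == "poisson_log" && !is.null(offset_col)) {
        lme4::glmer(formula, data = data, family = stats::poisson(),
                    offset = .offset_log, nAGQ = nAGQ,
                    control = lme4::glmerControl(optimizer = "bobyqa",
                                                 calc.derivs = FALSE))
      } else if (family == "poisson_log") {
        lme4::glmer(formula, data = data, family = stats::poisson(),
                    nAGQ = nAGQ,
                    control = lme4::glmerControl(optimizer = "bobyqa",
                                                 calc.derivs = FALSE))
      } else {
        glmmTMB::glmmTMB(formula, data = data,
                         family = glmmTMB::beta_family())
      }
    },
    warning = function(w) {
      msgs <<- c(msgs, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  converged <- if (family == "poisson_log") {
    is.null(fit@optinfo$conv$lme4$code) &&
      !any(grepl("failed to converge", msgs))
  } else {
    isTRUE(fit$fit$convergence == 0)
  }
  structure(list(model = fit, family = family, data = data, formula = formula,
                 offset_col = offset_col, converged = converged,
                 boundary = boundary, messages = msgs),
            class = "bbn_glmm")
}

#' @export
print.bbn_glmm <- function(x, ...) {
  cat(sprintf("<bbn_glmm> %s | n = %d%s%s\n", x$family, nrow(x$data),
              if (!x$converged) " | NOT CONVERGED" else "",
              if (x$boundary) " | BOUNDARY" else ""))
  print(tidy(x))
  invisible(x)
}

fixef_of <- function(fit) {
  if (fit$family == "poisson_log") lme4::fixef(fit$model)
  else glmmTMB::fixef(fit$model)$cond
}

se_of <- function(fit) {
  v <- if (fit$family == "poisson_log") as.matrix(stats::vcov(fit$model))
  else as.matrix(stats::vcov(fit$model)$cond)
  sqrt(diag(v))
}

#' @exportS3Method generics::tidy
tidy.bbn_glmm <- function(x, ...) {
  est <- fixef_of(x)
  se <- se_of(x)
  z <- est / se
  out <- tibble(term = names(est), estimate = unname(est),
                std_error = unname(se), statistic = unname(z),
                p_value = 2 * pnorm(-abs(z)))
  inf <- x$inference
  if (!is.null(inf$boot_ci)) {
    out <- out %>% left_join(inf$boot_ci, by = "term")
  }
  if (!is.null(inf$drop1)) {
    out <- out %>% left_join(inf$drop1 %>%
                               select("term", p_lrt = "p_value"),
                             by = "term")
  }
  out
}

#' @exportS3Method generics::glance
glance.bbn_glmm <- function(x, ...) {
  ll <- as.numeric(logLik(x$model))
  r2 <- tryCatch(r2_trigamma(x), error = function(e) c(NA_real_, NA_real_))
  tibble(nobs = nrow(x$data), logLik = ll,
         df = attr(logLik(x$model), "df"),
         dispersion = overdispersion(x)$phi,
         converged = x$converged,
         r2_marginal = r2[1], r2_conditional = r2[2])
}

re_variances <- function(fit) {
  if (fit$family == "poisson_log") {
    vc <- lme4::VarCorr(fit$model)
    vapply(vc, function(m) sum(diag(m)), double(1))
  } else {
    vc <- glmmTMB::VarCorr(fit$model)$cond
    vapply(vc, function(m) sum(diag(m)), double(1))
  }
}

# Marginal / conditional R2 on the latent scale; for Poisson log-link models
# the observation-level variance uses the trigamma method, trigamma(lambda)
# with lambda the fixed-effects mean count.
r2_trigamma <- function(fit) {
  if (fit$family != "poisson_log") {
    return(c(NA_real_, NA_real_))
  }
  X <- model.matrix(lme4::nobars(fit$formula)[-2], fit$data)
  beta <- fixef_of(fit)
  eta <- as.numeric(X[, names(beta), drop = FALSE] %*% beta)
  var_f <- var(eta)
  var_r <- sum(re_variances(fit))
  lambda <- exp(mean(eta) + var_r / 2)
  var_d <- trigamma(lambda)
  tot <- var_f + var_r + var_d
  c(var_f / tot, (var_f + var_r) / tot)
}

#' Overdispersion parameter of a fitted model
#'
#' `phi = sum(Pearson residuals^2) / residual df`; values well above 1
#' indicate overdispersion inflating type-I error rates.
#'
#' @param fit a [fit_glmm()] object.
#' @return list `phi`, `df`, `chisq`.
#' @export
overdispersion <- function(fit) {
  df <- df.residual(fit$model)
  if (is.null(df) || df <= 0) abort("overdispersion: residual df <= 0")
  if (fit$family == "beta_logit") {
    # full beta variance mu(1-mu)/(1+precision); glmmTMB's pearson
    # residuals omit the precision factor
    resp <- all.vars(fit$formula)[1]
    y <- fit$data[[resp]]
    mu <- stats::fitted(fit$model)
    prec <- stats::sigma(fit$model)
    r <- (y - mu) / sqrt(mu * (1 - mu) / (1 + prec))
  } else {
    r <- residuals(fit$model, type = "pearson")
  }
  list(phi = sum(r^2) / df, df = df, chisq = sum(r^2))
}

#' Overdispersion-adjusted standard errors and p-values
#'
#' Standard errors are scaled by the square root of the dispersion parameter
#' (`SE_adj = SE * sqrt(phi)`); z and p are recomputed as
#' `z = estimate / SE_adj`, `p = 2 * pnorm(-abs(z))`.
#'
#' @param fit a [fit_glmm()] object (or its [tidy()] table via `table`).
#' @param phi dispersion parameter; defaults to the model's own.
#' @return tidy coefficient tibble with `std_error_adj`, `statistic_adj`,
#'   `p_value_adj` columns.
#' @export
dispersion_adjust <- function(fit, phi = NULL) {
  tab <- tidy(fit)
  if (is.null(phi)) phi <- overdispersion(fit)$phi
  tab %>%
    mutate(std_error_adj = .data$std_error * sqrt(phi),
           statistic_adj = .data$estimate / .data$std_error_adj,
           p_value_adj = 2 * pnorm(-abs(.data$statistic_adj)))
}

#' Full-null comparison, single-term deletions and bootstrap intervals
#'
#' Augments a fitted model with the validation suite used throughout the
#' analyses: a likelihood ratio test of the full model against a null model
#' keeping only the control predictors and the random structure; per-predictor
#' likelihood ratio tests by single-term deletion; and percentile 95%
#' confidence intervals from a seeded parametric bootstrap.
#'
#' @param fit a [fit_glmm()] object.
#' @param null_formula formula of the null model (same data, nested fixed
#'   effects, same random structure).
#' @param predictors fixed-effect terms of interest to test by single-term
#'   deletion (default: terms present in the full but not the null formula).
#' @param n_boot parametric bootstrap draws (0 skips the bootstrap).
#' @param seed RNG seed for the bootstrap.
#' @return the `bbn_glmm` object with an `inference` element: `full_null`
#'   (chisq, df, p), `drop1` (term, chisq, df, p), `boot_ci` (term, conf_low,
#'   conf_high), `n_boot`.
#' @export
inference_suite <- function(fit, null_formula, predictors = NULL,
                            n_boot = 1000, seed = 1) {
  full_terms <- attr(stats::terms(lme4::nobars(fit$formula)), "term.labels")
  null_terms <- attr(stats::terms(lme4::nobars(null_formula)), "term.labels")
  if (!all(null_terms %in% full_terms)) {
    abort("inference_suite: null model is not nested in the full model")
  }
  if (is.null(predictors)) predictors <- setdiff(full_terms, null_terms)

  refit <- function(f) fit_glmm(fit$data, f, fit$family, fit$offset_col)
  null_fit <- refit(null_formula)
  ll_full <- as.numeric(logLik(fit$model))
  ll_null <- as.numeric(logLik(null_fit$model))
  df_full <- attr(logLik(fit$model), "df")
  df_null <- attr(logLik(null_fit$model), "df")
  chisq <- max(0, 2 * (ll_full - ll_null))
  dfd <- df_full - df_null
  full_null <- tibble(chisq = chisq, df = dfd,
                      p_value = if (dfd > 0) pchisq(chisq, dfd,
                                                    lower.tail = FALSE)
                      else 1)

  drop1_tab <- purrr::map_dfr(predictors, function(tm) {
    f_red <- drop_fixed_term(fit$formula, tm)
    red <- refit(f_red)
    ch <- max(0, 2 * (ll_full - as.numeric(logLik(red$model))))
    dfi <- df_full - attr(logLik(red$model), "df")
    tibble(term = tm, chisq = ch, df = dfi,
           p_value = if (dfi > 0) pchisq(ch, dfi, lower.tail = FALSE) else 1)
  })

  boot_ci <- NULL
  if (n_boot > 0) {
    boot_ci <- parametric_boot_ci(fit, n_boot = n_boot, seed = seed)
  }
  fit$inference <- list(full_null = full_null, drop1 = drop1_tab,
                        boot_ci = boot_ci, n_boot = n_boot,
                        null_formula = null_formula)
  fit
}

# remove one fixed-effect term from a mixed formula, keeping the bars
drop_fixed_term <- function(f, term) {
  rhs_bars <- lme4::findbars(f)
  fixed <- lme4::nobars(f)
  tt <- attr(stats::terms(fixed), "term.labels")
  keep <- setdiff(tt, term)
  resp <- deparse(f[[2]])
  bars <- vapply(rhs_bars, function(b) paste0("(", deparse(b), ")"),
                 character(1))
  rhs <- paste(c(if (length(keep)) keep else "1", bars), collapse = " + ")
  as.formula(paste(resp, "~", rhs), env = environment(f))
}

#' Percentile confidence intervals from a parametric bootstrap
#'
#' Simulates `n_boot` response vectors from the fitted model, refits, and
#' takes percentile 2.5/97.5 quantiles of the fixed effects. Uses
#' `lme4::bootMer` machinery semantics for Poisson fits and an explicit
#' simulate-refit loop for beta fits. Failed refits are dropped (their count
#' is reported in the attribute `n_failed`).
#'
#' @param fit a [fit_glmm()] object.
#' @param n_boot number of draws.
#' @param seed RNG seed.
#' @param level confidence level.
#' @return tibble `term`, `conf_low`, `conf_high`.
#' @export
parametric_boot_ci <- function(fit, n_boot = 1000, seed = 1, level = 0.95) {
  a <- (1 - level) / 2
  draws <- withr::with_seed(seed, {
    if (fit$family == "poisson_log") {
      bo <- suppressWarnings(suppressMessages(
        lme4::bootMer(fit$model, FUN = lme4::fixef, nsim = n_boot,
                      type = "parametric", use.u = FALSE)))
      bo$t
    } else {
      sims <- simulate(fit$model, nsim = n_boot)
      resp <- all.vars(fit$formula)[1]
      t(vapply(seq_len(n_boot), function(i) {
        d <- fit$data
        d[[resp]] <- sims[[i]]
        out <- tryCatch(
          glmmTMB::fixef(glmmTMB::glmmTMB(fit$formula, data = d,
                                          family = glmmTMB::beta_family()))$cond,
          error = function(e) rep(NA_real_, length(fixef_of(fit))))
        out
      }, double(length(fixef_of(fit)))))
    }
  })
  ok <- complete.cases(draws)
  ci <- apply(draws[ok, , drop = FALSE], 2, quantile,
              probs = c(a, 1 - a), na.rm = TRUE)
  out <- tibble(term = colnames(draws), conf_low = ci[1, ],
                conf_high = ci[2, ])
  attr(out, "n_failed") <- sum(!ok)
  out
}

#' Variance inflation factors of the fixed-effects design
#'
#' Collinearity diagnostic computed, as in standard practice for mixed
#' models, on the fixed-effects-only linear design: each predictor column is
#' regressed on all others and `VIF_j = 1 / (1 - R2_j)`. Perfectly collinear
#' columns get `Inf` and are flagged.
#'
#' @param data model data.
#' @param fixed_formula one-sided or two-sided formula of the fixed effects
#'   (random-effect bars are ignored).
#' @return tibble `term`, `vif`, `collinear`.
#' @export
vif_table <- function(data, fixed_formula) {
  f <- lme4::nobars(fixed_formula)
  if (length(f) == 3) f <- f[-2]
  X <- model.matrix(f, data)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 2) abort("vif_table: need at least two fixed-effect columns")
  vifs <- vapply(seq_len(ncol(X)), function(j) {
    y <- X[, j]
    Z <- X[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, Z), y)
    r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, double(1))
  tibble(term = colnames(X), vif = vifs, collinear = !is.finite(vifs))
}
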