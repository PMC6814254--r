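#' Between-person / within-person decomposition of a panel predictor
#'
#' Splits a time-varying predictor into a between-person component BP (the
#' person mean across the patient's panel quarters) and a within-person
#' component WP (the deviation of the current quarter from that mean), each
#' divided by `scale` so that coefficients on percentile metrics are
#' reported per 10 percentile points. By construction the per-patient mean
#' of WP is exactly 0 and `scale * (bp + wp)` reconstructs the original
#' column.
#'
#' The BP effect compares patients to each other; the WP effect compares a
#' patient to their own average over time and is analogous to a
#' fixed-effects estimate.
#'
#' @param panel Panel with `patient_id` and the predictor column.
#' @param column Predictor column name (default `"pr_pct"`).
#' @param scale Divisor (10 for percentile metrics, 1 for standardized or
#'   logged metrics).
#' @return data.table with `bp` and `wp`, row-aligned with `panel`.
#' @export
decompose_predictor <- function(panel, column = "pr_pct", scale = 10) {
  x <- panel[[column]]
  if (is.null(x)) stop("panel lacks column '", column, "'", call. = FALSE)
  pm <- stats::ave(x, panel[["patient_id"]])
  data.table(bp = pm / scale, wp = (x - pm) / scale)
}

#' Specification of one panel model
#'
#' @param outcome One of `n_rx` (count), `mme_gt90`, `overdose_any`, `oud`
#'   (binary).
#' @param metric Prominence column to decompose into BP/WP (`pr_pct`,
#'   `bip_pr_pct`, `pr_std`, `degree_log`).
#' @param family `"auto"` picks negative binomial (log link) for `n_rx` and
#'   binomial (logit) otherwise; `"poisson"` available for nested-limit
#'   checks.
#' @param random_intercept Include the per-patient random intercept? Setting
#'   `FALSE` fits the corresponding fixed-effects-only GLM (the sigma_u = 0
#'   limit).
#' @param insurance_ref,state_ref Reference categories for the dummies.
#' @param scale Per-`scale`-unit coefficient scaling passed to
#'   [decompose_predictor()]; `NULL` picks 10 for percentile metrics and 1
#'   otherwise.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome = c("n_rx", "mme_gt90", "overdose_any", "oud"),
                       metric = "pr_pct",
                       family = c("auto", "nbinom", "binomial", "poisson"),
                       random_intercept = TRUE,
                       insurance_ref = "Other",
                       state_ref = "West Virginia",
                       scale = NULL) {
  outcome <- match.arg(outcome)
  family <- match.arg(family)
  if (family == "auto") family <- if (outcome == "n_rx") "nbinom" else
    "binomial"
  if (outcome == "n_rx" && family == "binomial")
    stop("count outcome requires a count family", call. = FALSE)
  if (outcome != "n_rx" && family %in% c("nbinom", "poisson"))
    stop("binary outcomes require the binomial family", call. = FALSE)
  if (is.null(scale))
    scale <- if (metric %in% c("pr_pct", "bip_pr_pct")) 10 else 1
  structure(list(outcome = outcome, metric = metric, family = family,
                 random_intercept = random_intercept,
                 insurance_ref = insurance_ref, state_ref = state_ref,
                 scale = scale),
            class = "model_spec")
}

prepare_model_frame <- function(panel, spec) {
  mf <- as.data.table(panel)
  dec <- decompose_predictor(mf, spec$metric, spec$scale)
  mf[, `:=`(bp = dec$bp, wp = dec$wp)]
  if ("insurance" %in% names(mf))
    mf[, insurance := stats::relevel(factor(insurance), ref =
                                       spec$insurance_ref)]
  if ("state" %in% names(mf)) {
    lev <- unique(as.character(mf$state))
    ref <- if (spec$state_ref %in% lev) spec$state_ref else lev[1]
    mf[, state := stats::relevel(factor(state), ref = ref)]
  }
  mf
}

# fixed-effect terms, dropping degenerate (constant) ones with a note
fixed_terms <- function(mf) {
  candidates <- c("female", "age_10yr", "insurance", "state", "cancer_dx",
                  "n_prescribers", "bp", "wp")
  present <- intersect(candidates, names(mf))
  notes <- character()
  keep <- character()
  for (v in present) {
    x <- mf[[v]]
    nlev <- if (is.factor(x)) nlevels(droplevels(x)) else
      length(unique(x))
    if (nlev < 2) {
      notes <- c(notes, sprintf("dropped constant covariate '%s'", v))
    } else {
      keep <- c(keep, v)
    }
  }
  list(terms = keep, notes = notes)
}

#' Fit a random-intercept panel model
#'
#' Fits the mixed-effects regression of one opioid outcome on the BP/WP
#' decomposition of a prominence metric plus controls (gender, age per 10
#' years, insurance dummies, state fixed effects, cancer history, number of
#' unique prescribers), with a patient-level random intercept absorbing the
#' correlation of observations within patients over time. Binary outcomes
#' use a logistic mixed model (Laplace approximation via `lme4::glmer`);
#' the count outcome a negative-binomial mixed model (`glmmTMB`, nbinom2
#' parameterization). Coefficients are reported exponentiated — odds ratios
#' for binary outcomes, incidence rate ratios for counts — with Wald 95%
#' CIs. Degenerate (constant) covariates are dropped automatically and
#' noted, mirroring omitted cells in sparse strata.
#'
#' @param panel An assembled analysis panel.
#' @param spec A [model_spec()].
#' @param backend Mixed-model engine for binary outcomes: `"glmmTMB"`
#'   (default) or `"glmer"` (lme4). Both maximize the same Laplace
#'   likelihood and agree to estimation tolerance; the alternative backend
#'   exists as an independent cross-check.
#' @return Object of class `model_result`: `coefficients` (term, log-scale
#'   estimate, SE, exponentiated estimate, 95% CI, p), `sigma_u2`, `icc`,
#'   `bic`, `family`, `n_obs`, `n_patients`, `notes`, plus internals used
#'   by [margins()].
#' @export
fit_glmm <- function(panel, spec, backend = c("glmmTMB", "glmer")) {
  stopifnot(inherits(spec, "model_spec"))
  backend <- match.arg(backend)
  mf <- prepare_model_frame(panel, spec)
  ft <- fixed_terms(mf)
  rhs <- paste(ft$terms, collapse = " + ")
  notes <- ft$notes

  if (spec$random_intercept) {
    f <- as.formula(paste(spec$outcome, "~", rhs, "+ (1 | patient_id)"))
    if (spec$family == "binomial" && backend == "glmer") {
      fit <- lme4::glmer(f, data = mf, family = binomial(),
                         nAGQ = 1L,
                         control = lme4::glmerControl(
                           optimizer = "bobyqa",
                           optCtrl = list(maxfun = 1e5),
                           calc.derivs = FALSE,
                           check.conv.singular = "ignore"))
      beta <- lme4::fixef(fit)
      V <- as.matrix(vcov(fit))
      sigma_u2 <- as.numeric(lme4::VarCorr(fit)$patient_id[1])
      theta <- NA_real_
    } else if (spec$family == "binomial") {
      fit <- glmmTMB::glmmTMB(f, data = mf, family = binomial())
      beta <- glmmTMB::fixef(fit)$cond
      V <- as.matrix(vcov(fit)$cond)
      sigma_u2 <- as.numeric(glmmTMB::VarCorr(fit)$cond$patient_id[1])
      theta <- NA_real_
    } else {
      fam <- if (spec$family == "nbinom") glmmTMB::nbinom2() else poisson()
      fit <- glmmTMB::glmmTMB(f, data = mf, family = fam)
      est <- glmmTMB::fixef(fit)$cond
      beta <- est
      V <- as.matrix(vcov(fit)$cond)
      sigma_u2 <- as.numeric(glmmTMB::VarCorr(fit)$cond$patient_id[1])
      theta <- if (spec$family == "nbinom") glmmTMB::sigma(fit) else
        NA_real_
    }
  } else {
    f <- as.formula(paste(spec$outcome, "~", rhs))
    if (spec$family == "binomial") {
      fit <- glm(f, data = mf, family = binomial())
      theta <- NA_real_
    } else if (spec$family == "poisson") {
      fit <- glm(f, data = mf, family = poisson())
      theta <- NA_real_
    } else {
      fit <- glmmTMB::glmmTMB(f, data = mf, family = glmmTMB::nbinom2())
      theta <- glmmTMB::sigma(fit)
    }
    beta <- if (inherits(fit, "glmmTMB")) glmmTMB::fixef(fit)$cond else
      coef(fit)
    V <- if (inherits(fit, "glmmTMB")) as.matrix(vcov(fit)$cond) else
      as.matrix(vcov(fit))
    sigma_u2 <- 0
  }

  se <- sqrt(diag(V))
  z <- beta / se
  coefs <- data.table(
    term = names(beta),
    estimate = as.numeric(beta),
    se = as.numeric(se),
    exp_estimate = exp(as.numeric(beta)),
    ci_lo = exp(as.numeric(beta) - 1.959964 * as.numeric(se)),
    ci_hi = exp(as.numeric(beta) + 1.959964 * as.numeric(se)),
    p = 2 * pnorm(-abs(as.numeric(z)))
  )
  mu_bar <- mean(mf[[spec$outcome]])
  res <- structure(list(
    spec = spec,
    coefficients = coefs,
    sigma_u2 = sigma_u2,
    theta = theta,
    bic = as.numeric(BIC(fit)),
    family = spec$family,
    n_obs = nrow(mf),
    n_patients = length(unique(mf$patient_id)),
    mu_bar = mu_bar,
    notes = notes,
    fit = fit,
    vcov = V,
    model_frame = mf,
    formula_rhs = rhs
  ), class = "model_result")
  res$icc <- icc(res)
  res
}

#' Intraclass correlation of a fitted panel model
#'
#' For logistic models the latent-scale ICC
#' `sigma_u^2 / (sigma_u^2 + pi^2/3)` (the logistic residual variance).
#' For count models the lognormal-Poisson latent-scale approximation
#' `sigma_u^2 / (sigma_u^2 + log(1 + 1/mu + alpha))`, with `mu` the mean
#' outcome and `alpha = 1/theta` the nbinom2 overdispersion (0 for
#' Poisson); this count-model variant is an approximation and comparisons
#' across families are qualitative.
#'
#' @param result A `model_result`, or a numeric `sigma_u2` (with
#'   `family`, `mu_bar`, `alpha` supplied) for closed-form checks.
#' @param family,mu_bar,alpha Used only when `result` is numeric.
#' @return ICC in [0, 1).
#' @export
icc <- function(result, family = "binomial", mu_bar = NULL, alpha = 0) {
  if (is.numeric(result)) {
    sigma_u2 <- result
  } else {
    sigma_u2 <- result$sigma_u2
    family <- result$family
    mu_bar <- result$mu_bar
    alpha <- if (!is.na(result$theta) && result$theta > 0)
      1 / result$theta else 0
  }
  if (sigma_u2 == 0) return(0)
  if (family %in% c("nbinom", "poisson")) {
    resid_var <- log(1 + 1 / mu_bar + alpha)
  } else {
    resid_var <- pi^2 / 3
  }
  sigma_u2 / (sigma_u2 + resid_var)
}

gauss_hermite_avg <- function(fun, sigma, n_nodes = 30L) {
  gh <- pracma::gaussHermite(n_nodes)
  function(eta) {
    vapply(eta, function(e)
      sum(gh$w * fun(e + sqrt(2) * sigma * gh$x)) / sqrt(pi),
      numeric(1))
  }
}

#' Predicted margins over a prominence component
#'
#' Population-averaged predictions at a grid over BP (or WP) spanning plus
#' or minus one standard deviation of its sample distribution, holding all
#' other covariates at their sample means (binary covariates at observed
#' proportions). Averaging over the patient random intercept uses
#' Gauss–Hermite quadrature; for the identity-link sanity variant the
#' margins are exactly the linear predictor. Confidence bands are
#' delta-method Wald intervals.
#'
#' @param result A `model_result`.
#' @param predictor `"bp"` or `"wp"`.
#' @param n_grid Grid points.
#' @param n_sd Half-width of the grid in sample SDs of the predictor.
#' @param n_nodes Gauss–Hermite nodes.
#' @return data.table with the grid value, `predicted`, `ci_lo`, `ci_hi`.
#' @export
margins <- function(result, predictor = c("bp", "wp"), n_grid = 25L,
                    n_sd = 1, n_nodes = 30L) {
  predictor <- match.arg(predictor)
  stopifnot(inherits(result, "model_result"))
  mf <- result$model_frame
  f_fixed <- as.formula(paste("~", result$formula_rhs))
  X <- stats::model.matrix(f_fixed, data = mf)
  beta <- result$coefficients$estimate
  names(beta) <- result$coefficients$term
  X <- X[, names(beta), drop = FALSE]
  xbar <- colMeans(X)

  v <- mf[[predictor]]
  ctr <- mean(v)
  hw <- n_sd * sd(v)
  grid <- seq(ctr - hw, ctr + hw, length.out = n_grid)
  if (min(grid) < min(v) || max(grid) > max(v))
    warning("margins grid extends beyond the observed support of ",
            predictor, call. = FALSE)

  sigma <- sqrt(result$sigma_u2)
  inv <- if (result$family == "binomial") plogis else exp
  dinv <- if (result$family == "binomial")
    function(x) plogis(x) * (1 - plogis(x)) else exp
  avg_inv <- gauss_hermite_avg(inv, sigma, n_nodes)
  avg_dinv <- gauss_hermite_avg(dinv, sigma, n_nodes)

  out <- rbindlist(lapply(grid, function(g) {
    x <- xbar
    x[predictor] <- g
    eta <- sum(x * beta)
    m <- avg_inv(eta)
    dm_deta <- avg_dinv(eta)
    gvec <- dm_deta * x
    se <- sqrt(as.numeric(t(gvec) %*% result$vcov %*% gvec))
    data.table(value = g, predicted = m,
               ci_lo = m - 1.959964 * se, ci_hi = m + 1.959964 * se)
  }))
  setnames(out, "value", predictor)
  out[]
}

#' @export
print.model_result <- function(x, digits = 3, ...) {
  lab <- if (x$family %in% c("nbinom", "poisson")) "IRR" else "OR"
  cat(sprintf("mixed-effects %s model of %s on BP/WP %s (n = %d patients, %d obs)\n",
              x$family, x$spec$outcome, x$spec$metric, x$n_patients, x$n_obs))
  tab <- x$coefficients[, .(term,
                            est = round(exp_estimate, digits),
                            ci = sprintf("(%.*f-%.*f)", digits, ci_lo,
                                         digits, ci_hi))]
  setnames(tab, "est", lab)
  print(tab, row.names = FALSE)
  cat(sprintf("sigma_u^2 = %.3f   ICC = %.3f   BIC = %.1f\n",
              x$sigma_u2, x$icc, x$bic))
  if (length(x$notes) > 0) cat("notes:", paste(x$notes, collapse = "; "),
                               "\n")
  invisible(x)
}

#' Fit the full suite of model variants
#'
#' One fitted model per combination of outcome, prominence metric and
#' sample (main panel vs. the high-risk restriction), mirroring the layout
#' of a main-results table plus its sensitivity variants. Failures in a
#' cell are captured, not propagated.
#'
#' @param panel An assembled analysis panel.
#' @param outcomes Outcomes to fit.
#' @param metrics Prominence metrics to decompose.
#' @param samples Subset of `c("main", "highrisk")`.
#' @return List with `results` (named list of `model_result`/condition) and
#'   `summary` (data.table: one row per fitted cell with BP/WP
#'   exponentiated estimates, ICC, BIC).
#' @export
run_model_suite <- function(panel,
                            outcomes = outcome_names(),
                            metrics = "pr_pct",
                            samples = c("main", "highrisk")) {
  samples <- match.arg(samples, several.ok = TRUE)
  results <- list()
  rows <- list()
  for (smp in samples) {
    dat <- if (smp == "highrisk") restrict_high_risk(panel) else panel
    for (met in metrics) {
      for (oc in outcomes) {
        key <- paste(smp, met, oc, sep = ".")
        res <- tryCatch(fit_glmm(dat, model_spec(oc, metric = met)),
                        error = function(e) e)
        results[[key]] <- res
        if (inherits(res, "model_result")) {
          cf <- res$coefficients
          rows[[key]] <- data.table(
            sample = smp, metric = met, outcome = oc,
            bp_exp = cf[term == "bp", exp_estimate],
            bp_lo = cf[term == "bp", ci_lo],
            bp_hi = cf[term == "bp", ci_hi],
            wp_exp = cf[term == "wp", exp_estimate],
            wp_lo = cf[term == "wp", ci_lo],
            wp_hi = cf[term == "wp", ci_hi],
            icc = res$icc, bic = res$bic,
            n_obs = res$n_obs, n_patients = res$n_patients)
        } else {
          rows[[key]] <- data.table(
            sample = smp, metric = met, outcome = oc,
            bp_exp = NA_real_, bp_lo = NA_real_, bp_hi = NA_real_,
            wp_exp = NA_real_, wp_lo = NA_real_, wp_hi = NA_real_,
            icc = NA_real_, bic = NA_real_,
            n_obs = NA_integer_, n_patients = NA_integer_)
        }
      }
    }
  }
  list(results = results, summary = rbindlist(rows))
}

#' Write the model-suite summary as delimited text
#' @param suite A [run_model_suite()] result.
#' @param path Output file.
#' @return `path` invisibly.
#' @export
write_model_report <- function(suite, path) {
  fwrite(suite$summary, path)
  invisible(path)
}
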