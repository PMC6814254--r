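test_that("BP/WP decomposition has closed-form values and an exact identity", {
  pan <- data.table::data.table(patient_id = rep("P1", 4),
                                pr_pct = c(60, 60, 60, 60))
  d <- decompose_predictor(pan)
  expect_equal(d$bp, rep(6, 4))
  expect_equal(d$wp, rep(0, 4))

  pan2 <- data.table::data.table(patient_id = rep("P1", 2),
                                 pr_pct = c(40, 60))
  d2 <- decompose_predictor(pan2)
  expect_equal(d2$bp, c(5, 5))
  expect_equal(d2$wp, c(-1, 1))

  set.seed(71)
  rp <- data.table::data.table(
    patient_id = rep(sprintf("P%03d", 1:50), each = 4),
    pr_pct = runif(200, 0, 100))
  dr <- decompose_predictor(rp)
  wp_means <- tapply(dr$wp, rp$patient_id, mean)
  expect_lt(max(abs(wp_means)), 1e-12)
  expect_equal(10 * (dr$bp + dr$wp), rp$pr_pct, tolerance = 1e-12)
  expect_true(all(tapply(dr$bp, rp$patient_id,
                         function(x) max(x) - min(x)) == 0))
})

test_that("model_spec enforces the outcome-family pairing", {
  expect_error(model_spec("n_rx", family = "binomial"), "count")
  expect_error(model_spec("oud", family = "nbinom"), "binomial")
  expect_equal(model_spec("n_rx")$family, "nbinom")
  expect_equal(model_spec("oud")$family, "binomial")
  expect_equal(model_spec("oud", metric = "pr_std")$scale, 1)
})

test_that("without a random intercept the Poisson panel model collapses to glm", {
  pan <- simulate_panel(
    n_patients = 400,
    sigma_u = c(n_rx = 0, mme_gt90 = 0, overdose_any = 0, oud = 0),
    dispersion = 1e8,  # effectively Poisson counts
    seed = 101L)
  spec <- model_spec("n_rx", family = "poisson", random_intercept = FALSE)
  res <- fit_glmm(pan, spec)
  mf <- coprescribenet:::prepare_model_frame(pan, spec)
  ref <- glm(n_rx ~ female + age_10yr + insurance + state + cancer_dx +
               n_prescribers + bp + wp, data = mf, family = poisson())
  expect_equal(setNames(res$coefficients$estimate,
                        res$coefficients$term)[names(coef(ref))],
               coef(ref), tolerance = 1e-3)
  expect_equal(res$sigma_u2, 0)
  expect_equal(res$icc, 0)
})

test_that("a planted within-person effect is recovered by the logistic GLMM", {
  pan <- simulate_panel(
    n_patients = 1500,
    beta_bp = c(n_rx = 0, mme_gt90 = log(1.5), overdose_any = 0, oud = 0),
    beta_wp = c(n_rx = 0, mme_gt90 = log(1.5), overdose_any = 0, oud = 0),
    baseline_rates = c(n_rx = 1.26, mme_gt90 = 0.10, overdose_any = 0.0016,
                       oud = 0.012),
    seed = 103L)
  res <- fit_glmm(pan, model_spec("mme_gt90"))
  wp_row <- res$coefficients[term == "wp"]
  expect_gt(wp_row$ci_hi, 1.5 * 0.98)  # CI reaches the planted OR
  expect_lt(wp_row$ci_lo, 1.5 * 1.02)
  expect_gt(res$sigma_u2, 0.3)         # planted sigma_u = 1
  expect_gt(res$icc, 0.1)
})

test_that("a planted null yields estimates within 3 SE of zero everywhere", {
  zero <- c(n_rx = 0, mme_gt90 = 0, overdose_any = 0, oud = 0)
  pan <- simulate_panel(
    n_patients = 1200, beta_bp = zero, beta_wp = zero,
    sigma_u = c(n_rx = 0.5, mme_gt90 = 0.5, overdose_any = 0.5, oud = 0.5),
    baseline_rates = c(n_rx = 1.26, mme_gt90 = 0.10, overdose_any = 0.0016,
                       oud = 0.05),
    seed = 107L)
  res <- fit_glmm(pan, model_spec("oud"))
  cf <- res$coefficients[term %in% c("bp", "wp", "female", "age_10yr",
                                     "cancer_dx")]
  expect_true(all(abs(cf$estimate) < 3 * cf$se))
})

test_that("the two logistic backends maximize the same likelihood", {
  pan <- simulate_panel(n_patients = 400,
                        baseline_rates = c(n_rx = 1.26, mme_gt90 = 0.10,
                                           overdose_any = 0.0016,
                                           oud = 0.012),
                        seed = 113L)
  a <- fit_glmm(pan, model_spec("mme_gt90"), backend = "glmmTMB")
  b <- fit_glmm(pan, model_spec("mme_gt90"), backend = "glmer")
  ea <- setNames(a$coefficients$estimate, a$coefficients$term)
  eb <- setNames(b$coefficients$estimate, b$coefficients$term)
  expect_equal(ea, eb[names(ea)], tolerance = 1e-3)
  expect_equal(a$sigma_u2, b$sigma_u2, tolerance = 1e-2)
})

test_that("ICC has its closed-form values and is monotone in sigma_u^2", {
  expect_equal(icc(0), 0)
  expect_equal(icc(pi^2 / 3), 0.5)
  expect_equal(icc(pi^2), 0.75)
  s <- seq(0, 5, by = 0.25)
  vals <- vapply(s, icc, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals < 1))
  # count-model variant: more overdispersion -> more residual variance ->
  # smaller ICC at fixed sigma_u^2
  i1 <- icc(1, family = "nbinom", mu_bar = 1.26, alpha = 0)
  i2 <- icc(1, family = "nbinom", mu_bar = 1.26, alpha = 1)
  expect_gt(i1, i2)
})

test_that("margins match direct numerical integration over the random intercept", {
  pan <- simulate_panel(n_patients = 500,
                        baseline_rates = c(n_rx = 1.26, mme_gt90 = 0.10,
                                           overdose_any = 0.0016,
                                           oud = 0.012),
                        seed = 109L)
  res <- fit_glmm(pan, model_spec("mme_gt90"))
  mg <- margins(res, "bp", n_grid = 7)
  expect_equal(nrow(mg), 7L)
  expect_true(all(mg$ci_lo <= mg$predicted & mg$predicted <= mg$ci_hi))
  expect_true(all(diff(mg$predicted) > 0))  # planted positive BP effect

  # independent quadrature oracle at each grid point via stats::integrate
  mf <- res$model_frame
  X <- stats::model.matrix(stats::as.formula(paste("~", res$formula_rhs)),
                           data = mf)
  beta <- setNames(res$coefficients$estimate, res$coefficients$term)
  X <- X[, names(beta), drop = FALSE]
  xbar <- colMeans(X)
  sigma <- sqrt(res$sigma_u2)
  for (k in c(1, 4, 7)) {
    x <- xbar; x["bp"] <- mg$bp[k]
    eta <- sum(x * beta)
    orc <- stats::integrate(function(u)
      stats::plogis(eta + u) * stats::dnorm(u, 0, sigma),
      -Inf, Inf, rel.tol = 1e-10)$value
    expect_equal(mg$predicted[k], orc, tolerance = 1e-6)
  }

  # null-effect model: flat margins within the CI band
  zero <- c(n_rx = 0, mme_gt90 = 0, overdose_any = 0, oud = 0)
  pan0 <- simulate_panel(n_patients = 500, beta_bp = zero, beta_wp = zero,
                         baseline_rates = c(n_rx = 1.26, mme_gt90 = 0.10,
                                            overdose_any = 0.0016,
                                            oud = 0.012),
                         seed = 111L)
  res0 <- fit_glmm(pan0, model_spec("mme_gt90"))
  mg0 <- margins(res0, "bp", n_grid = 7)
  spread <- max(mg0$predicted) - min(mg0$predicted)
  width <- mean(mg0$ci_hi - mg0$ci_lo)
  expect_lt(spread, width)
})

test_that("the model suite covers its grid, is deterministic, and recovers signs", {
  cfg <- small_synth_config(seed = 15L)
  sy <- synth_claims(cfg)
  rx_f <- filter_opioid_claims(sy$rx)
  included <- sort(unique(rx_f$patient_id))
  pq <- panel_quarters(cfg)
  ct <- centrality_table(rx_f, pq, patients = included,
                         n_quarters = cfg$n_quarters)
  panel <- assemble_panel(sy$patients, sy$rx, sy$dx, ct, pq)

  suite <- run_model_suite(panel, outcomes = c("n_rx", "mme_gt90"),
                           metrics = c("pr_pct", "degree_log"),
                           samples = "main")
  expect_equal(nrow(suite$summary), 4L)
  suite2 <- run_model_suite(panel, outcomes = c("n_rx", "mme_gt90"),
                            metrics = c("pr_pct", "degree_log"),
                            samples = "main")
  expect_equal(suite$summary, suite2$summary)
  # planted positive prominence effects surface where the claims layer
  # transmits them: BP on the dose outcome, WP on both. (The BP count
  # channel is structurally absorbed by the n_prescribers control, since
  # n_rx >= n_prescribers holds by definition in a claims table.)
  expect_gt(suite$summary[metric == "pr_pct" & outcome == "mme_gt90",
                          bp_exp], 1)
  expect_true(all(suite$summary[metric == "pr_pct", wp_exp] > 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_model_report(suite, path)
  expect_true(file.exists(path))
})
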