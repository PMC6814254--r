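#' Default opioid drug dictionary
#'
#' Maps drug codes to CDC-style morphine-milligram-equivalent conversion
#' factors and flags agents used primarily for medication-assisted treatment
#' (MAT). The factors follow the published CDC conversion table; the set is
#' deliberately small and fully configurable.
#'
#' @return A data.table with columns `drug_code`, `mme_factor`, `is_mat`.
#' @export
default_drug_dictionary <- function() {
  data.table(
    drug_code  = c("hydrocodone", "oxycodone", "morphine",
                   "fentanyl_patch", "codeine", "buprenorphine"),
    mme_factor = c(1.0, 1.5, 1.0, 2.4, 0.15, 30),
    is_mat     = c(0L, 0L, 0L, 0L, 0L, 1L)
  )
}

#' Configuration for the synthetic claims generator
#'
#' Bundles every knob of the generator: population sizes, the share of
#' "at-risk" prescribers around whom doctor shopping concentrates, the share
#' of latent doctor-shopper patients, planted between-person (BP) and
#' within-person (WP) prominence effects per 10 percentile points, baseline
#' outcome rates, negative-binomial overdispersion, random-intercept SDs and
#' the root seed.
#'
#' Defaults emulate the structure of a large commercial-claims opioid cohort:
#' quarterly observation over 7 quarters with the last 4 forming the analysis
#' panel, 13% of prescribers in the at-risk stratum, baseline quarterly rates
#' of roughly 8% for maximum daily MME > 90 mg, 1.2% for opioid use disorder
#' and 0.16% for overdose, a mean of about 1.26 opioid fills per
#' patient-quarter, and per-10-percentile prominence odds/rate ratios of
#' published magnitude (BP 1.18/1.88/1.20/2.00 and WP 1.15/1.27/1.10/1.11 for
#' prescription counts, MME>90, overdose and OUD respectively).
#'
#' @param n_patients Number of patients.
#' @param n_prescribers Number of prescribers.
#' @param n_quarters Number of observed quarters (>= 3 so the pooled
#'   three-quarter network window fits).
#' @param n_panel Number of trailing quarters forming the analysis panel.
#' @param frac_at_risk_prescribers Proportion of prescribers flagged at-risk.
#' @param frac_shopper_patients Proportion of patients who are latent doctor
#'   shoppers.
#' @param frac_mat_patients Proportion of patients receiving MAT
#'   (buprenorphine) fills, used to exercise the MAT exclusion filter.
#' @param prominence_effect_bp,prominence_effect_wp Named numeric vectors of
#'   planted log-scale effects per 10 percentile points for outcomes
#'   `n_rx`, `mme_gt90`, `overdose_any`, `oud`.
#' @param baseline_rates Named numeric: mean quarterly fills (`n_rx`) and
#'   probabilities for the three binary outcomes.
#' @param dispersion Negative-binomial size (theta) for the fill-count
#'   outcome; must be > 0.
#' @param sigma_u Named numeric of random-intercept SDs per outcome (>= 0).
#' @param shopper_extra_prescribers Mean number of additional prescribers a
#'   shopper visits per active quarter (Poisson).
#' @param p_active_nonshopper Probability a non-shopper fills any opioid in a
#'   quarter.
#' @param drug_dictionary Drug code to MME-factor table; see
#'   [default_drug_dictionary()].
#' @param seed Integer root seed; all randomness derives from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_patients = 2000L,
                         n_prescribers = 200L,
                         n_quarters = 7L,
                         n_panel = 4L,
                         frac_at_risk_prescribers = 0.13,
                         frac_shopper_patients = 0.10,
                         frac_mat_patients = 0.02,
                         prominence_effect_bp = c(n_rx = log(1.18),
                                                  mme_gt90 = log(1.88),
                                                  overdose_any = log(1.20),
                                                  oud = log(2.00)),
                         prominence_effect_wp = c(n_rx = log(1.15),
                                                  mme_gt90 = log(1.27),
                                                  overdose_any = log(1.10),
                                                  oud = log(1.11)),
                         baseline_rates = c(n_rx = 1.26,
                                            mme_gt90 = 0.08,
                                            overdose_any = 0.0016,
                                            oud = 0.012),
                         dispersion = 1.0,
                         sigma_u = c(n_rx = 1, mme_gt90 = 1,
                                     overdose_any = 1, oud = 1),
                         shopper_extra_prescribers = 3,
                         p_active_nonshopper = 0.45,
                         drug_dictionary = default_drug_dictionary(),
                         seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_prescribers = as.integer(n_prescribers),
    n_quarters = as.integer(n_quarters),
    n_panel = as.integer(n_panel),
    frac_at_risk_prescribers = frac_at_risk_prescribers,
    frac_shopper_patients = frac_shopper_patients,
    frac_mat_patients = frac_mat_patients,
    prominence_effect_bp = prominence_effect_bp,
    prominence_effect_wp = prominence_effect_wp,
    baseline_rates = baseline_rates,
    dispersion = dispersion,
    sigma_u = sigma_u,
    shopper_extra_prescribers = shopper_extra_prescribers,
    p_active_nonshopper = p_active_nonshopper,
    drug_dictionary = as.data.table(drug_dictionary),
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

outcome_names <- function() c("n_rx", "mme_gt90", "overdose_any", "oud")

validate_synth_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid synth_config field '%s': %s", field, msg),
                  call. = FALSE)
  }
  chk(cfg$n_patients >= 2, "n_patients", "need at least 2 patients")
  chk(cfg$n_prescribers >= 1, "n_prescribers", "need at least 1 prescriber")
  chk(cfg$n_quarters >= 3, "n_quarters",
      "must be >= 3 so the pooled window fits")
  chk(cfg$n_panel >= 2 && cfg$n_panel <= cfg$n_quarters, "n_panel",
      "must be in [2, n_quarters]")
  for (f in c("frac_at_risk_prescribers", "frac_shopper_patients",
              "frac_mat_patients", "p_active_nonshopper")) {
    chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
          cfg[[f]] >= 0 && cfg[[f]] <= 1, f, "must be a proportion in [0,1]")
  }
  for (f in c("prominence_effect_bp", "prominence_effect_wp",
              "baseline_rates", "sigma_u")) {
    chk(all(outcome_names() %in% names(cfg[[f]])), f,
        sprintf("must be named with %s",
                paste(outcome_names(), collapse = ", ")))
  }
  chk(all(cfg$sigma_u >= 0), "sigma_u", "must be >= 0")
  chk(cfg$dispersion > 0, "dispersion", "must be > 0")
  chk(all(cfg$baseline_rates[c("mme_gt90", "overdose_any", "oud")] > 0 &
            cfg$baseline_rates[c("mme_gt90", "overdose_any", "oud")] < 1),
      "baseline_rates", "binary-outcome rates must lie in (0,1)")
  chk(cfg$baseline_rates["n_rx"] > 0, "baseline_rates",
      "mean fill count must be > 0")
  chk(all(c("drug_code", "mme_factor", "is_mat") %in%
            names(cfg$drug_dictionary)),
      "drug_dictionary", "needs columns drug_code, mme_factor, is_mat")
  chk(all(cfg$drug_dictionary$mme_factor > 0), "drug_dictionary",
      "mme_factor must be > 0")
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  invisible(cfg)
}

# Run code under a derived seed without disturbing the caller's RNG stream.
# Sub-streams are split by fixed offsets from the root seed (documented in
# the pipeline: population +0, claims +1, outcomes +2, panel sim +3).
with_stream <- function(seed, offset, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  force(code)
}
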