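#' Generate a synthetic patient and prescriber population
#'
#' Samples patient demographics from fixed marginals typical of a
#' commercially insured opioid cohort (59% female; age ~ N(56, 17) truncated
#' to 18–95; insurance HMO/POS/Other at 17/43/40%; seven Appalachian-region
#' states with Georgia and North Carolina dominant), flags a configured
#' fraction of patients as latent doctor shoppers and a configured fraction
#' of prescribers as "at-risk" (the minority of clinicians around whom
#' doctor shopping concentrates).
#'
#' Latent fields (`latent_shopper`, the at-risk flag) are ground truth for
#' tests only; no analysis stage reads them.
#'
#' @param config A [synth_config()].
#' @return List with `patients` and `prescribers` data.tables.
#' @export
generate_population <- function(config) {
  validate_synth_config(config)
  with_stream(config$seed, 0L, {
    n <- config$n_patients
    m <- config$n_prescribers
    states <- c("Georgia", "Kentucky", "North Carolina", "Ohio",
                "Tennessee", "Virginia", "West Virginia")
    state_p <- c(0.3150, 0.0310, 0.2727, 0.1891, 0.1032, 0.0834, 0.0056)

    n_shop <- round(config$frac_shopper_patients * n)
    shoppers <- rep(0L, n)
    shoppers[sample.int(n, n_shop)] <- 1L
    n_mat <- round(config$frac_mat_patients * n)
    mat_pat <- rep(0L, n)
    mat_pat[sample.int(n, n_mat)] <- 1L

    age <- pmin(pmax(rnorm(n, 55.98, 17.17), 18), 95)
    patients <- data.table(
      patient_id = sprintf("P%06d", seq_len(n)),
      female = rbinom(n, 1L, 0.5867),
      age_years = round(age, 1),
      insurance = sample(c("HMO", "POS", "Other"), n, replace = TRUE,
                         prob = c(0.1692, 0.4306, 0.4001)),
      state = sample(states, n, replace = TRUE, prob = state_p),
      cancer_dx = rbinom(n, 1L, 0.138),
      latent_shopper = shoppers,
      mat_user = mat_pat
    )

    n_risk <- round(config$frac_at_risk_prescribers * m)
    at_risk <- rep(0L, m)
    at_risk[sample.int(m, n_risk)] <- 1L
    # Zipf-like popularity among at-risk prescribers concentrates shopper
    # traffic on a few hubs, producing the heavy right tail of patient degree.
    pop <- runif(m, 0.5, 1.5)
    if (n_risk > 0) pop[at_risk == 1L] <- 1 / seq_len(n_risk)^0.8 * 8
    prescribers <- data.table(
      prescriber_id = sprintf("D%05d", seq_len(m)),
      at_risk = at_risk,
      popularity = pop
    )
    list(patients = patients, prescribers = prescribers)
  })
}

#' Generate synthetic prescription and diagnosis claims
#'
#' Non-shopper patients mostly fill from a single "home" prescriber in
#' quarters when they are active; latent shoppers visit their home prescriber
#' plus a Poisson number of additional prescribers sampled preferentially
#' from the popular at-risk stratum, which yields the skewed
#' shared-prescriber degree distribution with hub patients that the analysis
#' assumes. A small fraction of patients receive MAT (buprenorphine) fills,
#' flagged `is_mat`, to exercise the exclusion filter. Baseline diagnosis
#' records carry cancer codes for patients with a cancer history plus
#' neutral filler codes; outcome-bearing codes (overdose, OUD) are planted
#' later by [plant_outcomes()] conditional on realized network prominence.
#'
#' @param patients,prescribers Tables from [generate_population()].
#' @param config The same [synth_config()].
#' @return List with `rx` (prescriptions) and `dx` (diagnoses) data.tables.
#' @export
generate_claims <- function(patients, prescribers, config) {
  validate_synth_config(config)
  with_stream(config$seed, 1L, {
    n <- nrow(patients)
    m <- nrow(prescribers)
    drugs <- config$drug_dictionary[is_mat == 0L]
    drug_p <- c(hydrocodone = 0.40, oxycodone = 0.30, morphine = 0.15,
                fentanyl_patch = 0.05, codeine = 0.10)
    drug_p <- drug_p[match(drugs$drug_code, names(drug_p))]
    drug_p[is.na(drug_p)] <- 0.05
    drug_p <- drug_p / sum(drug_p)

    home <- sample.int(m, n, replace = TRUE)
    risk_w <- prescribers$popularity * ifelse(prescribers$at_risk == 1L, 1, 0.02)

    rx_list <- vector("list", n * config$n_quarters)
    k <- 0L
    for (i in seq_len(n)) {
      shopper <- patients$latent_shopper[i] == 1L
      p_active <- if (shopper) 0.90 else config$p_active_nonshopper
      for (q in seq_len(config$n_quarters) - 1L) {
        if (runif(1) > p_active) next
        pres <- home[i]
        if (shopper) {
          extra <- rpois(1, config$shopper_extra_prescribers)
          if (extra > 0) {
            pres <- unique(c(pres, sample.int(m, extra, replace = TRUE,
                                              prob = risk_w)))
          }
        } else if (runif(1) < 0.10 && m > 1) {
          pres <- unique(c(pres, sample.int(m, 1)))  # occasional referral
        }
        n_fill <- length(pres) + rpois(1, 0.25)
        fill_pres <- pres[c(seq_along(pres),
                            sample.int(length(pres), n_fill - length(pres),
                                       replace = TRUE))]
        k <- k + 1L
        rx_list[[k]] <- data.table(
          patient_id = patients$patient_id[i],
          prescriber_id = prescribers$prescriber_id[fill_pres],
          drug_code = sample(drugs$drug_code, n_fill, replace = TRUE,
                             prob = drug_p),
          quarter = q,
          daily_dose_mg = round(exp(rnorm(n_fill, log(30), 0.5)), 1),
          fill_day = sample(0:89, n_fill, replace = TRUE),
          days_supply = 30L,
          is_mat = 0L
        )
      }
    }
    rx <- rbindlist(rx_list[seq_len(k)])
    rx <- merge(rx, config$drug_dictionary[, .(drug_code, mme_factor)],
                by = "drug_code", sort = FALSE)
    setcolorder(rx, c("patient_id", "prescriber_id", "drug_code", "quarter",
                      "daily_dose_mg", "mme_factor", "fill_day",
                      "days_supply", "is_mat"))

    # MAT fills for the configured fraction of patients
    mat_idx <- which(patients$mat_user == 1L)
    if (length(mat_idx) > 0) {
      mat_rows <- rbindlist(lapply(mat_idx, function(i) {
        qs <- which(runif(config$n_quarters) < 0.5) - 1L
        if (length(qs) == 0) return(NULL)
        data.table(
          patient_id = patients$patient_id[i],
          prescriber_id = prescribers$prescriber_id[sample.int(m, 1)],
          drug_code = "buprenorphine",
          quarter = qs,
          daily_dose_mg = 8,
          mme_factor = config$drug_dictionary[drug_code == "buprenorphine",
                                              mme_factor][1],
          fill_day = sample(0:89, length(qs), replace = TRUE),
          days_supply = 30L,
          is_mat = 1L
        )
      }))
      if (!is.null(mat_rows) && nrow(mat_rows) > 0) rx <- rbind(rx, mat_rows)
    }
    setkey(rx, patient_id, quarter, prescriber_id)

    # baseline diagnoses: cancer history + neutral filler codes
    dx_cancer <- patients[cancer_dx == 1L,
                          .(patient_id,
                            quarter = sample(0:(config$n_quarters - 1L),
                                             .N, replace = TRUE),
                            icd10_code = sample(c("C50911", "C3490", "C189"),
                                                .N, replace = TRUE))]
    n_fill_dx <- round(0.3 * n)
    dx_fill <- data.table(
      patient_id = patients$patient_id[sample.int(n, n_fill_dx, replace = TRUE)],
      quarter = sample(0:(config$n_quarters - 1L), n_fill_dx, replace = TRUE),
      icd10_code = sample(c("Z0000", "J069", "M545"), n_fill_dx,
                          replace = TRUE)
    )
    dx <- rbind(dx_cancer, dx_fill)
    setkey(dx, patient_id, quarter)
    list(rx = rx, dx = dx)
  })
}

#' Plant outcome processes on realized network prominence
#'
#' Given the "truth pass" centrality table (PageRank percentile per patient
#' and panel quarter computed from the generated claims), draws the four
#' outcomes from the generative counterpart of the analysis models: for each
#' outcome the linear predictor is
#' `intercept + beta_bp * (BP - 5) + beta_wp * WP + u_i`, with BP the person
#' mean of the percentile divided by 10 (centered at the population mean of
#' 50/10 = 5 so the configured baseline rate holds at average prominence),
#' WP the per-quarter deviation divided by 10, and `u_i ~ N(0, sigma_u)` a
#' per-outcome patient random intercept. Binary outcomes use a logit link;
#' fill counts a negative binomial with log link and size `dispersion`.
#'
#' Overdose and OUD draws are emitted as ICD-10 diagnosis records; planted
#' fill counts and MME exceedances are realized in the prescription table by
#' [apply_planted_outcomes()].
#'
#' @param patients Patient table (for ids).
#' @param centrality_truth data.table with `patient_id`, `quarter`, `pr_pct`
#'   for the panel quarters.
#' @param config The [synth_config()].
#' @return List: `planted` (per patient-quarter outcome draws and linear
#'   predictors), `dx_extra` (diagnosis records to append), `truth` (planted
#'   coefficients, random intercepts, dispersion).
#' @export
plant_outcomes <- function(patients, centrality_truth, config) {
  validate_synth_config(config)
  if (is.null(centrality_truth) || nrow(centrality_truth) == 0 ||
      !all(c("patient_id", "quarter", "pr_pct") %in% names(centrality_truth)))
    stop("centrality must be computed before planting outcomes ",
         "(need patient_id, quarter, pr_pct)", call. = FALSE)
  with_stream(config$seed, 2L, {
    ct <- as.data.table(centrality_truth)[, .(patient_id, quarter, pr_pct)]
    dec <- decompose_predictor(ct, "pr_pct")
    pl <- cbind(ct, dec)

    ids <- unique(pl$patient_id)
    u <- sapply(outcome_names(), function(o)
      rnorm(length(ids), 0, config$sigma_u[[o]]))
    rownames(u) <- ids
    pl[, `:=`(u_nrx = u[patient_id, "n_rx"],
              u_mme = u[patient_id, "mme_gt90"],
              u_od  = u[patient_id, "overdose_any"],
              u_oud = u[patient_id, "oud"])]

    bb <- config$prominence_effect_bp
    bw <- config$prominence_effect_wp
    r0 <- config$baseline_rates
    pl[, eta_nrx := log(r0[["n_rx"]]) + bb[["n_rx"]] * (bp - 5) +
         bw[["n_rx"]] * wp + u_nrx]
    pl[, eta_mme := qlogis(r0[["mme_gt90"]]) + bb[["mme_gt90"]] * (bp - 5) +
         bw[["mme_gt90"]] * wp + u_mme]
    pl[, eta_od := qlogis(r0[["overdose_any"]]) +
         bb[["overdose_any"]] * (bp - 5) + bw[["overdose_any"]] * wp + u_od]
    pl[, eta_oud := qlogis(r0[["oud"]]) + bb[["oud"]] * (bp - 5) +
         bw[["oud"]] * wp + u_oud]

    pl[, y_nrx := rnbinom(.N, size = config$dispersion, mu = exp(eta_nrx))]
    pl[, y_mme := rbinom(.N, 1L, plogis(eta_mme))]
    pl[, y_od  := rbinom(.N, 1L, plogis(eta_od))]
    pl[, y_oud := rbinom(.N, 1L, plogis(eta_oud))]

    od_rows <- pl[y_od == 1L]
    dx_od <- if (nrow(od_rows) > 0) {
      # ~80% coded as opioid poisoning, rest as unspecified-drug poisoning
      od_rows[, .(patient_id, quarter,
                  icd10_code = ifelse(runif(.N) < 0.8,
                                      sample(c("T402X1A", "T401X1A", "T404X1A"),
                                             .N, replace = TRUE),
                                      "T50901A"))]
    } else data.table(patient_id = character(), quarter = integer(),
                      icd10_code = character())
    oud_rows <- pl[y_oud == 1L]
    dx_oud <- if (nrow(oud_rows) > 0) {
      oud_rows[, .(patient_id, quarter,
                   icd10_code = sample(c("F1120", "F1110", "F1121"),
                                       .N, replace = TRUE))]
    } else data.table(patient_id = character(), quarter = integer(),
                      icd10_code = character())

    list(
      planted = pl,
      dx_extra = rbind(dx_od, dx_oud),
      truth = list(
        beta_bp = bb, beta_wp = bw,
        baseline_rates = r0,
        sigma_u = config$sigma_u,
        dispersion = config$dispersion,
        u = data.table(patient_id = ids, u)
      )
    )
  })
}

#' Realize planted counts and MME exceedances in the prescription table
#'
#' Rewrites panel-quarter fills so that each patient-quarter cell carries
#' one structural fill per unique prescriber contact plus the planted
#' negative-binomial number of additional refills, attributed to
#' prescribers the patient already saw in that quarter. Two coherence
#' constraints keep the claims table and the network consistent: cells
#' with no prescriber contact stay empty (a fill needs a prescriber), and
#' because structural fills are retained and extras reuse existing
#' prescribers, the bipartite edge set — and hence every centrality score
#' — is unchanged. Planted MME>90 cells have one fill's dose raised above
#' the 90 mg morphine-equivalent threshold; planted-zero cells are scaled
#' below it.
#'
#' @param rx,dx Claims tables from [generate_claims()].
#' @param planted Result of [plant_outcomes()].
#' @param config The [synth_config()].
#' @return List with updated `rx`, `dx` and the `realized` planted table
#'   (adds `y_nrx_realized`, `y_mme_realized` columns).
#' @export
apply_planted_outcomes <- function(rx, dx, planted, config) {
  validate_synth_config(config)
  with_stream(config$seed, 3L, {
    pl <- copy(planted$planted)
    rx <- as.data.table(rx)
    panel_q <- sort(unique(pl$quarter))
    rx_panel <- rx[quarter %in% panel_q & is_mat == 0L]
    rx_keep <- rx[!(quarter %in% panel_q & is_mat == 0L)]

    # one representative fill per (patient, prescriber, quarter) pair
    base <- rx_panel[, .SD[1], by = .(patient_id, quarter, prescriber_id)]
    cell <- base[, .(n_pres = .N), by = .(patient_id, quarter)]
    pl <- merge(pl, cell, by = c("patient_id", "quarter"), all.x = TRUE)
    pl[is.na(n_pres), n_pres := 0L]
    # one structural fill per (patient, prescriber) pair keeps the edge set;
    # the planted NB draw adds refills on top, so the prominence signal in
    # the count outcome survives intact. Cells with no prescriber contact
    # cannot carry fills and stay at zero.
    pl[, y_nrx_realized := ifelse(n_pres == 0L, 0L, n_pres + y_nrx)]

    extra_n <- pl[y_nrx_realized > n_pres & n_pres > 0L,
                  .(patient_id, quarter, extra = y_nrx_realized - n_pres)]
    new_rx <- base
    if (nrow(extra_n) > 0) {
      dup <- merge(base, extra_n, by = c("patient_id", "quarter"))
      dup <- dup[, {
        idx <- rep(seq_len(.N), length.out = extra[1])
        .SD[idx]
      }, by = .(patient_id, quarter)]
      dup[, extra := NULL]
      dup[, fill_day := sample(0:89, .N, replace = TRUE)]
      new_rx <- rbind(base, dup)
    }

    # realize planted MME>90: only cells with fills can exceed
    pl[, y_mme_realized := ifelse(n_pres == 0L, 0L, y_mme)]
    mme_cells <- new_rx[, .(cur_max = max_daily_mme_cell(.SD)),
                        by = .(patient_id, quarter)]
    new_rx <- adjust_mme(new_rx, pl, mme_cells)

    rx_out <- rbind(rx_keep, new_rx)
    setkey(rx_out, patient_id, quarter, prescriber_id)
    dx_out <- rbind(as.data.table(dx), planted$dx_extra)
    setkey(dx_out, patient_id, quarter)
    list(rx = rx_out, dx = dx_out, realized = pl)
  })
}

# scale/boost doses so the day-grid max matches the planted MME>90 flag
adjust_mme <- function(new_rx, pl, mme_cells) {
  tgt <- merge(mme_cells,
               pl[, .(patient_id, quarter, y_mme_realized)],
               by = c("patient_id", "quarter"))
  boost <- tgt[y_mme_realized == 1L & cur_max <= 90]
  damp <- tgt[y_mme_realized == 0L & cur_max > 90]
  if (nrow(boost) > 0) {
    new_rx[boost, on = c("patient_id", "quarter"), by = .EACHI,
           daily_dose_mg := {
             d <- daily_dose_mg
             j <- which.max(d * mme_factor)
             d[j] <- round((91 + runif(1, 1, 40)) / mme_factor[j], 1)
             d
           }]
  }
  if (nrow(damp) > 0) {
    damp[, scale := 88 / cur_max]
    new_rx[damp, on = c("patient_id", "quarter"),
           daily_dose_mg := round(daily_dose_mg * i.scale, 2)]
  }
  new_rx
}

#' Run the full two-stage synthetic data generation
#'
#' Stage one generates the population and claims; a first network/centrality
#' pass computes every included patient's realized PageRank percentile for
#' each panel quarter; stage two plants the outcome processes on that
#' realized prominence and rewrites the claims accordingly. The returned
#' truth object is the test-only channel for planted parameters.
#'
#' @param config A [synth_config()].
#' @return List: `patients`, `prescribers`, `rx`, `dx`, `centrality_truth`,
#'   `planted` (realized draws), `truth` (planted parameters), `config`.
#' @export
synth_claims <- function(config = synth_config()) {
  pop <- generate_population(config)
  cl <- generate_claims(pop$patients, pop$prescribers, config)
  panel_q <- panel_quarters(config)
  rx_f <- filter_opioid_claims(cl$rx)
  included <- sort(unique(rx_f$patient_id))
  ct <- rbindlist(lapply(panel_q, function(q) {
    g <- project_patients(build_bipartite(rx_f, q,
                                          patients = included,
                                          n_quarters = config$n_quarters))
    pr <- pagerank(g)
    data.table(patient_id = names(pr), quarter = q,
               pr_pct = to_percentile(pr))
  }))
  po <- plant_outcomes(pop$patients, ct, config)
  ap <- apply_planted_outcomes(cl$rx, cl$dx, po, config)
  list(patients = pop$patients, prescribers = pop$prescribers,
       rx = ap$rx, dx = ap$dx, centrality_truth = ct,
       planted = ap$realized, truth = po$truth, config = config)
}

#' Panel quarters implied by a config (the trailing `n_panel` quarters)
#' @param config A [synth_config()].
#' @return Integer vector of quarter indices.
#' @export
panel_quarters <- function(config) {
  seq(config$n_quarters - config$n_panel, config$n_quarters - 1L)
}

#' Simulate an analysis-ready panel directly (no claims layer)
#'
#' Draws a per-patient latent prominence level plus quarter-level noise,
#' converts to within-quarter percentiles, decomposes into BP/WP, and plants
#' the four outcomes from the same generative model as [plant_outcomes()].
#' This is the clean channel for parameter-recovery tests of the panel
#' models: unlike the full claims pipeline it has no coherence constraints
#' (every cell can realize any outcome draw).
#'
#' @param n_patients Patients in the panel.
#' @param n_quarters Panel quarters per patient.
#' @param beta_bp,beta_wp Named planted log-scale effects per 10 percentile
#'   points (names as [outcome_names()]).
#' @param baseline_rates,sigma_u,dispersion As in [synth_config()].
#' @param seed Integer seed.
#' @return data.table panel with controls, `pr_pct`, `bp`, `wp` and outcome
#'   columns `n_rx`, `mme_gt90`, `overdose_any`, `oud`; planted parameters
#'   attached as attribute `"truth"`.
#' @export
simulate_panel <- function(n_patients = 2000L, n_quarters = 4L,
                           beta_bp = c(n_rx = log(1.18), mme_gt90 = log(1.88),
                                       overdose_any = log(1.20),
                                       oud = log(2.00)),
                           beta_wp = c(n_rx = log(1.15), mme_gt90 = log(1.27),
                                       overdose_any = log(1.10),
                                       oud = log(1.11)),
                           baseline_rates = c(n_rx = 1.26, mme_gt90 = 0.08,
                                              overdose_any = 0.0016,
                                              oud = 0.012),
                           sigma_u = c(n_rx = 1, mme_gt90 = 1,
                                       overdose_any = 1, oud = 1),
                           dispersion = 1.0, seed = 1L) {
  with_stream(seed, 4L, {
    n <- as.integer(n_patients)
    a_i <- rnorm(n)               # stable prominence level
    states <- c("Georgia", "Kentucky", "North Carolina", "Ohio",
                "Tennessee", "Virginia", "West Virginia")
    pan <- CJ(patient_id = sprintf("P%06d", seq_len(n)),
              quarter = seq_len(n_quarters) - 1L)
    pan[, score := a_i[match(patient_id, sprintf("P%06d", seq_len(n)))] +
          rnorm(.N, 0, 0.6)]
    pan[, pr_pct := to_percentile(score), by = quarter]
    pan[, score := NULL]
    dec <- decompose_predictor(pan, "pr_pct")
    pan <- cbind(pan, dec)

    demo <- data.table(
      patient_id = sprintf("P%06d", seq_len(n)),
      female = rbinom(n, 1L, 0.5867),
      age_10yr = round(pmin(pmax(rnorm(n, 55.98, 17.17), 18), 95) / 10, 2),
      insurance = sample(c("HMO", "POS", "Other"), n, replace = TRUE,
                         prob = c(0.1692, 0.4306, 0.4001)),
      state = sample(states, n, replace = TRUE,
                     prob = c(0.3150, 0.0310, 0.2727, 0.1891, 0.1032,
                              0.0834, 0.0056)),
      cancer_dx = rbinom(n, 1L, 0.138)
    )
    pan <- merge(pan, demo, by = "patient_id")
    pan[, n_prescribers := rpois(.N, 0.6)]

    u <- sapply(outcome_names(), function(o) rnorm(n, 0, sigma_u[[o]]))
    rownames(u) <- demo$patient_id
    for (o in outcome_names()) {
      eta <- if (o == "n_rx") log(baseline_rates[[o]]) else
        qlogis(baseline_rates[[o]])
      eta <- eta + beta_bp[[o]] * (pan$bp - 5) + beta_wp[[o]] * pan$wp +
        u[pan$patient_id, o]
      if (o == "n_rx") {
        pan[, (o) := rnbinom(.N, size = dispersion, mu = exp(eta))]
      } else {
        pan[, (o) := rbinom(.N, 1L, plogis(eta))]
      }
    }
    setkey(pan, patient_id, quarter)
    setattr(pan, "truth",
            list(beta_bp = beta_bp, beta_wp = beta_wp,
                 baseline_rates = baseline_rates, sigma_u = sigma_u,
                 dispersion = dispersion))
    pan[]
  })
}

#' Write the synthetic claims tables to a directory
#'
#' Emits `patients.csv`, `prescriptions.csv`, `diagnoses.csv` and
#' `truth.json` (planted parameters; omit with `include_truth = FALSE`).
#'
#' @param synth Result of [synth_claims()].
#' @param dir Output directory (created if needed).
#' @param include_truth Write the planted-parameter JSON?
#' @return `dir`, invisibly.
#' @export
write_synth_tables <- function(synth, dir, include_truth = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fwrite(synth$patients, file.path(dir, "patients.csv"))
  fwrite(synth$rx, file.path(dir, "prescriptions.csv"))
  fwrite(synth$dx, file.path(dir, "diagnoses.csv"))
  if (include_truth) {
    tr <- synth$truth
    tr$u <- NULL  # per-patient intercepts stay in-memory only
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read claims tables written by [write_synth_tables()]
#'
#' Columns are header-keyed, so column order is free; types are coerced to
#' the documented schema.
#'
#' @param dir Directory containing `patients.csv`, `prescriptions.csv`,
#'   `diagnoses.csv`.
#' @return List with `patients`, `rx`, `dx` data.tables.
#' @export
read_claims_tables <- function(dir) {
  patients <- fwrite_read(file.path(dir, "patients.csv"))
  rx <- fwrite_read(file.path(dir, "prescriptions.csv"))
  dx <- fwrite_read(file.path(dir, "diagnoses.csv"))
  rx[, `:=`(quarter = as.integer(quarter), is_mat = as.integer(is_mat),
            daily_dose_mg = as.numeric(daily_dose_mg),
            mme_factor = as.numeric(mme_factor))]
  dx[, quarter := as.integer(quarter)]
  list(patients = patients, rx = rx, dx = dx)
}

fwrite_read <- function(path) {
  if (!file.exists(path)) stop("missing claims table: ", path, call. = FALSE)
  fread(path)
}
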