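#' Default ICD-10 code dictionary for outcome flags
#'
#' Reconstructed code groups for the outcome definitions: accidental opioid
#' poisoning (T40.0x–T40.4x and T40.6x), accidental poisoning by
#' unspecified drugs (T50.9x), opioid abuse/dependence (F11.1x, F11.2x) and
#' any malignancy (C00–C96). Prefixes are matched on normalized codes
#' (uppercased, dots stripped); for the poisoning groups the intent
#' character — position 6 of the normalized code — must be '1'
#' (accidental) when the code is long enough to carry one.
#'
#' @return A `code_dictionary` list of prefix vectors.
#' @export
default_code_dictionary <- function() {
  structure(list(
    overdose_opioid_prefixes = c("T400", "T401", "T402", "T403", "T404",
                                 "T406"),
    overdose_unspecified_prefixes = "T509",
    oud_prefixes = c("F111", "F112"),
    cancer_prefixes = sprintf("C%02d", 0:96),
    intent_char = "1",
    intent_pos = 6L
  ), class = "code_dictionary")
}

normalize_icd10 <- function(codes) toupper(gsub("[.]", "", codes))

match_prefix_set <- function(codes_norm, prefixes, check_intent = FALSE,
                             dict = default_code_dictionary()) {
  hit <- rep(FALSE, length(codes_norm))
  for (p in prefixes) hit <- hit | startsWith(codes_norm, p)
  if (check_intent) {
    long_enough <- nchar(codes_norm) >= dict$intent_pos
    intent_ok <- !long_enough |
      substr(codes_norm, dict$intent_pos, dict$intent_pos) == dict$intent_char
    hit <- hit & intent_ok
  }
  hit
}

#' Flag diagnosis-based outcomes for a patient-quarter
#'
#' `which = "overdose_opioid_only"` matches the opioid-poisoning set;
#' `"overdose_inclusive"` additionally matches unspecified-drug poisoning
#' (the more inclusive measure, motivated by undercounting of opioid
#' overdoses under nonspecific coding); `"oud"` matches abuse/dependence
#' codes; `"cancer"` matches any malignancy.
#'
#' @param dx Diagnosis table (`patient_id`, `quarter`, `icd10_code`).
#' @param patient,quarter Cell to flag; `quarter = NULL` flags the whole
#'   study period (used for the cancer control).
#' @param dict A [default_code_dictionary()].
#' @param which Outcome name.
#' @return 0/1 integer.
#' @export
flag_codes <- function(dx, patient, quarter = NULL,
                       dict = default_code_dictionary(),
                       which = c("overdose_inclusive",
                                 "overdose_opioid_only", "oud", "cancer")) {
  which <- match.arg(which)
  dx <- as.data.table(dx)
  qq <- quarter  # bare names inside DT[...] resolve to columns
  rows <- dx[patient_id == patient]
  rows <- if (is.null(qq)) rows else rows[quarter == qq]
  if (nrow(rows) == 0) return(0L)
  cn <- normalize_icd10(rows$icd10_code)
  hit <- switch(which,
    overdose_opioid_only = match_prefix_set(cn, dict$overdose_opioid_prefixes,
                                            TRUE, dict),
    overdose_inclusive = match_prefix_set(cn, dict$overdose_opioid_prefixes,
                                          TRUE, dict) |
      match_prefix_set(cn, dict$overdose_unspecified_prefixes, TRUE, dict),
    oud = match_prefix_set(cn, dict$oud_prefixes),
    cancer = match_prefix_set(cn, dict$cancer_prefixes)
  )
  as.integer(any(hit))
}

#' Count opioid fills for a patient-quarter
#'
#' Number of unique prescription records (fills, not prescribers) obtained
#' in the quarter across all prescribers; MAT-filtered input.
#'
#' @param rx_filtered MAT-filtered prescription table.
#' @param patient,quarter Cell.
#' @return Integer count (0 when no fills).
#' @export
count_rx <- function(rx_filtered, patient, quarter) {
  rx_filtered <- as.data.table(rx_filtered)
  qq <- quarter
  nrow(rx_filtered[patient_id == patient & quarter == qq])
}

#' Count unique prescribers for a patient-quarter
#'
#' Distinct prescriber ids within the single quarter (not the pooled
#' network window).
#'
#' @inheritParams count_rx
#' @return Integer count.
#' @export
count_prescribers <- function(rx_filtered, patient, quarter) {
  rx_filtered <- as.data.table(rx_filtered)
  qq <- quarter
  length(unique(rx_filtered[patient_id == patient &
                              quarter == qq]$prescriber_id))
}

# day-grid max daily MME for one cell's records (internal workhorse)
max_daily_mme_cell <- function(sd, quarter_days = 90L) {
  if (nrow(sd) == 0) return(0)
  if (any(sd$daily_dose_mg <= 0))
    stop("nonpositive daily dose in prescription records", call. = FALSE)
  fd <- if ("fill_day" %in% names(sd)) sd$fill_day else rep(0L, nrow(sd))
  ds <- if ("days_supply" %in% names(sd)) sd$days_supply
  else rep(quarter_days, nrow(sd))
  daily <- numeric(quarter_days)
  mme <- sd$daily_dose_mg * sd$mme_factor
  for (r in seq_len(nrow(sd))) {
    lo <- max(fd[r], 0L) + 1L
    hi <- min(fd[r] + ds[r] - 1L, quarter_days - 1L) + 1L
    if (hi >= lo) daily[lo:hi] <- daily[lo:hi] + mme[r]
  }
  max(daily)
}

#' Maximum daily morphine-milligram-equivalent dose in a quarter
#'
#' Each fill contributes `daily_dose_mg * mme_factor` (the CDC conversion)
#' on every day it is active (from `fill_day` for `days_supply` days,
#' clipped to the 90-day quarter); concurrent fills are summed per day and
#' the quarter maximum is returned. The high-overdose-potential flag is
#' strict: `mme_gt90 = 1` iff the maximum exceeds 90 mg (90.0 itself does
#' not trip it). Fills lacking `fill_day`/`days_supply` are treated as
#' active all quarter.
#'
#' @param rx Prescription table (MAT-filtered for the analysis pipeline).
#' @param patient,quarter Cell.
#' @param quarter_days Days per quarter (default 90).
#' @return List with `max_daily_mme` and `mme_gt90`.
#' @export
max_daily_mme <- function(rx, patient, quarter, quarter_days = 90L) {
  rx <- as.data.table(rx)
  qq <- quarter
  sd <- rx[patient_id == patient & quarter == qq]
  m <- max_daily_mme_cell(sd, quarter_days)
  list(max_daily_mme = m, mme_gt90 = as.integer(m > 90))
}

#' Assemble the patient-quarter analysis panel
#'
#' One row per included patient per panel quarter. Inclusion follows the
#' study rule: a patient enters iff they have at least one non-MAT opioid
#' fill anywhere in the observation window, and then contributes a row for
#' every panel quarter (zero-fill quarters included). Outcome columns are
#' derived from the claims (`n_rx`, `n_prescribers`, `max_daily_mme`,
#' `mme_gt90`) and diagnoses (`overdose_any` — the inclusive measure,
#' `overdose_opioid_only`, `oud`); the cancer control is a study-period
#' flag, constant within patient. Centrality columns are joined per
#' patient-quarter.
#'
#' @param patients Patient table (demographics, state).
#' @param rx Prescription table (MAT records tolerated; filtered here).
#' @param dx Diagnosis table.
#' @param centrality A [centrality_table()] covering every panel quarter.
#' @param panel_quarters Integer vector of panel quarters.
#' @param dict A [default_code_dictionary()].
#' @return data.table panel, keyed by patient and quarter.
#' @export
assemble_panel <- function(patients, rx, dx, centrality, panel_quarters,
                           dict = default_code_dictionary()) {
  patients <- as.data.table(patients)
  rx_f <- filter_opioid_claims(rx)
  dx <- as.data.table(dx)
  centrality <- as.data.table(centrality)
  missing_q <- setdiff(panel_quarters, unique(centrality$quarter))
  if (length(missing_q) > 0)
    stop("centrality table missing panel quarter(s): ",
         paste(missing_q, collapse = ", "), call. = FALSE)

  included <- sort(unique(rx_f$patient_id))
  panel <- CJ(patient_id = included, quarter = as.integer(panel_quarters))

  cell_rx <- rx_f[quarter %in% panel_quarters,
                  .(n_rx = .N,
                    n_prescribers = uniqueN(prescriber_id),
                    max_daily_mme = max_daily_mme_cell(.SD)),
                  by = .(patient_id, quarter)]
  panel <- merge(panel, cell_rx, by = c("patient_id", "quarter"),
                 all.x = TRUE)
  for (cc in c("n_rx", "n_prescribers")) {
    panel[is.na(get(cc)), (cc) := 0L]
  }
  panel[is.na(max_daily_mme), max_daily_mme := 0]
  panel[, mme_gt90 := as.integer(max_daily_mme > 90)]

  dxn <- dx[patient_id %in% included]
  dxn[, code_norm := normalize_icd10(icd10_code)]
  dxn[, `:=`(
    od_op = match_prefix_set(code_norm, dict$overdose_opioid_prefixes,
                             TRUE, dict),
    od_un = match_prefix_set(code_norm, dict$overdose_unspecified_prefixes,
                             TRUE, dict),
    oud_hit = match_prefix_set(code_norm, dict$oud_prefixes),
    ca_hit = match_prefix_set(code_norm, dict$cancer_prefixes)
  )]
  flags <- dxn[quarter %in% panel_quarters,
               .(overdose_opioid_only = as.integer(any(od_op)),
                 overdose_any = as.integer(any(od_op | od_un)),
                 oud = as.integer(any(oud_hit))),
               by = .(patient_id, quarter)]
  panel <- merge(panel, flags, by = c("patient_id", "quarter"), all.x = TRUE)
  for (cc in c("overdose_opioid_only", "overdose_any", "oud")) {
    panel[is.na(get(cc)), (cc) := 0L]
  }
  cancer <- dxn[, .(cancer_dx = as.integer(any(ca_hit))), by = patient_id]
  panel <- merge(panel, cancer, by = "patient_id", all.x = TRUE)
  panel[is.na(cancer_dx), cancer_dx := 0L]

  demo <- patients[, .(patient_id, female,
                       age_10yr = round(age_years / 10, 3),
                       insurance, state)]
  panel <- merge(panel, demo, by = "patient_id")

  ct_cols <- intersect(c("pr_raw", "pr_pct", "pr_std", "degree",
                         "degree_log", "bip_pr_raw", "bip_pr_pct"),
                       names(centrality))
  panel <- merge(panel,
                 centrality[, c("patient_id", "quarter", ct_cols),
                            with = FALSE],
                 by = c("patient_id", "quarter"), all.x = TRUE)
  if (anyNA(panel$pr_pct))
    stop("centrality scores missing for some panel patients; compute ",
         "centrality over the full panel patient set first", call. = FALSE)
  setkey(panel, patient_id, quarter)
  panel[]
}

#' Restrict the panel to moderate/high-risk patients
#'
#' Drops patients who never had more than one unique opioid prescriber in
#' any quarter; retained patients keep all their panel quarters. This is
#' the sensitivity sample that removes patients who are clearly not doctor
#' shoppers.
#'
#' @param panel An [assemble_panel()] result.
#' @return The filtered panel.
#' @export
restrict_high_risk <- function(panel) {
  panel <- as.data.table(panel)
  keep <- panel[, .(mx = max(n_prescribers)), by = patient_id][mx >= 2,
                                                               patient_id]
  panel[patient_id %in% keep]
}

#' Write / read the analysis panel as delimited text
#' @param panel An [assemble_panel()] result.
#' @param path Output file.
#' @return `path` invisibly; the reader returns the panel.
#' @export
write_panel <- function(panel, path) {
  fwrite(panel, path)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  p <- fread(path)
  intcols <- intersect(c("quarter", "n_rx", "n_prescribers", "mme_gt90",
                         "overdose_any", "overdose_opioid_only", "oud",
                         "female", "cancer_dx", "degree"), names(p))
  p[, (intcols) := lapply(.SD, as.integer), .SDcols = intcols]
  setkey(p, patient_id, quarter)
  p[]
}
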