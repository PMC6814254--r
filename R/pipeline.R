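#' Configuration for an end-to-end pipeline run
#'
#' @param synth A [synth_config()]; its seed is the root seed for the whole
#'   run.
#' @param window_width Pooled network window width in quarters.
#' @param centrality A [centrality_params()].
#' @param metrics Prominence metrics fitted in the model stage.
#' @param samples Model samples (`"main"`, `"highrisk"`).
#' @param outcomes Outcomes fitted in the model stage.
#' @param code_dictionary A [default_code_dictionary()].
#' @return A `run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       window_width = 3L,
                       centrality = centrality_params(),
                       metrics = "pr_pct",
                       samples = c("main", "highrisk"),
                       outcomes = outcome_names(),
                       code_dictionary = default_code_dictionary()) {
  structure(list(synth = synth, window_width = as.integer(window_width),
                 centrality = centrality, metrics = metrics,
                 samples = samples, outcomes = outcomes,
                 code_dictionary = code_dictionary),
            class = "run_config")
}

#' Run the full pipeline
#'
#' synth claims -> co-prescription networks -> centrality -> outcome panel
#' -> panel models -> report, with every intermediate artifact persisted as
#' delimited text under `out_dir` plus a manifest recording the seed,
#' package version and an MD5 checksum per artifact. Reruns with an
#' identical config reproduce identical artifact checksums.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created).
#' @return Invisibly, a list with the in-memory artifacts (`synth`,
#'   `centrality`, `panel`, `suite`, `manifest`) and `out_dir`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("cpnrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "synth"
  result <- tryCatch({
    sy <- synth_claims(config$synth)
    write_synth_tables(sy, out_dir)

    stage <- "network"
    rx_f <- filter_opioid_claims(sy$rx)
    included <- sort(unique(rx_f$patient_id))
    pq <- panel_quarters(config$synth)
    for (q in pq) {
      g <- project_patients(build_bipartite(
        rx_f, q, patients = included, n_quarters = config$synth$n_quarters,
        width = config$window_width))
      write_edgelist(g, file.path(out_dir, sprintf("edges_q%d.csv", q)))
    }

    stage <- "centrality"
    ct <- centrality_table(rx_f, pq, patients = included,
                           n_quarters = config$synth$n_quarters,
                           params = config$centrality,
                           width = config$window_width)
    write_centrality(ct, file.path(out_dir, "centrality.csv"))

    stage <- "outcomes"
    panel <- assemble_panel(sy$patients, sy$rx, sy$dx, ct, pq,
                            dict = config$code_dictionary)
    write_panel(panel, file.path(out_dir, "panel.csv"))

    stage <- "models"
    suite <- run_model_suite(panel, outcomes = config$outcomes,
                             metrics = config$metrics,
                             samples = config$samples)
    write_model_report(suite, file.path(out_dir, "model_report.csv"))

    stage <- "manifest"
    cfg_echo <- config
    cfg_echo$synth$drug_dictionary <-
      as.data.frame(cfg_echo$synth$drug_dictionary)
    jsonlite::write_json(
      list(synth = cfg_echo$synth[setdiff(names(cfg_echo$synth),
                                          "drug_dictionary")],
           drug_dictionary = cfg_echo$synth$drug_dictionary,
           window_width = config$window_width,
           metrics = config$metrics, samples = config$samples),
      file.path(out_dir, "config_echo.json"), auto_unbox = TRUE,
      digits = NA)
    manifest <- build_manifest(out_dir, config$synth$seed)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(synth = sy, centrality = ct, panel = panel, suite = suite,
         manifest = manifest, out_dir = out_dir)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}

build_manifest <- function(out_dir, seed) {
  files <- setdiff(list.files(out_dir), "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  list(seed = seed,
       package_version = as.character(utils::packageVersion("coprescribenet")),
       files = as.list(setNames(as.character(sums), files)))
}

#' Verify a run directory against its manifest
#'
#' Recomputes every artifact checksum and reports mismatches (e.g., a
#' tampered or truncated intermediate file).
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @return Character vector of mismatching file names (empty when clean).
#' @export
verify_manifest <- function(out_dir) {
  manifest <- jsonlite::read_json(file.path(out_dir, "manifest.json"))
  bad <- character()
  for (f in names(manifest$files)) {
    path <- file.path(out_dir, f)
    cur <- if (file.exists(path)) as.character(tools::md5sum(path)) else NA
    if (is.na(cur) || !identical(cur, manifest$files[[f]]))
      bad <- c(bad, f)
  }
  bad
}

#' Validate external claims tables
#'
#' Schema, type, range and referential-integrity checks for externally
#' supplied claims tables (header-keyed, so column order is free). Returns
#' a violation table with row indices; an empty table means the inputs are
#' acceptable.
#'
#' @param patients,rx,dx Claims tables (data.frames).
#' @param max_violations Row examples retained per check.
#' @return data.table with `table`, `check`, `row`, `detail`.
#' @export
validate_inputs <- function(patients, rx, dx, max_violations = 20L) {
  v <- list()
  add <- function(tbl, check, rows, detail) {
    rows <- head(rows, max_violations)
    if (length(rows) > 0)
      v[[length(v) + 1]] <<- data.table(table = tbl, check = check,
                                        row = as.integer(rows),
                                        detail = detail)
  }
  patients <- as.data.table(patients)
  rx <- as.data.table(rx)
  dx <- as.data.table(dx)

  need_p <- c("patient_id", "female", "age_years", "insurance", "state")
  need_rx <- c("patient_id", "prescriber_id", "drug_code", "quarter",
               "daily_dose_mg", "mme_factor", "is_mat")
  need_dx <- c("patient_id", "quarter", "icd10_code")
  for (spec in list(list("patients", patients, need_p),
                    list("prescriptions", rx, need_rx),
                    list("diagnoses", dx, need_dx))) {
    miss <- setdiff(spec[[3]], names(spec[[2]]))
    if (length(miss) > 0)
      add(spec[[1]], "missing_columns", 0L, paste(miss, collapse = ","))
  }
  if (length(v) > 0) return(rbindlist(v))  # structural failure: stop here

  add("patients", "duplicate_patient_id",
      which(duplicated(patients$patient_id)), "duplicated id")
  add("rx", "nonpositive_dose", which(!(rx$daily_dose_mg > 0)),
      "daily_dose_mg must be > 0")
  add("rx", "nonpositive_mme_factor", which(!(rx$mme_factor > 0)),
      "mme_factor must be > 0")
  add("rx", "bad_mat_flag", which(!rx$is_mat %in% c(0L, 1L)),
      "is_mat must be 0/1")
  add("rx", "negative_quarter", which(rx$quarter < 0),
      "quarter index must be >= 0")
  add("rx", "unknown_patient",
      which(!rx$patient_id %in% patients$patient_id),
      "patient_id not in patient table")
  add("dx", "unknown_patient",
      which(!dx$patient_id %in% patients$patient_id),
      "patient_id not in patient table")
  add("dx", "negative_quarter", which(dx$quarter < 0),
      "quarter index must be >= 0")
  if (length(v) == 0)
    data.table(table = character(), check = character(), row = integer(),
               detail = character())
  else rbindlist(v)
}
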