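#' Drop MAT prescriptions from a claims table
#'
#' Agents used exclusively or primarily for medication-assisted treatment
#' (e.g., buprenorphine) are excluded before any network construction, so
#' centrality cannot be an artifact of clustering around sparse MAT-licensed
#' providers. Row order is preserved.
#'
#' @param rx Prescription table with an `is_mat` column (0/1).
#' @return The rows with `is_mat == 0`.
#' @export
filter_opioid_claims <- function(rx) {
  rx <- as.data.table(rx)
  if (!"is_mat" %in% names(rx))
    stop("prescription table lacks the is_mat flag", call. = FALSE)
  rx[is_mat == 0L]
}

#' Pooled three-quarter network window
#'
#' Ties are pooled across quarters T-2, T-1 and T to absorb lags in
#' information diffusion and the arbitrary cut points of quarterly
#' observation. Quarters before the start of the panel are truncated by
#' default (`policy = "truncate"`); `policy = "drop"` instead refuses focal
#' quarters whose full window does not fit.
#'
#' @param focal_quarter Integer quarter index T.
#' @param width Window width (default 3: T-2, T-1, T).
#' @param available Integer vector of observable quarter indices.
#' @param policy `"truncate"` or `"drop"`.
#' @return Sorted integer vector of quarters in the window.
#' @export
pooled_window <- function(focal_quarter, width = 3L,
                          available = NULL,
                          policy = c("truncate", "drop")) {
  policy <- match.arg(policy)
  focal_quarter <- as.integer(focal_quarter)
  if (!is.null(available) && !(focal_quarter %in% available))
    stop(sprintf("focal quarter %d outside the available range [%d, %d]",
                 focal_quarter, min(available), max(available)),
         call. = FALSE)
  win <- seq(focal_quarter - width + 1L, focal_quarter)
  if (!is.null(available)) {
    kept <- intersect(win, available)
    if (policy == "drop" && length(kept) < width)
      stop(sprintf("full %d-quarter window does not fit at focal quarter %d",
                   width, focal_quarter), call. = FALSE)
    win <- kept
  } else {
    win <- win[win >= 0L]
  }
  sort(win)
}

#' Build the patient–prescriber bipartite graph for a focal quarter
#'
#' An edge (patient, prescriber) is present iff the patient received at
#' least one non-MAT opioid fill from that prescriber within the pooled
#' window; fill multiplicity is not retained (presence semantics). All panel
#' patients appear as nodes even when isolated, so downstream PageRank uses
#' the full panel N.
#'
#' @param rx_filtered MAT-filtered prescription table.
#' @param focal_quarter Integer quarter T.
#' @param patients Optional character vector of panel patient ids (defaults
#'   to the patients present in `rx_filtered`).
#' @param n_quarters Optional number of observed quarters (defines the
#'   available range 0..n_quarters-1; defaults to the range seen in the data).
#' @param width,policy Passed to [pooled_window()].
#' @return Object of class `bipartite_graph`: `edges` (patient_id,
#'   prescriber_id), `patients`, `prescribers`, `focal_quarter`, `window`.
#' @export
build_bipartite <- function(rx_filtered, focal_quarter, patients = NULL,
                            n_quarters = NULL, width = 3L,
                            policy = c("truncate", "drop")) {
  rx_filtered <- as.data.table(rx_filtered)
  if (any(rx_filtered$is_mat != 0L))
    stop("records must be MAT-filtered before graph construction",
         call. = FALSE)
  available <- if (!is.null(n_quarters)) 0:(as.integer(n_quarters) - 1L)
  else if (nrow(rx_filtered) > 0) sort(unique(rx_filtered$quarter))
  else 0L
  win <- pooled_window(focal_quarter, width, available, match.arg(policy))
  edges <- unique(rx_filtered[quarter %in% win,
                              .(patient_id, prescriber_id)])
  if (is.null(patients)) patients <- sort(unique(rx_filtered$patient_id))
  structure(
    list(edges = edges,
         patients = as.character(patients),
         prescribers = sort(unique(edges$prescriber_id)),
         focal_quarter = as.integer(focal_quarter),
         window = win),
    class = "bipartite_graph"
  )
}

#' Project the bipartite graph onto patients
#'
#' Produces the undirected patient–patient co-prescription graph: for every
#' patient pair the edge weight is the number of unique prescribers they
#' share within the window (e.g., two patients prescribed opioids by the
#' same three providers get a tie of weight 3). Enumeration is sparse — per
#' prescriber, all patient pairs in that prescriber's neighborhood are
#' counted — and the result is independent of enumeration order. Isolates
#' are retained as zero-strength nodes.
#'
#' @param bip A `bipartite_graph`.
#' @return Object of class `coprescription_graph`: `edges` (patient_a <
#'   patient_b, weight), `patients`, named `strength` vector, plus the
#'   window metadata.
#' @export
project_patients <- function(bip) {
  stopifnot(inherits(bip, "bipartite_graph"))
  e <- bip$edges
  if (nrow(e) > 0) {
    pairs <- e[e, on = "prescriber_id", allow.cartesian = TRUE,
               .(a = x.patient_id, b = i.patient_id)][a < b]
    w <- pairs[, .(weight = .N), by = .(patient_a = a, patient_b = b)]
  } else {
    w <- data.table(patient_a = character(), patient_b = character(),
                    weight = integer())
  }
  strength <- setNames(numeric(length(bip$patients)), bip$patients)
  if (nrow(w) > 0) {
    s <- rbind(w[, .(patient_id = patient_a, weight)],
               w[, .(patient_id = patient_b, weight)])[
                 , .(s = sum(weight)), by = patient_id]
    strength[s$patient_id] <- s$s
  }
  structure(
    list(edges = w, patients = bip$patients, strength = strength,
         focal_quarter = bip$focal_quarter, window = bip$window),
    class = "coprescription_graph"
  )
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(
    "bipartite co-prescription graph: %d patients, %d prescribers, %d edges\n",
    length(x$patients), length(x$prescribers), nrow(x$edges)))
  cat(sprintf("focal quarter %d, pooled window {%s}\n",
              x$focal_quarter, paste(x$window, collapse = ", ")))
  invisible(x)
}

#' @export
print.coprescription_graph <- function(x, ...) {
  n_iso <- sum(x$strength == 0)
  cat(sprintf(
    "co-prescription graph: %d patients (%d isolates), %d weighted ties\n",
    length(x$patients), n_iso, nrow(x$edges)))
  cat(sprintf("focal quarter %d, pooled window {%s}\n",
              x$focal_quarter, paste(x$window, collapse = ", ")))
  invisible(x)
}

#' Write / read a weighted patient edge list
#'
#' Delimited text round-trip for a `coprescription_graph` (patient_a,
#' patient_b, weight, focal_quarter). Isolates are preserved through a
#' header comment carrying the full node set.
#'
#' @param graph A `coprescription_graph`.
#' @param path Output file.
#' @return `path` invisibly; `read_edgelist()` returns the graph.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "coprescription_graph"))
  hdr <- sprintf("# patients=%s | window=%s",
                 paste(graph$patients, collapse = ","),
                 paste(graph$window, collapse = ","))
  writeLines(hdr, path)
  out <- copy(graph$edges)[, focal_quarter := graph$focal_quarter]
  fwrite(out, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- sub("^# ", "", hdr)
  parts <- strsplit(meta, " \\| ")[[1]]
  patients <- strsplit(sub("^patients=", "", parts[1]), ",")[[1]]
  win <- as.integer(strsplit(sub("^window=", "", parts[2]), ",")[[1]])
  e <- fread(path, skip = 1L)
  focal <- if (nrow(e) > 0) e$focal_quarter[1] else max(win)
  bip_like <- structure(list(
    edges = if (nrow(e) > 0)
      e[, .(patient_a, patient_b, weight = as.integer(weight))]
    else data.table(patient_a = character(), patient_b = character(),
                    weight = integer()),
    patients = patients, focal_quarter = focal, window = win),
    class = "coprescription_graph")
  strength <- setNames(numeric(length(patients)), patients)
  if (nrow(bip_like$edges) > 0) {
    s <- rbind(bip_like$edges[, .(patient_id = patient_a, weight)],
               bip_like$edges[, .(patient_id = patient_b, weight)])[
                 , .(s = sum(weight)), by = patient_id]
    strength[s$patient_id] <- s$s
  }
  bip_like$strength <- strength
  bip_like
}
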