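#' Centrality computation parameters
#'
#' @param d Damping factor for PageRank, in (0,1); default 0.85.
#' @param tol Convergence tolerance on the L1 change per iteration.
#' @param max_iter Iteration cap.
#' @param dangling `"uniform"` redistributes the walk mass of zero-strength
#'   nodes uniformly, keeping the scores a probability distribution
#'   (sum = 1). `"literal"` applies the damped recursion verbatim, in which
#'   case isolates receive exactly (1-d)/N and the total mass is below 1 on
#'   graphs with isolates.
#' @param cohits_lambda_patient,cohits_lambda_prescriber Per-side damping for
#'   the bipartite Co-HITS iteration.
#' @return A `centrality_params` list.
#' @export
centrality_params <- function(d = 0.85, tol = 1e-10, max_iter = 1000L,
                              dangling = c("uniform", "literal"),
                              cohits_lambda_patient = 0.85,
                              cohits_lambda_prescriber = 0.85) {
  stopifnot(d > 0, d < 1, tol > 0, max_iter >= 1)
  structure(list(d = d, tol = tol, max_iter = as.integer(max_iter),
                 dangling = match.arg(dangling),
                 cohits_lambda_patient = cohits_lambda_patient,
                 cohits_lambda_prescriber = cohits_lambda_prescriber),
            class = "centrality_params")
}

#' Weighted PageRank on the co-prescription graph
#'
#' Fixed point of `PR(i) = (1-d)/N + d * sum_j w_ij PR(j) / s_j` over the
#' patient graph, with every undirected edge treated as two directed edges
#' and `s_j` the strength (sum of incident weights) of node j. Computed by
#' sparse power iteration from a uniform start, stopping when the L1 change
#' drops below `tol`. Under the default dangling policy the mass that
#' isolates cannot forward is redistributed uniformly, so the result is a
#' stationary probability distribution over all nodes (sum exactly 1 up to
#' numerical tolerance).
#'
#' @param graph A `coprescription_graph`.
#' @param params A [centrality_params()].
#' @return Named numeric vector of PageRank mass per patient.
#' @export
pagerank <- function(graph, params = centrality_params()) {
  stopifnot(inherits(graph, "coprescription_graph"))
  nodes <- graph$patients
  n <- length(nodes)
  if (n == 0) stop("graph has no nodes", call. = FALSE)
  if (n == 1) return(setNames(1, nodes))
  d <- params$d
  e <- graph$edges
  idx <- setNames(seq_len(n), nodes)
  s <- graph$strength[nodes]
  if (nrow(e) > 0) {
    ii <- c(idx[e$patient_b], idx[e$patient_a])  # transition j -> i
    jj <- c(idx[e$patient_a], idx[e$patient_b])
    ww <- c(e$weight, e$weight) / s[jj]
    P <- sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  } else {
    P <- sparseMatrix(i = integer(), j = integer(), x = numeric(),
                      dims = c(n, n))
  }
  dangling <- s == 0
  pr <- rep(1 / n, n)
  for (it in seq_len(params$max_iter)) {
    if (params$dangling == "uniform") {
      new <- (1 - d) / n + d * (as.numeric(P %*% pr) + sum(pr[dangling]) / n)
    } else {
      new <- (1 - d) / n + d * as.numeric(P %*% pr)
    }
    delta <- sum(abs(new - pr))
    pr <- new
    if (delta < params$tol) return(setNames(pr, nodes))
  }
  stop(sprintf(
    "PageRank did not converge in %d iterations (final L1 residual %.3e)",
    params$max_iter, delta), call. = FALSE)
}

#' Average-rank percentile transform
#'
#' Converts raw scores to a 0–100 percentile scale using midranks:
#' `pct_i = 100 * (rank_i - 0.5) / N`, with ties sharing their mean rank
#' (`ties = "average"`, default) or taking the minimum rank
#' (`ties = "min"`). With average ranks the percentile mean is exactly 50.
#' Used to tame the pronounced positive skew of raw PageRank.
#'
#' @param scores Numeric vector (names preserved).
#' @param ties `"average"` or `"min"`.
#' @return Numeric vector of percentiles in [0, 100].
#' @export
to_percentile <- function(scores, ties = c("average", "min")) {
  ties <- match.arg(ties)
  if (length(scores) == 0) stop("need at least one score", call. = FALSE)
  r <- rank(scores, ties.method = ties)
  setNames(100 * (r - 0.5) / length(scores), names(scores))
}

#' Z-score standardization
#'
#' `(x - mean) / sd` with the sample (n-1) standard deviation. Errors on
#' degenerate input (fewer than 2 values or zero variance).
#'
#' @param scores Numeric vector.
#' @return Standardized vector (mean 0, sample SD 1).
#' @export
standardize <- function(scores) {
  if (length(scores) < 2)
    stop("standardization needs at least 2 scores", call. = FALSE)
  s <- sd(scores)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize scores with zero variance", call. = FALSE)
  (scores - mean(scores)) / s
}

#' Degree metrics on the co-prescription graph
#'
#' Degree is the number of distinct patients with whom a patient shares at
#' least one prescriber (unweighted neighbor count); `degree_log` is
#' `log(degree + 1)` — the +1 offset keeps isolates (degree 0, common in
#' this sparse network) defined on the log scale.
#'
#' @param graph A `coprescription_graph`.
#' @param offset Offset inside the log (default 1).
#' @return data.table with `patient_id`, `degree`, `degree_log`.
#' @export
degree_metrics <- function(graph, offset = 1) {
  stopifnot(inherits(graph, "coprescription_graph"))
  deg <- setNames(integer(length(graph$patients)), graph$patients)
  if (nrow(graph$edges) > 0) {
    tab <- table(c(graph$edges$patient_a, graph$edges$patient_b))
    deg[names(tab)] <- as.integer(tab)
  }
  data.table(patient_id = names(deg), degree = as.integer(deg),
             degree_log = log(as.numeric(deg) + offset))
}

#' Generalized Co-HITS scores on the bipartite graph
#'
#' Coupled damped iteration propagating prominence between the two node
#' classes with all edge weights constrained to 1:
#' `x_p = (1-l_p)/N_p + l_p * sum_{d in N(p)} y_d / deg(d)` and
#' `y_d = (1-l_d)/N_d + l_d * sum_{p in N(d)} x_p / deg(p)`. A patient's
#' score thus reflects both their own position and the prominence of the
#' prescribers they reach directly and indirectly. Iterates from uniform
#' starts until the joint L1 change falls below `tol`.
#'
#' @param bip A `bipartite_graph`.
#' @param params A [centrality_params()] (lambdas and tolerance are used).
#' @return List with named vectors `patient_scores` and `prescriber_scores`.
#' @export
cohits <- function(bip, params = centrality_params()) {
  stopifnot(inherits(bip, "bipartite_graph"))
  pats <- bip$patients
  docs <- bip$prescribers
  np <- length(pats); nd <- length(docs)
  if (np == 0) stop("bipartite graph has no patients", call. = FALSE)
  lp <- params$cohits_lambda_patient
  ld <- params$cohits_lambda_prescriber
  x <- setNames(rep(1 / np, np), pats)
  if (nd == 0) {
    return(list(patient_scores = setNames(rep((1 - lp) / np, np), pats),
                prescriber_scores = setNames(numeric(0), character(0))))
  }
  y <- setNames(rep(1 / nd, nd), docs)
  e <- bip$edges
  pi <- setNames(seq_len(np), pats)
  di <- setNames(seq_len(nd), docs)
  A <- sparseMatrix(i = pi[e$patient_id], j = di[e$prescriber_id], x = 1,
                    dims = c(np, nd))
  deg_p <- as.numeric(rowSums(A))
  deg_d <- as.numeric(colSums(A))
  Axd <- A %*% Matrix::Diagonal(nd, ifelse(deg_d > 0, 1 / deg_d, 0))
  Atp <- Matrix::t(A) %*% Matrix::Diagonal(np, ifelse(deg_p > 0, 1 / deg_p, 0))
  for (it in seq_len(params$max_iter)) {
    x_new <- (1 - lp) / np + lp * as.numeric(Axd %*% y)
    y_new <- (1 - ld) / nd + ld * as.numeric(Atp %*% x_new)
    delta <- sum(abs(x_new - x)) + sum(abs(y_new - y))
    x <- x_new; y <- y_new
    if (delta < params$tol)
      return(list(patient_scores = setNames(x, pats),
                  prescriber_scores = setNames(y, docs)))
  }
  stop(sprintf(
    "Co-HITS did not converge in %d iterations (final L1 residual %.3e)",
    params$max_iter, delta), call. = FALSE)
}

#' Per-quarter centrality table
#'
#' Builds the pooled-window bipartite and projected graphs for each
#' requested focal quarter and assembles raw PageRank, its percentile and
#' z-score, degree and logged degree, and bipartite Co-HITS percentile.
#'
#' @param rx_filtered MAT-filtered prescription table.
#' @param quarters Focal quarters to compute.
#' @param patients Panel patient ids (isolates included).
#' @param n_quarters Number of observed quarters.
#' @param params A [centrality_params()].
#' @param width Pooling window width.
#' @return data.table: one row per patient per quarter with columns
#'   `pr_raw`, `pr_pct`, `pr_std`, `degree`, `degree_log`, `bip_pr_raw`,
#'   `bip_pr_pct`.
#' @export
centrality_table <- function(rx_filtered, quarters, patients = NULL,
                             n_quarters = NULL,
                             params = centrality_params(), width = 3L) {
  rbindlist(lapply(quarters, function(q) {
    bip <- build_bipartite(rx_filtered, q, patients = patients,
                           n_quarters = n_quarters, width = width)
    g <- project_patients(bip)
    pr <- pagerank(g, params)
    deg <- degree_metrics(g)
    ch <- cohits(bip, params)
    bip_raw <- setNames(numeric(length(g$patients)), g$patients)
    bip_raw[names(ch$patient_scores)] <- ch$patient_scores
    out <- data.table(
      patient_id = names(pr), quarter = as.integer(q),
      pr_raw = as.numeric(pr),
      pr_pct = as.numeric(to_percentile(pr)),
      pr_std = if (length(unique(pr)) > 1) as.numeric(standardize(pr))
      else rep(0, length(pr)),
      bip_pr_raw = as.numeric(bip_raw[names(pr)]),
      bip_pr_pct = as.numeric(to_percentile(bip_raw[names(pr)]))
    )
    merge(out, deg, by = "patient_id")
  }))
}

#' Write / read a centrality table as delimited text
#' @param ct A [centrality_table()] result.
#' @param path Output file.
#' @return `path` invisibly; the reader returns the data.table.
#' @export
write_centrality <- function(ct, path) {
  fwrite(ct, path)
  invisible(path)
}

#' @rdname write_centrality
#' @export
read_centrality <- function(path) {
  ct <- fread(path)
  ct[, quarter := as.integer(quarter)]
  ct
}
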