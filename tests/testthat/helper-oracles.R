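# Independent oracles and small fixture builders. These deliberately use
# naive base-R implementations (dense matrices, nested loops, set
# intersections) so they share no code with the package's sparse paths.

library(data.table)

# random MAT-free prescription table
rand_rx <- function(n_records, n_patients, n_prescribers, n_quarters = 7,
                    mat_frac = 0) {
  data.table(
    patient_id = sprintf("P%03d", sample.int(n_patients, n_records,
                                             replace = TRUE)),
    prescriber_id = sprintf("D%03d", sample.int(n_prescribers, n_records,
                                                replace = TRUE)),
    drug_code = "oxycodone",
    quarter = sample(0:(n_quarters - 1), n_records, replace = TRUE),
    daily_dose_mg = round(runif(n_records, 5, 80), 1),
    mme_factor = 1.5,
    fill_day = sample(0:89, n_records, replace = TRUE),
    days_supply = sample(c(7L, 14L, 30L, 60L), n_records, replace = TRUE),
    is_mat = as.integer(runif(n_records) < mat_frac)
  )
}

# brute-force bipartite projection: pairwise prescriber-set intersection
oracle_project <- function(edges, patients) {
  nb <- lapply(setNames(patients, patients), function(p)
    unique(edges$prescriber_id[edges$patient_id == p]))
  out <- list()
  for (i in seq_along(patients)) {
    for (j in seq_len(i - 1L)) {
      a <- patients[j]; b <- patients[i]
      w <- length(intersect(nb[[a]], nb[[b]]))
      if (w > 0) out[[length(out) + 1]] <-
          data.table(patient_a = min(a, b), patient_b = max(a, b),
                     weight = w)
    }
  }
  if (length(out) == 0)
    return(data.table(patient_a = character(), patient_b = character(),
                      weight = integer()))
  setkey(rbindlist(out), patient_a, patient_b)[]
}

# dense power-iteration PageRank with uniform dangling redistribution
oracle_pagerank <- function(nodes, edges, d = 0.85, tol = 1e-13,
                            max_iter = 5000) {
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      a <- edges$patient_a[r]; b <- edges$patient_b[r]
      W[a, b] <- W[a, b] + edges$weight[r]
      W[b, a] <- W[b, a] + edges$weight[r]
    }
  }
  s <- colSums(W)
  A <- matrix(1 / n, n, n)
  for (j in seq_len(n)) if (s[j] > 0) A[, j] <- W[, j] / s[j]
  pr <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    new <- (1 - d) / n + d * as.numeric(A %*% pr)
    if (sum(abs(new - pr)) < tol) break
    pr <- new
  }
  setNames(new, nodes)
}

# plain-loop Co-HITS fixed point, scalar updates per node
oracle_cohits <- function(pats, docs, edges, lp = 0.85, ld = 0.85,
                          tol = 1e-13, max_iter = 5000) {
  np <- length(pats); nd <- length(docs)
  nb_p <- lapply(setNames(pats, pats), function(p)
    unique(edges$prescriber_id[edges$patient_id == p]))
  nb_d <- lapply(setNames(docs, docs), function(dd)
    unique(edges$patient_id[edges$prescriber_id == dd]))
  x <- setNames(rep(1 / np, np), pats)
  y <- setNames(rep(1 / nd, nd), docs)
  for (it in seq_len(max_iter)) {
    x_new <- x
    for (p in pats) {
      acc <- 0
      for (dd in nb_p[[p]]) acc <- acc + y[dd] / length(nb_d[[dd]])
      x_new[p] <- (1 - lp) / np + lp * acc
    }
    y_new <- y
    for (dd in docs) {
      acc <- 0
      for (p in nb_d[[dd]]) acc <- acc + x_new[p] / length(nb_p[[p]])
      y_new[dd] <- (1 - ld) / nd + ld * acc
    }
    delta <- sum(abs(x_new - x)) + sum(abs(y_new - y))
    x <- x_new; y <- y_new
    if (delta < tol) break
  }
  list(patient_scores = x, prescriber_scores = y)
}

# brute-force day-grid maximum daily MME for one cell
oracle_max_mme <- function(cell, quarter_days = 90) {
  best <- 0
  for (day in 0:(quarter_days - 1)) {
    tot <- 0
    for (r in seq_len(nrow(cell))) {
      if (day >= cell$fill_day[r] &&
          day <= cell$fill_day[r] + cell$days_supply[r] - 1) {
        tot <- tot + cell$daily_dose_mg[r] * cell$mme_factor[r]
      }
    }
    best <- max(best, tot)
  }
  best
}

# random co-prescription graph (direct edge construction, isolates included)
rand_patient_graph <- function(n_nodes, p_edge = 0.2, max_w = 5) {
  nodes <- sprintf("P%03d", seq_len(n_nodes))
  out <- list()
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(i - 1L)) {
      if (runif(1) < p_edge) {
        out[[length(out) + 1]] <- data.table(
          patient_a = nodes[j], patient_b = nodes[i],
          weight = sample.int(max_w, 1))
      }
    }
  }
  edges <- if (length(out) > 0) rbindlist(out) else
    data.table(patient_a = character(), patient_b = character(),
               weight = integer())
  make_graph(nodes, edges)
}

# assemble a coprescription_graph object from explicit parts
make_graph <- function(nodes, edges, focal = 2L, window = 0:2) {
  strength <- setNames(numeric(length(nodes)), nodes)
  if (nrow(edges) > 0) {
    s <- rbind(edges[, .(patient_id = patient_a, weight)],
               edges[, .(patient_id = patient_b, weight)])[
                 , .(s = sum(weight)), by = patient_id]
    strength[s$patient_id] <- s$s
  }
  structure(list(edges = edges, patients = nodes, strength = strength,
                 focal_quarter = focal, window = window),
            class = "coprescription_graph")
}

small_synth_config <- function(...) {
  synth_config(n_patients = 200L, n_prescribers = 40L, ...)
}
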