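test_that("PageRank handles degenerate graphs exactly", {
  g1 <- make_graph("P001", data.table::data.table(
    patient_a = character(), patient_b = character(), weight = integer()))
  expect_equal(pagerank(g1), c(P001 = 1.0))

  g2 <- make_graph(c("P001", "P002"), data.table::data.table(
    patient_a = "P001", patient_b = "P002", weight = 7L))
  pr <- pagerank(g2)
  expect_equal(as.numeric(pr), c(0.5, 0.5), tolerance = 1e-12)

  # all-isolate graph: uniform distribution, sum exactly 1
  g3 <- make_graph(sprintf("P%03d", 1:5), data.table::data.table(
    patient_a = character(), patient_b = character(), weight = integer()))
  pr3 <- pagerank(g3)
  expect_equal(as.numeric(pr3), rep(0.2, 5), tolerance = 1e-12)
  expect_equal(sum(pr3), 1, tolerance = 1e-9)
})

test_that("PageRank matches dense power iteration and stays normalized", {
  set.seed(13)
  for (rep in 1:8) {
    g <- rand_patient_graph(sample(5:20, 1), p_edge = runif(1, 0.1, 0.4))
    pr <- pagerank(g)
    orc <- oracle_pagerank(g$patients, g$edges)
    expect_lt(max(abs(pr - orc[names(pr)])), 1e-8)
    expect_equal(sum(pr), 1, tolerance = 1e-9)
  }
})

test_that("PageRank agrees with igraph on connected weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(17)
  g <- rand_patient_graph(12, p_edge = 0.5)
  # keep only the connected core so dangling conventions cannot differ
  con <- unique(c(g$edges$patient_a, g$edges$patient_b))
  e <- g$edges
  g2 <- make_graph(con, e)
  pr <- pagerank(g2)
  ig <- igraph::graph_from_data_frame(
    data.frame(from = e$patient_a, to = e$patient_b), directed = FALSE,
    vertices = con)
  ipr <- igraph::page_rank(ig, damping = 0.85, weights = e$weight)$vector
  expect_lt(max(abs(pr[con] - ipr[con])), 1e-7)
})

test_that("PageRank is invariant to weight scaling and equivariant to relabeling", {
  set.seed(19)
  g <- rand_patient_graph(15, p_edge = 0.25)
  pr <- pagerank(g)
  g_scaled <- g
  g_scaled$edges <- data.table::copy(g$edges)[, weight := weight * 10L]
  g_scaled$strength <- g$strength * 10
  expect_equal(pagerank(g_scaled), pr, tolerance = 1e-10)

  perm <- sample(g$patients)
  relab <- setNames(perm, g$patients)
  g_perm <- make_graph(perm, data.table::data.table(
    patient_a = relab[g$edges$patient_a],
    patient_b = relab[g$edges$patient_b],
    weight = g$edges$weight))
  pr_perm <- pagerank(g_perm)
  expect_equal(as.numeric(pr_perm[relab[names(pr)]]), as.numeric(pr),
               tolerance = 1e-10)
})

test_that("isolates get the minimum PageRank; literal dangling policy yields (1-d)/N", {
  set.seed(23)
  g <- rand_patient_graph(12, p_edge = 0.4)
  iso <- g$patients[g$strength == 0]
  if (length(iso) == 0) {
    g <- make_graph(c(g$patients, "P999"), g$edges)
    iso <- "P999"
  }
  pr <- pagerank(g)
  expect_true(all(pr[iso] <= min(pr[setdiff(g$patients, iso)]) + 1e-12))

  pr_lit <- pagerank(g, centrality_params(dangling = "literal"))
  expect_equal(as.numeric(pr_lit[iso]),
               rep(0.15 / length(g$patients), length(iso)),
               tolerance = 1e-9)
  expect_lt(sum(pr_lit), 1)
})

test_that("percentile transform uses midranks on a 0-100 scale", {
  expect_equal(as.numeric(to_percentile(c(5, 5, 5))), rep(50, 3))
  expect_equal(as.numeric(to_percentile(c(1, 2, 3, 4))),
               c(12.5, 37.5, 62.5, 87.5))
  set.seed(29)
  x <- sample(round(runif(1000, 0, 10), 1))  # duplicates guaranteed
  got <- to_percentile(x)
  ord <- sort(x)
  orc <- vapply(x, function(v) {
    rk <- mean(which(ord == v))
    100 * (rk - 0.5) / length(x)
  }, numeric(1))
  expect_equal(as.numeric(got), orc, tolerance = 1e-12)
  expect_equal(mean(got), 50, tolerance = 1e-12)
  # min-rank alternative
  expect_equal(as.numeric(to_percentile(c(5, 5, 5), ties = "min")),
               rep(100 * 0.5 / 3, 3))
})

test_that("standardization is exact and rejects degenerate input", {
  z <- standardize(c(0, 1))
  expect_equal(z, c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_error(standardize(rep(3, 4)), "variance")
  expect_error(standardize(1), "at least 2")
  set.seed(31)
  x <- rnorm(100)
  expect_equal(standardize(x), (x - mean(x)) / sd(x))
  expect_equal(mean(standardize(x)), 0, tolerance = 1e-12)
  expect_equal(sd(standardize(x)), 1, tolerance = 1e-12)
})

test_that("degree metrics count distinct co-prescribed patients", {
  hub_edges <- data.table::data.table(
    patient_a = "P001", patient_b = sprintf("P%03d", 2:10), weight = 1L)
  g <- make_graph(sprintf("P%03d", 1:11), hub_edges)
  dm <- degree_metrics(g)
  expect_equal(dm[patient_id == "P001", degree], 9L)
  expect_equal(dm[patient_id == "P011", degree], 0L)
  expect_equal(dm[patient_id == "P011", degree_log], 0)
  expect_equal(dm[patient_id == "P001", degree_log], log(10))

  set.seed(37)
  g2 <- rand_patient_graph(20, p_edge = 0.2)
  dm2 <- degree_metrics(g2)
  adj <- setNames(integer(20), g2$patients)
  for (r in seq_len(nrow(g2$edges))) {
    adj[g2$edges$patient_a[r]] <- adj[g2$edges$patient_a[r]] + 1L
    adj[g2$edges$patient_b[r]] <- adj[g2$edges$patient_b[r]] + 1L
  }
  expect_equal(setNames(dm2$degree, dm2$patient_id), adj)
})

test_that("Co-HITS is uniform on complete bipartite graphs and exact at lambda 0", {
  k22 <- build_bipartite(data.table::data.table(
    patient_id = rep(c("A", "B"), each = 2),
    prescriber_id = rep(c("D1", "D2"), 2),
    quarter = 0L, is_mat = 0L), 0L)
  ch <- cohits(k22)
  expect_equal(ch$patient_scores[["A"]], ch$patient_scores[["B"]],
               tolerance = 1e-12)
  expect_equal(ch$prescriber_scores[["D1"]], ch$prescriber_scores[["D2"]],
               tolerance = 1e-12)

  ch0 <- cohits(k22, centrality_params(cohits_lambda_patient = 0,
                                       cohits_lambda_prescriber = 0))
  expect_equal(as.numeric(ch0$patient_scores), c(0.5, 0.5))
})

test_that("Co-HITS matches the independent per-node fixed-point oracle", {
  set.seed(43)
  for (rep in 1:5) {
    rx <- rand_rx(120, 25, 8)
    bip <- build_bipartite(rx, 4L, n_quarters = 7L)
    ch <- cohits(bip)
    orc <- oracle_cohits(bip$patients, bip$prescribers, bip$edges)
    common <- names(ch$patient_scores)
    expect_lt(max(abs(ch$patient_scores[common] -
                        orc$patient_scores[common])), 1e-8)
    expect_lt(max(abs(ch$prescriber_scores - orc$prescriber_scores[
      names(ch$prescriber_scores)])), 1e-8)
  }
})

test_that("star-plus-clique percentile ordering matches the brute-force oracle", {
  # star: 6 patients all sharing prescriber D1; clique pair sharing D2-D4;
  # one patient with no fills in the window at all
  rx <- rbind(
    data.table::data.table(patient_id = sprintf("S%d", 1:6),
                           prescriber_id = "D1", quarter = 0L, is_mat = 0L),
    data.table::data.table(patient_id = rep(c("C1", "C2"), 3),
                           prescriber_id = rep(c("D2", "D3", "D4"), each = 2),
                           quarter = 0L, is_mat = 0L))
  bip <- build_bipartite(rx, 0L,
                         patients = c(sprintf("S%d", 1:6), "C1", "C2", "I1"))
  g <- project_patients(bip)
  pr <- pagerank(g)
  pct <- to_percentile(pr)
  orc <- oracle_pagerank(g$patients, g$edges)
  expect_equal(as.numeric(pct),
               as.numeric(to_percentile(orc[names(pr)])), tolerance = 1e-9)
  # every connected patient outranks the isolate
  expect_gt(pct[["S1"]], pct[["I1"]])
  expect_gt(pct[["C1"]], pct[["I1"]])
})

test_that("the per-quarter centrality table is complete and internally consistent", {
  cfg <- small_synth_config(seed = 12L)
  sy <- synth_claims(cfg)
  rx_f <- filter_opioid_claims(sy$rx)
  included <- sort(unique(rx_f$patient_id))
  ct <- centrality_table(rx_f, panel_quarters(cfg), patients = included,
                         n_quarters = cfg$n_quarters)
  expect_equal(nrow(ct), length(included) * cfg$n_panel)
  expect_true(all(ct$pr_pct >= 0 & ct$pr_pct <= 100))
  expect_equal(ct[, sum(pr_raw), by = quarter]$V1,
               rep(1, cfg$n_panel), tolerance = 1e-9)
  expect_true(all(ct$degree >= 0))
  expect_equal(ct$degree_log, log(ct$degree + 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_centrality(ct, path)
  expect_equal(as.data.frame(read_centrality(path)), as.data.frame(ct),
               tolerance = 1e-12)
})
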