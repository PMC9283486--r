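make_paths <- function(...) {
  # build a paths table from per-patient lists of date-bucketed code sets
  pats <- list(...)
  rows <- lapply(seq_along(pats), function(k) {
    buckets <- pats[[k]]
    data.table::rbindlist(lapply(seq_along(buckets), function(b)
      data.table::data.table(patient_id = sprintf("P%d", k),
                             date = as.Date("2010-01-01") + 30 * b,
                             code = buckets[[b]], bucket = b)))
  })
  data.table::rbindlist(rows)
}

test_that("transitions link consecutive buckets bipartitely", {
  tr <- count_transitions(make_paths(list("A", c("B", "C"), "D")))
  expect_equal(nrow(tr$edges), 4L)
  expect_setequal(paste(tr$edges$source, tr$edges$target), c("A B", "A C", "B D", "C D"))
  expect_true(all(tr$edges$w == 1))
  # additivity across patients
  tr2 <- count_transitions(make_paths(list("A", "B"), list("A", "B")))
  expect_equal(tr2$edges$w, 2L)
  expect_equal(tr2$nodes[code == "A", N], 2L)
  # no intra-bucket edges
  tr3 <- count_transitions(make_paths(list(c("A", "B"))))
  expect_equal(nrow(tr3$edges), 0L)
  expect_equal(sort(tr3$nodes$code), c("A", "B"))
})

test_that("contingency tables count transition events", {
  edges <- data.table::data.table(source = c("A", "A", "D", "D"),
                                  target = c("B", "C", "B", "E"), w = 1L)
  expect_equal(build_contingency("A", "B", edges), c(a = 1L, b = 1L, c = 1L, d = 1L))
  expect_equal(build_contingency("A", "E", edges)[["a"]], 0L)
  only <- data.table::data.table(source = "A", target = "B", w = 5L)
  expect_equal(build_contingency("A", "B", only), c(a = 5L, b = 0L, c = 0L, d = 0L))
  expect_error(build_contingency("A", "A", edges), "self")
})

test_that("one-sided Fisher p matches the exhaustive enumeration oracle", {
  # worked example: P(X >= 4) with margins (5,5,5,5) = 26/252
  expect_equal(fisher_one_sided(4, 1, 1, 4), 26 / 252, tolerance = 1e-12)
  expect_equal(fisher_one_sided(0, 3, 2, 5), 1)  # a = 0 -> P(X >= 0) = 1
  expect_equal(fisher_one_sided(0, 0, 0, 0), 1)  # no evidence
  set.seed(21)
  for (rep in 1:200) {
    tb <- as.vector(stats::rmultinom(1, sample(1:50, 1), prob = stats::runif(4)))
    expect_equal(fisher_one_sided(tb[1], tb[2], tb[3], tb[4]),
                 hyper_tail_oracle(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-12)
  }
})

test_that("one-sided Fisher p agrees with stats::fisher.test", {
  set.seed(22)
  for (rep in 1:50) {
    tb <- as.vector(stats::rmultinom(1, sample(5:80, 1), prob = stats::runif(4)))
    ft <- stats::fisher.test(matrix(tb, 2, byrow = TRUE), alternative = "greater")
    expect_equal(fisher_one_sided(tb[1], tb[2], tb[3], tb[4]), ft$p.value,
                 tolerance = 1e-10)
  }
})

test_that("phi coefficient matches its closed form and conventions", {
  expect_equal(phi_coefficient(1, 0, 0, 1), 1)
  expect_equal(phi_coefficient(4, 1, 1, 4), 0.6)   # 15 / 25
  expect_equal(phi_coefficient(1, 1, 1, 1), 0)
  expect_equal(phi_coefficient(0, 0, 3, 5), 0)     # zero marginal convention
  set.seed(23)
  for (rep in 1:100) {
    tb <- sample(0:30, 4, replace = TRUE)
    phi <- phi_coefficient(tb[1], tb[2], tb[3], tb[4])
    expect_lte(abs(phi), 1)
    if (phi != 0) expect_equal(sign(phi), sign(tb[1] * tb[4] - tb[2] * tb[3]))
  }
  # vectorized with large counts (no integer overflow)
  expect_equal(phi_coefficient(100000L, 50L, 50L, 100000L),
               phi_coefficient(100000, 50, 50, 100000))
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_adjust(numeric()), numeric())
  set.seed(24)
  for (rep in 1:20) {
    p <- stats::runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-14)
    expect_true(all(adj >= p))         # pointwise no smaller
    expect_true(all(adj <= 1))
    expect_equal(order(adj[order(p)]), seq_along(p)) # order-preserving in rank
  }
})

test_that("nearest-rank percentile follows its definition", {
  expect_equal(nearest_rank_percentile(1:100, 10), 10)
  expect_equal(nearest_rank_percentile(c(5, 1, 9), 50), 5)
  expect_equal(nearest_rank_percentile(7, 10), 7)
})

test_that("filters remove edges at the stage their rule names", {
  # pair-count boundary: w = 99 dies at min_pair = 100; p_adj = 0.049 survives alpha
  nodes <- data.table::data.table(code = c("100", "200", "300"), N = c(1000L, 1000L, 1000L))
  edges <- data.table::data.table(
    source = c("100", "100"), target = c("200", "300"),
    w = c(99L, 150L), a = c(99L, 150L), b = c(1L, 1L), c = c(1L, 1L), d = c(10L, 10L),
    p = c(1e-6, 0.049), phi = 0.5)
  net <- apply_filters(edges, nodes, alpha = 0.05, node_percentile = 0, min_pair = 100,
                       death_codes = character())
  expect_equal(net$provenance$pair_count$edges_removed, 1L)
  expect_equal(nrow(net$edges), 1L)       # 0.049 < 0.05 retained (m = 1 here)
  expect_equal(net$edges$target, "300")
  expect_error(apply_filters(edges, nodes, death_codes = "79.8"), "3-digit")
})

test_that("filters are contractive and provenance counts reconcile", {
  set.seed(25)
  spec <- cohort_spec(n_patients = 150, seed = 77)
  ch <- generate_cohort(spec)
  paths <- extract_paths(filter_cohort(parse_records(ch$visits), parse_patients(ch$patients)))
  tr <- count_transitions(paths)
  cand <- edge_statistics(tr)
  net <- build_tdn(paths, min_pair = 5, node_percentile = 10)
  pr <- net$provenance
  expect_lte(nrow(net$edges), nrow(cand))
  expect_true(all(paste(net$edges$source, net$edges$target) %in%
                    paste(cand$source, cand$target)))
  expect_equal(pr$input$edges - nrow(net$edges),
               pr$node_prevalence$edges_removed + pr$pair_count$edges_removed +
                 pr$death_codes$edges_removed + pr$significance$edges_removed)
  # w never exceeds either endpoint's prevalence
  merged <- merge(merge(net$edges, net$nodes, by.x = "source", by.y = "code"),
                  net$nodes, by.x = "target", by.y = "code", suffixes = c("_s", "_t"))
  expect_true(all(merged$w <= pmin(merged$N_s, merged$N_t)))
})

test_that("null cohorts retain few edges at alpha 0.05", {
  frac <- vapply(1:3, function(k) {
    ch <- generate_cohort(cohort_spec(n_patients = 400, seed = 400 + k))
    paths <- extract_paths(filter_cohort(parse_records(ch$visits),
                                         parse_patients(ch$patients)))
    es <- edge_statistics(count_transitions(paths))
    mean(bh_adjust(es$p) < 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})
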