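test_that("weighted degree sums both directions", {
  net <- toy_tdn(data.frame(source = c("A", "B"), target = c("B", "A"), w = c(5, 7)))
  expect_equal(weighted_degree(net, "A"), 12)
  expect_equal(weighted_degree(net, "B"), 12)
  recip <- toy_tdn(data.frame(source = c("A", "B"), target = c("B", "A"), w = c(3, 3)))
  expect_equal(weighted_degree(recip, "A"), 6)
  iso <- toy_tdn(data.frame(source = "A", target = "B", w = 1), nodes = c("A", "B", "C"))
  expect_equal(weighted_degree(iso, "C"), 0)
  expect_error(weighted_degree(net, "Z"), "unknown node")
})

test_that("PageRank is symmetric on a 2-cycle and conserves mass", {
  cyc <- toy_tdn(data.frame(source = c("A", "B"), target = c("B", "A"), w = c(4, 4)))
  pr <- tdn_pagerank(cyc)
  expect_equal(unname(pr["A"]), 0.5, tolerance = 1e-10)
  expect_equal(sum(pr), 1, tolerance = 1e-9)
  set.seed(31)
  for (rep in 1:5) {
    g <- random_toy_graph(sample(4:8, 1))
    if (!nrow(g)) next
    for (d in c(0.5, 0.85, 0.99)) {
      pr <- tdn_pagerank(toy_tdn(g), damping = d)
      expect_equal(sum(pr), 1, tolerance = 1e-9)
    }
  }
})

test_that("PageRank matches dense power iteration on fixtures", {
  set.seed(32)
  for (rep in 1:8) {
    g <- random_toy_graph(sample(4:8, 1))
    if (!nrow(g)) next
    net <- toy_tdn(g)
    nodes <- net$nodes$code
    W <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
    W[cbind(g$source, g$target)] <- g$w
    pr <- tdn_pagerank(net)
    expect_equal(unname(pr[nodes]), unname(pagerank_oracle(W)), tolerance = 1e-8)
  }
})

test_that("betweenness matches brute-force path counting", {
  # middle vertex of a directed path holds all intermediation
  path <- toy_tdn(data.frame(source = c("A", "B"), target = c("B", "C"), w = c(2, 2)))
  bc <- tdn_betweenness(path)
  # raw bc(B) = 1 (the A->C pair), over (n-1)(n-2) = 2 ordered pairs
  expect_equal(unname(bc["B"]), 0.5)
  expect_equal(unname(bc["A"]), 0)
  # complete symmetric digraph: all shortest paths direct
  nodes <- c("A", "B", "C", "D")
  grid <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  grid$w <- 4
  expect_true(all(tdn_betweenness(toy_tdn(grid)) == 0))
  # random fixtures vs exhaustive enumeration
  set.seed(33)
  for (rep in 1:5) {
    g <- random_toy_graph(sample(5:6, 1))
    if (!nrow(g)) next
    net <- toy_tdn(g)
    bc <- tdn_betweenness(net)
    oracle <- betweenness_oracle(g, net$nodes$code)
    expect_equal(unname(bc[net$nodes$code]), unname(oracle), tolerance = 1e-10)
  }
})

test_that("fixed-horizon fatality respects eligibility and horizon", {
  mkpaths <- function(n) data.table::data.table(
    patient_id = sprintf("P%d", 1:n), date = as.Date("2005-01-01"),
    code = "250", bucket = 1L)
  end <- as.Date("2018-01-01")
  # 10 eligible patients, 4 die within 8 years
  meta <- data.table::data.table(
    patient_id = sprintf("P%d", 1:10),
    death_date = c(rep(as.Date("2006-01-01"), 4), rep(as.Date(NA), 6)))
  expect_equal(fatality(mkpaths(10), meta, "250", data_end = end), 0.4)
  # no patient with the code
  expect_true(is.na(fatality(mkpaths(2), meta[1:2], "999", data_end = end)))
  # diagnosed 3 years before data_end and alive -> not eligible
  late <- data.table::data.table(patient_id = "P1", date = end - round(3 * 365.25),
                                 code = "250", bucket = 1L)
  expect_true(is.na(fatality(late, data.table::data.table(patient_id = "P1",
                                                          death_date = as.Date(NA)),
                             "250", data_end = end)))
  # but a death within the horizon makes the patient eligible
  expect_equal(fatality(late, data.table::data.table(patient_id = "P1",
                                                     death_date = end - 100),
                        "250", data_end = end), 1)
  # longer horizon never decreases deaths for a fixed eligible cohort
  f8 <- fatality(mkpaths(10), meta, "250", horizon_years = 8, data_end = end)
  f10 <- fatality(mkpaths(10), meta, "250", horizon_years = 10, data_end = end)
  expect_gte(f10, f8)
})

test_that("planted death probabilities are recovered within binomial error", {
  spec <- cohort_spec(n_patients = 800, death_model = c("401" = 0.35), seed = 55)
  ch <- generate_cohort(spec)
  paths <- extract_paths(filter_cohort(parse_records(ch$visits), parse_patients(ch$patients)))
  est <- fatality(paths, parse_patients(ch$patients), "401",
                  data_end = max(paths$date) + 3000)
  n <- sum(paths$code == "401")
  expect_lt(abs(est - 0.35), 3 * sqrt(0.35 * 0.65 / n) + 0.02)
})

test_that("Spearman correlation uses average ranks and drops missing pairs", {
  expect_equal(spearman(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman(1:3, c(3, 2, 1))$rho, -1)
  expect_true(is.na(spearman(c(1, 1, 1), 1:3)$rho))  # constant vector
  set.seed(34)
  for (rep in 1:10) {
    x <- sample(1:5, 20, replace = TRUE)   # heavy ties
    y <- x + sample(0:3, 20, replace = TRUE)
    expect_equal(spearman(x, y)$rho, spearman_oracle(x, y), tolerance = 1e-12)
  }
  # missing values are dropped pairwise
  s <- spearman(c(1, 2, 3, NA, 5), c(5, 4, NA, 2, 1))
  expect_equal(s$n, 3L)
  expect_equal(s$rho, spearman_oracle(c(1, 2, 5), c(5, 4, 1)))
})

test_that("centrality table assembles all metrics over the network", {
  net <- toy_tdn(data.frame(source = c("A", "B", "C"), target = c("B", "C", "A"),
                            w = c(2, 4, 8)))
  tab <- centrality_table(net)
  expect_setequal(tab$code, c("A", "B", "C"))
  expect_equal(sum(tab$pr), 1, tolerance = 1e-9)
  expect_equal(tab[tab$code == "A", ]$k_w, 10)
  cors <- correlation_table(tab)
  expect_equal(nrow(cors), 3L)  # k_w/pr/bc pairs, no fatality column
})
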