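# Hand-built 20-patient cohort whose filter trace was worked out by hand and
# cross-checked with a standalone choose()-product Fisher/BH computation.
#
# Structure (dates d1 < d2 < d3; one row per diagnosis):
#   P01-P10: 250 -> 401 -> 272                 (w: 250>401 = 10, 401>272 = 10)
#   P11-P14: {401, rare} -> 250                (401>250 = 4; 491/492>250 = 2 each)
#   P15-P17: {250, rare} -> 798                (250>798 = 3; 493/494>798 = 2 each)
#   P18    : 300 -> 272                        (300>272 = 1)
#   P19-P20: {272, 490} -> 585                 (272>585 = 2, 490>585 = 2)
# plus one V-code row on P01 (excluded upstream) and decimal suffixes on a
# few raw codes to exercise truncation.
fixture_cohort <- function() {
  d1 <- "2010-01-15"; d2 <- "2010-06-15"; d3 <- "2010-12-15"
  rows <- list()
  add <- function(pid, date, code) rows[[length(rows) + 1]] <<- data.frame(
    patient_id = pid, visit_date = date, icd9 = code)
  for (k in 1:10) {
    pid <- sprintf("P%02d", k)
    add(pid, d1, "250.00"); add(pid, d2, "401.9"); add(pid, d3, "272")
  }
  rare1 <- c(P11 = "491", P12 = "491", P13 = "492", P14 = "492")
  for (k in 11:14) {
    pid <- sprintf("P%02d", k)
    add(pid, d1, "401"); add(pid, d1, rare1[[pid]]); add(pid, d2, "250")
  }
  add("P15", d1, "250"); add("P15", d1, "493"); add("P15", d2, "798")
  add("P16", d1, "250"); add("P16", d1, "493"); add("P16", d1, "494"); add("P16", d2, "798")
  add("P17", d1, "250"); add("P17", d1, "494"); add("P17", d2, "798")
  add("P18", d1, "300"); add("P18", d2, "272")
  add("P19", d1, "272"); add("P19", d1, "490"); add("P19", d2, "585")
  add("P20", d1, "272"); add("P20", d1, "490"); add("P20", d2, "585")
  add("P01", d2, "V70.0")
  visits <- do.call(rbind, rows)
  patients <- data.frame(patient_id = sprintf("P%02d", 1:20),
                         birth_date = "1950-01-01", death_date = "", sex = "male")
  list(visits = visits, patients = patients)
}

# frozen oracle values for the fixture filter trace at
# node_percentile = 10, min_pair = 3, death_codes = "798", alpha = 0.05
fixture_oracle <- list(
  n_path_rows = 60L,
  n_nodes_in = 11L, n_edges_in = 11L,
  prevalence_threshold = 2L,       # nearest-rank 10th pct of {1,2x6,3,13,13,14}
  nodes_removed_prevalence = 1L,   # "300" (N = 1)
  edges_removed_prevalence = 1L,   # 300 -> 272
  edges_removed_pair = 6L,         # the six w = 2 edges
  edges_removed_death = 1L,        # 250 -> 798
  bh_family_size = 3L,
  edges_removed_significance = 1L, # 401 -> 250, p_adj = 0.2761647...
  final_edges = data.frame(source = c("250", "401"), target = c("401", "272")),
  p_adj_final = c(1.012198e-06, 1.712301e-05),   # choose()-product + manual BH
  p_adj_removed_401_250 = 0.276164709601
)
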