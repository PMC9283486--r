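# Synthetic EHR-like cohorts with planted ground truth.
#
# The generator emulates the structure of longitudinal outpatient extracts:
# multiple visits per patient, several codes per visit date, raw 3-to-5-digit
# ICD-9 codes including excluded V/E rows, patient ages, death dates, planted
# directed precedence tendencies and planted disease blocks with high
# within-block patient flow.

#' Specify a synthetic cohort
#'
#' @param n_patients number of core (male, in-age) patients.
#' @param background_codes pool of 3-digit codes drawn at random as noise.
#' @param background_rate probability that a visit contributes one random
#'   background diagnosis.
#' @param visits_mean mean visits per patient (geometric-like, minimum 2).
#' @param precedence_pairs list of `list(i, j, excess, co_rate)`: a fraction
#'   `co_rate` of patients acquires both diseases on consecutive visits, and
#'   among those the source precedes the target with probability
#'   `0.5 + excess/2` (excess 0 = symmetric null, 1 = always i before j).
#' @param disease_blocks list of `list(members, within_prob, participation)`:
#'   a fraction `participation` of patients enters the block and then
#'   acquires each member independently with probability `within_prob`, in a
#'   random order on consecutive visits — generating high within-block flow.
#' @param death_model named numeric vector, code -> probability of death
#'   within 8 years of the first diagnosis of that code (death date uniform
#'   in the window).
#' @param date_range first/last possible visit dates.
#' @param decoy_fraction fraction of extra patients that violate the cohort
#'   filters (female or older than 99 years) to exercise filtering.
#' @param ve_rate rate of extra supplementary-classification (V/E) rows.
#' @param seed integer RNG seed; the generated tables are byte-identical
#'   across runs for a fixed spec.
#' @return a validated `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 500,
                        background_codes = sprintf("%03d", c(250, 272, 278, 285, 300, 311,
                                                             327, 338, 365, 401, 427, 434,
                                                             436, 443, 486, 530, 585, 600,
                                                             715, 780)),
                        background_rate = 0.6,
                        visits_mean = 8,
                        precedence_pairs = list(),
                        disease_blocks = list(),
                        death_model = numeric(),
                        date_range = as.Date(c("2002-01-01", "2018-09-30")),
                        decoy_fraction = 0.02,
                        ve_rate = 0.03,
                        seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients), background_codes = background_codes,
               background_rate = background_rate, visits_mean = visits_mean,
               precedence_pairs = precedence_pairs, disease_blocks = disease_blocks,
               death_model = death_model, date_range = as.Date(date_range),
               decoy_fraction = decoy_fraction, ve_rate = ve_rate, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_patients >= 1, spec$visits_mean >= 2,
            spec$background_rate >= 0, spec$background_rate <= 1,
            spec$decoy_fraction >= 0, spec$ve_rate >= 0,
            length(spec$date_range) == 2, spec$date_range[1] < spec$date_range[2])
  chk3 <- function(x) all(grepl("^[0-9]{3}$", x))
  if (!chk3(spec$background_codes)) stop("background_codes must be 3-digit numeric strings")
  block_members <- unlist(lapply(spec$disease_blocks, `[[`, "members"))
  if (anyDuplicated(block_members)) stop("disease blocks must be disjoint")
  if (length(block_members) && !chk3(block_members)) stop("block members must be 3-digit codes")
  for (bl in spec$disease_blocks) {
    stopifnot(bl$within_prob >= 0, bl$within_prob <= 1,
              bl$participation >= 0, bl$participation <= 1,
              length(bl$members) >= 2)
  }
  for (pp in spec$precedence_pairs) {
    stopifnot(chk3(pp$i), chk3(pp$j), pp$i != pp$j,
              pp$excess >= 0, pp$excess <= 1, pp$co_rate >= 0, pp$co_rate <= 1)
  }
  if (length(spec$death_model)) {
    stopifnot(!is.null(names(spec$death_model)), chk3(names(spec$death_model)),
              all(spec$death_model >= 0), all(spec$death_model <= 1))
  }
  n_codes <- length(unique(c(spec$background_codes, block_members,
                             unlist(lapply(spec$precedence_pairs, function(p) c(p$i, p$j))))))
  if (n_codes > 999) stop("infeasible spec: more planted diseases than 3-digit codes")
  invisible(spec)
}

#' Generate a synthetic cohort
#'
#' Draws visit tables conforming to the ingest schema: `visits`
#' (patient_id, visit_date, icd9 — raw codes, some with 5-digit decimal
#' suffixes, plus V/E rows) and `patients` (patient_id, birth_date,
#' death_date, sex), together with a ground-truth record of everything
#' planted. Visit rows after a patient's death are removed.
#'
#' @param spec a [cohort_spec()].
#' @return list with `visits`, `patients` (data.tables) and `truth`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  # visit skeleton: per-patient visit dates (strictly increasing)
  n_visits <- pmax(2L, 1L + stats::rgeom(n, prob = 1 / spec$visits_mean))
  span <- as.integer(spec$date_range[2] - spec$date_range[1])
  start <- spec$date_range[1] + sample.int(span %/% 2, n, replace = TRUE) - 1L
  vt <- data.table::data.table(
    patient_id = rep(ids, n_visits),
    visit = unlist(lapply(n_visits, seq_len), use.names = FALSE))
  vt[, gap := sample(7:120, .N, replace = TRUE)]
  vt[, s0 := rep(start, n_visits)]
  vt[, visit_date := s0 + cumsum(gap) - gap[1L], by = patient_id]
  vt[, c("gap", "s0") := NULL]
  nv <- stats::setNames(n_visits, ids)

  rows <- list()
  # background noise: each visit contributes one random code with prob background_rate
  bg <- vt[stats::runif(.N) < spec$background_rate]
  if (nrow(bg)) {
    bg[, code := sample(spec$background_codes, .N, replace = TRUE)]
    rows[[length(rows) + 1L]] <- bg[, .(patient_id, visit_date, code)]
  }
  # planted precedence pairs on consecutive visits
  for (pp in spec$precedence_pairs) {
    affected <- ids[stats::runif(n) < pp$co_rate]
    if (!length(affected)) next
    k <- vapply(nv[affected], function(m) sample.int(m - 1L, 1L), integer(1))
    fwd <- stats::runif(length(affected)) < 0.5 + pp$excess / 2
    plant <- data.table::data.table(
      patient_id = rep(affected, each = 2L),
      visit = as.integer(rbind(k, k + 1L)),
      code = as.vector(vapply(fwd, function(f) if (f) c(pp$i, pp$j) else c(pp$j, pp$i),
                              character(2))))
    plant <- merge(plant, vt, by = c("patient_id", "visit"))
    rows[[length(rows) + 1L]] <- plant[, .(patient_id, visit_date, code)]
  }
  # planted blocks: members in random order on consecutive visits
  for (bl in spec$disease_blocks) {
    affected <- ids[stats::runif(n) < bl$participation]
    if (!length(affected)) next
    plant <- data.table::rbindlist(lapply(affected, function(pid) {
      got <- bl$members[stats::runif(length(bl$members)) < bl$within_prob]
      if (length(got) < 1L) return(NULL)
      got <- sample(got, length(got))
      m <- nv[[pid]]
      start_v <- sample.int(max(1L, m - length(got) + 1L), 1L)
      data.table::data.table(patient_id = pid,
                             visit = pmin(start_v + seq_along(got) - 1L, m),
                             code = got)
    }))
    if (!is.null(plant) && nrow(plant)) {
      plant <- merge(plant, vt, by = c("patient_id", "visit"))
      rows[[length(rows) + 1L]] <- plant[, .(patient_id, visit_date, code)]
    }
  }
  visits <- data.table::rbindlist(rows)
  if (nrow(visits) == 0L) stop("infeasible spec: no diagnoses generated")

  # deaths triggered by first diagnosis of modeled diseases
  horizon_days <- round(8 * 365.25)
  death <- rep(as.Date(NA), n); names(death) <- ids
  if (length(spec$death_model)) {
    firsts <- visits[code %in% names(spec$death_model),
                     .(t0 = min(visit_date)), by = .(patient_id, code)]
    firsts[, p_death := spec$death_model[code]]
    firsts <- firsts[stats::runif(.N) < p_death]
    if (nrow(firsts)) {
      firsts[, death_date := t0 + floor(stats::runif(.N, 1, horizon_days))]
      dd <- firsts[, .(death_date = min(death_date)), by = patient_id]
      death[dd$patient_id] <- dd$death_date
    }
  }
  # no records after death
  visits <- merge(visits, data.table::data.table(patient_id = ids, dd = death),
                  by = "patient_id")
  visits <- visits[is.na(dd) | visit_date <= dd][, dd := NULL]

  # raw-code dressing: some codes carry 4th/5th digits
  detail <- stats::runif(nrow(visits)) < 0.5
  visits[detail, code := paste0(code, ".", sprintf("%02d", sample(0:99, sum(detail), replace = TRUE)))]
  # supplementary-classification rows, excluded downstream
  n_ve <- round(spec$ve_rate * nrow(visits))
  if (n_ve > 0) {
    ve <- vt[sample.int(nrow(vt), n_ve, replace = TRUE)]
    ve[, code := sample(c("V70.0", "V58.69", "E849.0", "E888"), n_ve, replace = TRUE)]
    visits <- rbind(visits, ve[, .(patient_id, visit_date, code)])
  }

  # patient table: core male patients aged 30-90 at the 2018 reference
  ref <- as.Date("2018-10-01")
  birth <- ref - floor(stats::runif(n, 30, 90) * 365.25)
  patients <- data.table::data.table(patient_id = ids, birth_date = birth,
                                     death_date = unname(death), sex = "male")
  # decoys: patients the cohort filters must remove
  n_decoy <- ceiling(spec$decoy_fraction * n)
  if (n_decoy > 0) {
    did <- sprintf("D%05d", seq_len(n_decoy))
    too_old <- seq_len(n_decoy) %% 2L == 0L
    decoy_pat <- data.table::data.table(
      patient_id = did,
      birth_date = ref - floor(stats::runif(n_decoy, ifelse(too_old, 100, 40),
                                            ifelse(too_old, 110, 70)) * 365.25),
      death_date = as.Date(NA),
      sex = ifelse(too_old, "male", "female"))
    decoy_vis <- data.table::data.table(
      patient_id = rep(did, each = 3L),
      visit_date = spec$date_range[1] + sample.int(span, 3L * n_decoy, replace = TRUE) - 1L,
      code = sample(spec$background_codes, 3L * n_decoy, replace = TRUE))
    patients <- rbind(patients, decoy_pat)
    visits <- rbind(visits, decoy_vis)
  }

  data.table::setorder(visits, patient_id, visit_date, code)
  data.table::setnames(visits, "code", "icd9")
  data.table::setorder(patients, patient_id)
  truth <- list(
    pairs = data.table::rbindlist(lapply(spec$precedence_pairs, function(p)
      data.table::data.table(source = p$i, target = p$j, excess = p$excess,
                             co_rate = p$co_rate))),
    blocks = lapply(spec$disease_blocks, `[[`, "members"),
    death_model = spec$death_model,
    core_ids = ids, spec = spec)
  list(visits = visits[], patients = patients[], truth = truth)
}

#' Recovery metrics against the planted ground truth
#'
#' Compares pipeline outputs with what the generator planted: directed-edge
#' recall/precision (true edges are the planted precedence pairs plus all
#' ordered within-block pairs), community-partition agreement over block
#' members (exact-match flag and pair-counting Rand index), and per-disease
#' fatality estimation error.
#'
#' @param truth ground-truth record from [generate_cohort()].
#' @param tdn fitted `tdn` object, or `NULL`.
#' @param partition from [detect_communities()], or `NULL`.
#' @param fatality_table `data.table` (`code`, `fatality`), or `NULL`.
#' @return list with `edge_recall`, `edge_precision`, `partition_exact`,
#'   `rand_index`, `fatality_errors`.
#' @export
ground_truth_report <- function(truth, tdn = NULL, partition = NULL,
                                fatality_table = NULL) {
  out <- list(edge_recall = NA_real_, edge_precision = NA_real_,
              partition_exact = NA, rand_index = NA_real_,
              fatality_errors = NULL)
  true_edges <- character()
  if (nrow(truth$pairs)) true_edges <- paste(truth$pairs$source, truth$pairs$target)
  for (members in truth$blocks) {
    grid <- expand.grid(source = members, target = members, stringsAsFactors = FALSE)
    grid <- grid[grid$source != grid$target, ]
    true_edges <- union(true_edges, paste(grid$source, grid$target))
  }
  if (!is.null(tdn)) {
    got <- paste(tdn$edges$source, tdn$edges$target)
    out$edge_recall <- if (length(true_edges)) mean(true_edges %in% got) else NA_real_
    out$edge_precision <- if (length(got)) mean(got %in% true_edges) else 0
  }
  if (!is.null(partition) && length(truth$blocks)) {
    members <- unlist(truth$blocks)
    planted <- rep(seq_along(truth$blocks), lengths(truth$blocks))
    names(planted) <- members
    part <- data.table::as.data.table(partition)
    part <- part[code %in% members]
    if (nrow(part) == length(members)) {
      found <- stats::setNames(part$community, part$code)[members]
      canon <- function(lab) {
        parts <- unname(lapply(split(members, lab), sort))
        parts[order(vapply(parts, min, character(1)))]
      }
      out$partition_exact <- identical(canon(planted), canon(found))
      out$rand_index <- rand_index(planted, found)
    } else {
      out$partition_exact <- FALSE
      out$rand_index <- 0
    }
  }
  if (!is.null(fatality_table) && length(truth$death_model)) {
    ft <- data.table::as.data.table(fatality_table)
    est <- stats::setNames(ft$fatality, ft$code)[names(truth$death_model)]
    out$fatality_errors <- data.table::data.table(
      code = names(truth$death_model), planted = unname(truth$death_model),
      estimated = unname(est), error = unname(est) - unname(truth$death_model))
  }
  out
}

# pair-counting Rand index between two labelings of the same elements
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  pairs <- utils::combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}
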