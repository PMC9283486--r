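# End-to-end pipeline: ingest -> network -> centrality -> communities ->
# trajectories, with provenance reporting.

#' Default pipeline configuration
#'
#' Every tunable of the pipeline with its default. Unknown keys in a user
#' config are a fatal error — there are no silent typos.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    visits = NULL,              # path to the visits table (or in-memory data)
    patients = NULL,            # path to the patient metadata table
    out_dir = "tdn_output",
    sex_filter = "male",
    max_age = 99,
    reference_date = "2018-10-01",
    alpha = 0.05,
    node_percentile = 10,
    explicit_min_node = NULL,
    min_pair = 100,
    death_codes = "798",
    contingency_mode = "transition",
    damping = 0.85,
    betweenness_weighted = TRUE,
    horizon_years = 8,
    data_end = NULL,            # defaults to the last visit date
    community_min_size = 5,
    infomap_trials = 10,
    teleportation = 0.15,
    trajectory_from = NULL,     # e.g. "250"
    trajectory_to = NULL,       # codes or a chapter name
    seed = 1L
  )
}

#' Read and validate a pipeline configuration
#'
#' @param config path to a YAML file, or a named list of overrides.
#' @return full configuration list (defaults overridden by `config`).
#' @export
read_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (!identical(out$contingency_mode, "transition")) {
    stop("unsupported contingency_mode: ", out$contingency_mode)
  }
  out
}

#' Run the full pipeline
#'
#' Executes ingest, network construction, centrality/fatality, community
#' detection and (when a query is configured) trajectory extraction, writing
#' every stage artifact plus a machine-readable provenance report into
#' `out_dir`.
#'
#' Artifacts: `paths.tsv`, `edges.tsv`, `network.graphml`,
#' `centrality.tsv`, `correlations.tsv`, `communities.tsv`,
#' `community_summary.tsv`, `chapter_incidence.tsv`, `trajectories.json`,
#' `trajectory_edges.tsv`, `provenance.json`.
#'
#' @param config path to a YAML config or a named list (see
#'   [default_config()]).
#' @param visits,patients optional in-memory tables overriding the config
#'   paths.
#' @return (invisibly) list with `tdn`, `metrics`, `communities`,
#'   `trajectories`, `provenance`.
#' @export
run_pipeline <- function(config = list(), visits = NULL, patients = NULL) {
  cfg <- read_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  visits_src <- if (!is.null(visits)) visits else cfg$visits
  patients_src <- if (!is.null(patients)) patients else cfg$patients
  if (is.null(visits_src) || is.null(patients_src)) {
    stop("stage ingest: both visits and patients inputs are required")
  }
  records <- parse_records(visits_src)
  meta <- parse_patients(patients_src)
  cohort <- filter_cohort(records, meta, max_age = cfg$max_age,
                          reference_date = as.Date(cfg$reference_date),
                          sex_filter = cfg$sex_filter)
  paths <- extract_paths(cohort)
  if (nrow(paths) == 0L) stop("stage ingest: no usable records after filtering")
  write_paths(paths, file.path(cfg$out_dir, "paths.tsv"))

  tdn <- build_tdn(paths, alpha = cfg$alpha, node_percentile = cfg$node_percentile,
                   explicit_min_node = cfg$explicit_min_node,
                   min_pair = cfg$min_pair, death_codes = cfg$death_codes)
  write_tdn(tdn, edge_file = file.path(cfg$out_dir, "edges.tsv"),
            graphml_file = file.path(cfg$out_dir, "network.graphml"))

  metrics <- communities <- traj <- NULL
  if (nrow(tdn$edges) > 0L) {
    data_end <- if (!is.null(cfg$data_end)) as.Date(cfg$data_end) else max(paths$date)
    metrics <- centrality_table(tdn, paths = paths, meta = meta, data_end = data_end,
                                damping = cfg$damping)
    data.table::fwrite(metrics, file.path(cfg$out_dir, "centrality.tsv"), sep = "\t")
    data.table::fwrite(correlation_table(metrics),
                       file.path(cfg$out_dir, "correlations.tsv"), sep = "\t")

    partition <- detect_communities(tdn, trials = cfg$infomap_trials, seed = cfg$seed,
                                    teleportation = cfg$teleportation)
    labeled <- filter_and_label(partition, min_size = cfg$community_min_size)
    cs <- community_summary(labeled, partition, fatality_table = metrics)
    data.table::fwrite(cs$assignments, file.path(cfg$out_dir, "communities.tsv"), sep = "\t")
    data.table::fwrite(cs$summary, file.path(cfg$out_dir, "community_summary.tsv"), sep = "\t")
    data.table::fwrite(cs$incidence, file.path(cfg$out_dir, "chapter_incidence.tsv"), sep = "\t")
    communities <- list(partition = partition, labeled = labeled, summary = cs)

    if (!is.null(cfg$trajectory_from) && !is.null(cfg$trajectory_to) &&
        cfg$trajectory_from %in% tdn$nodes$code) {
      traj <- tryCatch(
        trajectories_to_set(tdn, cfg$trajectory_from, cfg$trajectory_to),
        error = function(e) { message("stage trajectories: ", conditionMessage(e)); NULL })
      if (!is.null(traj)) {
        write_trajectories(traj, json_file = file.path(cfg$out_dir, "trajectories.json"),
                           edges_file = file.path(cfg$out_dir, "trajectory_edges.tsv"))
      }
    }
  }

  provenance <- list(
    parameters = cfg[setdiff(names(cfg), c("visits", "patients"))],
    counts = list(
      rows_parsed = nrow(records), rows_rejected = attr(records, "n_rejected"),
      patients_removed_by_cohort = attr(cohort, "n_patients_removed"),
      rows_excluded_ve = attr(paths, "n_excluded_ve"),
      rows_invalid_code = attr(paths, "n_invalid"),
      patients_in_paths = length(unique(paths$patient_id)),
      filters = tdn$provenance),
    versions = list(tdnet = as.character(utils::packageVersion("tdnet")),
                    igraph = as.character(utils::packageVersion("igraph")),
                    R = paste(R.version$major, R.version$minor, sep = "."))
  )
  jsonlite::write_json(provenance, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  invisible(list(tdn = tdn, metrics = metrics, communities = communities,
                 trajectories = traj, provenance = provenance))
}
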