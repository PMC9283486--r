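# Inverted-weight shortest-path disease trajectories and their aggregation.

#' Invert edge weights into random-walk distances
#'
#' Each directed edge of weight w (patients) gets distance 1/w, so pairs
#' travelled by many patients are close. Topology is unchanged.
#'
#' @param tdn a `tdn` object with all edge weights > 0.
#' @return an igraph graph with edge attribute `distance` (= 1/w) alongside
#'   `weight` (= w).
#' @export
invert_weights <- function(tdn) {
  stopifnot(inherits(tdn, "tdn"))
  if (nrow(tdn$edges) && any(tdn$edges$w <= 0)) stop("edge weights must be positive")
  g <- tdn_igraph(tdn)
  igraph::E(g)$distance <- 1 / igraph::E(g)$weight
  g
}

#' Most likely trajectories between two diagnoses
#'
#' All minimum-cost simple directed paths from `from` to `to` under the
#' inverted weights (cost = sum of 1/w along the path), interpreted as the
#' most likely progression routes. Co-optimal paths are all returned, in
#' lexicographic order of their node sequences.
#'
#' @param tdn a `tdn` object.
#' @param from,to distinct 3-digit codes present in the network.
#' @return list of trajectories, each a list with `nodes` (character vector
#'   from source to target) and `cost` (sum of 1/w); empty list when `to`
#'   is unreachable.
#' @export
shortest_trajectory <- function(tdn, from, to) {
  if (identical(from, to)) stop("source and target must differ")
  g <- invert_weights(tdn)
  nm <- igraph::V(g)$name
  if (!from %in% nm) stop("unknown node: ", from)
  if (!to %in% nm) stop("unknown node: ", to)
  sp <- suppressWarnings(
    igraph::all_shortest_paths(g, from = from, to = to,
                               mode = "out", weights = igraph::E(g)$distance))
  vpaths <- sp$vpaths
  if (!length(vpaths)) return(list())
  paths <- lapply(vpaths, function(v) igraph::as_ids(v))
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths <- paths[order(keys)]
  lapply(paths, function(nodes) {
    eid <- igraph::get_edge_ids(g, rbind(nodes[-length(nodes)], nodes[-1]))
    list(nodes = nodes, cost = sum(igraph::E(g)$distance[eid]))
  })
}

#' Aggregate trajectories into a trajectory network
#'
#' Each trajectory contributes one count to every ordered consecutive pair
#' it traverses; the aggregated edge multiplicity is the number of input
#' trajectories containing that step.
#'
#' @param trajectories list of trajectories, as from [shortest_trajectory()]
#'   (possibly concatenated over many queries).
#' @return list with `edges` (`data.table`: `source`, `target`,
#'   `multiplicity`) and `nodes` (character vector, union of trajectory
#'   nodes).
#' @export
aggregate_trajectories <- function(trajectories) {
  if (!length(trajectories)) {
    return(list(edges = data.table::data.table(source = character(), target = character(),
                                               multiplicity = integer()),
                nodes = character()))
  }
  steps <- data.table::rbindlist(lapply(trajectories, function(tr) {
    nodes <- tr$nodes
    if (length(nodes) < 2) return(NULL)
    data.table::data.table(source = nodes[-length(nodes)], target = nodes[-1])
  }))
  edges <- steps[, .(multiplicity = .N), by = .(source, target)]
  data.table::setorder(edges, source, target)
  list(edges = edges[],
       nodes = sort(unique(unlist(lapply(trajectories, `[[`, "nodes")))))
}

#' Trajectory network from one source to a set of targets
#'
#' Aggregates the shortest trajectories from `from` to every reachable
#' member of the target set; unreachable targets are skipped and counted,
#' not fatal (chapter-wide queries routinely contain unreachable codes).
#'
#' @param tdn a `tdn` object.
#' @param from source 3-digit code.
#' @param to character vector of target codes, or a single chapter name
#'   (matched case-insensitively against `chapter_map`), resolved to the
#'   network's member codes of that chapter. The source itself is never a
#'   target.
#' @param chapter_map chapter ranges used to resolve a chapter name.
#' @return list with `edges`, `nodes` (as [aggregate_trajectories()]),
#'   `targets` (resolved target codes), `n_unreachable` and `trajectories`
#'   (the underlying list).
#' @export
trajectories_to_set <- function(tdn, from, to, chapter_map = icd9_chapters()) {
  stopifnot(inherits(tdn, "tdn"))
  codes <- tdn$nodes$code
  if (length(to) == 1L && !grepl("^[0-9]{3}$", to)) {
    hit <- which(tolower(chapter_map$chapter) == tolower(to) |
                   grepl(tolower(to), tolower(chapter_map$chapter), fixed = TRUE))
    if (!length(hit)) stop("unknown chapter: ", to)
    num <- as.integer(codes)
    to <- codes[num >= min(chapter_map$low[hit]) & num <= max(chapter_map$high[hit])]
  }
  to <- setdiff(intersect(to, codes), from)
  if (!length(to)) stop("empty resolved target set")
  trajs <- list()
  unreachable <- 0L
  for (tgt in to) {
    tr <- shortest_trajectory(tdn, from, tgt)
    if (!length(tr)) unreachable <- unreachable + 1L else trajs <- c(trajs, tr)
  }
  agg <- aggregate_trajectories(trajs)
  c(agg, list(targets = to, n_unreachable = unreachable, trajectories = trajs))
}

#' Write trajectories (JSON) and an aggregated trajectory network (TSV)
#'
#' @param result from [trajectories_to_set()] or a list of trajectories.
#' @param json_file JSON path for the trajectory list (ordered codes +
#'   cost), or `NULL`.
#' @param edges_file TSV path for the aggregated edge list, or `NULL`.
#' @export
write_trajectories <- function(result, json_file = NULL, edges_file = NULL) {
  trajs <- if (!is.null(result$trajectories)) result$trajectories else result
  if (!is.null(json_file)) {
    jsonlite::write_json(lapply(trajs, function(tr) list(nodes = tr$nodes, cost = tr$cost)),
                         json_file, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(edges_file)) {
    edges <- if (!is.null(result$edges)) result$edges else aggregate_trajectories(trajs)$edges
    data.table::fwrite(edges, edges_file, sep = "\t")
  }
  invisible(result)
}
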