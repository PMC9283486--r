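# Map-equation flow communities of the TDN and the chapter-entropy H score.

#' Detect flow communities with the map equation
#'
#' Two-level Infomap partition of the directed TDN, using edge weights as
#' random-walk flow; the best of `trials` optimization attempts is kept.
#' Deterministic given (network, trials, seed). Per-node flow is the
#' stationary visit rate of the damped random walk (PageRank at
#' `1 - teleportation`).
#'
#' @param tdn a `tdn` object with at least one node.
#' @param trials number of Infomap optimization attempts (default 10).
#' @param seed RNG seed making the partition reproducible.
#' @param teleportation random-walk restart probability used for node flow
#'   (default 0.15).
#' @return `data.table` with columns `code`, `community` (integer id) and
#'   `flow` (node visit rate, sums to 1); attribute `"codelength"`.
#' @export
detect_communities <- function(tdn, trials = 10, seed = 1, teleportation = 0.15) {
  stopifnot(inherits(tdn, "tdn"))
  if (nrow(tdn$nodes) == 0L) stop("empty network")
  g <- tdn_igraph(tdn)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  cl <- igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight,
                                nb.trials = trials)
  flow <- igraph::page_rank(g, damping = 1 - teleportation,
                            weights = igraph::E(g)$weight, directed = TRUE)$vector
  out <- data.table::data.table(code = igraph::V(g)$name,
                                community = as.integer(igraph::membership(cl)),
                                flow = unname(flow))
  data.table::setorder(out, code)
  attr(out, "codelength") <- igraph::code_len(cl)
  out[]
}

#' Filter small communities and label survivors by flow
#'
#' Communities below `min_size` members are dropped; survivors are sorted by
#' descending total member flow (ties: larger size first, then smallest
#' member code) and labeled TDN1, TDN2, ... — the lower the index, the
#' higher the patient flow within the community.
#'
#' @param partition from [detect_communities()].
#' @param min_size minimum community size (default 5).
#' @param chapter_map chapter ranges for the H score and chapter counts.
#' @return `data.table`, one row per retained community: `label`, `n`,
#'   `flow`, `h`, `members` (list column of codes).
#' @export
filter_and_label <- function(partition, min_size = 5, chapter_map = icd9_chapters()) {
  dt <- data.table::as.data.table(partition)
  comm <- dt[, .(n = .N, flow = sum(flow), members = list(sort(code)),
                 min_member = min(code)), by = community]
  comm <- comm[n >= min_size]
  if (nrow(comm) == 0L) {
    return(data.table::data.table(label = character(), n = integer(),
                                  flow = numeric(), h = numeric(), members = list()))
  }
  data.table::setorder(comm, -flow, -n, min_member)
  comm[, label := paste0("TDN", .I)]
  comm[, h := vapply(members, h_score, numeric(1), chapter_map = chapter_map)]
  comm[, .(label, n, flow, h, members)]
}

#' Chapter-entropy H score of a community
#'
#' Normalized entropy of the community's ICD-9 chapter composition,
#' H = sum_i -p_i log2(p_i) / log2(n), where p_i is the proportion of the
#' community's n member diseases falling in chapter i. H is 0 when all
#' members share one chapter and 1 when every member is from a distinct
#' chapter; the normalization uses the community size n (not the chapter
#' count), exactly as the score is defined.
#'
#' @param members character vector of 3-digit member codes.
#' @param chapter_map chapter ranges, as from [icd9_chapters()].
#' @return H in \[0, 1\]. A singleton community returns 0 (trivially
#'   homogeneous; log2(1) would be 0).
#' @export
h_score <- function(members, chapter_map = icd9_chapters()) {
  n <- length(members)
  if (n == 0L) stop("empty community")
  if (n == 1L) return(0)
  chap <- chapter_of(members, chapter_map) # errors on unmappable codes
  p <- as.numeric(table(chap)) / n
  sum(-p * log2(p)) / log2(n)
}

#' Community summary with chapter composition and mean fatality
#'
#' @param communities labeled table from [filter_and_label()].
#' @param partition node-level partition from [detect_communities()].
#' @param fatality_table optional per-code fatality, e.g. from
#'   [centrality_table()] (`code`, `fatality`).
#' @param chapter_map chapter ranges.
#' @return list with `summary` (`label`, `n`, `flow`, `h`, `mean_fatality`),
#'   `assignments` (`code`, `label`, `chapter`) and `incidence`
#'   (chapter x community member counts, long format).
#' @export
community_summary <- function(communities, partition, fatality_table = NULL,
                              chapter_map = icd9_chapters()) {
  assign <- data.table::rbindlist(c(
    list(data.table::data.table(code = character(), label = character())),
    lapply(seq_len(nrow(communities)), function(k) {
      data.table::data.table(code = communities$members[[k]],
                             label = communities$label[k])
    })))
  assign[, chapter := if (.N) chapter_of(code, chapter_map) else character()]
  incidence <- if (nrow(assign)) assign[, .(n = .N), by = .(chapter, label)]
               else data.table::data.table(chapter = character(), label = character(),
                                           n = integer())
  summary <- data.table::copy(communities)[, .(label, n, flow, h)]
  if (!is.null(fatality_table) && nrow(assign)) {
    ft <- data.table::as.data.table(fatality_table)
    m <- merge(assign, ft[, .(code, fatality)], by = "code", all.x = TRUE)
    mf <- m[, .(mean_fatality = mean(fatality, na.rm = TRUE)), by = label]
    summary <- merge(summary, mf, by = "label", all.x = TRUE, sort = FALSE)
  }
  list(summary = summary[], assignments = assign[], incidence = incidence[])
}
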