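# Node centralities, the 8-year fatality metric, and their rank correlations.

#' Weighted degree of TDN nodes
#'
#' The sum of outgoing and incoming patient counts (edge weights) of a
#' disease; for a reciprocal pair both directions count.
#'
#' @param tdn a `tdn` object.
#' @param node optional single code; when given, returns a scalar (error if
#'   the node is not in the network).
#' @return named numeric vector over all nodes, or a scalar.
#' @export
weighted_degree <- function(tdn, node = NULL) {
  e <- tdn$edges
  out <- e[, .(k = sum(w)), by = .(code = source)]
  inc <- e[, .(k = sum(w)), by = .(code = target)]
  both <- rbind(out, inc)[, .(k_w = sum(k)), by = code]
  kw <- stats::setNames(rep(0, nrow(tdn$nodes)), tdn$nodes$code)
  kw[both$code] <- both$k_w
  if (!is.null(node)) {
    if (!node %in% names(kw)) stop("unknown node: ", node)
    return(unname(kw[node]))
  }
  kw
}

#' PageRank flow of TDN nodes
#'
#' Stationary density of damped random walkers on the directed network,
#' with transition probability from i proportional to w_ij, uniform
#' teleportation, and uniform redistribution from dangling nodes.
#'
#' @param tdn a `tdn` object.
#' @param damping damping factor (default 0.85).
#' @return named numeric vector summing to 1.
#' @export
tdn_pagerank <- function(tdn, damping = 0.85) {
  g <- tdn_igraph(tdn)
  if (igraph::vcount(g) == 0L) stop("empty network")
  pr <- igraph::page_rank(g, damping = damping, weights = igraph::E(g)$weight,
                          directed = TRUE)$vector
  pr
}

#' Betweenness centrality of TDN nodes
#'
#' Directed betweenness on shortest paths. With `weighted = TRUE` (default)
#' the edge distance is 1/w, so heavily travelled edges are short, matching
#' the trajectory metric; `weighted = FALSE` uses hop counts. Normalized by
#' (n-1)(n-2).
#'
#' @param tdn a `tdn` object.
#' @param weighted use 1/w distances (default) or unit distances.
#' @return named numeric vector in \[0, 1\].
#' @export
tdn_betweenness <- function(tdn, weighted = TRUE) {
  g <- tdn_igraph(tdn)
  if (igraph::vcount(g) == 0L) stop("empty network")
  w <- if (weighted) 1 / igraph::E(g)$weight else NA
  igraph::betweenness(g, directed = TRUE, weights = w, normalized = TRUE)
}

#' Fixed-horizon fatality of a disease
#'
#' The fraction of patients that die within `horizon_years` of their first
#' diagnosis of `code`. The denominator is restricted to patients whose
#' follow-up covers the full horizon (first diagnosis at least
#' `horizon_years` before `data_end`) or who died within the horizon;
#' patients diagnosed too recently and still alive are not counted, so
#' incomplete follow-up does not dilute the estimate.
#'
#' @param paths from [extract_paths()].
#' @param meta patient metadata carrying `death_date`.
#' @param code single 3-digit code, or `NULL` for all codes in `paths`.
#' @param horizon_years horizon in years (default 8).
#' @param data_end last date covered by the records.
#' @return for a single code, the fraction in \[0, 1\] or `NA` if no patient
#'   is eligible; for `code = NULL`, a `data.table` (`code`, `n_eligible`,
#'   `n_dead`, `fatality`).
#' @export
fatality <- function(paths, meta, code = NULL, horizon_years = 8, data_end) {
  stopifnot(!missing(data_end))
  data_end <- as.Date(data_end)
  dt <- data.table::as.data.table(paths)
  query <- code
  if (!is.null(query)) dt <- dt[code %in% query]
  meta <- data.table::as.data.table(meta)
  first <- merge(dt[, .(patient_id, code, date)],
                 meta[, .(patient_id, death_date)], by = "patient_id", all.x = TRUE)
  horizon_days <- round(horizon_years * 365.25)
  first[, dead_in_horizon := !is.na(death_date) & death_date <= date + horizon_days]
  first[, eligible := (date + horizon_days <= data_end) | dead_in_horizon]
  res <- first[eligible == TRUE,
               .(n_eligible = .N, n_dead = sum(dead_in_horizon)), by = .(code)]
  res[, fatality := n_dead / n_eligible]
  if (is.null(code)) {
    data.table::setorder(res, code)
    return(res[])
  }
  if (nrow(res) == 0L) return(NA_real_)
  res$fatality
}

#' Spearman rank correlation with missing-pair removal
#'
#' Average-rank handling of ties; pairs where either value is missing are
#' dropped. Returns `rho = NA` when fewer than 3 complete pairs remain or a
#' vector is constant.
#'
#' @param x,y equal-length numeric vectors.
#' @return list with `rho`, `p`, `n` (complete pairs used).
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3 || length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Centrality and fatality table for all TDN nodes
#'
#' @param tdn a `tdn` object.
#' @param paths,meta,data_end passed to [fatality()]; omit all three to skip
#'   the fatality column.
#' @param damping PageRank damping.
#' @return `data.table` with columns `code`, `k_w`, `pr`, `bc` and, when
#'   fatality inputs are given, `fatality` (NA where undefined).
#' @export
centrality_table <- function(tdn, paths = NULL, meta = NULL, data_end = NULL,
                             damping = 0.85) {
  kw <- weighted_degree(tdn)
  pr <- tdn_pagerank(tdn, damping = damping)
  bc <- tdn_betweenness(tdn)
  out <- data.table::data.table(code = names(kw), k_w = unname(kw),
                                pr = unname(pr[names(kw)]), bc = unname(bc[names(kw)]))
  if (!is.null(paths) && !is.null(meta) && !is.null(data_end)) {
    fat <- fatality(paths, meta, code = NULL, data_end = data_end)
    out <- merge(out, fat[, .(code, fatality)], by = "code", all.x = TRUE)
  }
  data.table::setorder(out, code)
  out[]
}

#' Pairwise Spearman correlations among centrality/fatality columns
#'
#' Missing fatality values are dropped pairwise.
#' @param metrics table from [centrality_table()].
#' @return `data.table` with columns `x`, `y`, `rho`, `p`, `n`.
#' @export
correlation_table <- function(metrics) {
  cols <- intersect(c("k_w", "pr", "bc", "fatality"), names(metrics))
  combs <- utils::combn(cols, 2)
  res <- lapply(seq_len(ncol(combs)), function(k) {
    s <- spearman(metrics[[combs[1, k]]], metrics[[combs[2, k]]])
    data.table::data.table(x = combs[1, k], y = combs[2, k],
                           rho = s$rho, p = s$p, n = s$n)
  })
  data.table::rbindlist(res)
}
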