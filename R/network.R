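# Directed transition counting, edge significance, and the filtered
# Temporal Disease Network (TDN).

#' Count directed consecutive transitions and node prevalence
#'
#' Within each patient path, every code of a bucket is linked to every code
#' of the next bucket (consecutive distinct first-occurrence dates only; no
#' intra-bucket and no skip edges). Because first occurrences are unique per
#' patient, a patient contributes at most 1 to any ordered pair, so the edge
#' weight w_ij is the number of patients progressing from i to j.
#'
#' @param paths from [extract_paths()].
#' @return list with `edges` (`data.table`: `source`, `target`, `w`) and
#'   `nodes` (`data.table`: `code`, `N` = number of patients whose path
#'   contains the code).
#' @export
count_transitions <- function(paths) {
  dt <- data.table::as.data.table(paths)
  nodes <- dt[, .(N = data.table::uniqueN(patient_id)), by = .(code)]
  data.table::setnames(nodes, "code", "code")
  if (nrow(dt) == 0L) {
    return(list(edges = data.table::data.table(source = character(), target = character(),
                                               w = integer()),
                nodes = nodes))
  }
  a <- dt[, .(patient_id, code, bucket)]
  b <- data.table::copy(a)[, bucket := bucket - 1L]
  pairs <- merge(a, b, by = c("patient_id", "bucket"), allow.cartesian = TRUE,
                 suffixes = c("_src", "_tgt"))
  edges <- pairs[, .(w = .N), by = .(source = code_src, target = code_tgt)]
  data.table::setorder(edges, source, target)
  data.table::setorder(nodes, code)
  list(edges = edges[], nodes = nodes[])
}

#' 2x2 contingency table for a directed disease pair
#'
#' Over the population of patient-level transition events: `a` = events
#' i -> j, `b` = source i but other target, `c` = target j but other source,
#' `d` = neither.
#'
#' @param i,j 3-digit source and target codes, `i != j`.
#' @param edges transition counts from [count_transitions()]`$edges`.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
build_contingency <- function(i, j, edges) {
  if (identical(i, j)) stop("self-transitions are not modeled (i == j)")
  edges <- data.table::as.data.table(edges)
  total <- sum(edges$w)
  a <- edges[source == i & target == j, sum(w)]
  row_i <- edges[source == i, sum(w)]
  col_j <- edges[target == j, sum(w)]
  c(a = as.integer(a), b = as.integer(row_i - a),
    c = as.integer(col_j - a), d = as.integer(total - row_i - col_j + a))
}

#' One-sided Fisher exact test (enrichment of the i -> j cell)
#'
#' Exact hypergeometric tail probability P(X >= a) with all margins fixed:
#' the significance of the tendency of the source disease to precede the
#' target. Vectorized over table cells.
#'
#' @param a,b,c,d non-negative integer cell counts (recycled to a common
#'   length).
#' @return p-values in (0, 1]; an all-zero table gives 1 (no evidence).
#' @export
fisher_one_sided <- function(a, b, c, d) {
  stopifnot(all(a >= 0), all(b >= 0), all(c >= 0), all(d >= 0))
  # X ~ Hypergeometric(m = a+b successes, n = c+d failures, k = a+c draws)
  stats::phyper(a - 1, m = a + b, n = c + d, k = a + c, lower.tail = FALSE)
}

#' Phi coefficient of a 2x2 table
#'
#' (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d)); any zero marginal yields 0 by
#' convention (the association is undefined; 0 avoids NaN propagation).
#'
#' @inheritParams fisher_one_sided
#' @return phi in \[-1, 1\], vectorized.
#' @export
phi_coefficient <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  denom2 <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(denom2 == 0, 0, (a * d - b * c) / sqrt(denom2))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate correction over the family of tested edges.
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric())
  stats::p.adjust(p, method = "BH")
}

#' Build the candidate edge table with statistics
#'
#' Attaches the 2x2 table, one-sided Fisher p and phi to every observed
#' directed transition pair. The table cells follow the transition-event
#' construction of [build_contingency()] but are computed vectorized from
#' the row/column margins.
#'
#' @param transitions list from [count_transitions()].
#' @return `data.table` with columns `source`, `target`, `w`, `a`, `b`, `c`,
#'   `d`, `p`, `phi`.
#' @export
edge_statistics <- function(transitions) {
  edges <- data.table::copy(transitions$edges)
  if (nrow(edges) == 0L) {
    return(data.table::data.table(source = character(), target = character(), w = integer(),
                                  a = integer(), b = integer(), c = integer(), d = integer(),
                                  p = numeric(), phi = numeric()))
  }
  total <- sum(edges$w)
  edges[, out_i := sum(w), by = source]
  edges[, in_j := sum(w), by = target]
  edges[, `:=`(a = w, b = out_i - w, c = in_j - w, d = total - out_i - in_j + w)]
  edges[, `:=`(p = fisher_one_sided(a, b, c, d), phi = phi_coefficient(a, b, c, d))]
  edges[, c("out_i", "in_j") := NULL]
  edges[]
}

#' Nearest-rank percentile
#'
#' The smallest value v such that at least P percent of the observations are
#' <= v (nearest-rank definition: the ceiling(P/100 * n)-th order statistic).
#' @param x numeric vector, `length(x) >= 1`.
#' @param probs percentile in \[0, 100\].
#' @return the threshold value.
#' @export
nearest_rank_percentile <- function(x, probs) {
  stopifnot(length(x) >= 1, probs >= 0, probs <= 100)
  if (probs == 0) return(min(x))
  sort(x)[ceiling(probs / 100 * length(x))]
}

#' Apply the TDN filters
#'
#' Removal order: (1) nodes below the prevalence percentile (or an explicit
#' minimum patient count) and all incident edges; (2) edges carried by fewer
#' than `min_pair` patients; (3) edges incident to a death-diagnosis code
#' (likely erroneous entries); (4) Benjamini-Hochberg correction over the
#' surviving (tested) family, dropping edges with adjusted p >= alpha.
#' Counts removed at each stage are recorded in the provenance.
#'
#' @param edges candidate edges from [edge_statistics()].
#' @param nodes node prevalence table from [count_transitions()]`$nodes`.
#' @param alpha significance level for the adjusted p-value (default 0.05).
#' @param node_percentile prevalence percentile below which nodes are
#'   dropped (default 10; nearest-rank).
#' @param explicit_min_node explicit minimum patient count per node,
#'   overriding the percentile when given.
#' @param min_pair minimum number of patients per directed pair (default 100).
#' @param death_codes 3-digit codes treated as death diagnoses; edges in
#'   either direction incident to any are dropped (default "798", sudden
#'   death of unknown cause).
#' @return a `tdn` object: list with `nodes` (`code`, `N`), `edges`
#'   (`source`, `target`, `w`, `a`..`d`, `p`, `p_adj`, `phi`) and
#'   `provenance` (parameters plus nodes/edges removed at each stage).
#' @export
apply_filters <- function(edges, nodes, alpha = 0.05, node_percentile = 10,
                          explicit_min_node = NULL, min_pair = 100,
                          death_codes = "798") {
  edges <- data.table::as.data.table(edges)
  nodes <- data.table::as.data.table(nodes)
  if (length(death_codes) && !all(grepl("^[0-9]{3}$", death_codes))) {
    stop("death_codes must be normalized 3-digit codes")
  }
  prov <- list(params = list(alpha = alpha, node_percentile = node_percentile,
                             explicit_min_node = explicit_min_node,
                             min_pair = min_pair, death_codes = death_codes),
               input = list(nodes = nrow(nodes), edges = nrow(edges)))

  # (1) node prevalence
  thr <- if (!is.null(explicit_min_node)) explicit_min_node
         else if (nrow(nodes)) nearest_rank_percentile(nodes$N, node_percentile)
         else 0
  keep_nodes <- nodes[N >= thr]
  prov$node_prevalence <- list(threshold = thr,
                               nodes_removed = nrow(nodes) - nrow(keep_nodes))
  n0 <- nrow(edges)
  edges <- edges[source %in% keep_nodes$code & target %in% keep_nodes$code]
  prov$node_prevalence$edges_removed <- n0 - nrow(edges)

  # (2) pair count
  n0 <- nrow(edges)
  edges <- edges[w >= min_pair]
  prov$pair_count <- list(edges_removed = n0 - nrow(edges))

  # (3) death diagnoses
  n0 <- nrow(edges)
  edges <- edges[!(source %in% death_codes) & !(target %in% death_codes)]
  prov$death_codes <- list(edges_removed = n0 - nrow(edges))

  # (4) significance over the tested family
  edges[, p_adj := bh_adjust(p)]
  n0 <- nrow(edges)
  prov$bh_family_size <- n0
  edges <- edges[p_adj < alpha]
  prov$significance <- list(edges_removed = n0 - nrow(edges))

  used <- union(edges$source, edges$target)
  out_nodes <- keep_nodes[code %in% used]
  prov$output <- list(nodes = nrow(out_nodes), edges = nrow(edges))
  data.table::setcolorder(edges, c("source", "target", "w", "a", "b", "c", "d",
                                   "p", "p_adj", "phi"))
  structure(list(nodes = out_nodes[], edges = edges[], provenance = prov),
            class = "tdn")
}

#' Build the Temporal Disease Network from paths
#'
#' Convenience wrapper: transition counting, edge statistics and filtering.
#' @param paths from [extract_paths()].
#' @param ... filter parameters passed to [apply_filters()].
#' @return a `tdn` object.
#' @export
build_tdn <- function(paths, ...) {
  tr <- count_transitions(paths)
  apply_filters(edge_statistics(tr), tr$nodes, ...)
}

#' @export
print.tdn <- function(x, ...) {
  cat(sprintf("Temporal Disease Network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  pr <- x$provenance
  cat(sprintf("  filters: prevalence (thr %s): -%d nodes/-%d edges; pair<%s: -%d; death codes: -%d; BH alpha %s: -%d\n",
              format(pr$node_prevalence$threshold), pr$node_prevalence$nodes_removed,
              pr$node_prevalence$edges_removed, format(pr$params$min_pair),
              pr$pair_count$edges_removed, pr$death_codes$edges_removed,
              format(pr$params$alpha), pr$significance$edges_removed))
  invisible(x)
}

#' Convert a TDN to an igraph graph
#'
#' Directed, with edge attributes `weight` (= w), `p_adj`, `phi` and node
#' attribute `prevalence`. Retained nodes with no surviving edges are kept
#' as isolates.
#' @param tdn a `tdn` object.
#' @return an `igraph` graph.
#' @export
tdn_igraph <- function(tdn) {
  stopifnot(inherits(tdn, "tdn"))
  g <- igraph::graph_from_data_frame(
    tdn$edges[, .(from = source, to = target, weight = w, p_adj, phi)],
    directed = TRUE, vertices = tdn$nodes[, .(name = code, prevalence = N)])
  g
}

#' Write the TDN edge list (TSV) and graph (GraphML)
#'
#' @param tdn a `tdn` object.
#' @param edge_file TSV path (columns source, target, w, a, b, c, d, p,
#'   p_adj, phi), or `NULL` to skip.
#' @param graphml_file GraphML path or `NULL`.
#' @export
write_tdn <- function(tdn, edge_file = NULL, graphml_file = NULL) {
  if (!is.null(edge_file)) data.table::fwrite(tdn$edges, edge_file, sep = "\t")
  if (!is.null(graphml_file)) igraph::write_graph(tdn_igraph(tdn), graphml_file, format = "graphml")
  invisible(tdn)
}
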