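# Independent oracles used to check the package implementations. These are
# deliberately naive (enumeration, dense iteration) and share no code with
# the functions they verify.

# exhaustive hypergeometric upper tail: P(X >= a) with all margins fixed,
# computed as a sum of choose() products
hyper_tail_oracle <- function(a, b, c, d) {
  R <- a + b; C <- a + c; N <- a + b + c + d
  if (N == 0) return(1)
  xs <- a:min(R, C)
  if (a > min(R, C)) return(0)
  sum(choose(R, xs) * choose(N - R, C - xs)) / choose(N, C)
}

# Benjamini-Hochberg step-up by explicit rank arithmetic
bh_oracle <- function(p) {
  m <- length(p)
  if (!m) return(numeric())
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# dense power-iteration PageRank on a weight matrix W (W[i,j] = w of i->j);
# dangling rows redistribute uniformly, uniform teleportation
pagerank_oracle <- function(W, damping = 0.85, tol = 1e-14, max_iter = 10000) {
  n <- nrow(W)
  P <- matrix(0, n, n)
  rs <- rowSums(W)
  for (i in seq_len(n)) {
    P[i, ] <- if (rs[i] > 0) W[i, ] / rs[i] else 1 / n
  }
  x <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    x_new <- damping * drop(crossprod(P, x)) + (1 - damping) / n
    if (sum(abs(x_new - x)) < tol) return(x_new)
    x <- x_new
  }
  x
}

# all simple directed paths from `from` to `to` over an edge data.frame
# (source, target, dist); returns list of list(nodes, cost)
simple_paths_oracle <- function(edges, from, to) {
  adj <- split(seq_len(nrow(edges)), edges$source)
  out <- list()
  walk <- function(node, visited, cost, nodes) {
    if (node == to) {
      out[[length(out) + 1]] <<- list(nodes = nodes, cost = cost)
      return(invisible())
    }
    for (ei in adj[[node]]) {
      nxt <- edges$target[ei]
      if (nxt %in% visited) next
      walk(nxt, c(visited, nxt), cost + edges$dist[ei], c(nodes, nxt))
    }
  }
  walk(from, from, 0, from)
  out
}

# brute-force directed betweenness by shortest-path enumeration with 1/w
# distances, normalized by (n-1)(n-2); ties counted at exact FP equality
# (fixtures use power-of-two weights so path costs are exact)
betweenness_oracle <- function(edges, nodes) {
  edges$dist <- 1 / edges$w
  n <- length(nodes)
  bc <- stats::setNames(rep(0, n), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    paths <- simple_paths_oracle(edges, s, t)
    if (!length(paths)) next
    costs <- vapply(paths, `[[`, numeric(1), "cost")
    best <- paths[costs == min(costs)]
    sigma <- length(best)
    inner <- unlist(lapply(best, function(p) setdiff(p$nodes, c(s, t))))
    if (length(inner)) {
      tab <- table(inner)
      bc[names(tab)] <- bc[names(tab)] + as.numeric(tab) / sigma
    }
  }
  if (n > 2) bc <- bc / ((n - 1) * (n - 2))
  bc
}

# average-rank Spearman: rank both vectors, then Pearson
spearman_oracle <- function(x, y) {
  stats::cor(rank(x), rank(y), method = "pearson")
}

# wrap an arbitrary weighted directed edge list as a tdn object so the
# graph-facing functions can be driven by hand-built fixtures
toy_tdn <- function(edges, nodes = NULL) {
  edges <- data.table::as.data.table(edges)
  if (is.null(nodes)) nodes <- sort(unique(c(edges$source, edges$target)))
  structure(list(
    nodes = data.table::data.table(code = nodes, N = rep(1000L, length(nodes))),
    edges = data.table::data.table(source = edges$source, target = edges$target,
                                   w = as.numeric(edges$w), p_adj = 0, phi = 0),
    provenance = list()), class = "tdn")
}

# random small weighted digraph with power-of-two weights (exact 1/w sums)
random_toy_graph <- function(n_nodes, p_edge = 0.45) {
  nodes <- sprintf("%03d", 100 + seq_len(n_nodes))
  grid <- expand.grid(source = nodes, target = nodes, stringsAsFactors = FALSE)
  grid <- grid[grid$source != grid$target, ]
  grid <- grid[stats::runif(nrow(grid)) < p_edge, ]
  grid$w <- 2^sample(0:6, nrow(grid), replace = TRUE)
  grid
}
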