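# Brute-force reference implementations, written against the definitions and
# independent of the package internals (and of igraph): breadth-first
# distances plus exhaustive enumeration of shortest paths. Only usable on
# small graphs (<= ~12 nodes).

oracleAdj <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  if (NROW(edges)) {
    for (i in seq_len(NROW(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      if (a == b) next
      if (!b %in% adj[[a]]) adj[[a]] <- c(adj[[a]], b)
      if (!a %in% adj[[b]]) adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

oracleBFS <- function(adj, s) {
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  dist
}

# All shortest s-t paths, by depth-first enumeration guided by distances to
# t (every step must decrease the remaining distance by exactly one, so the
# walk enumerates precisely the shortest paths).
oracleShortestPaths <- function(adj, s, t) {
  dist_t <- oracleBFS(adj, t)
  if (is.infinite(dist_t[s])) return(list())
  paths <- list()
  walk <- function(v, path) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (dist_t[w] == dist_t[v] - 1) walk(w, c(path, w))
    }
  }
  walk(s, s)
  paths
}

# Betweenness by direct path counting: for every unordered pair, the
# fraction of shortest paths through each interior node.
oracleBetweenness <- function(nodes, edges) {
  adj <- oracleAdj(nodes, edges)
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  if (length(nodes) < 3L) return(bc)
  for (i in seq_len(length(nodes) - 1L)) {
    for (j in seq.int(i + 1L, length(nodes))) {
      paths <- oracleShortestPaths(adj, nodes[i], nodes[j])
      if (!length(paths)) next
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        bc[interior] <- bc[interior] + 1 / length(paths)
      }
    }
  }
  bc
}

# Node set of all-shortest-path sampling: seeds present in the graph plus
# every node on any shortest path between a pair of present seeds.
oracleSampledNodes <- function(nodes, edges, seeds) {
  adj <- oracleAdj(nodes, edges)
  seeds <- intersect(seeds, nodes)
  keep <- seeds
  if (length(seeds) >= 2L) {
    for (i in seq_len(length(seeds) - 1L)) {
      for (j in seq.int(i + 1L, length(seeds))) {
        for (p in oracleShortestPaths(adj, seeds[i], seeds[j]))
          keep <- union(keep, p)
      }
    }
  }
  sort(keep)
}

# Induced edge set (canonical two-column data frame) of a node subset.
oracleInducedEdges <- function(edges, keep) {
  if (!NROW(edges))
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  sel <- a %in% keep & b %in% keep & a != b
  df <- unique(data.frame(a = a[sel], b = b[sel], stringsAsFactors = FALSE))
  df <- df[order(df$a, df$b), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Small random simple graph for property batteries: 4-12 nodes, moderate
# density, reproducible from one integer.
randomTestGraph <- function(seed) {
  set.seed(seed)
  n <- sample(4:12, 1)
  nodes <- sprintf("n%02d", seq_len(n))
  p <- stats::runif(1, 0.25, 0.6)
  pairs <- t(utils::combn(nodes, 2))
  edges <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  list(nodes = nodes, edges = edges)
}
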