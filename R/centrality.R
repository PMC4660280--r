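#' Betweenness centrality table of a network
#'
#' For each node v, BC(v) is the sum over unordered node pairs (s, t) with
#' s != v != t of sigma_st(v) / sigma_st, where sigma_st counts shortest s-t
#' paths and sigma_st(v) those passing through v as an interior node (path
#' endpoints earn no credit). Pairs in different components contribute 0.
#' Computed with the Brandes algorithm (\pkg{igraph}). Unnormalized values
#' are in pair-count units and bounded by (n-1)(n-2)/2; the normalized
#' variant divides by that bound and is intended for display only — the
#' differential statistic requires raw counts (see [deltaBC()]).
#'
#' @param net a [ProteinNetwork-class].
#' @param normalized divide by (n-1)(n-2)/2.
#' @return a [CentralityTable-class] labelled after the network.
#' @examples
#' path3 <- ProteinNetwork(cbind(c("a", "b"), c("b", "c")))
#' bcValues(betweennessTable(path3))  # b brokers the single a-c path
#' @export
betweennessTable <- function(net, normalized = FALSE) {
  stopifnot(is(net, "ProteinNetwork"))
  g <- asIgraph(net)
  n <- vcount(g)
  if (n == 0L) {
    bc <- stats::setNames(numeric(0), character(0))
  } else if (n < 3L) {
    bc <- stats::setNames(numeric(n), V(g)$name)
  } else {
    bc <- betweenness(g, directed = FALSE, normalized = normalized)
  }
  new("CentralityTable", networkLabel = networkLabel(net), bc = bc,
      normalized = normalized, nNodes = as.integer(n))
}

#' Write a centrality table as TSV
#'
#' Two columns (\code{node}, \code{bc}), sorted by descending betweenness
#' with ties broken by node identifier for deterministic output.
#'
#' @param tab a [CentralityTable-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeCentrality <- function(tab, path) {
  bc <- bcValues(tab)
  ord <- order(-bc, names(bc))
  df <- data.frame(node = names(bc)[ord], bc = unname(bc)[ord],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
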