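#' Union of two process sub-networks
#'
#' Merges two networks by identifier equality: nodes are the union of the two
#' node sets and edges the union of the two edge sets. When the two
#' sub-networks were sampled from a common background interactome, pass it as
#' \code{background} to additionally restore every background edge whose
#' endpoints were sampled into \emph{different} sub-networks, i.e. the union
#' becomes the induced subgraph of the background on the combined node set.
#' Those cross-process interactions are real curated edges and are exactly
#' the crosstalk the differential-betweenness statistic measures; at full
#' interactome scale the two conventions nearly coincide because the
#' sub-networks overlap heavily, but on small or disjoint sub-networks only
#' the completed union lets cross-process shortest paths exist (see the
#' package vignette).
#'
#' @param a,b [ProteinNetwork-class] objects.
#' @param background optional [ProteinNetwork-class] both sub-networks were
#'   sampled from; its node set must cover both.
#' @param label label of the result.
#' @return a [ProteinNetwork-class].
#' @examples
#' a <- ProteinNetwork(cbind(c("x", "y"), c("y", "z")), label = "auto")
#' b <- ProteinNetwork(cbind("y", "w"), label = "mito")
#' numEdges(unionNetwork(a, b))  # 3
#' @export
unionNetwork <- function(a, b, background = NULL, label = "union") {
  stopifnot(is(a, "ProteinNetwork"), is(b, "ProteinNetwork"))
  nodes <- union(networkNodes(a), networkNodes(b))
  if (is.null(background)) {
    edges <- unique(rbind(edgeTable(a), edgeTable(b)))
    return(ProteinNetwork(edges, nodes = nodes, label = label))
  }
  stopifnot(is(background, "ProteinNetwork"))
  if (!all(nodes %in% networkNodes(background)))
    stop("the union node set is not contained in the background network")
  g <- induced_subgraph(asIgraph(background), nodes)
  new("ProteinNetwork", graph = g, label = label)
}
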