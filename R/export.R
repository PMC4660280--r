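#' Export a network as a two-column edge list
#'
#' Tab-separated, canonical order (each pair sorted, rows sorted), with a
#' header; isolated nodes do not appear (use GraphML to preserve them).
#'
#' @param net a [ProteinNetwork-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(net, path) {
  et <- edgeTable(net)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("a\tb", paste(et$a, et$b, sep = "\t")), con, sep = "\n")
  invisible(path)
}

#' Export a network as GraphML
#'
#' Preserves isolated nodes and optionally attaches per-node numeric
#' attributes (e.g. \code{bc_union}, \code{delta_bc}) for use in external
#' layout tools.
#'
#' @param net a [ProteinNetwork-class].
#' @param path output file path.
#' @param nodeAttrs optional named list of named numeric vectors; each is
#'   attached as a vertex attribute, matched by node identifier (nodes not
#'   covered get NA).
#' @return the path, invisibly.
#' @export
writeGraphML <- function(net, path, nodeAttrs = NULL) {
  g <- asIgraph(net)
  if (!is.null(nodeAttrs)) {
    for (nm in names(nodeAttrs)) {
      vals <- nodeAttrs[[nm]]
      g <- set_vertex_attr(g, nm, value = unname(vals[V(g)$name]))
    }
  }
  write_graph(g, path, format = "graphml")
  invisible(path)
}
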