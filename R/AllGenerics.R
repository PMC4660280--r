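#' Accessors for network, seed-list and centrality objects
#'
#' Small accessor generics in place of direct slot access.
#'
#' @param x a [ProteinNetwork-class], [SeedList-class],
#'   [CentralityTable-class] or [SamplingReport-class] object.
#' @return `networkLabel`: the provenance label; `networkNodes`: character
#'   vector of node identifiers; `edgeTable`: two-column character data frame
#'   of undirected edges in canonical order (each row sorted, rows sorted);
#'   `numNodes`/`numEdges`: integer counts; `asIgraph`: the underlying
#'   \pkg{igraph} graph; `seedName`/`seedMembers`: label and members of a
#'   seed list; `bcValues`: named numeric betweenness vector;
#'   `isNormalized`: normalization flag.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkLabel", function(x) standardGeneric("networkLabel"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))
#' @rdname accessors
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))
#' @rdname accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))
#' @rdname accessors
#' @export
setGeneric("seedName", function(x) standardGeneric("seedName"))
#' @rdname accessors
#' @export
setGeneric("seedMembers", function(x) standardGeneric("seedMembers"))
#' @rdname accessors
#' @export
setGeneric("bcValues", function(x) standardGeneric("bcValues"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname accessors
setMethod("networkLabel", "ProteinNetwork", function(x) x@label)

#' @rdname accessors
setMethod("networkNodes", "ProteinNetwork", function(x) {
  if (vcount(x@graph) == 0L) character(0) else V(x@graph)$name
})

#' @rdname accessors
setMethod("edgeTable", "ProteinNetwork", function(x) {
  el <- as_edgelist(x@graph, names = TRUE)
  if (nrow(el) == 0L)
    return(data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE))
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  ord <- order(a, b)
  data.frame(a = a[ord], b = b[ord], stringsAsFactors = FALSE)
})

#' @rdname accessors
setMethod("numNodes", "ProteinNetwork", function(x) vcount(x@graph))

#' @rdname accessors
setMethod("numEdges", "ProteinNetwork", function(x) ecount(x@graph))

#' @rdname accessors
setMethod("asIgraph", "ProteinNetwork", function(x) x@graph)

#' @rdname accessors
setMethod("seedName", "SeedList", function(x) x@name)

#' @rdname accessors
setMethod("seedMembers", "SeedList", function(x) x@members)

#' @rdname accessors
setMethod("networkLabel", "CentralityTable", function(x) x@networkLabel)

#' @rdname accessors
setMethod("bcValues", "CentralityTable", function(x) x@bc)

#' @rdname accessors
setMethod("isNormalized", "CentralityTable", function(x) x@normalized)

setMethod("show", "ProteinNetwork", function(object) {
  cat(sprintf("ProteinNetwork \"%s\": %d nodes, %d edges\n",
              object@label, vcount(object@graph), ecount(object@graph)))
})

setMethod("show", "SeedList", function(object) {
  m <- object@members
  preview <- paste(utils::head(m, 5), collapse = ", ")
  if (length(m) > 5) preview <- paste0(preview, ", ...")
  cat(sprintf("SeedList \"%s\": %d identifiers (%s)\n",
              object@name, length(m), preview))
})

setMethod("show", "CentralityTable", function(object) {
  cat(sprintf("CentralityTable for \"%s\": %d nodes (%s)\n",
              object@networkLabel, length(object@bc),
              if (object@normalized) "normalized" else "pair-count units"))
  if (length(object@bc)) {
    top <- sort(object@bc, decreasing = TRUE)
    top <- utils::head(top, 5)
    cat("  top:", paste(sprintf("%s=%.4g", names(top), top),
                        collapse = ", "), "\n")
  }
})

setMethod("show", "SamplingReport", function(object) {
  cat(sprintf(paste0("SamplingReport: %d seeds found, %d missing; ",
                     "%d pairs connected, %d disconnected\n"),
              length(object@seedsFound), length(object@seedsMissing),
              object@pairsConnected, object@pairsDisconnected))
})

setMethod("show", "PlantedBridgeSpec", function(object) {
  cat(sprintf(paste0("PlantedBridgeSpec: 2 x %d nodes (p=%g, %s), ",
                     "%d bridges (degree %d/side), %d seeds/community, ",
                     "decoy taxon %.0f%%, predicted %.0f%%, seed %d\n"),
              object@nPerCommunity, object@intraEdgeProb, object@attachment,
              object@nBridges, object@bridgeDegreePerSide,
              object@nSeedsPerCommunity, 100 * object@decoyTaxonFraction,
              100 * object@predictedFraction, object@rngSeed))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(paste0("SyntheticTruth: %d nodes (%d bridges), seed lists ",
                     "\"%s\" (%d) and \"%s\" (%d)\n"),
              length(object@communityOf), length(object@bridgeNodes),
              object@seedLists[[1]]@name, length(object@seedLists[[1]]@members),
              object@seedLists[[2]]@name,
              length(object@seedLists[[2]]@members)))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  cat("  mitab:      ", object@mitabPath, "\n")
  for (i in 1:2)
    cat(sprintf("  seeds[%s]: %s\n", names(object@seedListPaths)[i],
                object@seedListPaths[i]))
  cat("  output:     ", object@outputDir, "\n")
  cat(sprintf("  topK: %d, union completion: %s\n",
              object@topK, object@unionCompletion))
})

setMethod("show", "CurationPolicy", function(object) {
  cat(sprintf(paste0("CurationPolicy: taxon %d on both interactors%s, ",
                     "%d predicted-method codes%s\n"),
              object@requiredTaxid,
              if (object@requireBothTaxaMatch) " (unknown dropped)" else "",
              length(object@predictedMethodCodes),
              if (object@dropSelfLoops) ", self loops dropped" else ""))
})
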