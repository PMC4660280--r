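#' @import methods
#' @importFrom igraph V E vcount ecount graph_from_data_frame simplify
#'   is_simple is_directed as_edgelist induced_subgraph distances betweenness
#'   add_vertices components write_graph set_vertex_attr make_empty_graph
NULL

setOldClass("igraph")

#' ProteinNetwork: a simple undirected protein interaction graph
#'
#' Wraps an \pkg{igraph} graph that is guaranteed simple (no self loops, no
#' parallel edges), undirected, and named by protein identifier, together with
#' a provenance label (\code{"background"}, \code{"auto"}, \code{"mito"},
#' \code{"union"}, ...).
#'
#' @slot graph an undirected simple \pkg{igraph} graph with a \code{name}
#'   vertex attribute.
#' @slot label single character string naming the network's provenance.
#'
#' @seealso [ProteinNetwork()] for the constructor, [networkNodes()],
#'   [edgeTable()], [asIgraph()] for accessors.
#' @export
setClass("ProteinNetwork",
  representation(graph = "igraph", label = "character"))

setValidity("ProteinNetwork", function(object) {
  g <- object@graph
  msg <- character(0)
  if (length(object@label) != 1L || is.na(object@label))
    msg <- c(msg, "'label' must be a single non-NA string")
  if (is_directed(g))
    msg <- c(msg, "graph must be undirected")
  if (!is_simple(g))
    msg <- c(msg, "graph must be simple (no self loops or multi-edges)")
  if (vcount(g) > 0 && is.null(V(g)$name))
    msg <- c(msg, "graph vertices must be named")
  if (vcount(g) > 0 && anyDuplicated(V(g)$name))
    msg <- c(msg, "vertex names must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinNetwork from an edge table
#'
#' @param edges two-column character matrix or data frame of undirected edges
#'   (one row per interaction); may be NULL or zero-row for an edgeless
#'   network. Duplicate pairs in either orientation and self pairs are
#'   removed.
#' @param nodes optional character vector of node identifiers; nodes that
#'   appear in no edge are kept as isolated vertices.
#' @param label provenance label for the network.
#' @return a [ProteinNetwork-class] object.
#' @examples
#' net <- ProteinNetwork(cbind(c("A", "B"), c("B", "C")), label = "toy")
#' numEdges(net)
#' @export
ProteinNetwork <- function(edges = NULL, nodes = NULL, label = "network") {
  if (is.null(edges) || NROW(edges) == 0L) {
    el <- matrix(character(0), ncol = 2)
  } else {
    el <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(el) <- "character"
  }
  all_nodes <- unique(c(as.character(el), as.character(nodes)))
  g <- graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = if (length(all_nodes)) all_nodes else NULL)
  g <- simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  new("ProteinNetwork", graph = g, label = label)
}

#' SeedList: ordered process membership list
#'
#' Identifiers asserted to belong to one biological process (for example an
#' autophagy or a mitochondrial-dysfunction list). Order of first occurrence
#' is preserved; duplicates are not allowed.
#'
#' @slot name process label.
#' @slot members character vector of unique protein identifiers, non-empty.
#' @seealso [readSeedList()]
#' @export
setClass("SeedList",
  representation(name = "character", members = "character"))

setValidity("SeedList", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@members) == 0L)
    msg <- c(msg, "a seed list must contain at least one identifier")
  if (anyDuplicated(object@members))
    msg <- c(msg, "seed members must be unique")
  if (any(!nzchar(object@members)))
    msg <- c(msg, "seed members must be non-empty strings")
  if (length(msg)) msg else TRUE
})

#' @rdname SeedList-class
#' @param members character vector of identifiers (deduplicated, order kept).
#' @param name process label.
#' @export
SeedList <- function(members, name) {
  members <- as.character(members)
  new("SeedList", name = name, members = unique(members))
}

#' CurationPolicy: filters applied to parsed MITAB records
#'
#' Encodes the curation applied to a raw interaction table before network
#' construction: keep a single taxon, drop computationally predicted
#' interactions, drop self interactions.
#'
#' @slot requiredTaxid NCBI taxon that both interactors must carry
#'   (default 9606, human).
#' @slot predictedMethodCodes PSI-MI detection-method codes treated as
#'   computational predictions and removed.
#' @slot dropSelfLoops drop records whose two interactors resolve to the same
#'   identifier.
#' @slot requireBothTaxaMatch when TRUE (default) a record with an unknown
#'   taxon on either side is dropped; the strictest reading of a
#'   single-species filter.
#' @seealso [curationPolicy()], [curateInteractions()]
#' @export
setClass("CurationPolicy",
  representation(requiredTaxid = "integer",
                 predictedMethodCodes = "character",
                 dropSelfLoops = "logical",
                 requireBothTaxaMatch = "logical"))

setValidity("CurationPolicy", function(object) {
  msg <- character(0)
  if (length(object@requiredTaxid) != 1L || is.na(object@requiredTaxid))
    msg <- c(msg, "'requiredTaxid' must be a single taxon id")
  if (length(object@predictedMethodCodes) == 0L)
    msg <- c(msg, "'predictedMethodCodes' must be non-empty")
  if (length(object@dropSelfLoops) != 1L || is.na(object@dropSelfLoops))
    msg <- c(msg, "'dropSelfLoops' must be TRUE or FALSE")
  if (length(object@requireBothTaxaMatch) != 1L ||
      is.na(object@requireBothTaxaMatch))
    msg <- c(msg, "'requireBothTaxaMatch' must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' @rdname CurationPolicy-class
#' @param requiredTaxid NCBI taxon id both interactors must match.
#' @param predictedMethodCodes PSI-MI codes to treat as predictions.
#' @param dropSelfLoops drop self interactions.
#' @param requireBothTaxaMatch drop records with unknown taxa.
#' @export
curationPolicy <- function(requiredTaxid = 9606L,
                           predictedMethodCodes = .defaultPredictedCodes,
                           dropSelfLoops = TRUE,
                           requireBothTaxaMatch = TRUE) {
  new("CurationPolicy",
      requiredTaxid = as.integer(requiredTaxid),
      predictedMethodCodes = predictedMethodCodes,
      dropSelfLoops = dropSelfLoops,
      requireBothTaxaMatch = requireBothTaxaMatch)
}

#' CentralityTable: per-node betweenness for one network
#'
#' Betweenness centrality of every node of one network. Unnormalized values
#' are in pair-count units: the sum over unordered node pairs of the fraction
#' of shortest paths through the node as an interior vertex, bounded by
#' (n-1)(n-2)/2.
#'
#' @slot networkLabel label of the network the table was computed on.
#' @slot bc named numeric vector, one entry per network node.
#' @slot normalized whether values were divided by (n-1)(n-2)/2.
#' @slot nNodes node count of the source network (bound for validity).
#' @seealso [betweennessTable()], [bcValues()]
#' @export
setClass("CentralityTable",
  representation(networkLabel = "character", bc = "numeric",
                 normalized = "logical", nNodes = "integer"))

setValidity("CentralityTable", function(object) {
  msg <- character(0)
  if (is.null(names(object@bc)) && length(object@bc) > 0)
    msg <- c(msg, "'bc' must be named by node identifier")
  if (anyDuplicated(names(object@bc)))
    msg <- c(msg, "each node must appear exactly once")
  if (any(object@bc < 0))
    msg <- c(msg, "betweenness values must be non-negative")
  n <- object@nNodes
  bound <- if (object@normalized) 1 else max(0, (n - 1) * (n - 2) / 2)
  if (any(object@bc > bound + 1e-8))
    msg <- c(msg, sprintf("betweenness values exceed the bound %g", bound))
  if (length(msg)) msg else TRUE
})

#' SamplingReport: bookkeeping from shortest-path sampling
#'
#' @slot seedsFound seed identifiers present in the background network.
#' @slot seedsMissing seed identifiers absent from the background network.
#' @slot pairsConnected number of seed pairs joined by at least one path.
#' @slot pairsDisconnected number of seed pairs in different components.
#' @seealso [sampleShortestPaths()]
#' @export
setClass("SamplingReport",
  representation(seedsFound = "character", seedsMissing = "character",
                 pairsConnected = "integer", pairsDisconnected = "integer"))

setValidity("SamplingReport", function(object) {
  nf <- length(object@seedsFound)
  msg <- character(0)
  if (object@pairsConnected + object@pairsDisconnected != choose(nf, 2))
    msg <- c(msg, "pair counts must total choose(|seedsFound|, 2)")
  if (length(intersect(object@seedsFound, object@seedsMissing)))
    msg <- c(msg, "a seed cannot be both found and missing")
  if (length(msg)) msg else TRUE
})

#' PlantedBridgeSpec: parameters of the synthetic interactome generator
#'
#' Describes a two-community planted-bridge interactome: two within-community
#' random graphs joined only through dedicated bridge nodes, plus seed lists
#' drawn from each community, and MITAB decoy fractions exercising the
#' curation filters.
#'
#' @slot nPerCommunity nodes per community.
#' @slot intraEdgeProb within-community edge probability (Erdos-Renyi model).
#' @slot nBridges number of planted bridge nodes.
#' @slot bridgeDegreePerSide neighbours each bridge gets in each community.
#' @slot nSeedsPerCommunity seeds drawn uniformly per community.
#' @slot decoyTaxonFraction fraction of MITAB rows given a non-human taxon.
#' @slot predictedFraction fraction of MITAB rows given a predicted
#'   detection-method code (MI:0063).
#' @slot rngSeed integer seed driving every random draw.
#' @slot attachment \code{"uniform"} for Erdos-Renyi communities (default) or
#'   \code{"preferential"} for a Barabasi-Albert-style degree distribution.
#' @seealso [plantedBridgeSpec()], [generatePlantedBridge()]
#' @export
setClass("PlantedBridgeSpec",
  representation(nPerCommunity = "integer", intraEdgeProb = "numeric",
                 nBridges = "integer", bridgeDegreePerSide = "integer",
                 nSeedsPerCommunity = "integer",
                 decoyTaxonFraction = "numeric", predictedFraction = "numeric",
                 rngSeed = "integer", attachment = "character"))

setValidity("PlantedBridgeSpec", function(object) {
  msg <- character(0)
  if (object@nPerCommunity < 1L)
    msg <- c(msg, "'nPerCommunity' must be positive")
  if (object@intraEdgeProb <= 0 || object@intraEdgeProb > 1)
    msg <- c(msg, "'intraEdgeProb' must be in (0, 1]")
  if (object@nBridges < 0L)
    msg <- c(msg, "'nBridges' must be non-negative")
  if (object@bridgeDegreePerSide < 1L ||
      object@bridgeDegreePerSide > object@nPerCommunity)
    msg <- c(msg, "'bridgeDegreePerSide' must be in 1..nPerCommunity")
  if (object@nSeedsPerCommunity < 1L ||
      object@nSeedsPerCommunity > object@nPerCommunity)
    msg <- c(msg, "'nSeedsPerCommunity' must be in 1..nPerCommunity")
  for (s in c("decoyTaxonFraction", "predictedFraction")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("'%s' must be in [0, 1]", s))
  }
  if (!object@attachment %in% c("uniform", "preferential"))
    msg <- c(msg, "'attachment' must be \"uniform\" or \"preferential\"")
  if (length(msg)) msg else TRUE
})

#' @rdname PlantedBridgeSpec-class
#' @param nPerCommunity,intraEdgeProb,nBridges,bridgeDegreePerSide
#'   graph-structure parameters, see slots.
#' @param nSeedsPerCommunity,decoyTaxonFraction,predictedFraction,rngSeed
#'   sampling parameters, see slots.
#' @param attachment community wiring model.
#' @export
plantedBridgeSpec <- function(nPerCommunity = 30L, intraEdgeProb = 0.15,
                              nBridges = 2L, bridgeDegreePerSide = 3L,
                              nSeedsPerCommunity = 5L,
                              decoyTaxonFraction = 0, predictedFraction = 0,
                              rngSeed = 1L, attachment = "uniform") {
  new("PlantedBridgeSpec",
      nPerCommunity = as.integer(nPerCommunity),
      intraEdgeProb = intraEdgeProb,
      nBridges = as.integer(nBridges),
      bridgeDegreePerSide = as.integer(bridgeDegreePerSide),
      nSeedsPerCommunity = as.integer(nSeedsPerCommunity),
      decoyTaxonFraction = decoyTaxonFraction,
      predictedFraction = predictedFraction,
      rngSeed = as.integer(rngSeed),
      attachment = attachment)
}

#' SyntheticTruth: ground truth of a generated interactome
#'
#' @slot communityOf named character vector mapping each node to
#'   \code{"1"}, \code{"2"} or \code{"bridge"}.
#' @slot bridgeNodes identifiers of the planted bridge nodes.
#' @slot seedLists list of two [SeedList-class] objects drawn from
#'   communities 1 and 2.
#' @slot edgeAnnotations data frame (one row per edge) with the MITAB fields
#'   the generator drew: columns \code{a}, \code{b}, \code{taxid_a},
#'   \code{taxid_b}, \code{method}.
#' @seealso [generatePlantedBridge()], [writeMitab()]
#' @export
setClass("SyntheticTruth",
  representation(communityOf = "character", bridgeNodes = "character",
                 seedLists = "list", edgeAnnotations = "data.frame"))

setValidity("SyntheticTruth", function(object) {
  msg <- character(0)
  labelled_bridges <- names(object@communityOf)[object@communityOf == "bridge"]
  if (!setequal(labelled_bridges, object@bridgeNodes))
    msg <- c(msg, "'bridgeNodes' must equal nodes labelled \"bridge\"")
  if (length(object@seedLists) != 2L ||
      !all(vapply(object@seedLists, is, logical(1), "SeedList")))
    msg <- c(msg, "'seedLists' must hold exactly two SeedList objects")
  else {
    for (sl in object@seedLists) {
      comm <- object@communityOf[sl@members]
      if (any(is.na(comm)) || any(comm == "bridge"))
        msg <- c(msg, "seeds must be drawn from communities 1 and 2 only")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RunConfig: configuration of an end-to-end pipeline run
#'
#' @slot mitabPath path to the MITAB interaction table.
#' @slot seedListPaths named character vector of exactly two seed-list files;
#'   the names are the process labels (the differential statistic subtracts
#'   exactly two sub-network centralities).
#' @slot curation a [CurationPolicy-class].
#' @slot idPreference identifier columns tried in order when naming nodes.
#' @slot topK how many top-ranked targets to report.
#' @slot outputDir directory all artifacts are written under.
#' @slot normalizedReport also emit display-normalized centrality tables.
#' @slot unionCompletion \code{"background"} (default) to complete the union
#'   of the two sub-networks against the curated background, or \code{"none"}
#'   for the plain edge union. See [unionNetwork()].
#' @seealso [runConfig()], [runCrosstalk()]
#' @export
setClass("RunConfig",
  representation(mitabPath = "character", seedListPaths = "character",
                 curation = "CurationPolicy", idPreference = "character",
                 topK = "integer", outputDir = "character",
                 normalizedReport = "logical", unionCompletion = "character"))

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (length(object@seedListPaths) != 2L)
    msg <- c(msg, "exactly two seed lists are required")
  labs <- names(object@seedListPaths)
  if (is.null(labs) || any(!nzchar(labs)) || anyDuplicated(labs))
    msg <- c(msg, "seed list paths must carry two distinct process labels")
  if (object@topK < 1L)
    msg <- c(msg, "'topK' must be at least 1")
  if (!object@unionCompletion %in% c("background", "none"))
    msg <- c(msg, "'unionCompletion' must be \"background\" or \"none\"")
  if (length(msg)) msg else TRUE
})
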