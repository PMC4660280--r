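#' Shortest-path sub-network sampling
#'
#' Extracts the process sub-network anchored on a seed list: the node set is
#' the union, over every unordered pair of seeds present in the background,
#' of every node lying on \emph{any} shortest path between that pair
#' (seed endpoints included); the edge set is the induced subgraph of the
#' background on that node set, so an edge between two sampled nodes is kept
#' even when it lies on no shortest path. Seeds absent from the background
#' are excluded and reported; seed pairs in different components contribute
#' nothing and are counted as disconnected; a seed that is present but
#' isolated from all other seeds still enters the node set (seeds are
#' asserted process members).
#'
#' A node v is on some shortest s-t path iff d(s,v) + d(v,t) = d(s,t), which
#' is how the sample is computed (two breadth-first distance fields per seed,
#' no path enumeration).
#'
#' @param background a [ProteinNetwork-class] to sample from.
#' @param seeds a [SeedList-class].
#' @return list with elements \code{network} (the sampled
#'   [ProteinNetwork-class], labelled by the seed-list name) and
#'   \code{report} (a [SamplingReport-class]).
#' @examples
#' bg <- ProteinNetwork(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "e")),
#'                      label = "background")
#' res <- sampleShortestPaths(bg, SeedList(c("a", "e"), "toy"))
#' networkNodes(res$network)
#' @export
sampleShortestPaths <- function(background, seeds) {
  stopifnot(is(background, "ProteinNetwork"), is(seeds, "SeedList"))
  g <- asIgraph(background)
  members <- seedMembers(seeds)
  found <- members[members %in% networkNodes(background)]
  missing <- setdiff(members, found)
  if (length(found) == 0L)
    stop("no seed of list \"", seedName(seeds),
         "\" is present in the background network (", length(missing),
         " missing)")
  if (length(missing))
    message(sprintf("seed list \"%s\": %d seed(s) absent from background: %s",
                    seedName(seeds), length(missing),
                    paste(missing, collapse = ", ")))

  keep <- found
  connected <- 0L
  disconnected <- 0L
  if (length(found) >= 2L) {
    D <- distances(g, v = found, to = V(g))
    nodes <- colnames(D)
    for (i in seq_len(length(found) - 1L)) {
      for (j in seq.int(i + 1L, length(found))) {
        dst <- D[i, found[j]]
        if (is.finite(dst)) {
          connected <- connected + 1L
          keep <- c(keep, nodes[D[i, ] + D[j, ] == dst])
        } else {
          disconnected <- disconnected + 1L
        }
      }
    }
    keep <- unique(keep)
  }
  sub <- induced_subgraph(g, keep)
  report <- new("SamplingReport", seedsFound = found, seedsMissing = missing,
                pairsConnected = connected, pairsDisconnected = disconnected)
  list(network = new("ProteinNetwork", graph = sub, label = seedName(seeds)),
       report = report)
}

#' Write a sampling report as TSV
#'
#' @param report a [SamplingReport-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSamplingReport <- function(report, path) {
  df <- data.frame(
    field = c("seeds_found", "seeds_missing", "pairs_connected",
              "pairs_disconnected"),
    value = c(paste(report@seedsFound, collapse = ","),
              paste(report@seedsMissing, collapse = ","),
              report@pairsConnected, report@pairsDisconnected),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
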