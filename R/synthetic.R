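## All randomness in the package lives in this file. Draws run through one
## seeded stream per generator call; the caller's RNG state is untouched.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.communityEdges <- function(ids, p, attachment) {
  n <- length(ids)
  if (n < 2L) return(matrix(character(0), ncol = 2))
  if (attachment == "uniform") {
    pairs <- t(utils::combn(ids, 2))
    pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
  } else {
    ## preferential attachment with the same expected edge count as the
    ## Erdos-Renyi variant: each incoming node attaches m = ceil(p*(n-1)/2)
    ## times to earlier nodes, weighted by current degree (+1 smoothing)
    m <- max(1L, ceiling(p * (n - 1) / 2))
    deg <- stats::setNames(numeric(n), ids)
    el <- NULL
    for (k in 2:n) {
      targets <- ids[seq_len(k - 1L)]
      nt <- min(m, k - 1L)
      w <- deg[targets] + 1
      to <- sample(targets, nt, prob = w / sum(w))
      deg[to] <- deg[to] + 1
      deg[ids[k]] <- deg[ids[k]] + nt
      el <- rbind(el, cbind(ids[k], to))
    }
    unname(el)
  }
}

#' Generate a planted-bridge synthetic interactome
#'
#' Emulates the structure the cross-talk analysis assumes: two densely
#' connected process communities joined \emph{only} through a small number of
#' bridge nodes, with seed identifiers drawn from each community. Each
#' community is an Erdos-Renyi graph (or a preferential-attachment graph,
#' see [plantedBridgeSpec()]); each bridge node is wired to
#' \code{bridgeDegreePerSide} uniformly chosen nodes in each community; there
#' are no direct community-to-community edges except through bridges. MITAB
#' field annotations (decoy non-human taxa, predicted detection methods) are
#' drawn here too, in the same seeded stream, so a fixed \code{rngSeed}
#' reproduces networks, seed lists and MITAB files byte-for-byte.
#'
#' When at least one bridge is requested, instances in which the seeds do not
#' all lie in one connected component are re-drawn (bounded retries, then an
#' error): the benchmark is about recovering bridges between \emph{connected}
#' processes.
#'
#' @param spec a [PlantedBridgeSpec-class].
#' @param maxRetries re-draw budget for the connectivity requirement.
#' @return list with elements \code{network} (a [ProteinNetwork-class]
#'   labelled "background") and \code{truth} (a [SyntheticTruth-class]).
#' @seealso [writeMitab()], [writeTruth()]
#' @export
generatePlantedBridge <- function(spec, maxRetries = 25L) {
  stopifnot(is(spec, "PlantedBridgeSpec"))
  .withSeed(spec@rngSeed, {
    for (attempt in seq_len(maxRetries)) {
      ids1 <- sprintf("C1_%03d", seq_len(spec@nPerCommunity))
      ids2 <- sprintf("C2_%03d", seq_len(spec@nPerCommunity))
      bids <- if (spec@nBridges > 0)
        sprintf("BR_%02d", seq_len(spec@nBridges)) else character(0)

      el <- rbind(.communityEdges(ids1, spec@intraEdgeProb, spec@attachment),
                  .communityEdges(ids2, spec@intraEdgeProb, spec@attachment))
      for (b in bids) {
        el <- rbind(el,
                    cbind(b, sample(ids1, spec@bridgeDegreePerSide)),
                    cbind(b, sample(ids2, spec@bridgeDegreePerSide)))
      }
      net <- ProteinNetwork(el, nodes = c(ids1, ids2, bids),
                            label = "background")
      seeds1 <- SeedList(sample(ids1, spec@nSeedsPerCommunity), "auto")
      seeds2 <- SeedList(sample(ids2, spec@nSeedsPerCommunity), "mito")

      ok <- TRUE
      if (spec@nBridges > 0) {
        comp <- components(asIgraph(net))
        mem <- comp$membership[c(seedMembers(seeds1), seedMembers(seeds2))]
        ok <- length(unique(mem)) == 1L
      }
      if (ok) {
        et <- edgeTable(net)
        ne <- nrow(et)
        decoy <- stats::runif(ne) < spec@decoyTaxonFraction
        decoy_tax <- sample(c(10090L, 10116L, 7227L, 4932L), ne,
                            replace = TRUE)
        predicted <- stats::runif(ne) < spec@predictedFraction
        real_method <- sample(c("MI:0018", "MI:0006", "MI:0004", "MI:0096"),
                              ne, replace = TRUE)
        ann <- data.frame(
          a = et$a, b = et$b,
          taxid_a = ifelse(decoy, decoy_tax, 9606L),
          taxid_b = ifelse(decoy, decoy_tax, 9606L),
          method = ifelse(predicted, "MI:0063", real_method),
          stringsAsFactors = FALSE)
        community <- stats::setNames(
          c(rep("1", length(ids1)), rep("2", length(ids2)),
            rep("bridge", length(bids))),
          c(ids1, ids2, bids))
        truth <- new("SyntheticTruth", communityOf = community,
                     bridgeNodes = bids, seedLists = list(seeds1, seeds2),
                     edgeAnnotations = ann)
        return(list(network = net, truth = truth))
      }
    }
    stop("could not generate a connected seeded instance in ", maxRetries,
         " attempts; relax the spec (more bridges or denser communities)")
  })
}

#' Write the generator's ground truth as TSV
#'
#' Columns \code{node}, \code{community} (1, 2 or bridge) and
#' \code{is_bridge}.
#'
#' @param truth a [SyntheticTruth-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTruth <- function(truth, path) {
  df <- data.frame(node = names(truth@communityOf),
                   community = unname(truth@communityOf),
                   is_bridge = unname(truth@communityOf == "bridge"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$node), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Expected number of curated records of a synthetic MITAB file
#'
#' Convenience for benchmark checks: counts the generator's edge rows that a
#' policy-conform curation must retain (human taxa on both sides, detection
#' method not in the predicted set; the generator never emits self pairs).
#'
#' @param truth a [SyntheticTruth-class].
#' @param policy a [CurationPolicy-class].
#' @return integer count.
#' @export
truthCuratedCount <- function(truth, policy = curationPolicy()) {
  ann <- truth@edgeAnnotations
  sum(ann$taxid_a == policy@requiredTaxid &
      ann$taxid_b == policy@requiredTaxid &
      !(ann$method %in% policy@predictedMethodCodes) &
      ann$a != ann$b)
}
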