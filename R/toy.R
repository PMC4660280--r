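#' The documented toy barbell fixture
#'
#' A fixed 9-node example small enough to check by hand: two 4-cliques
#' \{A1..A4\} and \{B1..B4\} joined by the path A1 - X - B1. The two process
#' seed lists are \{A2, A3, A4, X\} and \{B2, B3, B4, X\}: each process
#' contributes its clique members, and the junction protein X is asserted in
#' both processes (a protein with roles in both, as shared-process proteins
#' are in real seed lists). Sampling then yields the sub-networks
#' \{A1..A4, X\} and \{B1..B4, X\}, whose union is the whole barbell; X
#' carries no betweenness inside either sub-network (it is a pendant there)
#' but brokers all 16 cross-clique shortest paths in the union, so its
#' delta BC of 16 tops the ranking, ahead of the clique gateways A1 and B1
#' (delta BC 12); all other nodes score 0.
#'
#' The expected table returned here is frozen from a brute-force
#' all-shortest-paths enumeration of the 9-node graph and is re-derived
#' against that oracle in the test suite.
#'
#' @return list with elements \code{network} (the background
#'   [ProteinNetwork-class]), \code{seedsAuto} and \code{seedsMito}
#'   ([SeedList-class]), and \code{expected} (the ranked delta-BC data frame
#'   in the format of [deltaBC()]).
#' @examples
#' toy <- makeToyBarbell()
#' toy$expected[1, ]
#' @export
makeToyBarbell <- function() {
  cliqueA <- t(utils::combn(paste0("A", 1:4), 2))
  cliqueB <- t(utils::combn(paste0("B", 1:4), 2))
  edges <- rbind(cliqueA, cliqueB, c("A1", "X"), c("X", "B1"))
  network <- ProteinNetwork(edges, label = "background")
  seedsAuto <- SeedList(c("A2", "A3", "A4", "X"), "auto")
  seedsMito <- SeedList(c("B2", "B3", "B4", "X"), "mito")

  expected <- data.frame(
    node     = c("X", "A1", "B1", "A2", "A3", "A4", "B2", "B3", "B4"),
    bc_auto  = c(0, 3, NA, 0, 0, 0, NA, NA, NA),
    bc_mito  = c(0, NA, 3, NA, NA, NA, 0, 0, 0),
    bc_union = c(16, 15, 15, 0, 0, 0, 0, 0, 0),
    delta_bc = c(16, 12, 12, 0, 0, 0, 0, 0, 0),
    in_auto  = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    in_mito  = c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    rank     = 1:9,
    stringsAsFactors = FALSE)

  list(network = network, seedsAuto = seedsAuto, seedsMito = seedsMito,
       expected = expected)
}
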