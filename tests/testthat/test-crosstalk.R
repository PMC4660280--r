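# Union formation, betweenness, delta BC and ranking.

test_that("edge union merges nodes and edges by identifier", {
  a <- ProteinNetwork(rbind(c("x", "y"), c("y", "z")), label = "auto")
  b <- ProteinNetwork(cbind("y", "w"), label = "mito")
  u <- unionNetwork(a, b)
  expect_equal(numNodes(u), 4L)
  expect_equal(numEdges(u), 3L)
  expect_equal(networkLabel(u), "union")
  # disjoint networks: sizes add
  c1 <- ProteinNetwork(cbind("p", "q"))
  u2 <- unionNetwork(a, c1)
  expect_equal(numNodes(u2), numNodes(a) + numNodes(c1))
  expect_equal(numEdges(u2), numEdges(a) + numEdges(c1))
  # self union: identity
  u3 <- unionNetwork(a, a)
  expect_equal(edgeTable(u3), edgeTable(a))
  expect_setequal(networkNodes(u3), networkNodes(a))
})

test_that("background completion restores cross-subnetwork edges only", {
  bg <- ProteinNetwork(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                       label = "background")
  a <- ProteinNetwork(cbind("a", "b"), label = "auto")
  b <- ProteinNetwork(cbind("b", "c"), label = "mito")
  plain <- unionNetwork(a, b)
  expect_equal(numEdges(plain), 2L)
  completed <- unionNetwork(a, b, background = bg)
  expect_equal(numEdges(completed), 3L)   # a-c restored from the background
  expect_error(unionNetwork(a, ProteinNetwork(cbind("q", "r")),
                            background = bg),
               "not contained")
})

test_that("betweenness matches forced small cases", {
  path3 <- ProteinNetwork(rbind(c("a", "b"), c("b", "c")))
  expect_equal(bcValues(betweennessTable(path3)),
               c(a = 0, b = 1, c = 0))
  star <- ProteinNetwork(cbind("c", paste0("l", 1:4)))
  expect_equal(bcValues(betweennessTable(star))[["c"]], 6)
  expect_equal(unname(bcValues(betweennessTable(star))[paste0("l", 1:4)]),
               rep(0, 4))
  cyc5 <- ProteinNetwork(cbind(letters[1:5], letters[c(2:5, 1)]))
  expect_equal(unname(bcValues(betweennessTable(cyc5))), rep(1, 5))
  cyc4 <- ProteinNetwork(cbind(letters[1:4], letters[c(2:4, 1)]))
  expect_equal(unname(bcValues(betweennessTable(cyc4))), rep(0.5, 4))
})

test_that("tiny and empty networks yield all-zero tables", {
  expect_length(bcValues(betweennessTable(ProteinNetwork(NULL))), 0L)
  two <- ProteinNetwork(cbind("a", "b"))
  expect_equal(bcValues(betweennessTable(two)), c(a = 0, b = 0))
  expect_equal(bcValues(betweennessTable(two, normalized = TRUE)),
               c(a = 0, b = 0))
})

test_that("normalization divides by (n-1)(n-2)/2", {
  star <- ProteinNetwork(cbind("c", paste0("l", 1:4)))
  raw <- bcValues(betweennessTable(star))
  norm <- bcValues(betweennessTable(star, normalized = TRUE))
  expect_equal(norm, raw / 6)   # n = 5
  expect_true(isNormalized(betweennessTable(star, normalized = TRUE)))
})

test_that("betweenness equals the brute-force path-counting oracle", {
  for (seed in 1:40) {
    g <- randomTestGraph(seed + 200)
    net <- ProteinNetwork(g$edges, nodes = g$nodes)
    got <- bcValues(betweennessTable(net))
    want <- oracleBetweenness(g$nodes, g$edges)
    expect_equal(got[g$nodes], want, tolerance = 1e-12,
                 info = paste("seed", seed))
  }
})

test_that("total betweenness equals the sum of interior path lengths", {
  # For unweighted graphs every shortest s-t path has d(s,t) - 1 interior
  # nodes, so sum_v BC(v) = sum over connected pairs of (d(s,t) - 1).
  for (seed in 1:10) {
    g <- randomTestGraph(seed + 300)
    net <- ProteinNetwork(g$edges, nodes = g$nodes)
    adj <- oracleAdj(g$nodes, g$edges)
    expected <- 0
    for (i in seq_len(length(g$nodes) - 1)) {
      d <- oracleBFS(adj, g$nodes[i])
      dj <- d[g$nodes[seq.int(i + 1, length(g$nodes))]]
      expected <- expected + sum(dj[is.finite(dj)] - 1)
    }
    expect_equal(sum(bcValues(betweennessTable(net))), expected,
                 info = paste("seed", seed))
  }
})

mkTab <- function(bc, label, n = length(bc)) {
  new("CentralityTable", networkLabel = label, bc = bc,
      normalized = FALSE, nNodes = as.integer(n))
}

test_that("delta BC applies the subtraction and absence conventions", {
  u <- mkTab(c(v = 10, w = 7), "union", n = 20)
  a <- mkTab(c(v = 3, w = 7), "auto", n = 10)
  m <- mkTab(c(v = 2), "mito", n = 10)
  d <- deltaBC(u, a, m)
  expect_equal(d$delta_bc[d$node == "v"], 5)       # 10 - 3 - 2
  expect_equal(d$delta_bc[d$node == "w"], 0)       # 7 - 7 - absent(0)
  expect_false(d$in_mito[d$node == "w"])
  expect_true(is.na(d$bc_mito[d$node == "w"]))
})

test_that("sub-network nodes missing from the union are fatal", {
  u <- mkTab(c(v = 1), "union", n = 5)
  a <- mkTab(c(v = 0, zz = 2), "auto", n = 5)
  expect_error(deltaBC(u, a, mkTab(c(v = 0), "mito", n = 5)),
               "missing from the union")
})

test_that("normalized tables are rejected for delta BC", {
  u <- new("CentralityTable", networkLabel = "union", bc = c(v = 0.5),
           normalized = TRUE, nNodes = 5L)
  raw <- mkTab(c(v = 1), "x", n = 5)
  expect_error(deltaBC(u, raw, raw), "unnormalized")
})

test_that("self-union gives -BC and disjoint sub-networks give zero", {
  for (seed in 1:10) {
    g <- randomTestGraph(seed + 400)
    a <- ProteinNetwork(g$edges, nodes = g$nodes, label = "auto")
    ua <- unionNetwork(a, a)
    d <- deltaBC(betweennessTable(ua), betweennessTable(a),
                 betweennessTable(a))
    bc <- bcValues(betweennessTable(a))
    expect_equal(stats::setNames(d$delta_bc, d$node)[names(bc)], -bc)

    g2 <- randomTestGraph(seed + 450)
    b <- ProteinNetwork(matrix(paste0("q_", g2$edges), ncol = 2),
                        nodes = paste0("q_", g2$nodes), label = "mito")
    u2 <- unionNetwork(a, b)
    d2 <- deltaBC(betweennessTable(u2), betweennessTable(a),
                  betweennessTable(b))
    expect_equal(d2$delta_bc, rep(0, nrow(d2)))
  }
})

test_that("ranking is by descending delta with lexicographic tie-break", {
  u <- mkTab(c(B = 5, A = 5, C = 1), "union", n = 10)
  z <- mkTab(c(B = 0, A = 0, C = 0), "auto", n = 10)
  d <- deltaBC(u, z, z)
  top2 <- rankTargets(d, 2)
  expect_equal(top2$node, c("A", "B"))
  expect_equal(top2$rank, 1:2)
  expect_equal(rankTargets(d, 99)$node, c("A", "B", "C"))
  expect_error(rankTargets(d, 0), "positive")
  # single record
  d1 <- deltaBC(mkTab(c(only = 2), "union", n = 4),
                mkTab(c(only = 0), "a", n = 3),
                mkTab(c(only = 0), "b", n = 3))
  expect_equal(d1$rank, 1L)
})

test_that("a shuffled table ranks like an independent sort", {
  set.seed(99)
  bc <- stats::setNames(sample(c(0, 1, 1, 2, 3, 5, 5, 5, 8, 13,
                                 sample(100, 10))),
                        sprintf("n%02d", 1:20))
  d <- deltaBC(mkTab(bc, "union", n = 40),
               mkTab(bc[1:5] * 0, "a", n = 10),
               mkTab(bc[6:10] * 0, "b", n = 10))
  ref <- names(bc)[order(-bc, names(bc))]
  expect_equal(d$node, ref)
  expect_equal(d$rank, 1:20)
})

test_that("a clique junction dominates delta BC in barbell graphs", {
  for (k in 3:5) {
    A <- paste0("A", seq_len(k)); B <- paste0("B", seq_len(k))
    edges <- rbind(t(utils::combn(A, 2)), t(utils::combn(B, 2)),
                   c(A[1], "v"), c("v", B[1]))
    bg <- ProteinNetwork(edges, label = "background")
    sa <- sampleShortestPaths(bg, SeedList(c(A[-1], "v"), "auto"))
    sm <- sampleShortestPaths(bg, SeedList(c(B[-1], "v"), "mito"))
    u <- unionNetwork(sa$network, sm$network, background = bg)
    d <- deltaBC(betweennessTable(u), betweennessTable(sa$network),
                 betweennessTable(sm$network))
    expect_equal(d$node[1], "v", info = paste("k =", k))
    expect_gt(d$delta_bc[1], max(d$delta_bc[-1]))
  }
})

test_that("the ranked TSV uses '-' for absent betweenness, in rank order", {
  u <- mkTab(c(v = 10, w = 7), "union", n = 20)
  a <- mkTab(c(v = 3, w = 7), "auto", n = 10)
  m <- mkTab(c(v = 2), "mito", n = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDeltaBC(deltaBC(u, a, m), path)
  lines <- readLines(path)
  expect_equal(lines[1],
               "node\tbc_auto\tbc_mito\tbc_union\tdelta_bc\tin_auto\tin_mito\trank")
  expect_equal(lines[2], "v\t3\t2\t10\t5\tTRUE\tTRUE\t1")
  expect_equal(lines[3], "w\t7\t-\t7\t0\tTRUE\tFALSE\t2")
})
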