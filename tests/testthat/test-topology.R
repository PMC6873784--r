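test_that("network assembly takes the union of triplet members and edges", {
  tr <- data.frame(lncrna_id = "L1", mirna_id = "m1", mrna_id = "g1",
                   stringsAsFactors = FALSE)
  net <- assembleNetwork(tr)
  expect_equal(nrow(networkNodes(net)), 3)
  expect_equal(nrow(networkEdges(net)), 2)
  withCoexpr <- assembleNetwork(tr, includeLncMrnaEdges = TRUE)
  expect_equal(nrow(networkEdges(withCoexpr)), 3)
  ## two triplets sharing a miRNA; duplicates collapse (idempotent)
  tr2 <- rbind(tr, data.frame(lncrna_id = "L2", mirna_id = "m1",
                              mrna_id = "g2"), tr)
  net2 <- assembleNetwork(tr2)
  expect_equal(nrow(networkNodes(net2)), 5)
  expect_equal(nrow(networkEdges(net2)), 4)
})

test_that("the path graph reproduces hand-computed centralities", {
  net <- TripartiteNetwork(
    nodes = data.frame(id = c("A", "B", "C"),
                       class = c("lncRNA", "miRNA", "mRNA")),
    edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                       relation = c("lnc_mir", "mir_mrna")))
  m <- nodeMetrics(net)
  rownames(m) <- m$node_id
  expect_equal(m["B", "degree"], 2L)
  expect_equal(m["B", "betweenness"], 1)
  expect_equal(m["A", "betweenness"], 0)
  expect_equal(m["B", "closeness"], 1)
  expect_equal(m["A", "closeness"], (1 + 1 / 2) / 2)
  expect_equal(sum(m$pagerank), 1, tolerance = 1e-9)
})

test_that("star-graph PageRank matches the analytic fixed point", {
  ## K_{1,3}: center c, leaves l1..l3, damping d = 0.85. By symmetry
  ## p_c = (1-d)/4 + d * 3 p_l, p_l = (1-d)/4 + d p_c / 3, solved exactly.
  net <- TripartiteNetwork(
    nodes = data.frame(id = c("c", "l1", "l2", "l3"),
                       class = c("miRNA", "mRNA", "mRNA", "mRNA")),
    edges = data.frame(from = "c", to = c("l1", "l2", "l3"),
                       relation = "mir_mrna"))
  d <- 0.85
  pc <- ((1 - d) / 4 + d * 3 * (1 - d) / 4) / (1 - d^2)
  pl <- (1 - d) / 4 + d * pc / 3
  m <- nodeMetrics(net)
  expect_equal(m$pagerank[m$node_id == "c"], pc, tolerance = 1e-8)
  expect_equal(m$pagerank[m$node_id == "l1"], pl, tolerance = 1e-8)
  expect_equal(pc, 0.4797, tolerance = 1e-3)
  expect_equal(pl, 0.1734, tolerance = 1e-3)
})

test_that("metric panel equals brute-force references on random graphs", {
  set.seed(902)
  for (i in 1:40) {
    net <- random_network(nMax = 12)
    m <- nodeMetrics(net)
    A <- adjacency_of(net)
    expect_equal(stats::setNames(as.numeric(m$degree), m$node_id),
                 rowSums(A)[m$node_id])
    expect_equal(stats::setNames(m$betweenness, m$node_id),
                 oracle_betweenness(A)[m$node_id], tolerance = 1e-10)
    expect_equal(stats::setNames(m$closeness, m$node_id),
                 oracle_harmonic_closeness(A)[m$node_id], tolerance = 1e-10)
    expect_equal(stats::setNames(m$pagerank, m$node_id),
                 oracle_pagerank(A)[m$node_id], tolerance = 1e-9)
    expect_equal(sum(m$degree), 2 * nrow(networkEdges(net)))
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(903)
  net <- random_network(nMax = 10)
  nd <- networkNodes(net); ed <- networkEdges(net)
  map <- stats::setNames(sprintf("X%02d", sample(nrow(nd))), nd$id)
  relabeled <- TripartiteNetwork(
    data.frame(id = unname(map[nd$id]), class = nd$class),
    if (nrow(ed)) data.frame(from = unname(map[ed$from]),
                             to = unname(map[ed$to]),
                             relation = ed$relation) else NULL)
  a <- nodeMetrics(net); b <- nodeMetrics(relabeled)
  rownames(a) <- unname(map[a$node_id]); rownames(b) <- b$node_id
  for (col in c("degree", "betweenness", "closeness", "pagerank"))
    expect_equal(a[rownames(b), col], b[[col]], tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("top-k ranking breaks ties lexicographically", {
  net <- toy_network()
  m <- nodeMetrics(net)
  rk <- rankTop(m, k = 3)
  expect_equal(rk$degree, m$node_id[order(-m$degree, m$node_id)][1:3])
  expect_equal(rk$degree[1], "m1")  # unique max degree
  full <- rankTop(m, k = 100)
  expect_setequal(full$degree, m$node_id)
  expect_true(all(c("degree", "betweenness", "closeness", "pagerank",
                    "hubs") %in% names(rk)))
  ## equal-degree nodes rank by id
  tied <- TripartiteNetwork(
    nodes = data.frame(id = c("mb", "ma", "g1", "g2"),
                       class = c("miRNA", "miRNA", "mRNA", "mRNA")),
    edges = data.frame(from = c("mb", "ma"), to = c("g1", "g2"),
                       relation = "mir_mrna"))
  rkT <- rankTop(nodeMetrics(tied), k = 4)
  expect_lt(which(rkT$degree == "ma"), which(rkT$degree == "mb"))
  expect_error(rankTop(m, k = 0), "k must be >= 1")
  expect_equal(rankTop(m, k = 5, classFilter = "miRNA")$hubs,
               intersect(rankTop(m, 5)$hubs,
                         m$node_id[m$class == "miRNA"]))
})

test_that("pair counting enumerates first and secondary relationships", {
  net <- toy_network()
  pc <- countPairs(net, "L")
  expect_equal(pc$n_first, 2)
  expect_equal(pc$n_secondary, 3)
  expect_equal(pc$total, 5)
  ## published-style record: totals are the exact sum
  expect_equal(8 + 61, 69)
  expect_error(countPairs(net, "m1"), "not a lncRNA")
  expect_error(countPairs(net, "nope"), "unknown")
  lonely <- TripartiteNetwork(
    nodes = data.frame(id = "L9", class = "lncRNA"))
  pc0 <- countPairs(lonely, "L9")
  expect_equal(c(pc0$n_first, pc0$n_secondary, pc0$total), c(0, 0, 0))
})

test_that("subnetwork extraction is the depth-2 miRNA/mRNA neighborhood", {
  net <- toy_network()
  sub <- extractSubnetwork(net, "L")
  expect_setequal(networkNodes(sub)$id, c("L", "m1", "m2", "g1", "g2"))
  expect_equal(nrow(networkEdges(sub)), 5)

  ## a disconnected triplet is excluded
  nd <- rbind(networkNodes(net),
              data.frame(id = c("L2", "m9", "g9"),
                         class = c("lncRNA", "miRNA", "mRNA")))
  ed <- rbind(networkEdges(net),
              data.frame(from = c("L2", "m9"), to = c("m9", "g9"),
                         relation = c("lnc_mir", "mir_mrna")))
  big <- TripartiteNetwork(nd, ed)
  sub2 <- extractSubnetwork(big, "L")
  expect_setequal(networkNodes(sub2)$id, c("L", "m1", "m2", "g1", "g2"))

  ## BFS-depth-2 oracle on random networks
  set.seed(904)
  for (i in 1:20) {
    rn <- random_network(nMax = 12)
    lncs <- networkNodes(rn)$id[networkNodes(rn)$class == "lncRNA"]
    if (!length(lncs)) next
    L <- lncs[1]
    A <- adjacency_of(rn)
    edr <- networkEdges(rn)
    mirNb <- unique(c(edr$to[edr$relation == "lnc_mir" & edr$from == L]))
    mrnaNb <- unique(edr$to[edr$relation == "mir_mrna" &
                            edr$from %in% mirNb])
    want <- unique(c(L, mirNb, mrnaNb))
    expect_setequal(networkNodes(extractSubnetwork(rn, L))$id, want)
  }
})
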