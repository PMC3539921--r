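test_that("node GO score is the mean incident-edge similarity", {
  net <- makeTestNetwork(data.frame(a = c("n", "n"), b = c("p", "q")),
                         goSim = c(0.2, 0.8),
                         nodes = c("n", "p", "q", "iso"))
  sc <- nodeGoScore(net)
  expect_equal(sc$go_score[sc$protein_id == "n"], 0.5)
  # isolated node: 0 with flag
  expect_equal(sc$go_score[sc$protein_id == "iso"], 0)
  expect_true(sc$flagged[sc$protein_id == "iso"])
  # constant similarity gives that constant
  net2 <- makeTestNetwork(data.frame(a = c("n", "n"), b = c("p", "q")),
                          goSim = c(0.5, 0.5))
  expect_equal(nodeGoScore(net2)$go_score,
               rep(0.5, 3))
})

test_that("propensity is the incident mean over the network mean", {
  # node n: incident mean 0.8; network mean (0.8+0.8+0.2+0.2)/4 = 0.5
  net <- makeTestNetwork(data.frame(a = c("n", "n", "p", "q"),
                                    b = c("p", "q", "x", "y")),
                         structScore = c(0.8, 0.8, 0.2, 0.2))
  pr <- nodePropensityScore(net)
  expect_equal(pr$propensity[pr$protein_id == "n"], 0.8 / 0.5)
  # all equal scores: every propensity 1
  netEq <- makeTestNetwork(data.frame(a = c("a", "b"), b = c("b", "c")),
                           structScore = c(0.3, 0.3))
  expect_equal(nodePropensityScore(netEq)$propensity, rep(1, 3))
  # node with only unscored edges: 0, flagged (others still scored)
  netMix <- makeTestNetwork(data.frame(a = c("a", "c"), b = c("b", "d")),
                            structScore = c(0.4, NA))
  prM <- nodePropensityScore(netMix)
  expect_equal(prM$propensity[prM$protein_id == "c"], 0)
  expect_true(prM$flagged[prM$protein_id == "c"])
  # fully unscored network: all zero, all flagged
  netNA <- makeTestNetwork(data.frame(a = "a", b = "b"))
  prNA <- nodePropensityScore(netNA)
  expect_equal(prNA$propensity, rep(0, 2))
  expect_true(all(prNA$flagged))
})

test_that("node strength schemes implement the documented weightings", {
  expect_equal(nodeStrength(0, 0, 0, 0, "unweighted"), 0)
  expect_equal(nodeStrength(0.5, 0.5, 0.5, 0.5, "unweighted"), 0.5)
  expect_equal(nodeStrength(0.2, 0.4, 0.6, 0.8, "unweighted"), 0.5)
  expect_equal(nodeStrength(0, 0, 0, 1, "weighted"), 0.4)
  expect_equal(nodeStrength(1, 1, 1, 1, "weighted"), 1.0)
  expect_equal(nodeStrength(1, 1, 1, 1, "weighted_literal"), 1.2)
  expect_equal(nodeStrength(0, 0, 0, 0, "weighted_literal"), 0)
  expect_error(nodeStrength(NA, 0, 0, 0, "weighted"), "missing")
  # strengths stay in [0, 1] under the default weighted scheme
  set.seed(4)
  f <- matrix(runif(400), ncol = 4)
  s <- nodeStrength(f[, 1], f[, 2], f[, 3], f[, 4], "weighted")
  expect_true(all(s >= 0 & s <= 1))
})

test_that("hypergeometric association equals exhaustive enumeration (N <= 12)", {
  for (N in c(4, 6, 9, 12)) {
    for (n1 in c(1, 2, N %/% 2)) for (n2 in c(1, 3, N %/% 2)) {
      for (m in max(0, n1 + n2 - N):min(n1, n2)) {
        expect_equal(hypergeomAssociation(n1, n2, m, N),
                     bruteHyperPoint(N, n1, n2, m), tolerance = 1e-12)
      }
    }
  }
  # hand values: N=4, n1=n2=2 -> P(m=2) = P(m=0) = 1/6
  expect_equal(hypergeomAssociation(2, 2, 2, 4), 1 / 6, tolerance = 1e-12)
  expect_equal(hypergeomAssociation(2, 2, 0, 4), 1 / 6, tolerance = 1e-12)
  # normalization over the support
  for (N in c(5, 8)) for (n1 in 1:4) for (n2 in 1:4) {
    ms <- max(0, n1 + n2 - N):min(n1, n2)
    expect_equal(sum(hypergeomAssociation(n1, n2, ms, N)), 1,
                 tolerance = 1e-12)
  }
  expect_error(hypergeomAssociation(3, 2, 3, 10), "invalid")
})

test_that("log-space evaluation matches factorial-free products at N = 1e4", {
  cases <- data.frame(n1 = c(50, 300, 1200), n2 = c(80, 500, 4000),
                      m = c(10, 40, 600))
  for (i in seq_len(nrow(cases))) {
    got <- hypergeomAssociation(cases$n1[i], cases$n2[i], cases$m[i], 1e4)
    want <- bruteHyperMassProduct(1e4, cases$n1[i], cases$n2[i], cases$m[i])
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("node ranking orders by strength with lexicographic tie-break", {
  net <- makeTestNetwork(data.frame(a = c("b2", "b2", "a1"),
                                    b = c("a1", "c3", "c3")),
                         isTf = c(TRUE, TRUE, FALSE),
                         goSim = c(0.5, 0.5, 0.5))
  net <- computeTopology(net)
  rk <- rankNodes(net, scheme = "weighted")
  # triangle: all features identical -> tie broken by id
  expect_identical(rk$protein_id, c("a1", "b2", "c3"))
  expect_true(all(diff(rk$node_strength) <= 0))
  expect_error(rankNodes(makeTestNetwork(data.frame(a = "x", b = "y"))),
               "topology")
})

test_that("a planted hub ranks first on network fixtures for every seed", {
  for (s in 1:10) {
    fx <- generateNetworkFixture(s, plantHub = TRUE)
    for (scheme in c("weighted", "unweighted")) {
      rk <- rankNodes(fx$net, scheme = scheme)
      expect_lte(rk$rank[rk$protein_id == fx$truth$hub], 3)
    }
  }
})

test_that("TF association table covers connected TF pairs and filters at alpha", {
  fx <- generateNetworkFixture(1, plantHub = TRUE)
  tab <- tfAssociations(fx$net, alpha = 0.05)
  g <- networkGraph(fx$net)
  isTf <- setNames(igraph::V(g)$is_tf, igraph::V(g)$name)
  if (nrow(tab)) {
    expect_true(all(isTf[tab$gene_a] & isTf[tab$gene_b]))
    expect_true(all(tab$m <= pmin(tab$n1, tab$n2)))
    expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
    expect_identical(tab$significant, tab$p_value < 0.05)
    expect_true(!is.unsorted(tab$p_value))
  }
  # alpha = 0: nothing significant
  tab0 <- tfAssociations(fx$net, alpha = 0)
  expect_false(any(tab0$significant))
})

test_that("ranking is invariant under node relabeling up to the tie rule", {
  fx <- generateNetworkFixture(3, plantHub = TRUE)
  g <- networkGraph(fx$net)
  perm <- setNames(sprintf("Z%03d", seq_len(igraph::vcount(g))),
                   igraph::V(g)$name)
  g2 <- igraph::set_vertex_attr(g, "name",
                                value = unname(perm[igraph::V(g)$name]))
  net2 <- computeTopology(new("TFNetwork", graph = g2))
  rk1 <- rankNodes(fx$net)
  rk2 <- rankNodes(net2)
  expect_equal(sort(rk1$node_strength), sort(rk2$node_strength))
  expect_identical(unname(perm[rk1$protein_id[1]]), rk2$protein_id[1])
})
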