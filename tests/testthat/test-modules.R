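mkRanking <- function(ids, strengths, isTf) {
  df <- data.frame(protein_id = ids, is_tf = isTf,
                   node_strength = strengths, stringsAsFactors = FALSE)
  df <- df[order(-df$node_strength, df$protein_id), ]
  df$rank <- seq_len(nrow(df))
  df
}

test_that("a TF with two neighbors yields exactly one size-3 module", {
  net <- makeTestNetwork(data.frame(a = c("T", "T"), b = c("x", "y")),
                         isTf = c(TRUE, FALSE, FALSE))
  rk <- mkRanking(c("T", "x", "y"), c(0.9, 0.5, 0.4),
                  c(TRUE, FALSE, FALSE))
  ms <- extractModules(net, rk, sizeCap = 5, rankPercentile = 1)
  expect_identical(length(moduleMembers(ms)), 1L)
  expect_setequal(moduleMembers(ms)[[1]], c("T", "x", "y"))
})

test_that("isolated TFs and TF-free networks give no modules", {
  net <- makeTestNetwork(data.frame(a = "x", b = "y"),
                         nodes = c("T", "x", "y"),
                         isTf = c(TRUE, FALSE, FALSE))
  rk <- mkRanking(c("T", "x", "y"), c(0.9, 0.5, 0.4),
                  c(TRUE, FALSE, FALSE))
  expect_identical(length(moduleMembers(
    extractModules(net, rk, rankPercentile = 1))), 0L)
  netNoTf <- makeTestNetwork(data.frame(a = c("x", "y"), b = c("y", "z")))
  rk2 <- mkRanking(c("x", "y", "z"), c(0.3, 0.2, 0.1), rep(FALSE, 3))
  expect_identical(length(moduleMembers(
    extractModules(netNoTf, rk2, rankPercentile = 1))), 0L)
  expect_error(extractModules(net, rk, sizeCap = 2), "sizeCap")
})

test_that("module enumeration matches brute-force connected-subgraph enumeration", {
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    adj <- randomAdjacency(n, runif(1, 0.25, 0.6))
    ids <- sprintf("V%02d", seq_len(n))
    el <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    if (!nrow(el)) next
    net <- makeTestNetwork(data.frame(a = ids[el[, 1]], b = ids[el[, 2]]),
                           nodes = ids, isTf = c(TRUE, rep(FALSE, n - 1)))
    rk <- mkRanking(ids, seq(1, 0.1, length.out = n),
                    c(TRUE, rep(FALSE, n - 1)))
    cap <- sample(3:6, 1)
    ms <- extractModules(net, rk, sizeCap = cap, rankPercentile = 1)
    got <- sort(unname(vapply(moduleMembers(ms), paste, "",
                              collapse = ",")))
    # oracle: subsets of the TF's ego network, connected, containing it
    ego <- sort(unique(c(1L, which(adj[1, ] == 1))))
    egoAdj <- adj[ego, ego, drop = FALSE]
    root <- match(1L, ego)
    want <- bruteSubgraphs(egoAdj, root, 3, min(cap, length(ego)))
    wantKeys <- sort(vapply(want, function(s)
      paste(ids[ego[s]], collapse = ","), ""))
    expect_identical(got, unique(wantKeys))
  }
})

test_that("every emitted module is connected, contains its anchor and respects the cap", {
  fx <- generateNetworkFixture(8, plantHub = TRUE)
  rk <- rankNodes(fx$net)
  ms <- extractModules(fx$net, rk, sizeCap = 4)
  tab <- moduleTable(ms)
  g <- networkGraph(fx$net)
  for (i in seq_along(moduleMembers(ms))) {
    mem <- moduleMembers(ms)[[i]]
    expect_gte(length(mem), 3)
    expect_lte(length(mem), 4)
    expect_true(tab$anchor_tf[i] %in% mem)
    sub <- igraph::induced_subgraph(g, mem)
    expect_true(igraph::is_connected(sub))
  }
  # deduplication: no repeated member sets
  keys <- vapply(moduleMembers(ms), paste, "", collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
})

test_that("module scores are member-strength means, order-invariant", {
  rk <- mkRanking(c("a", "b", "c"), c(0.2, 0.4, 0.6), rep(TRUE, 3))
  expect_equal(scoreModule(c("a", "b", "c"), rk), 0.4)
  expect_equal(scoreModule(c("c", "a", "b"), rk), 0.4)
  expect_equal(scoreModule(c("a", "a", "b"), rk),
               scoreModule(c("a", "b", "a"), rk))
  expect_error(scoreModule(c("a", "zz"), rk), "zz")
})

test_that("module TF p-value matches exhaustive enumeration and boundary rules", {
  # k = 0: empty sum, p = 1
  expect_equal(as.numeric(moduleTFPvalue(0, N = 10, S = 4, C = 5)), 1)
  # hand value: N=10, S=4, C=5, k=1 -> 1 - C(6,5)/C(10,5)
  expect_equal(as.numeric(moduleTFPvalue(1, N = 10, S = 4, C = 5)),
               1 - 6 / 252, tolerance = 1e-12)
  # k beyond the support: full mass summed, p = 0
  expect_equal(as.numeric(moduleTFPvalue(5, N = 10, S = 4, C = 5)), 0)
  # exhaustive agreement for small grids
  for (N in c(6, 8)) for (S in 1:4) for (C in 2:4) for (k in 0:4) {
    expect_equal(as.numeric(moduleTFPvalue(k, N = N, S = S, C = C)),
                 bruteHyperTailGE(N, S, C, k), tolerance = 1e-12)
  }
  # p is non-increasing in k
  for (k in 0:4)
    expect_gte(as.numeric(moduleTFPvalue(k, N = 8, S = 3, C = 4)),
               as.numeric(moduleTFPvalue(k + 1, N = 8, S = 3, C = 4)))
  expect_error(moduleTFPvalue(1, N = 5, S = 9, C = 3), "infeasible")
  # alternative binding is recorded
  p <- moduleTFPvalue(1, N = 10, S = 6, C = 3, I = 2, binding = "modules")
  expect_identical(attr(p, "binding"), "modules")
})

test_that("module ranking filters at the anchor-TF p-value and sorts by score", {
  fx <- generateNetworkFixture(5, plantHub = FALSE, plantModule = TRUE)
  rk <- rankNodes(fx$net)
  ms <- extractModules(fx$net, rk, sizeCap = 3, rankPercentile = 0.15)
  mr <- rankModules(ms, fx$net, rk)
  expect_true(all(mr$ranked$p_value < 0.05))
  within3 <- mr$ranked[mr$ranked$size == 3, ]
  expect_true(!is.unsorted(-within3$score))
  # alpha = 1 keeps every module with a defined p-value
  mrAll <- rankModules(ms, fx$net, rk, alpha = 1)
  expect_identical(nrow(mrAll$ranked), sum(!is.na(mrAll$table$p_value)))
  # per-size summary counts every enumerated module
  expect_identical(sum(mr$sizeSummary$n_modules),
                   length(moduleMembers(ms)))
})

test_that("a planted high-strength module tops its size class across seeds", {
  hits <- 0L
  for (s in 1:20) {
    fx <- generateNetworkFixture(s, plantHub = FALSE, plantModule = TRUE)
    rk <- rankNodes(fx$net)
    ms <- extractModules(fx$net, rk, sizeCap = 3, rankPercentile = 0.15)
    mr <- rankModules(ms, fx$net, rk)
    top <- mr$ranked[mr$ranked$size == 3, ][1, ]
    if (!is.na(top$module_id) &&
        identical(top$members,
                  paste(sort(fx$truth$moduleMembers), collapse = ",")))
      hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})
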