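# Independent brute-force oracles used to check the package's
# implementations.  These deliberately use naive loops / exhaustive
# enumeration and share no code with the package internals.

# Association matrix by explicit double loop over documents.
bruteAssociation <- function(W) {
  M <- ncol(W)
  A <- matrix(0, M, M, dimnames = list(colnames(W), colnames(W)))
  for (k in seq_len(M)) for (l in seq_len(M)) {
    if (k == l) next
    for (i in seq_len(nrow(W))) A[k, l] <- A[k, l] + W[i, k] * W[i, l]
  }
  A
}

# Degree, clustering coefficient and betweenness from a 0/1 adjacency
# matrix, via triangle counting and BFS shortest-path counting.
bruteTopology <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    cc[i] <- if (k < 2) 0 else
      (sum(adj[nb, nb]) / 2) / (k * (k - 1) / 2)
  }
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) for (w in which(adj[v, ] == 1)) {
        if (!is.finite(dist[s, w])) {
          dist[s, w] <- d
          nxt <- c(nxt, w)
        }
        if (dist[s, w] == d) sigma[s, w] <- sigma[s, w] + sigma[s, v]
      }
      frontier <- unique(nxt)
    }
  }
  btw <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (j < k && j != i && k != i && is.finite(dist[j, k]) &&
        dist[j, i] + dist[i, k] == dist[j, k])
      btw[i] <- btw[i] + sigma[j, i] * sigma[i, k] / sigma[j, k]
  }
  list(degree = deg, clustering = cc, betweenness = btw)
}

# P(overlap == m) between a fixed n1-set and a random n2-subset of N,
# by exhaustive enumeration of all C(N, n2) subsets.
bruteHyperPoint <- function(N, n1, n2, m) {
  first <- seq_len(n1)
  subsets <- combn(N, n2)
  mean(apply(subsets, 2, function(s) length(intersect(s, first)) == m))
}

# P(overlap >= k) when `draws` items are drawn from N of which the
# first `succ` are successes; exhaustive enumeration.
bruteHyperTailGE <- function(N, succ, draws, k) {
  good <- seq_len(succ)
  subsets <- combn(N, draws)
  mean(apply(subsets, 2, function(s) length(intersect(s, good)) >= k))
}

# Hypergeometric point mass by an overflow-safe factorial-free product
# (independent of lchoose/lfactorial): C(K,m) C(N-K, n-m) / C(N, n).
bruteHyperMassProduct <- function(N, K, n, m) {
  lo <- max(0, n - (N - K)); hi <- min(K, n)
  if (m < lo || m > hi) return(0)
  logfac <- function(a, b) if (b < a) 0 else sum(log(seq(a, b)))
  # log C(x, y) via sums of logs of integers
  lchoose2 <- function(x, y) logfac(x - y + 1, x) - logfac(1, y)
  exp(lchoose2(K, m) + lchoose2(N - K, n - m) - lchoose2(N, n))
}

# All connected induced subgraphs containing `root`, by filtering every
# subset of the vertex set.
bruteSubgraphs <- function(adj, root, minSize, maxSize) {
  n <- nrow(adj)
  verts <- seq_len(n)
  out <- list()
  for (sz in minSize:maxSize) {
    if (sz > n) break
    for (cmb in asplit(combn(verts, sz), 2)) {
      if (!(root %in% cmb)) next
      sub <- adj[cmb, cmb, drop = FALSE]
      # connectivity by reachability from the first vertex
      reach <- c(1L)
      repeat {
        nxt <- unique(c(reach, which(colSums(sub[reach, , drop = FALSE]) > 0)))
        if (length(nxt) == length(reach)) break
        reach <- nxt
      }
      if (length(reach) == sz) out[[length(out) + 1L]] <- sort(cmb)
    }
  }
  out
}

# Structure pair interaction score by naive all-pairs distance loops.
bruteStructureScore <- function(chainA, predA, chainB, predB, cutoff) {
  ca <- chainA[chainA$resno %in% predA, ]
  cb <- chainB[chainB$resno %in% predB, ]
  probable <- nrow(ca) + nrow(cb)
  if (probable == 0) return(NA_real_)
  close <- function(p, q)
    sqrt((p$x - q$x)^2 + (p$y - q$y)^2 + (p$z - q$z)^2) <= cutoff
  nInt <- 0
  for (i in seq_len(nrow(ca))) {
    hit <- FALSE
    for (j in seq_len(nrow(cb))) if (close(ca[i, ], cb[j, ])) hit <- TRUE
    if (hit) nInt <- nInt + 1
  }
  for (j in seq_len(nrow(cb))) {
    hit <- FALSE
    for (i in seq_len(nrow(ca))) if (close(ca[i, ], cb[j, ])) hit <- TRUE
    if (hit) nInt <- nInt + 1
  }
  nInt / probable
}

# Random undirected igraph-free adjacency matrix.
randomAdjacency <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(runif(length(up)) < p)
  adj + t(adj)
}

# Build a small TFNetwork directly from an edge list for unit tests.
makeTestNetwork <- function(edges, isTf = NULL, goSim = NULL,
                            structScore = NULL, nodes = NULL) {
  ids <- if (is.null(nodes)) sort(unique(c(edges$a, edges$b))) else nodes
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$a, to = edges$b), directed = FALSE,
    vertices = data.frame(name = ids))
  ne <- igraph::ecount(g)
  if (is.null(goSim)) goSim <- rep(0.5, ne)
  if (is.null(structScore)) structScore <- rep(NA_real_, ne)
  if (is.null(isTf)) isTf <- rep(FALSE, length(ids))
  g <- igraph::set_edge_attr(g, "go_distance", value = 1 - goSim)
  g <- igraph::set_edge_attr(g, "go_similarity", value = goSim)
  g <- igraph::set_edge_attr(g, "structural_score", value = structScore)
  g <- igraph::set_vertex_attr(g, "is_tf", value = isTf)
  new("TFNetwork", graph = g)
}
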