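## Node prioritization: node-level GO and interaction-propensity scores,
## un-weighted / weighted node strength, and hypergeometric node-node
## association p-values.

#' Node-level GO annotation similarity score
#'
#' The mean GO similarity (1 - Czekanowski-Dice distance) over a node's
#' incident edges.  Isolated nodes score 0 and are flagged.
#'
#' @param net a [TFNetwork-class] with edge attribute `go_similarity`.
#' @return data.frame with columns `protein_id`, `go_score`, `K`
#'   (neighbor count), `flagged`.
#' @export
nodeGoScore <- function(net) {
  stopifnot(is(net, "TFNetwork"))
  g <- net@graph
  ids <- igraph::V(g)$name
  sim <- igraph::edge_attr(g, "go_similarity")
  inc <- igraph::incident_edges(g, igraph::V(g))
  sc <- vapply(inc, function(e) {
    if (!length(e)) return(0)
    mean(sim[as.integer(e)])
  }, numeric(1))
  K <- vapply(inc, length, integer(1))
  data.frame(protein_id = ids, go_score = unname(sc), K = unname(K),
             flagged = unname(K == 0L), stringsAsFactors = FALSE)
}

#' Node-level protein interaction propensity score
#'
#' The mean structural interaction score over a node's incident edges,
#' divided by the mean structural score over all network edges.  Edges
#' without a structural score contribute 0 to both means (they remain in
#' the denominators) provided at least one structurally scored edge
#' exists in the network; a network with no structural scores at all
#' yields propensity 0 for every node, flagged.
#'
#' @param net a [TFNetwork-class] with edge attribute `structural_score`.
#' @return data.frame with columns `protein_id`, `propensity`, `K`,
#'   `flagged`.
#' @export
nodePropensityScore <- function(net) {
  stopifnot(is(net, "TFNetwork"))
  g <- net@graph
  ids <- igraph::V(g)$name
  ss <- igraph::edge_attr(g, "structural_score")
  if (is.null(ss)) ss <- rep(NA_real_, igraph::ecount(g))
  anyScored <- any(!is.na(ss))
  ss0 <- ifelse(is.na(ss), 0, ss)
  netMean <- if (length(ss0)) mean(ss0) else 0
  inc <- igraph::incident_edges(g, igraph::V(g))
  K <- vapply(inc, length, integer(1))
  nodeMean <- vapply(inc, function(e) {
    if (!length(e)) return(0)
    mean(ss0[as.integer(e)])
  }, numeric(1))
  if (!anyScored || netMean == 0) {
    prop <- rep(0, length(ids))
    flag <- rep(TRUE, length(ids))
  } else {
    prop <- nodeMean / netMean
    flag <- K == 0L | vapply(inc, function(e)
      !length(e) || all(is.na(ss[as.integer(e)])), logical(1))
  }
  data.frame(protein_id = ids, propensity = unname(prop),
             K = unname(K), flagged = unname(flag),
             stringsAsFactors = FALSE)
}

#' Combine node features into node strength
#'
#' Schemes: `"unweighted"` — the arithmetic mean of the four features
#' (clustering coefficient, normalized betweenness, GO score,
#' propensity); `"weighted"` — `0.4 * propensity + 0.2 * (clustering +
#' betweenness + go_score)` (weights sum to 1, keeping the 2:1 emphasis
#' on the structure-based feature); `"weighted_literal"` — the printed
#' form in which the propensity also appears inside the 0.2 bracket
#' (weights sum to 1.2).
#'
#' @param clustering,betweenness,goScore,propensity numeric feature
#'   vectors of equal length (no missing values allowed).
#' @param scheme one of `"unweighted"`, `"weighted"`,
#'   `"weighted_literal"`.
#' @param wPropensity,wOther the weights (defaults 0.4 and 0.2).
#' @return numeric vector of node strengths.
#' @export
nodeStrength <- function(clustering, betweenness, goScore, propensity,
                         scheme = c("weighted", "unweighted",
                                    "weighted_literal"),
                         wPropensity = 0.4, wOther = 0.2) {
  scheme <- match.arg(scheme)
  feats <- list(clustering = clustering, betweenness = betweenness,
                goScore = goScore, propensity = propensity)
  for (nm in names(feats))
    if (any(is.na(feats[[nm]])))
      stop("missing feature values in ", nm)
  switch(scheme,
    unweighted = (clustering + betweenness + goScore + propensity) / 4,
    weighted = wPropensity * propensity +
      wOther * (clustering + betweenness + goScore),
    weighted_literal = wPropensity * propensity +
      wOther * (clustering + betweenness + goScore + propensity))
}

#' Hypergeometric node-node association probability
#'
#' Point probability that two nodes with `n1` and `n2` interaction
#' partners out of `N` network proteins share exactly `m` partners,
#' evaluated in log-factorial space:
#' `P = (N-n1)! (N-n2)! n1! n2! / (N! m! (n1-m)! (n2-m)! (N-n1-n2+m)!)`,
#' equal to the classical hypergeometric mass
#' `C(n1, m) C(N-n1, n2-m) / C(N, n2)`.
#'
#' @param n1,n2 neighbor counts of the two nodes.
#' @param m shared neighbor count.
#' @param N total number of network proteins.
#' @return numeric vector of point probabilities.
#' @export
hypergeomAssociation <- function(n1, n2, m, N) {
  ok <- m >= 0 & m <= pmin(n1, n2) & n1 <= N & n2 <= N &
    (N - n1 - n2 + m) >= 0 & n1 >= 0 & n2 >= 0
  if (any(!ok))
    stop("invalid hypergeometric parameters: need 0 <= m <= min(n1, n2), ",
         "n1, n2 <= N and N - n1 - n2 + m >= 0")
  lp <- lfactorial(N - n1) + lfactorial(N - n2) +
    lfactorial(n1) + lfactorial(n2) -
    lfactorial(N) - lfactorial(m) - lfactorial(n1 - m) -
    lfactorial(n2 - m) - lfactorial(N - n1 - n2 + m)
  exp(lp)
}

#' Rank network nodes by node strength
#'
#' Requires topology annotation ([computeTopology()]); computes the
#' node-level GO and propensity scores, combines them under the chosen
#' scheme and returns the ranking (descending strength, ties broken by
#' lexicographic protein id).
#'
#' @param net a [TFNetwork-class] with topology computed.
#' @param scheme strength scheme, see [nodeStrength()].
#' @return data.frame with one row per node: `protein_id`, `is_tf`,
#'   the four features, `node_strength`, `rank`; attribute `"scheme"`
#'   records the scheme.
#' @export
rankNodes <- function(net, scheme = c("weighted", "unweighted",
                                      "weighted_literal")) {
  scheme <- match.arg(scheme)
  g <- net@graph
  if (is.null(igraph::vertex_attr(g, "degree")))
    stop("topology not computed; run computeTopology() first")
  goS <- nodeGoScore(net)
  pr <- nodePropensityScore(net)
  df <- data.frame(
    protein_id = igraph::V(g)$name,
    is_tf = igraph::V(g)$is_tf,
    degree = igraph::V(g)$degree,
    clustering = igraph::V(g)$clustering,
    betweenness_raw = igraph::V(g)$betweenness_raw,
    betweenness_norm = igraph::V(g)$betweenness_norm,
    go_score = goS$go_score[match(igraph::V(g)$name, goS$protein_id)],
    propensity = pr$propensity[match(igraph::V(g)$name, pr$protein_id)],
    stringsAsFactors = FALSE)
  df$node_strength <- nodeStrength(df$clustering, df$betweenness_norm,
                                   df$go_score, df$propensity, scheme)
  df <- df[order(-df$node_strength, df$protein_id), ]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  attr(df, "scheme") <- scheme
  df
}

#' Hypergeometric association table for connected TF pairs
#'
#' For every network edge joining two TFs, computes the probability
#' (under [hypergeomAssociation()]) of the observed number of shared
#' interaction partners; smaller p-values indicate stronger functional
#' association.  Benjamini-Hochberg q-values are added; no correction is
#' applied to the significance filter itself.
#'
#' @param net a [TFNetwork-class].
#' @param alpha significance level for the `significant` flag (default
#'   0.05).
#' @return data.frame sorted by p: `gene_a`, `gene_b`, `n1`, `n2`, `m`,
#'   `N`, `p_value`, `q_value`, `significant`.
#' @export
tfAssociations <- function(net, alpha = 0.05) {
  stopifnot(is(net, "TFNetwork"), alpha >= 0, alpha <= 1)
  g <- net@graph
  N <- igraph::vcount(g)
  if (igraph::ecount(g) == 0)
    return(data.frame(gene_a = character(), gene_b = character(),
                      n1 = integer(), n2 = integer(), m = integer(),
                      N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical()))
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  isTf <- setNames(igraph::V(g)$is_tf, igraph::V(g)$name)
  keep <- isTf[ends[, 1]] & isTf[ends[, 2]]
  ends <- ends[keep, , drop = FALSE]
  deg <- igraph::degree(g)
  adj <- igraph::adjacent_vertices(g, igraph::V(g))
  names(adj) <- igraph::V(g)$name
  rows <- lapply(seq_len(nrow(ends)), function(i) {
    a <- ends[i, 1]; b <- ends[i, 2]
    m <- length(intersect(as.integer(adj[[a]]), as.integer(adj[[b]])))
    data.frame(gene_a = min(a, b), gene_b = max(a, b),
               n1 = unname(deg[a]), n2 = unname(deg[b]), m = m, N = N,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      n1 = integer(), n2 = integer(), m = integer(),
                      N = integer(), p_value = numeric(),
                      q_value = numeric(), significant = logical()))
  out$p_value <- hypergeomAssociation(out$n1, out$n2, out$m, out$N)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}
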