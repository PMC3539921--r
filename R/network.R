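## Network assembly, topology annotation (degree, clustering
## coefficient, betweenness) and pathway-membership evidence tiering.

#' Build the validated TF interaction network
#'
#' Edges are the retained association pairs whose Czekanowski-Dice GO
#' distance is defined and strictly below 1.  Structure-based scores are
#' attached where available; edges lacking structural data are retained
#' with `structural_score = NA`.  Nodes are all proteins appearing in
#' the retained pairs, so a protein whose every association failed the
#' GO criterion remains as an isolated node.
#'
#' @param retained data.frame with columns `gene_a`, `gene_b`, `score`
#'   and optionally `best_relation`, `relation_score`.
#' @param goTable data.frame from [goDistanceTable()] covering every
#'   retained pair.
#' @param structureCalls optional `calls` table from
#'   [scoreStructurePairs()].
#' @param tfFlags data.frame from [classifyTF()] covering every protein.
#' @return a [TFNetwork-class]; edges carry `association`, `go_distance`,
#'   `go_similarity`, `structural_score`, `structure_fraction`,
#'   `structure_interacting`, `relation`, `touches_tf`.
#' @export
buildNetwork <- function(retained, goTable, structureCalls = NULL,
                         tfFlags) {
  stopifnot(all(c("gene_a", "gene_b") %in% names(retained)))
  prot <- sort(unique(c(retained$gene_a, retained$gene_b)))
  missGo <- setdiff(prot, unique(c(goTable$gene_a, goTable$gene_b)))
  key <- .pairKey(retained$gene_a, retained$gene_b)
  goKey <- .pairKey(goTable$gene_a, goTable$gene_b)
  missPair <- key[!key %in% goKey]
  missTf <- setdiff(prot, tfFlags$protein_id)
  if (length(missPair) || length(missTf))
    stop("id mismatch between stages; missing GO distances for pairs: [",
         paste(gsub("\r", ":", missPair), collapse = ", "),
         "]; missing TF flags for: [",
         paste(missTf, collapse = ", "), "]")
  gi <- match(key, goKey)
  ed <- data.frame(
    gene_a = retained$gene_a, gene_b = retained$gene_b,
    association = if ("score" %in% names(retained)) retained$score
                  else NA_real_,
    go_distance = goTable$distance[gi],
    go_similarity = 1 - goTable$distance[gi],
    relation = if ("best_relation" %in% names(retained))
                 retained$best_relation else NA_character_,
    structural_score = NA_real_,
    structure_fraction = NA_real_,
    structure_interacting = NA,
    stringsAsFactors = FALSE)
  if (!is.null(structureCalls) && nrow(structureCalls)) {
    scKey <- .pairKey(structureCalls$gene_a, structureCalls$gene_b)
    si <- match(key, scKey)
    has <- !is.na(si) & structureCalls$status[si] == "scored"
    ed$structural_score[has] <- structureCalls$structural_score[si[has]]
    ed$structure_fraction[has] <- structureCalls$structure_fraction[si[has]]
    ed$structure_interacting[has] <- structureCalls$is_interacting[si[has]]
  }
  keep <- isGoInteracting(ed$go_distance)
  ed <- ed[keep & ed$gene_a != ed$gene_b, , drop = FALSE]
  isTf <- setNames(tfFlags$is_tf, tfFlags$protein_id)[prot]
  ed$touches_tf <- isTf[ed$gene_a] | isTf[ed$gene_b]
  vx <- data.frame(name = prot, is_tf = unname(isTf),
                   stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vx)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = "first")
  new("TFNetwork", graph = g)
}

#' Annotate network topology
#'
#' Adds per-node degree, clustering coefficient
#' `C_i = 2n / (k_i (k_i - 1))` (0 for degree < 2), and betweenness
#' `C_B(i) = sum_{j<k} g_jk(i) / g_jk` — raw, plus a version normalized
#' by `(n_c - 1)(n_c - 2) / 2` within each connected component of size
#' `n_c` (0 for components smaller than 3).  Isolated nodes get 0 for
#' all three metrics.
#'
#' @param net a [TFNetwork-class].
#' @return the network with node attributes `degree`, `clustering`,
#'   `betweenness_raw`, `betweenness_norm`.
#' @export
computeTopology <- function(net) {
  stopifnot(is(net, "TFNetwork"))
  g <- net@graph
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[!is.finite(cc)] <- 0
  btw <- igraph::betweenness(g, directed = FALSE)
  comp <- igraph::components(g)
  csize <- comp$csize[comp$membership]
  denom <- (csize - 1) * (csize - 2) / 2
  btwNorm <- ifelse(denom > 0, btw / denom, 0)
  g <- igraph::set_vertex_attr(g, "degree", value = as.numeric(deg))
  g <- igraph::set_vertex_attr(g, "clustering", value = cc)
  g <- igraph::set_vertex_attr(g, "betweenness_raw", value = btw)
  g <- igraph::set_vertex_attr(g, "betweenness_norm", value = btwNorm)
  initialize(net, graph = g)
}

.tierLevels <- c("HIGH", "MEDIUM", "LOW", "UNKNOWN")

#' Edge evidence tier from its endpoint tiers
#'
#' Rule: HIGH if both endpoints HIGH or HIGH-MEDIUM or HIGH-LOW; MEDIUM
#' if both MEDIUM or MEDIUM-LOW; LOW if both LOW.  UNKNOWN endpoints are
#' treated as LOW for the rule but flag the edge.
#'
#' @param tierA,tierB endpoint tiers (HIGH/MEDIUM/LOW/UNKNOWN).
#' @return character vector of edge tiers.
#' @export
edgeTier <- function(tierA, tierB) {
  stopifnot(all(tierA %in% .tierLevels), all(tierB %in% .tierLevels))
  a <- ifelse(tierA == "UNKNOWN", "LOW", tierA)
  b <- ifelse(tierB == "UNKNOWN", "LOW", tierB)
  ifelse(a == "HIGH" | b == "HIGH", "HIGH",
         ifelse(a == "MEDIUM" | b == "MEDIUM", "MEDIUM", "LOW"))
}

#' Tier nodes and edges by pathway-membership evidence
#'
#' Node tier: member of the disease-specific list -> HIGH; of the
#' cancer/signalling list -> MEDIUM; of any other pathway list -> LOW;
#' of none -> UNKNOWN (treated as LOW in the edge rule, flagged).
#'
#' @param net a [TFNetwork-class].
#' @param colonList,cancerList,otherList character vectors of protein
#'   ids (one id per line when read from file).
#' @return the network with node attribute `tier`, edge attributes
#'   `tier` and `tier_flagged`.
#' @export
tierEvidence <- function(net, colonList = character(),
                         cancerList = character(),
                         otherList = character()) {
  stopifnot(is(net, "TFNetwork"))
  g <- net@graph
  ids <- igraph::V(g)$name
  tier <- ifelse(ids %in% colonList, "HIGH",
          ifelse(ids %in% cancerList, "MEDIUM",
          ifelse(ids %in% otherList, "LOW", "UNKNOWN")))
  g <- igraph::set_vertex_attr(g, "tier", value = tier)
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = TRUE)
    ta <- tier[match(ends[, 1], ids)]
    tb <- tier[match(ends[, 2], ids)]
    g <- igraph::set_edge_attr(g, "tier", value = edgeTier(ta, tb))
    g <- igraph::set_edge_attr(g, "tier_flagged",
                               value = ta == "UNKNOWN" | tb == "UNKNOWN")
  }
  initialize(net, graph = g)
}

#' Write a TFNetwork as GraphML
#'
#' @param net a [TFNetwork-class].
#' @param path output file.
#' @export
writeNetworkGraphML <- function(net, path) {
  stopifnot(is(net, "TFNetwork"))
  g <- net@graph
  # GraphML cannot carry NA: recode sentinel values.
  for (at in igraph::edge_attr_names(g)) {
    v <- igraph::edge_attr(g, at)
    if (is.numeric(v)) v[is.na(v)] <- -1
    if (is.character(v)) v[is.na(v)] <- ""
    if (is.logical(v)) v <- as.integer(v)
    g <- igraph::set_edge_attr(g, at, value = v)
  }
  for (at in setdiff(igraph::vertex_attr_names(g), "name")) {
    v <- igraph::vertex_attr(g, at)
    if (is.numeric(v)) v[is.na(v)] <- -1
    if (is.character(v)) v[is.na(v)] <- ""
    if (is.logical(v)) v <- as.integer(v)
    g <- igraph::set_vertex_attr(g, at, value = v)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
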