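#' @import methods
NULL

#' TermVectorSet: tf*idf weight vectors for a corpus
#'
#' Holds the per-document term-frequency matrix and the derived tf*idf
#' weight matrix for a corpus mined against a gene thesaurus.  The weight
#' of term k in document i is `T_ik * log(N / n_k)` where `N` is the
#' number of documents and `n_k` the number of documents containing the
#' term; terms absent from a document (and terms absent from the whole
#' corpus) carry weight zero.
#'
#' @slot weights numeric matrix, documents x terms, tf*idf weights.
#' @slot termFreq numeric matrix, documents x terms, raw (or binary)
#'   term frequencies.
#' @slot docFreq named integer vector, per-term document frequency n_k.
#' @slot nDocs integer, number of documents N.
#' @slot logBase numeric, logarithm base used for the idf factor.
#' @export
setClass("TermVectorSet",
  representation(weights = "matrix", termFreq = "matrix",
                 docFreq = "integer", nDocs = "integer",
                 logBase = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@weights), dim(object@termFreq)))
      msg <- c(msg, "weights and termFreq dimensions differ")
    if (length(object@docFreq) != ncol(object@weights))
      msg <- c(msg, "docFreq length != number of terms")
    if (any(object@docFreq < 0L) || any(object@docFreq > object@nDocs))
      msg <- c(msg, "docFreq outside [0, nDocs]")
    if (any(object@weights < 0))
      msg <- c(msg, "negative tf*idf weight")
    if (any(object@weights[object@termFreq == 0] != 0))
      msg <- c(msg, "non-zero weight where term frequency is zero")
    if (length(msg)) msg else TRUE
  })

#' AssociationMatrix: symmetric gene-gene co-occurrence association scores
#'
#' The association between terms k and l is the dot product of their
#' per-document tf*idf weight columns, summed over all documents.  After
#' thresholding, `retainedPairs` lists the unordered pairs whose score
#' meets the threshold (zero-score pairs are never retained).
#'
#' @slot scores symmetric non-negative numeric matrix, zero diagonal.
#' @slot threshold numeric scalar (NA until thresholding is applied).
#' @slot retainedPairs data.frame with columns gene_a, gene_b, score.
#' @export
setClass("AssociationMatrix",
  representation(scores = "matrix", threshold = "numeric",
                 retainedPairs = "data.frame"),
  validity = function(object) {
    msg <- character()
    s <- object@scores
    if (nrow(s) != ncol(s)) msg <- c(msg, "scores not square")
    if (!isTRUE(all.equal(s, t(s), tolerance = 1e-12)))
      msg <- c(msg, "scores not symmetric")
    if (any(s < 0)) msg <- c(msg, "negative association score")
    if (any(diag(s) != 0)) msg <- c(msg, "non-zero diagonal")
    rp <- object@retainedPairs
    if (nrow(rp) && !is.na(object@threshold) &&
        any(rp$score < object@threshold))
      msg <- c(msg, "retained pair below threshold")
    if (length(msg)) msg else TRUE
  })

#' TFNetwork: validated transcription-factor interaction network
#'
#' An undirected graph whose edges are literature-mined associations that
#' passed the Gene Ontology distance criterion (distance < 1), carrying
#' GO distance/similarity, optional structure-based interaction scores,
#' relation labels and evidence tiers; nodes carry the TF flag, topology
#' metrics and node-level biological scores once computed.
#'
#' @slot graph an igraph object holding all node and edge attributes.
#' @export
setClass("TFNetwork",
  representation(graph = "ANY"),
  validity = function(object) {
    msg <- character()
    g <- object@graph
    if (!inherits(g, "igraph")) return("graph slot is not an igraph object")
    if (igraph::is_directed(g)) msg <- c(msg, "graph must be undirected")
    if (any(igraph::which_loop(g))) msg <- c(msg, "self-loops not allowed")
    d <- igraph::edge_attr(g, "go_distance")
    if (!is.null(d) && length(d) && any(!is.na(d) & d >= 1))
      msg <- c(msg, "edge with GO distance >= 1 retained")
    if (length(msg)) msg else TRUE
  })

#' ModuleSet: TF-anchored functional modules of a TFNetwork
#'
#' Each module is a connected induced subgraph of a prioritized TF's ego
#' network that contains the TF, with 3 to `sizeCap` members.  The table
#' carries the average module score (mean member node strength) and the
#' anchor-TF hypergeometric p-value under the recorded parameter binding.
#'
#' @slot modules named list of character vectors (member ids).
#' @slot table data.frame, one row per module.
#' @slot truncated logical, TRUE if the per-TF enumeration guard fired.
#' @export
setClass("ModuleSet",
  representation(modules = "list", table = "data.frame",
                 truncated = "logical"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@table) != length(object@modules))
      msg <- c(msg, "table rows != number of modules")
    sz <- lengths(object@modules)
    if (length(sz) && any(sz < 3L))
      msg <- c(msg, "module smaller than 3 nodes")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "TermVectorSet", function(object) {
  cat(sprintf("TermVectorSet: %d documents x %d terms (log base %g)\n",
              object@nDocs, ncol(object@weights), object@logBase))
  cat(sprintf("  terms present in corpus: %d\n", sum(object@docFreq > 0L)))
})

setMethod("show", "AssociationMatrix", function(object) {
  nz <- sum(object@scores[upper.tri(object@scores)] > 0)
  cat(sprintf("AssociationMatrix: %d terms, %d non-zero pairs\n",
              nrow(object@scores), nz))
  if (is.na(object@threshold)) {
    cat("  not thresholded\n")
  } else {
    cat(sprintf("  threshold %.6g, %d retained pairs\n",
                object@threshold, nrow(object@retainedPairs)))
  }
})

setMethod("show", "TFNetwork", function(object) {
  g <- object@graph
  tf <- igraph::vertex_attr(g, "is_tf")
  cat(sprintf("TFNetwork: %d nodes (%d TFs), %d edges\n",
              igraph::vcount(g),
              if (is.null(tf)) 0L else sum(tf, na.rm = TRUE),
              igraph::ecount(g)))
  ss <- igraph::edge_attr(g, "structural_score")
  if (!is.null(ss))
    cat(sprintf("  structurally scored edges: %d\n", sum(!is.na(ss))))
})

setMethod("show", "ModuleSet", function(object) {
  cat(sprintf("ModuleSet: %d modules\n", length(object@modules)))
  if (length(object@modules)) {
    tb <- table(lengths(object@modules))
    cat("  per size:", paste(sprintf("%s nodes: %d", names(tb), tb),
                             collapse = ", "), "\n")
  }
  if (isTRUE(object@truncated)) cat("  (enumeration guard truncated)\n")
})

#' Extract the node table of a TFNetwork
#'
#' @param net a [TFNetwork-class] object.
#' @return data.frame of node attributes, one row per node.
#' @export
nodeTable <- function(net) {
  stopifnot(is(net, "TFNetwork"))
  df <- igraph::as_data_frame(net@graph, what = "vertices")
  names(df)[names(df) == "name"] <- "protein_id"
  rownames(df) <- NULL
  df
}

#' Extract the edge table of a TFNetwork
#'
#' @param net a [TFNetwork-class] object.
#' @return data.frame of edge attributes, one row per edge.
#' @export
edgeTable <- function(net) {
  stopifnot(is(net, "TFNetwork"))
  df <- igraph::as_data_frame(net@graph, what = "edges")
  names(df)[names(df) == "from"] <- "gene_a"
  names(df)[names(df) == "to"] <- "gene_b"
  rownames(df) <- NULL
  df
}

#' The underlying igraph of a TFNetwork
#'
#' @param net a [TFNetwork-class] object.
#' @return the igraph object with all attributes.
#' @export
networkGraph <- function(net) {
  stopifnot(is(net, "TFNetwork"))
  net@graph
}

#' Association scores of an AssociationMatrix
#'
#' @param x an [AssociationMatrix-class] object.
#' @return the symmetric score matrix.
#' @export
associationScores <- function(x) {
  stopifnot(is(x, "AssociationMatrix"))
  x@scores
}

#' Retained pairs of a thresholded AssociationMatrix
#'
#' @param x an [AssociationMatrix-class] object.
#' @return data.frame with columns gene_a, gene_b, score.
#' @export
retainedPairs <- function(x) {
  stopifnot(is(x, "AssociationMatrix"))
  x@retainedPairs
}

#' tf*idf weight matrix of a TermVectorSet
#'
#' @param x a [TermVectorSet-class] object.
#' @return numeric matrix, documents x terms.
#' @export
termWeights <- function(x) {
  stopifnot(is(x, "TermVectorSet"))
  x@weights
}

#' Module member sets of a ModuleSet
#'
#' @param x a [ModuleSet-class] object.
#' @return named list of character vectors.
#' @export
moduleMembers <- function(x) {
  stopifnot(is(x, "ModuleSet"))
  x@modules
}

#' Module table of a ModuleSet
#'
#' @param x a [ModuleSet-class] object.
#' @return data.frame, one row per module.
#' @export
moduleTable <- function(x) {
  stopifnot(is(x, "ModuleSet"))
  x@table
}
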