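## TF-anchored module extraction (connected ego-network subgraphs of
## size >= 3), average module scoring and per-TF hypergeometric module
## significance.

# Enumerate all connected induced subgraphs of `adj` (adjacency list of
# integer neighbor vectors) that contain `root`, with sizes in
# [minSize, maxSize].  Each subgraph is emitted exactly once: candidates
# considered earlier at a level are excluded from deeper extensions.
.connectedSubgraphs <- function(adj, root, minSize, maxSize, maxCount) {
  out <- list(); nOut <- 0L; truncated <- FALSE
  emit <- function(sub) {
    nOut <<- nOut + 1L
    out[[nOut]] <<- sub
  }
  rec <- function(sub, ext, excluded) {
    if (truncated) return()
    for (i in seq_along(ext)) {
      if (nOut >= maxCount) { truncated <<- TRUE; return() }
      v <- ext[i]
      sub2 <- c(sub, v)
      if (length(sub2) >= minSize) emit(sub2)
      if (length(sub2) < maxSize) {
        excl2 <- c(excluded, ext[seq_len(i)])
        newNb <- setdiff(adj[[v]], c(sub2, excl2, ext))
        rec(sub2, c(ext[-seq_len(i)], newNb), excl2)
      }
    }
  }
  rec(root, setdiff(adj[[root]], root), integer())
  list(sets = if (nOut) out[seq_len(nOut)] else list(),
       truncated = truncated)
}

#' Extract TF-anchored functional modules
#'
#' For each prioritized TF (the top `rankPercentile` fraction of TFs by
#' node strength), enumerates the connected induced subgraphs of the
#' TF's ego network (the TF plus its direct interactors and the edges
#' among them) that contain the TF, with sizes from 3 up to `sizeCap`.
#' Identical node sets arising from different anchors are deduplicated,
#' keeping the anchor of the higher-ranked TF.  A per-TF enumeration
#' guard caps the number of subgraphs; truncation is logged and
#' recorded.
#'
#' @param net a [TFNetwork-class].
#' @param ranking data.frame from [rankNodes()].
#' @param sizeCap largest module size to enumerate (default 8; must be
#'   >= 3).
#' @param rankPercentile fraction of TFs (by strength) treated as
#'   prioritized (default 0.5).
#' @param maxPerTF per-TF subgraph enumeration guard (default 1e5).
#' @return a [ModuleSet-class]; its table has columns `module_id`,
#'   `anchor_tf`, `size`, `members`.
#' @export
extractModules <- function(net, ranking, sizeCap = 8,
                           rankPercentile = 0.5, maxPerTF = 1e5) {
  stopifnot(is(net, "TFNetwork"))
  if (sizeCap < 3) stop("sizeCap must be >= 3")
  g <- net@graph
  ids <- igraph::V(g)$name
  tfRank <- ranking[ranking$is_tf, , drop = FALSE]
  nKeep <- ceiling(nrow(tfRank) * rankPercentile)
  anchors <- tfRank$protein_id[seq_len(nKeep)]
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  seen <- new.env(parent = emptyenv())
  modules <- list(); anchorOf <- character(); truncated <- FALSE
  for (tf in anchors) {
    ri <- match(tf, ids)
    ego <- c(ri, adj[[ri]])
    if (length(ego) < 3L) next
    # adjacency restricted to the ego vertex set
    egoAdj <- lapply(setNames(adj[ego], ego), function(nb)
      intersect(nb, ego))
    names(egoAdj) <- as.character(ego)
    localAdj <- lapply(seq_along(ego), function(i)
      match(egoAdj[[i]], ego))
    res <- .connectedSubgraphs(localAdj, 1L, 3L, sizeCap, maxPerTF)
    if (res$truncated) {
      truncated <- TRUE
      .log("module enumeration truncated for TF ", tf,
           " at ", maxPerTF, " subgraphs", level = "WARN")
    }
    for (s in res$sets) {
      members <- sort(ids[ego[s]])
      key <- paste(members, collapse = "\r")
      if (!exists(key, seen)) {
        assign(key, TRUE, seen)
        modules[[length(modules) + 1L]] <- members
        anchorOf <- c(anchorOf, tf)
      }
    }
  }
  n <- length(modules)
  names(modules) <- sprintf("M%04d", seq_len(n))
  tab <- data.frame(
    module_id = names(modules) %||% character(),
    anchor_tf = if (n) anchorOf else character(),
    size = if (n) lengths(modules) else integer(),
    members = if (n) vapply(modules, paste, character(1), collapse = ",")
              else character(),
    stringsAsFactors = FALSE, row.names = NULL)
  new("ModuleSet", modules = modules, table = tab, truncated = truncated)
}

`%||%` <- function(a, b) if (is.null(a) || !length(a)) b else a

#' Average module score
#'
#' The arithmetic mean of the node strengths of the module members.
#'
#' @param members character vector of member protein ids.
#' @param ranking data.frame from [rankNodes()].
#' @return scalar mean strength.
#' @export
scoreModule <- function(members, ranking) {
  idx <- match(members, ranking$protein_id)
  if (any(is.na(idx)))
    stop("module members missing from ranking: ",
         paste(members[is.na(idx)], collapse = ", "))
  mean(ranking$node_strength[idx])
}

#' Hypergeometric module significance of a TF
#'
#' `p = 1 - sum_{i=0}^{k-1} pmf(i)`, the probability of observing at
#' least `k` under a hypergeometric mass.  Parameter bindings:
#' `"network"` (default, the symbols as listed): population `N` (total
#' network nodes), successes `S` (modules excluding the TF), draws `C`
#' (module size); `"modules"`: population `S` (total modules), successes
#' `I` (modules containing the TF), draws `C`.  Every result records its
#' binding.
#'
#' @param k observed-count threshold (p is the upper tail at `k`).
#' @param N total number of network nodes.
#' @param S number of modules excluding the TF under consideration.
#' @param C module size.
#' @param I number of modules containing the TF (used by the
#'   `"modules"` binding).
#' @param binding `"network"` or `"modules"`.
#' @return p-value in `[0, 1]`, with attribute `"binding"`.
#' @export
moduleTFPvalue <- function(k, N, S, C, I = NA_integer_,
                           binding = c("network", "modules")) {
  binding <- match.arg(binding)
  if (k < 0) stop("k must be >= 0")
  par <- switch(binding,
    network = list(pop = N, succ = S, draws = C),
    modules = list(pop = S, succ = I, draws = C))
  if (any(is.na(unlist(par))))
    stop("missing parameters for binding ", binding)
  if (par$succ > par$pop)
    stop("infeasible binding: successes (", par$succ,
         ") exceed population (", par$pop, ")")
  if (par$draws > par$pop)
    stop("infeasible binding: draws (", par$draws,
         ") exceed population (", par$pop, ")")
  lo <- max(0, par$draws - (par$pop - par$succ))
  hi <- min(par$succ, par$draws)
  # 1 - sum_{i<k} pmf(i), evaluated as the direct upper-tail sum to
  # avoid cancellation
  p <- if (k <= lo) 1
       else if (k > hi) 0
       else sum(exp(lchoose(par$succ, k:hi) +
                    lchoose(par$pop - par$succ, par$draws - (k:hi)) -
                    lchoose(par$pop, par$draws)))
  p <- min(max(p, 0), 1)
  attr(p, "binding") <- binding
  p
}

#' Score, test and rank a module set
#'
#' Computes the average module score (mean member node strength) and the
#' anchor-TF hypergeometric p-value for every module, filters modules at
#' `p < alpha`, and sorts by score (descending) within each size class.
#'
#' @param moduleSet a [ModuleSet-class] from [extractModules()].
#' @param net the [TFNetwork-class] the modules came from.
#' @param ranking data.frame from [rankNodes()].
#' @param alpha anchor-TF significance cutoff (default 0.05).
#' @param binding p-value parameter binding, see [moduleTFPvalue()].
#' @return list with `table` (all modules, scored), `ranked` (the
#'   filtered, ordered table) and `sizeSummary` (per-size module
#'   counts).
#' @export
rankModules <- function(moduleSet, net, ranking, alpha = 0.05,
                        binding = c("network", "modules")) {
  binding <- match.arg(binding)
  stopifnot(is(moduleSet, "ModuleSet"))
  tab <- moduleSet@table
  mods <- moduleSet@modules
  N <- igraph::vcount(net@graph)
  nMod <- length(mods)
  if (nMod) {
    tab$score <- vapply(mods, scoreModule, numeric(1), ranking = ranking)
    inCount <- vapply(seq_len(nMod), function(i)
      sum(vapply(mods, function(m) tab$anchor_tf[i] %in% m, logical(1))),
      integer(1))
    exCount <- nMod - inCount
    tab$S <- exCount
    tab$I <- inCount
    tab$k <- inCount
    # an infeasible binding (e.g. more modules than network nodes under
    # the "network" binding) yields NA rather than aborting the run
    tab$p_value <- vapply(seq_len(nMod), function(i) {
      tryCatch(as.numeric(moduleTFPvalue(k = tab$k[i], N = N, S = tab$S[i],
                                         C = tab$size[i], I = tab$I[i],
                                         binding = binding)),
               error = function(e) NA_real_)
    }, numeric(1))
    if (anyNA(tab$p_value))
      .log(sum(is.na(tab$p_value)),
           " module p-value(s) undefined (infeasible parameter binding)",
           level = "WARN")
    tab$binding <- binding
  } else {
    tab$score <- numeric(); tab$S <- integer(); tab$I <- integer()
    tab$k <- integer(); tab$p_value <- numeric()
    tab$binding <- character()
  }
  ranked <- tab[!is.na(tab$p_value) & tab$p_value < alpha, , drop = FALSE]
  ranked <- ranked[order(ranked$size, -ranked$score, ranked$module_id), ,
                   drop = FALSE]
  rownames(ranked) <- NULL
  sizes <- if (nMod) table(factor(tab$size, levels = 3:max(tab$size)))
           else table(integer())
  sizeSummary <- data.frame(size = as.integer(names(sizes)),
                            n_modules = as.integer(sizes))
  list(table = tab, ranked = ranked, sizeSummary = sizeSummary)
}
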