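## Hypergeometric pathway enrichment and major/minor functional-group
## classification.

#' Read a GMT gene-set file
#'
#' @param path GMT file (name, description, member genes per line).
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' Read a pathway functional-group label table
#'
#' @param path 2-column TSV: pathway_id <TAB> group (no header).
#' @return named character vector mapping pathway id to group.
#' @export
readGroupLabels <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("group label file must have 2 columns")
  setNames(df[[2]], df[[1]])
}

# log(sum(exp(x))) without overflow.
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Hypergeometric upper-tail p-value
#'
#' `P(X >= r)` for the overlap `X` between a user list of size `R` and a
#' pathway of size `n` drawn from a background of `N` genes:
#' `p = sum_{i = max(r, R+n-N)}^{min(n, R)} C(R, i) C(N-R, n-i) / C(N, n)`,
#' evaluated in log space.  At the lower support bound the sum covers
#' the whole support, so p is exactly 1.
#'
#' @param r observed overlap.
#' @param n pathway size (within the background).
#' @param R user-list size.
#' @param N background size.
#' @return the tail probability.
#' @export
hypergeomTail <- function(r, n, R, N) {
  stopifnot(r >= 0, n >= 0, R >= 0, N >= max(n, R), r <= min(n, R))
  lo <- max(r, R + n - N)
  hi <- min(n, R)
  if (lo <= max(0, R + n - N)) return(1)
  i <- lo:hi
  lp <- lchoose(R, i) + lchoose(N - R, n - i) - lchoose(N, n)
  min(exp(.logSumExp(lp)), 1)
}

#' Hypergeometric pathway enrichment of a protein list
#'
#' Tests each pathway for over-representation of the user list against
#' the background (default: the union of all pathway genes).  User-list
#' entries absent from the background are dropped with a logged count.
#'
#' @param userList character vector of gene/protein ids.
#' @param pathways named list of character vectors (e.g. from
#'   [readGMT()]).
#' @param background character vector of background genes, or NULL for
#'   the union of all pathway genes.
#' @param alpha significance level (default 0.05); the filter uses raw
#'   p-values, mirroring common practice for this analysis, with BH
#'   q-values reported alongside.
#' @param groups optional named character vector mapping pathway id to
#'   functional group.
#' @return data.frame sorted by ascending p: `pathway_id`, `R`, `n`,
#'   `r`, `p_value`, `q_value`, `significant`, `functional_group`.
#' @export
enrichPathways <- function(userList, pathways, background = NULL,
                           alpha = 0.05, groups = NULL) {
  if (!length(userList)) stop("empty user list")
  if (!length(pathways)) stop("empty pathway collection")
  if (is.null(background))
    background <- unique(unlist(pathways, use.names = FALSE))
  userList <- unique(userList)
  inBg <- userList %in% background
  if (any(!inBg))
    .log(sprintf("enrichPathways: dropped %d user gene(s) not in background",
                 sum(!inBg)), level = "WARN")
  user <- userList[inBg]
  if (!length(user)) stop("no user genes remain within the background")
  N <- length(unique(background))
  R <- length(user)
  out <- data.frame(
    pathway_id = names(pathways),
    R = R,
    n = vapply(pathways, function(p)
      length(intersect(unique(p), background)), integer(1)),
    r = vapply(pathways, function(p)
      length(intersect(unique(p), user)), integer(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out$p_value <- vapply(seq_len(nrow(out)), function(i)
    hypergeomTail(out$r[i], out$n[i], R, N), numeric(1))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < alpha
  out$functional_group <-
    if (is.null(groups)) "ungrouped"
    else {
      gl <- unname(groups[out$pathway_id])
      ifelse(is.na(gl) | !nzchar(gl), "ungrouped", gl)
    }
  out <- out[order(out$p_value, out$pathway_id), ]
  rownames(out) <- NULL
  out
}

#' Classify functional groups as major or minor
#'
#' Counts significant pathways per functional group; a group is `major`
#' when associated with more than 3 pathways and `minor` with 3 or
#' fewer.  Groups with no significant pathway are omitted.
#'
#' @param results data.frame from [enrichPathways()].
#' @return data.frame: `functional_group`, `n_pathways`, `class`.
#' @export
classifyFunctionalGroups <- function(results) {
  sig <- results[results$significant, , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(functional_group = character(),
                      n_pathways = integer(), class = character()))
  tb <- table(sig$functional_group)
  out <- data.frame(functional_group = names(tb),
                    n_pathways = as.integer(tb),
                    stringsAsFactors = FALSE)
  out$class <- ifelse(out$n_pathways > 3L, "major", "minor")
  out <- out[order(-out$n_pathways, out$functional_group), ]
  rownames(out) <- NULL
  out
}
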