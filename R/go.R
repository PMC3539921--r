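## Gene Ontology annotation similarity: Czekanowski-Dice distance on
## annotation sets, the distance < 1 interaction rule, and TF flagging by
## GO functionality terms.

#' Read GO annotations
#'
#' `readGAF` reads a GAF 2.x file (columns 2, 5 and 9: object id, GO id,
#' aspect); comment lines start with `!`.  Malformed lines (too few
#' columns or an aspect outside P/F/C) are skipped and counted.
#' `readAnnotationTSV` reads the simple 3-column alternative:
#' protein <TAB> go_id <TAB> aspect (BP/MF/CC).
#'
#' @param path input file.
#' @return data.frame with columns `protein`, `go_id`, `aspect`
#'   (BP/MF/CC).
#' @export
readGAF <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 9L
  aspectMap <- c(P = "BP", F = "MF", C = "CC")
  prot <- vapply(parts[ok], `[[`, character(1), 2L)
  goid <- vapply(parts[ok], `[[`, character(1), 5L)
  asp <- aspectMap[vapply(parts[ok], `[[`, character(1), 9L)]
  good <- !is.na(asp) & nzchar(prot) & nzchar(goid)
  nbad <- sum(!ok) + sum(!good)
  if (nbad > 0L)
    .log(sprintf("readGAF: skipped %d malformed line(s) of %d", nbad,
                 length(lines)), level = "WARN")
  data.frame(protein = prot[good], go_id = goid[good],
             aspect = unname(asp[good]), stringsAsFactors = FALSE)
}

#' @rdname readGAF
#' @export
readAnnotationTSV <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  need <- c("protein", "go_id", "aspect")
  if (!all(need %in% names(df)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  ok <- df$aspect %in% c("BP", "MF", "CC")
  if (any(!ok))
    .log(sprintf("readAnnotationTSV: skipped %d line(s) with bad aspect",
                 sum(!ok)), level = "WARN")
  df[ok, need]
}

#' Group an annotation table into per-protein GO term sets
#'
#' @param annotations data.frame with columns `protein`, `go_id`,
#'   `aspect`.
#' @return named list; each element has `terms` (all GO ids) and
#'   `byAspect` (list BP/MF/CC).
#' @export
goAnnotationSets <- function(annotations) {
  stopifnot(all(c("protein", "go_id", "aspect") %in% names(annotations)))
  split_ <- split(annotations[, c("go_id", "aspect")], annotations$protein)
  lapply(split_, function(d) {
    list(terms = unique(d$go_id),
         byAspect = list(BP = unique(d$go_id[d$aspect == "BP"]),
                         MF = unique(d$go_id[d$aspect == "MF"]),
                         CC = unique(d$go_id[d$aspect == "CC"])))
  })
}

#' Czekanowski-Dice distance between two annotation sets
#'
#' `d(A, B) = |A delta B| / (|A union B| + |A intersect B|)`, where delta
#' is the symmetric set difference.  d is 0 for identical non-empty sets,
#' 1 for disjoint non-empty sets, and undefined (NA) when both sets are
#' empty.
#'
#' @param a,b character vectors of GO term ids (treated as sets).
#' @return distance in `[0, 1]`, or NA if both sets are empty.
#' @export
czekanowskiDice <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) && !length(b)) return(NA_real_)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  (uni - inter) / (uni + inter)
}

#' The GO interaction rule
#'
#' A protein pair is considered interacting when its overall
#' Czekanowski-Dice annotation distance is strictly below 1.  An
#' undefined distance (both annotation sets empty) is not interacting.
#'
#' @param distance numeric vector of distances (NA = undefined).
#' @return logical vector.
#' @export
isGoInteracting <- function(distance) {
  !is.na(distance) & distance < 1
}

#' Pairwise GO distance table
#'
#' Computes, for each requested pair, the overall Czekanowski-Dice
#' distance plus the per-aspect (BP/MF/CC) distances, the similarity
#' (1 - distance) used as the downstream edge weight, and the
#' interaction call.
#'
#' @param annots result of [goAnnotationSets()].
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @return data.frame with one row per pair.
#' @export
goDistanceTable <- function(annots, pairs) {
  getSet <- function(id) {
    if (id %in% names(annots)) annots[[id]]
    else list(terms = character(),
              byAspect = list(BP = character(), MF = character(),
                              CC = character()))
  }
  n <- nrow(pairs)
  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    distance = NA_real_, distance_BP = NA_real_,
                    distance_MF = NA_real_, distance_CC = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    A <- getSet(pairs$gene_a[i]); B <- getSet(pairs$gene_b[i])
    out$distance[i] <- czekanowskiDice(A$terms, B$terms)
    for (asp in c("BP", "MF", "CC"))
      out[[paste0("distance_", asp)]][i] <-
        czekanowskiDice(A$byAspect[[asp]], B$byAspect[[asp]])
  }
  out$similarity <- 1 - out$distance
  out$interacting <- isGoInteracting(out$distance)
  out
}

#' Flag transcription factors by GO functionality terms
#'
#' A protein is flagged as a TF when its annotation set intersects the
#' configured list of TF-functionality GO terms (the six functionalities:
#' TF, TF activator, TF co-activator, TF repressor, TF co-repressor
#' activity, DNA-binding transcription activity — supplied as term ids).
#'
#' @param annots result of [goAnnotationSets()].
#' @param tfTerms non-empty character vector of GO term ids.
#' @return data.frame with columns `protein_id`, `is_tf`,
#'   `matched_functionalities` (comma-separated, empty if none).
#' @export
classifyTF <- function(annots, tfTerms) {
  if (!length(tfTerms)) stop("tfTerms must be non-empty")
  ids <- names(annots)
  matched <- lapply(annots, function(a) sort(intersect(a$terms, tfTerms)))
  data.frame(
    protein_id = ids,
    is_tf = lengths(matched) > 0L,
    matched_functionalities = vapply(matched, paste, character(1),
                                     collapse = ","),
    stringsAsFactors = FALSE, row.names = NULL)
}
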