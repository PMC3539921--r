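## Corpus mining: dictionary NER against a gene thesaurus, tf*idf term
## vectors, the gene-gene association matrix and typed relation extraction.

#' Read a corpus of abstracts
#'
#' Accepts either a JSON-lines file (one object per abstract with fields
#' `id` and `text`) or a directory of plain-text files named `<id>.txt`.
#'
#' @param path file or directory path.
#' @return data.frame with columns `doc_id`, `text`.
#' @export
readCorpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no .txt files found in corpus directory: ", path)
    docs <- data.frame(
      doc_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f)
        paste(readLines(f, warn = FALSE, encoding = "UTF-8"), collapse = " "),
        character(1)),
      stringsAsFactors = FALSE)
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("empty corpus file: ", path)
    recs <- lapply(lines, jsonlite::fromJSON)
    docs <- data.frame(
      doc_id = vapply(recs, function(r) as.character(r$id), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      stringsAsFactors = FALSE)
  } else {
    stop("corpus path does not exist: ", path)
  }
  if (anyDuplicated(docs$doc_id))
    stop("duplicate document ids in corpus: ",
         paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "))
  docs
}

#' Construct a gene thesaurus
#'
#' @param entries named list mapping canonical id to a character vector of
#'   synonyms (the canonical id itself need not be listed; it is added).
#' @return an object of class `GeneThesaurus`.
#' @details Matching is case-insensitive, so synonyms are stored
#'   lower-cased; a synonym mapping to two canonical ids is a load error.
#' @export
geneThesaurus <- function(entries) {
  stopifnot(is.list(entries), length(entries) > 0, !is.null(names(entries)))
  .makeGeneThesaurus(entries)
}

#' @rdname geneThesaurus
#' @param path two-column TSV: canonical_id <TAB> synonym, one per line.
#' @export
readGeneThesaurus <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("gene thesaurus must have 2 tab-separated columns")
  entries <- split(df[[2]], df[[1]])
  .makeGeneThesaurus(entries)
}

.makeGeneThesaurus <- function(entries) {
  ids <- names(entries)
  syns <- lapply(seq_along(entries), function(i)
    unique(tolower(c(ids[i], as.character(entries[[i]])))))
  names(syns) <- ids
  flat <- data.frame(
    canonical = rep(ids, lengths(syns)),
    synonym = unlist(syns, use.names = FALSE),
    stringsAsFactors = FALSE)
  dup <- flat$synonym[duplicated(flat$synonym)]
  bad <- unique(dup[vapply(dup, function(s)
    length(unique(flat$canonical[flat$synonym == s])) > 1, logical(1))])
  if (length(bad))
    stop("synonym collision across canonical ids: ",
         paste(bad, collapse = ", "))
  if (any(!nzchar(flat$synonym))) stop("empty synonym in thesaurus")
  structure(list(entries = syns, M = length(ids)), class = "GeneThesaurus")
}

#' Construct or read a relation thesaurus
#'
#' @param entries named list mapping a relation label to its trigger words.
#' @return object of class `RelationThesaurus`; triggers are lower-cased
#'   and must be unique across labels.
#' @export
relationThesaurus <- function(entries) {
  stopifnot(is.list(entries), length(entries) > 0, !is.null(names(entries)))
  trig <- lapply(entries, function(x) unique(tolower(as.character(x))))
  flat <- unlist(trig, use.names = FALSE)
  if (anyDuplicated(flat))
    stop("trigger word assigned to two relation labels: ",
         paste(unique(flat[duplicated(flat)]), collapse = ", "))
  structure(list(entries = trig), class = "RelationThesaurus")
}

#' @rdname relationThesaurus
#' @param path two-column TSV: label <TAB> trigger.
#' @export
readRelationThesaurus <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) < 2) stop("relation thesaurus must have 2 tab-separated columns")
  relationThesaurus(split(df[[2]], df[[1]]))
}

#' Split text into sentences
#'
#' Default rule: split after `.`, `!` or `?` followed by whitespace and an
#' upper-case letter or digit.  The pattern is configurable.
#'
#' @param text character vector.
#' @param pattern perl regex used as the split point.
#' @return list of character vectors of sentences.
#' @export
splitSentences <- function(text,
                           pattern = "(?<=[.!?])\\s+(?=[A-Z0-9])") {
  strsplit(text, pattern, perl = TRUE)
}

# Dictionary matcher: counts non-overlapping, token-boundary,
# case-insensitive synonym matches, longest synonym first, resolved
# left-to-right.  Returns a named integer vector over canonical ids.
.matchCounts <- function(text, thesaurus) {
  ids <- names(thesaurus$entries)
  counts <- setNames(integer(length(ids)), ids)
  low <- tolower(text)
  n <- nchar(low)
  if (n == 0L) return(counts)
  consumed <- logical(n)
  flat <- data.frame(
    canonical = rep(ids, lengths(thesaurus$entries)),
    synonym = unlist(thesaurus$entries, use.names = FALSE),
    stringsAsFactors = FALSE)
  flat <- flat[order(-nchar(flat$synonym), flat$synonym, flat$canonical), ]
  for (i in seq_len(nrow(flat))) {
    rx <- paste0("\\b", .rxEscape(flat$synonym[i]), "\\b")
    m <- gregexpr(rx, low, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (j in seq_along(m)) {
      span <- m[j]:(m[j] + len[j] - 1L)
      if (!any(consumed[span])) {
        counts[flat$canonical[i]] <- counts[flat$canonical[i]] + 1L
        consumed[span] <- TRUE
      }
    }
  }
  counts
}

# TRUE for each canonical id with at least one (unmasked) match.
.genesPresent <- function(text, thesaurus) {
  names(which(.matchCounts(text, thesaurus) > 0L))
}

#' Build tf*idf term vectors for a corpus
#'
#' Converts each document into an M-dimensional weight vector over the
#' gene thesaurus: `W_ik = T_ik * log(N / n_k)`, where `T_ik` counts
#' occurrences of any synonym of term k in document i, `N` is the corpus
#' size and `n_k` the number of documents containing term k.  Terms that
#' occur in every document get weight zero; terms absent from the corpus
#' get an all-zero column.
#'
#' @param corpus data.frame with columns `doc_id`, `text`.
#' @param thesaurus a `GeneThesaurus`.
#' @param logBase base of the idf logarithm (default 10).
#' @param termFreq `"count"` (raw occurrence counts, default) or
#'   `"binary"` (presence/absence).
#' @return a [TermVectorSet-class].
#' @export
buildTermVectors <- function(corpus, thesaurus, logBase = 10,
                             termFreq = c("count", "binary")) {
  termFreq <- match.arg(termFreq)
  stopifnot(inherits(thesaurus, "GeneThesaurus"))
  if (!is.data.frame(corpus) || !nrow(corpus))
    stop("corpus is empty: at least one document is required")
  if (anyDuplicated(corpus$doc_id)) stop("duplicate document ids")
  ids <- names(thesaurus$entries)
  N <- nrow(corpus)
  tf <- t(vapply(corpus$text, .matchCounts, integer(length(ids)),
                 thesaurus = thesaurus))
  dimnames(tf) <- list(corpus$doc_id, ids)
  storage.mode(tf) <- "double"
  if (termFreq == "binary") tf <- (tf > 0) + 0
  nk <- as.integer(colSums(tf > 0))
  idf <- ifelse(nk > 0L, log(N / nk, base = logBase), 0)
  W <- sweep(tf, 2L, idf, `*`)
  new("TermVectorSet", weights = W, termFreq = tf,
      docFreq = setNames(nk, ids), nDocs = as.integer(N),
      logBase = logBase)
}

#' Compute the gene-gene association matrix
#'
#' `association_kl = sum_i W_ik * W_il` over documents i, for term pairs
#' k != l; the diagonal is set to zero and ignored.
#'
#' @param vectors a [TermVectorSet-class].
#' @return an (unthresholded) [AssociationMatrix-class].
#' @export
computeAssociationMatrix <- function(vectors) {
  stopifnot(is(vectors, "TermVectorSet"))
  W <- vectors@weights
  A <- crossprod(W)
  diag(A) <- 0
  A <- (A + t(A)) / 2  # enforce exact numerical symmetry
  new("AssociationMatrix", scores = A, threshold = NA_real_,
      retainedPairs = data.frame(gene_a = character(), gene_b = character(),
                                 score = numeric()))
}

#' Threshold an association matrix
#'
#' Retains exactly the unordered pairs whose association score meets the
#' threshold.  Pairs with score zero are never retained, even at
#' threshold zero.  When `threshold` is NULL the default is the 95th
#' percentile of the non-zero pair scores.
#'
#' @param matrix an [AssociationMatrix-class].
#' @param threshold non-negative scalar, or NULL for the percentile
#'   default.
#' @param percentile quantile used for the default threshold.
#' @return the matrix with `threshold` and `retainedPairs` filled in.
#' @export
thresholdAssociations <- function(matrix, threshold = NULL,
                                  percentile = 0.95) {
  stopifnot(is(matrix, "AssociationMatrix"))
  s <- matrix@scores
  ut <- upper.tri(s)
  nz <- s[ut & s > 0]
  if (is.null(threshold)) {
    threshold <- if (length(nz)) unname(quantile(nz, percentile)) else 0
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold < 0)
    stop("threshold must be a single non-negative number")
  idx <- which(ut & s > 0 & s >= threshold, arr.ind = TRUE)
  rp <- data.frame(
    gene_a = rownames(s)[idx[, 1]],
    gene_b = colnames(s)[idx[, 2]],
    score = s[idx],
    stringsAsFactors = FALSE)
  rp <- rp[order(-rp$score, rp$gene_a, rp$gene_b), ]
  rownames(rp) <- NULL
  initialize(matrix, threshold = threshold, retainedPairs = rp)
}

#' Extract typed relations for retained gene pairs
#'
#' For each pair, a relation label m scores the number of sentences in
#' the corpus that contain a synonym of both genes and a trigger word of
#' the relation; the label with the highest count is assigned (ties
#' broken by lexicographically smallest label; none if all counts are
#' zero).
#'
#' @param corpus data.frame with columns `doc_id`, `text`.
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param thesaurus a `GeneThesaurus`.
#' @param relations a `RelationThesaurus`.
#' @param sentencePattern regex passed to [splitSentences()].
#' @return data.frame with columns `gene_a`, `gene_b`, `best_relation`
#'   (NA if no evidence), `relation_score`; the full per-relation count
#'   matrix is attached as attribute `"counts"`.
#' @export
extractRelations <- function(corpus, pairs, thesaurus, relations,
                             sentencePattern = "(?<=[.!?])\\s+(?=[A-Z0-9])") {
  stopifnot(inherits(thesaurus, "GeneThesaurus"),
            inherits(relations, "RelationThesaurus"))
  labels <- sort(names(relations$entries))
  if (!nrow(pairs)) {
    out <- data.frame(gene_a = character(), gene_b = character(),
                      best_relation = character(), relation_score = integer())
    attr(out, "counts") <- matrix(0L, 0L, length(labels),
                                  dimnames = list(NULL, labels))
    return(out)
  }
  sents <- unlist(splitSentences(corpus$text, sentencePattern),
                  use.names = FALSE)
  geneSets <- lapply(sents, .genesPresent, thesaurus = thesaurus)
  lowSents <- tolower(sents)
  labHits <- vapply(labels, function(lab) {
    rx <- paste0("\\b(",
                 paste(.rxEscape(relations$entries[[lab]]), collapse = "|"),
                 ")\\b")
    grepl(rx, lowSents, perl = TRUE)
  }, logical(length(sents)))
  if (length(sents) == 1L) labHits <- matrix(labHits, nrow = 1L,
                                             dimnames = list(NULL, labels))
  counts <- matrix(0L, nrow = nrow(pairs), ncol = length(labels),
                   dimnames = list(NULL, labels))
  for (p in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[p]; b <- pairs$gene_b[p]
    both <- vapply(geneSets, function(g) a %in% g && b %in% g, logical(1))
    if (any(both))
      counts[p, ] <- as.integer(colSums(labHits[both, , drop = FALSE]))
  }
  storage.mode(counts) <- "integer"
  best <- apply(counts, 1L, function(x) {
    if (all(x == 0L)) NA_character_ else labels[which.max(x)]
  })
  out <- data.frame(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    best_relation = best,
    relation_score = as.integer(apply(counts, 1L, max)),
    stringsAsFactors = FALSE)
  attr(out, "counts") <- counts
  out
}
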