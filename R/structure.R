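## Structure-based interaction validation: interface-residue prediction,
## the per-structure-pair interaction score on 6 A C-alpha contacts, and
## the 30%-of-structures protein-pair call.

# Kyte-Doolittle hydrophobicity scale, three-letter residue codes.
.kdHydrophobicity <- c(
  ILE =  4.5, VAL =  4.2, LEU =  3.8, PHE =  2.8, CYS =  2.5, MET =  1.9,
  ALA =  1.8, GLY = -0.4, THR = -0.7, SER = -0.8, TRP = -0.9, TYR = -1.3,
  PRO = -1.6, HIS = -3.2, GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
  LYS = -3.9, ARG = -4.5)

#' Default hydrophobicity table for interface prediction
#'
#' @return named numeric vector (Kyte-Doolittle scale, 3-letter codes).
#' @export
hydrophobicityTable <- function() .kdHydrophobicity

#' Configuration for the default interface-residue predictor
#'
#' The default predictor scores each residue as a weighted sum of a
#' scaled hydrophobicity-table value and a centroid-distance exposure
#' proxy (distance from the chain centroid, scaled to the chain maximum),
#' and keeps residues whose score meets the cutoff.
#'
#' @param hydroWeight,exposureWeight weights of the two components.
#' @param cutoff minimum combined score for a residue to be predicted.
#' @param table named hydrophobicity table (3-letter residue codes).
#' @return list of class `InterfacePredictorConfig`.
#' @export
interfacePredictorConfig <- function(hydroWeight = 0.5,
                                     exposureWeight = 0.5,
                                     cutoff = 0.5,
                                     table = hydrophobicityTable()) {
  stopifnot(hydroWeight >= 0, exposureWeight >= 0,
            hydroWeight + exposureWeight > 0)
  structure(list(hydroWeight = hydroWeight, exposureWeight = exposureWeight,
                 cutoff = cutoff, table = table),
            class = "InterfacePredictorConfig")
}

#' Read one chain of a PDB coordinate file as C-alpha residues
#'
#' Only ATOM coordinate records are used.  Residues with no resolved
#' C-alpha are skipped and reported in the `coverage` attribute.
#'
#' @param path PDB-format file.
#' @param chain chain identifier; default: the first chain in the file.
#' @param structureId identifier attached to the result (default: file
#'   name without extension).
#' @return data.frame with columns `resno`, `resid`, `x`, `y`, `z`;
#'   attributes `structure_id`, `chain`, `coverage`.
#' @export
readChainStructure <- function(path, chain = NULL, structureId = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(atoms)) stop("no ATOM coordinate records in ", path)
  if (is.null(chain)) chain <- atoms$chain[1]
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (!nrow(atoms)) stop("chain ", chain, " not found in ", path)
  nres <- length(unique(atoms$resno))
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  bad <- !is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z)
  ca <- ca[!bad, , drop = FALSE]
  out <- data.frame(resno = ca$resno, resid = ca$resid,
                    x = ca$x, y = ca$y, z = ca$z,
                    stringsAsFactors = FALSE)
  attr(out, "structure_id") <-
    if (is.null(structureId)) sub("\\.[^.]*$", "", basename(path))
    else structureId
  attr(out, "chain") <- chain
  attr(out, "coverage") <- if (nres) nrow(out) / nres else 0
  out
}

#' Predict probable interface residues of a chain
#'
#' @param chain data.frame as returned by [readChainStructure()].
#' @param config an [interfacePredictorConfig()].
#' @param predictor `"default"` (hydrophobicity + exposure proxy),
#'   `"all"` (every residue; useful for testing), or a function
#'   `function(chain, config)` returning residue numbers.
#' @return integer vector of predicted residue numbers (subset of
#'   `chain$resno`); deterministic for fixed inputs.
#' @export
predictInterfaceResidues <- function(chain,
                                     config = interfacePredictorConfig(),
                                     predictor = "default") {
  if (is.function(predictor)) return(predictor(chain, config))
  predictor <- match.arg(predictor, c("default", "all"))
  if (!nrow(chain)) return(integer())
  if (predictor == "all") return(chain$resno)
  tbl <- config$table
  rng <- range(tbl)
  h <- unname(tbl[chain$resid])
  h[is.na(h)] <- rng[1]  # unknown residue type: least hydrophobic
  hScaled <- (h - rng[1]) / (rng[2] - rng[1])
  xyz <- as.matrix(chain[, c("x", "y", "z")])
  centroid <- colMeans(xyz)
  d <- sqrt(rowSums(sweep(xyz, 2L, centroid)^2))
  dScaled <- if (max(d) > 0) d / max(d) else rep(1, length(d))
  w <- config$hydroWeight + config$exposureWeight
  score <- (config$hydroWeight * hScaled +
            config$exposureWeight * dScaled) / w
  chain$resno[score >= config$cutoff]
}

#' Score one structure pair for interaction
#'
#' A predicted residue counts as interacting when its C-alpha lies
#' within `distanceThreshold` of any predicted residue of the partner
#' chain.  The interaction score is the number of interacting residues
#' over the total number of probable (predicted) residues on both
#' chains; a pair satisfies the criterion when the score is at least
#' `minFraction` (inclusive).
#'
#' @param chainA,chainB data.frames from [readChainStructure()].
#' @param predA,predB predicted residue numbers for each chain.
#' @param distanceThreshold C-alpha distance cutoff in angstroms
#'   (default 6).
#' @param minFraction minimum interacting-residue fraction (default
#'   0.10).
#' @return one-row data.frame: `interacting_count`, `probable_count`,
#'   `interaction_score` (NA when no residues were predicted),
#'   `satisfies`, `flagged`.
#' @export
structurePairScore <- function(chainA, predA, chainB, predB,
                               distanceThreshold = 6,
                               minFraction = 0.10) {
  ca <- as.matrix(chainA[chainA$resno %in% predA, c("x", "y", "z")])
  cb <- as.matrix(chainB[chainB$resno %in% predB, c("x", "y", "z")])
  probable <- nrow(ca) + nrow(cb)
  if (probable == 0L)
    return(data.frame(interacting_count = 0L, probable_count = 0L,
                      interaction_score = NA_real_, satisfies = FALSE,
                      flagged = TRUE))
  nInter <- 0L
  if (nrow(ca) && nrow(cb)) {
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), `+`) - 2 * tcrossprod(ca, cb)
    d2[d2 < 0] <- 0
    close <- d2 <= distanceThreshold^2
    nInter <- sum(apply(close, 1L, any)) + sum(apply(close, 2L, any))
  }
  score <- nInter / probable
  data.frame(interacting_count = as.integer(nInter),
             probable_count = as.integer(probable),
             interaction_score = score,
             satisfies = score >= minFraction,
             flagged = FALSE)
}

#' Call a protein pair from its per-structure-pair results
#'
#' A protein pair is called interacting when at least
#' `structureFractionThreshold` (default 30%, inclusive) of its
#' structure pairs satisfy the distance/residue criterion.  A pair with
#' no mapped structures yields the distinct status
#' `"no_structural_evidence"` rather than a negative call.
#'
#' @param satisfies logical vector, one element per structure pair.
#' @param structureFractionThreshold fraction of satisfying structures
#'   required (default 0.30).
#' @return one-row data.frame: `n_structures`, `n_satisfying`,
#'   `structure_fraction`, `is_interacting`, `status`.
#' @export
pairInteractionCall <- function(satisfies,
                                structureFractionThreshold = 0.30) {
  satisfies <- as.logical(satisfies)
  satisfies[is.na(satisfies)] <- FALSE
  n <- length(satisfies)
  if (n == 0L)
    return(data.frame(n_structures = 0L, n_satisfying = 0L,
                      structure_fraction = NA_real_,
                      is_interacting = NA,
                      status = "no_structural_evidence",
                      stringsAsFactors = FALSE))
  frac <- sum(satisfies) / n
  data.frame(n_structures = n, n_satisfying = sum(satisfies),
             structure_fraction = frac,
             is_interacting = frac >= structureFractionThreshold,
             status = "scored", stringsAsFactors = FALSE)
}

#' Read a protein-to-structure mapping table
#'
#' @param path TSV with columns `protein_id`, `pdb_file`, `chain`
#'   (header required); `pdb_file` is resolved relative to `dir` when
#'   not absolute.
#' @param dir base directory for relative file names.
#' @return data.frame with columns `protein_id`, `pdb_file`, `chain`.
#' @export
readStructureMap <- function(path, dir = dirname(path)) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  need <- c("protein_id", "pdb_file", "chain")
  if (!all(need %in% names(df)))
    stop("structure map must have columns: ", paste(need, collapse = ", "))
  abs <- grepl("^(/|[A-Za-z]:)", df$pdb_file)
  df$pdb_file[!abs] <- file.path(dir, df$pdb_file[!abs])
  df[, need]
}

#' Run the structure-based interaction algorithm over protein pairs
#'
#' For each protein pair, every mapped structure of the first protein is
#' paired all-vs-all with every mapped structure of the second; each
#' structure pair is scored with [structurePairScore()] and the pair is
#' called with [pairInteractionCall()].  The per-pair `structural_score`
#' attached to network edges is the mean per-structure-pair interaction
#' score.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param structureMap data.frame from [readStructureMap()].
#' @param config an [interfacePredictorConfig()].
#' @param predictor predictor selector, see [predictInterfaceResidues()].
#' @param distanceThreshold,minFraction,structureFractionThreshold the
#'   6 angstrom / 10% / 30% algorithm thresholds.
#' @return list with `structurePairs` (per-structure-pair table) and
#'   `calls` (per-protein-pair table incl. `structural_score`).
#' @export
scoreStructurePairs <- function(pairs, structureMap,
                                config = interfacePredictorConfig(),
                                predictor = "default",
                                distanceThreshold = 6,
                                minFraction = 0.10,
                                structureFractionThreshold = 0.30) {
  cache <- new.env(parent = emptyenv())
  getChain <- function(file, chain) {
    key <- paste(file, chain, sep = "|")
    if (!exists(key, cache)) {
      ch <- readChainStructure(file, chain = chain)
      assign(key, list(chain = ch,
                       pred = predictInterfaceResidues(ch, config,
                                                       predictor)),
             cache)
    }
    get(key, cache)
  }
  spRows <- list(); callRows <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    mapA <- structureMap[structureMap$protein_id == a, , drop = FALSE]
    mapB <- structureMap[structureMap$protein_id == b, , drop = FALSE]
    if (!nrow(mapA) || !nrow(mapB)) {
      cc <- pairInteractionCall(logical(), structureFractionThreshold)
      cc$gene_a <- a; cc$gene_b <- b; cc$structural_score <- NA_real_
      callRows[[length(callRows) + 1L]] <- cc
      next
    }
    sat <- logical(); scores <- numeric()
    for (ia in seq_len(nrow(mapA))) for (ib in seq_len(nrow(mapB))) {
      A <- getChain(mapA$pdb_file[ia], mapA$chain[ia])
      B <- getChain(mapB$pdb_file[ib], mapB$chain[ib])
      r <- structurePairScore(A$chain, A$pred, B$chain, B$pred,
                              distanceThreshold, minFraction)
      r$gene_a <- a; r$gene_b <- b
      r$structure_a <- attr(A$chain, "structure_id")
      r$structure_b <- attr(B$chain, "structure_id")
      spRows[[length(spRows) + 1L]] <- r
      sat <- c(sat, r$satisfies)
      scores <- c(scores, r$interaction_score)
    }
    cc <- pairInteractionCall(sat, structureFractionThreshold)
    cc$gene_a <- a; cc$gene_b <- b
    cc$structural_score <- if (all(is.na(scores))) NA_real_
                           else mean(scores, na.rm = TRUE)
    callRows[[length(callRows) + 1L]] <- cc
  }
  list(structurePairs = do.call(rbind, spRows),
       calls = do.call(rbind, callRows))
}
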