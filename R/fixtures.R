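## Deterministic synthetic-fixture generators: corpora with planted
## co-mentioned gene pairs, GO annotations with planted overlap, toy
## C-alpha structures with planted interfaces, pathway collections with
## a planted enriched set, and network-level fixtures with planted hubs
## and modules.  Every generator is a pure function of (config, seed);
## each draws from its own stream derived from the master seed by a
## stable label.

#' Fixture configuration
#'
#' Defines the study conditions emulated by the synthetic generators:
#' corpus size, planted co-mention rates, GO overlap of planted
#' interacting pairs, structure geometry and pathway sizes.
#'
#' @param seed master seed; all generator streams derive from it.
#' @param nGenes number of genes in the thesaurus.
#' @param nTFs number of TF genes (the first `nTFs` gene ids).
#' @param nDocs number of abstracts in the corpus.
#' @param coMentionRate per-document probability that a planted pair is
#'   co-mentioned in a relation sentence.
#' @param backgroundRate per-document, per-gene probability of an
#'   independent background mention.
#' @param goTermsPerGene GO terms annotated per gene.
#' @param goOverlap fraction of terms shared within a planted pair.
#' @param goPoolSize size of the background GO term pool.
#' @param tfTerms GO term ids marking the six TF functionalities.
#' @param nResidues residues per synthetic chain.
#' @param interfaceOffset inter-chain offset (angstroms) of planted
#'   dimers; below the 6 angstrom contact threshold.
#' @param decoyOffset offset of pulled-apart decoy dimers.
#' @param structuresPerPair replicate structures per structured pair.
#' @param nPathways number of pathways in the GMT.
#' @param pathwaySizeRange min/max pathway size.
#' @param nBackgroundGenes extra non-network genes in the pathway
#'   universe.
#' @param plantedEnrichment plant one enriched pathway (TRUE) or
#'   generate a null collection (FALSE).
#' @return list of class `FixtureConfig`.
#' @export
fixtureConfig <- function(seed = 1L, nGenes = 30L, nTFs = 6L,
                          nDocs = 200L, coMentionRate = 0.15,
                          backgroundRate = 0.05,
                          goTermsPerGene = 6L, goOverlap = 0.5,
                          goPoolSize = 40L,
                          tfTerms = c("GO:0003700", "GO:0001228",
                                      "GO:0003712", "GO:0001227",
                                      "GO:0003714", "GO:0000981"),
                          nResidues = 30L, interfaceOffset = 5,
                          decoyOffset = 50, structuresPerPair = 3L,
                          nPathways = 20L,
                          pathwaySizeRange = c(8L, 15L),
                          nBackgroundGenes = 120L,
                          plantedEnrichment = TRUE) {
  rates <- c(coMentionRate, backgroundRate, goOverlap)
  if (any(rates < 0 | rates > 1))
    stop("rates must lie in [0, 1]")
  stopifnot(nGenes >= 12, nTFs >= 1, nTFs < nGenes, nDocs >= 1,
            nResidues >= 5, length(tfTerms) >= 1)
  genes <- sprintf("GENE%03d", seq_len(nGenes))
  tfs <- genes[seq_len(nTFs)]
  # Planted association pairs: a hub TF with three interconnected
  # partners, plus two further TF-anchored pairs.
  planted <- data.frame(
    gene_a = c(genes[1], genes[1], genes[1], genes[7], genes[2], genes[3]),
    gene_b = c(genes[7], genes[8], genes[9], genes[8], genes[10], genes[11]),
    relation = c("activation", "binding", "inhibition",
                 "binding", "activation", "inhibition"),
    stringsAsFactors = FALSE)
  structure(list(
    seed = as.integer(seed), nGenes = as.integer(nGenes),
    nTFs = as.integer(nTFs), nDocs = as.integer(nDocs),
    genes = genes, tfs = tfs, plantedPairs = planted,
    nullPair = c(genes[nGenes - 1L], genes[nGenes]),
    coMentionRate = coMentionRate, backgroundRate = backgroundRate,
    goTermsPerGene = as.integer(goTermsPerGene), goOverlap = goOverlap,
    goPoolSize = as.integer(goPoolSize), tfTerms = tfTerms,
    nResidues = as.integer(nResidues),
    interfaceOffset = interfaceOffset, decoyOffset = decoyOffset,
    structuresPerPair = as.integer(structuresPerPair),
    nPathways = as.integer(nPathways),
    pathwaySizeRange = as.integer(pathwaySizeRange),
    nBackgroundGenes = as.integer(nBackgroundGenes),
    plantedEnrichment = isTRUE(plantedEnrichment)),
    class = "FixtureConfig")
}

.relationTriggers <- list(
  activation = c("activates", "stimulates"),
  binding = c("binds", "interacts with"),
  inhibition = c("inhibits", "represses"))

#' Generate a synthetic corpus with planted co-mentions
#'
#' Planted pairs are co-mentioned in single sentences containing the
#' pair's relation trigger at the configured rate; background mentions
#' of every gene are independent; the planted null pair has the same
#' marginal mention frequency as a planted pair but its two genes never
#' share a document.
#'
#' @param config a [fixtureConfig()].
#' @return list: `documents` (data.frame `doc_id`, `text`),
#'   `geneThesaurus`, `relationThesaurus`, `truth` (planted pairs with
#'   exact co-mention counts, TF ids, null pair).
#' @export
generateCorpus <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  .withSeed(deriveSeed(config$seed, "corpus"), {
    genes <- config$genes
    nDocs <- config$nDocs
    planted <- config$plantedPairs
    coCount <- integer(nrow(planted))
    # null pair: same expected marginal frequency, disjoint documents
    nullDocs <- round(config$coMentionRate * nDocs)
    nullA <- config$nullPair[1]; nullB <- config$nullPair[2]
    nullADocs <- seq(1L, by = 2L, length.out = nullDocs)
    nullBDocs <- seq(2L, by = 2L, length.out = nullDocs)
    texts <- character(nDocs)
    for (i in seq_len(nDocs)) {
      sents <- character()
      for (p in seq_len(nrow(planted))) {
        if (stats::runif(1) < config$coMentionRate) {
          trig <- .relationTriggers[[planted$relation[p]]][1]
          sents <- c(sents, sprintf("%s %s %s.", planted$gene_a[p],
                                    trig, planted$gene_b[p]))
          coCount[p] <- coCount[p] + 1L
        }
      }
      if (i %in% nullADocs)
        sents <- c(sents, sprintf("Expression of %s was observed.", nullA))
      if (i %in% nullBDocs)
        sents <- c(sents, sprintf("Expression of %s was observed.", nullB))
      bgGenes <- setdiff(genes, c(nullA, nullB))
      hit <- stats::runif(length(bgGenes)) < config$backgroundRate
      for (gn in bgGenes[hit]) {
        k <- match(gn, genes)
        nm <- if (k %% 2L == 0L) sprintf("SYN%03d", k) else gn
        sents <- c(sents, sprintf("Levels of %s increased in tumours.", nm))
      }
      if (!length(sents))
        sents <- "Colorectal cancer remains a challenging disease."
      texts[i] <- paste(sents, collapse = " ")
    }
    thesaurus <- geneThesaurus(setNames(
      lapply(seq_along(genes), function(k) sprintf("SYN%03d", k)),
      genes))
    relations <- relationThesaurus(.relationTriggers)
    truth <- config$plantedPairs
    truth$co_mentions <- coCount
    list(documents = data.frame(doc_id = sprintf("D%04d", seq_len(nDocs)),
                                text = texts, stringsAsFactors = FALSE),
         geneThesaurus = thesaurus,
         relationThesaurus = relations,
         truth = list(plantedPairs = truth, tfs = config$tfs,
                      nullPair = config$nullPair))
  })
}

#' Generate synthetic GO annotations
#'
#' Each planted interacting pair shares a configured fraction of
#' pair-specific GO terms (so its Czekanowski-Dice distance is below 1);
#' remaining terms are drawn from a background pool; TF genes receive
#' one term from the configured TF-functionality list.
#'
#' @param config a [fixtureConfig()].
#' @return data.frame with columns `protein`, `go_id`, `aspect`.
#' @export
generateAnnotations <- function(config) {
  stopifnot(inherits(config, "FixtureConfig"))
  .withSeed(deriveSeed(config$seed, "annotations"), {
    pool <- sprintf("GO:B%04d", seq_len(config$goPoolSize))
    aspects <- c("BP", "MF", "CC")
    nShared <- max(1L, ceiling(config$goOverlap * config$goTermsPerGene))
    # planted pairs first: shared pair-specific terms accumulate (a hub
    # gene keeps the shared terms of every pair it belongs to)
    terms <- setNames(vector("list", length(config$genes)), config$genes)
    for (g in config$genes) terms[[g]] <- character()
    for (p in seq_len(nrow(config$plantedPairs))) {
      shared <- sprintf("GO:P%02d%02d", p, seq_len(nShared))
      a <- config$plantedPairs$gene_a[p]
      b <- config$plantedPairs$gene_b[p]
      terms[[a]] <- c(terms[[a]], shared)
      terms[[b]] <- c(terms[[b]], shared)
    }
    for (g in config$genes) {
      pad <- config$goTermsPerGene - length(terms[[g]])
      if (pad > 0L) terms[[g]] <- c(terms[[g]], sample(pool, pad))
    }
    for (i in seq_along(config$tfs))
      terms[[config$tfs[i]]] <-
        c(terms[[config$tfs[i]]],
          config$tfTerms[(i - 1L) %% length(config$tfTerms) + 1L])
    rows <- lapply(names(terms), function(g) {
      tt <- unique(terms[[g]])
      data.frame(protein = g, go_id = tt,
                 aspect = aspects[(seq_along(tt) - 1L) %% 3L + 1L],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

# C-alpha coordinates of an idealized alpha-helix.
.helixCoords <- function(n) {
  t <- seq_len(n)
  ang <- t * 100 * pi / 180
  cbind(x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * t)
}

# Write one CA-only dimer PDB: chain A at the origin, chain B offset
# along x.
.writeDimerPDB <- function(path, nRes, residA, residB, offset, jitter = 0) {
  A <- .helixCoords(nRes)
  B <- A
  B[, "x"] <- B[, "x"] + offset + jitter
  xyz <- rbind(A, B)
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(xyz)),
    type = rep("ATOM", 2L * nRes),
    resno = c(seq_len(nRes), seq_len(nRes)),
    resid = c(residA, residB),
    eleno = seq_len(2L * nRes),
    elety = rep("CA", 2L * nRes),
    chain = rep(c("A", "B"), each = nRes))
  invisible(path)
}

#' Generate toy dimer structures with planted interfaces
#'
#' Writes CA-only PDB files for the first three planted pairs: dimers
#' whose chains sit `interfaceOffset` angstroms apart (inside the 6
#' angstrom contact threshold) plus, for the last of those pairs, decoy
#' replicas pulled apart by `decoyOffset`.
#'
#' @param config a [fixtureConfig()].
#' @param dir output directory for PDB files (created if needed).
#' @return list: `map` (data.frame `protein_id`, `pdb_file`, `chain`),
#'   `truth` (interacting pairs, decoy pairs).
#' @export
generateStructures <- function(config, dir) {
  stopifnot(inherits(config, "FixtureConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .withSeed(deriveSeed(config$seed, "structures"), {
    aaNames <- names(hydrophobicityTable())
    pairs <- utils::head(config$plantedPairs, 3L)
    decoyPair <- config$nullPair
    rows <- list()
    mkResid <- function() sample(aaNames, config$nResidues, replace = TRUE)
    for (p in seq_len(nrow(pairs))) {
      a <- pairs$gene_a[p]; b <- pairs$gene_b[p]
      residA <- mkResid(); residB <- mkResid()
      for (r in seq_len(config$structuresPerPair)) {
        f <- sprintf("dimer_%s_%s_r%d.pdb", a, b, r)
        .writeDimerPDB(file.path(dir, f), config$nResidues,
                       residA, residB, config$interfaceOffset,
                       jitter = 0.05 * (r - 1L))
        rows[[length(rows) + 1L]] <-
          data.frame(protein_id = c(a, b), pdb_file = f,
                     chain = c("A", "B"), stringsAsFactors = FALSE)
      }
    }
    residA <- mkResid(); residB <- mkResid()
    for (r in seq_len(config$structuresPerPair)) {
      f <- sprintf("decoy_%s_%s_r%d.pdb", decoyPair[1], decoyPair[2], r)
      .writeDimerPDB(file.path(dir, f), config$nResidues,
                     residA, residB, config$decoyOffset,
                     jitter = 0.05 * (r - 1L))
      rows[[length(rows) + 1L]] <-
        data.frame(protein_id = decoyPair, pdb_file = f,
                   chain = c("A", "B"), stringsAsFactors = FALSE)
    }
    map <- do.call(rbind, rows)
    map$pdb_file <- file.path(dir, map$pdb_file)
    list(map = map,
         truth = list(interactingPairs = pairs[, c("gene_a", "gene_b")],
                      decoyPair = decoyPair))
  })
}

#' Generate a synthetic pathway collection
#'
#' Random pathways over a gene universe containing the fixture genes
#' plus background genes.  With `plantedEnrichment`, the first pathway
#' is built to overlap the planted user list strongly enough that its
#' hypergeometric tail p-value is below 0.01.
#'
#' @param config a [fixtureConfig()].
#' @param userList the gene list the planted pathway should enrich
#'   (default: the genes of the planted pairs).
#' @return list: `pathways` (named list), `groups` (named character
#'   vector), `universe`, `truth` (planted pathway id or NA).
#' @export
generatePathways <- function(config, userList = NULL) {
  stopifnot(inherits(config, "FixtureConfig"))
  if (is.null(userList))
    userList <- unique(c(config$plantedPairs$gene_a,
                         config$plantedPairs$gene_b))
  if (!length(userList)) stop("empty planted user list")
  .withSeed(deriveSeed(config$seed, "pathways"), {
    universe <- c(config$genes,
                  sprintf("BGGENE%03d", seq_len(config$nBackgroundGenes)))
    szr <- config$pathwaySizeRange
    ids <- sprintf("PW%02d", seq_len(config$nPathways))
    pathways <- setNames(vector("list", config$nPathways), ids)
    bgOnly <- setdiff(universe, userList)
    # in null mode pathways are random w.r.t. the user list; when
    # planting, the non-planted pathways avoid it so the single planted
    # set carries the signal
    drawFrom <- if (config$plantedEnrichment) bgOnly else universe
    for (i in seq_len(config$nPathways)) {
      sz <- sample(szr[1]:szr[2], 1L)
      pathways[[i]] <- sort(sample(drawFrom, sz))
    }
    plantedId <- NA_character_
    if (config$plantedEnrichment) {
      sz <- szr[2]
      nHit <- min(length(userList), max(6L, ceiling(sz / 2)))
      pathways[[1L]] <- sort(c(sample(userList, nHit),
                               sample(bgOnly, sz - nHit)))
      plantedId <- ids[1L]
    }
    groupPool <- c("cell_cycle", "immune_response", "apoptosis",
                   "wnt_signalling", "dna_damage")
    groups <- setNames(groupPool[(seq_len(config$nPathways) - 1L) %%
                                   length(groupPool) + 1L], ids)
    if (!is.na(plantedId)) groups[plantedId] <- "planted_group"
    list(pathways = pathways, groups = groups, universe = universe,
         truth = list(plantedPathway = plantedId))
  })
}

#' Generate a synthetic TFNetwork with planted signal
#'
#' Builds a random undirected network with GO similarities and partial
#' structural scores on its edges, and optionally plants (a) a hub TF
#' with top-quartile values of all four node features and (b) a
#' three-node TF-anchored clique whose members carry the highest node
#' strengths (a planted top module).
#'
#' @param seed integer seed.
#' @param nNodes,nTFs network size and TF count.
#' @param edgeProb background edge probability.
#' @param plantHub,plantModule plant the corresponding signal.
#' @return list: `net` (a [TFNetwork-class] with topology computed),
#'   `truth` (`hub`, `moduleMembers`).
#' @export
generateNetworkFixture <- function(seed, nNodes = 40L, nTFs = 8L,
                                   edgeProb = 0.12, plantHub = TRUE,
                                   plantModule = FALSE) {
  .withSeed(deriveSeed(seed, "network"), {
    ids <- sprintf("N%03d", seq_len(nNodes))
    g <- igraph::sample_gnp(nNodes, edgeProb, directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = ids)
    isTf <- ids %in% ids[seq_len(nTFs)]
    hub <- NA_character_; modMembers <- NULL
    addEdges <- function(g, pairs) {
      m <- igraph::as_edgelist(g, names = FALSE)
      key <- paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
      new <- pairs[!paste(pmin(pairs[, 1], pairs[, 2]),
                          pmax(pairs[, 1], pairs[, 2])) %in% key, ,
                   drop = FALSE]
      if (nrow(new)) g <- igraph::add_edges(g, t(new))
      g
    }
    if (plantHub) {
      hub <- ids[1]
      nb <- sample(setdiff(seq_len(nNodes), 1L), 9L)
      g <- addEdges(g, cbind(1L, nb))
      nbPairs <- t(combn(nb, 2L))
      pick <- nbPairs[sample(nrow(nbPairs), ceiling(0.6 * nrow(nbPairs))), ,
                      drop = FALSE]
      g <- addEdges(g, pick)
    }
    if (plantModule) {
      modMembers <- ids[c(2L, 10L, 11L)]
      g <- addEdges(g, rbind(c(2L, 10L), c(2L, 11L), c(10L, 11L)))
    }
    g <- igraph::simplify(g)
    ne <- igraph::ecount(g)
    goDist <- stats::runif(ne, 0.1, 0.9)
    structScore <- ifelse(stats::runif(ne) < 0.6,
                          stats::runif(ne, 0.05, 0.5), NA_real_)
    ends <- igraph::as_edgelist(g, names = TRUE)
    planted <- character()
    if (plantHub) planted <- c(planted, hub)
    if (plantModule) planted <- c(planted, modMembers)
    onPlanted <- ends[, 1] %in% planted | ends[, 2] %in% planted
    goDist[onPlanted] <- 0.05
    structScore[onPlanted] <- 0.95
    g <- igraph::set_edge_attr(g, "go_distance", value = goDist)
    g <- igraph::set_edge_attr(g, "go_similarity", value = 1 - goDist)
    g <- igraph::set_edge_attr(g, "structural_score", value = structScore)
    g <- igraph::set_vertex_attr(g, "is_tf", value = isTf)
    net <- computeTopology(new("TFNetwork", graph = g))
    list(net = net, truth = list(hub = hub, moduleMembers = modMembers))
  })
}

#' Write a complete fixture set to disk
#'
#' Emits every input format the pipeline consumes: corpus JSON-lines,
#' gene and relation thesauri, GO annotation TSV, CA-only PDB structures
#' with a mapping TSV, pathway GMT with group labels, evidence-tier
#' membership lists, and truth tables.
#'
#' @param config a [fixtureConfig()].
#' @param outDir output directory (created if needed).
#' @return named list of file paths plus `truth`.
#' @export
generateFixtures <- function(config, outDir) {
  stopifnot(inherits(config, "FixtureConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  corp <- generateCorpus(config)
  annot <- generateAnnotations(config)
  struct <- generateStructures(config, file.path(outDir, "structures"))
  paths <- list()
  paths$corpus <- file.path(outDir, "corpus.jsonl")
  writeLines(vapply(seq_len(nrow(corp$documents)), function(i)
    as.character(jsonlite::toJSON(list(id = corp$documents$doc_id[i],
                                       text = corp$documents$text[i]),
                                  auto_unbox = TRUE)), character(1)),
    paths$corpus)
  paths$geneThesaurus <- file.path(outDir, "gene_thesaurus.tsv")
  gt <- corp$geneThesaurus
  .writeTSV(data.frame(V1 = rep(names(gt$entries), lengths(gt$entries)),
                       V2 = unlist(gt$entries, use.names = FALSE)),
            paths$geneThesaurus)
  # thesaurus files are headerless two-column TSVs
  writeLines(readLines(paths$geneThesaurus)[-1], paths$geneThesaurus)
  paths$relationThesaurus <- file.path(outDir, "relation_thesaurus.tsv")
  rt <- corp$relationThesaurus
  writeLines(paste(rep(names(rt$entries), lengths(rt$entries)),
                   unlist(rt$entries, use.names = FALSE), sep = "\t"),
             paths$relationThesaurus)
  paths$annotations <- file.path(outDir, "annotations.tsv")
  .writeTSV(annot, paths$annotations)
  paths$structureMap <- file.path(outDir, "structure_map.tsv")
  relMap <- struct$map
  relMap$pdb_file <- file.path("structures", basename(relMap$pdb_file))
  .writeTSV(relMap, paths$structureMap)
  paths$structureDir <- file.path(outDir, "structures")
  pw <- generatePathways(config)
  paths$pathways <- file.path(outDir, "pathways.gmt")
  writeLines(vapply(names(pw$pathways), function(id)
    paste(c(id, "synthetic", pw$pathways[[id]]), collapse = "\t"),
    character(1)), paths$pathways)
  paths$groups <- file.path(outDir, "pathway_groups.tsv")
  writeLines(paste(names(pw$groups), pw$groups, sep = "\t"), paths$groups)
  plantedGenes <- unique(c(config$plantedPairs$gene_a,
                           config$plantedPairs$gene_b))
  paths$highList <- file.path(outDir, "high_list.txt")
  writeLines(plantedGenes[1:3], paths$highList)
  paths$mediumList <- file.path(outDir, "medium_list.txt")
  writeLines(plantedGenes[4:6], paths$mediumList)
  paths$lowList <- file.path(outDir, "low_list.txt")
  writeLines(setdiff(config$genes, plantedGenes[1:6]), paths$lowList)
  paths$truthPairs <- file.path(outDir, "truth_planted_pairs.tsv")
  .writeTSV(corp$truth$plantedPairs, paths$truthPairs)
  paths$truthTFs <- file.path(outDir, "truth_tfs.txt")
  writeLines(corp$truth$tfs, paths$truthTFs)
  c(paths, list(truth = list(corpus = corp$truth,
                             structures = struct$truth,
                             pathways = pw$truth)))
}
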