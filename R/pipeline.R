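## Pipeline orchestration: the six stages (mining, GO validation,
## structure validation, network + topology + tiers, prioritization,
## modules + enrichment) behind one declarative configuration, with a
## run manifest recording counts and every resolved design decision.

#' Pipeline configuration
#'
#' @param corpus path to the corpus (JSON-lines file or directory of
#'   `<id>.txt` files).
#' @param geneThesaurus,relationThesaurus thesaurus TSV paths.
#' @param annotations GO annotation file (`.gaf` read as GAF 2.x,
#'   anything else as 3-column TSV).
#' @param structureMap optional protein-to-structure mapping TSV (PDB
#'   paths resolved relative to it); NULL skips structural scoring.
#' @param pathways GMT file for enrichment.
#' @param groups optional pathway functional-group TSV.
#' @param highList,mediumList,lowList optional membership lists (one id
#'   per line) for HIGH / MEDIUM / LOW evidence tiering.
#' @param outDir output directory.
#' @param tfTerms GO term ids marking TF functionality.
#' @param associationThreshold association score threshold, NULL for the
#'   95th-percentile default.
#' @param logBase idf logarithm base.
#' @param termFreq `"count"` or `"binary"` term frequency.
#' @param scheme node-strength scheme, see [nodeStrength()].
#' @param binding module p-value binding, see [moduleTFPvalue()].
#' @param distanceThreshold,minFraction,structureFraction the 6
#'   angstrom / 0.10 / 0.30 structure-algorithm thresholds.
#' @param alphaAssociation,alphaModule,alphaPathway significance levels.
#' @param sizeCap,rankPercentile module extraction parameters.
#' @param seed integer seed recorded in the manifest (the pipeline
#'   itself is deterministic).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(corpus, geneThesaurus, relationThesaurus,
                           annotations, structureMap = NULL,
                           pathways, groups = NULL,
                           highList = NULL, mediumList = NULL,
                           lowList = NULL, outDir,
                           tfTerms = c("GO:0003700", "GO:0001228",
                                       "GO:0003712", "GO:0001227",
                                       "GO:0003714", "GO:0000981"),
                           associationThreshold = NULL, logBase = 10,
                           termFreq = "count",
                           scheme = "weighted", binding = "network",
                           distanceThreshold = 6, minFraction = 0.10,
                           structureFraction = 0.30,
                           alphaAssociation = 0.05, alphaModule = 0.05,
                           alphaPathway = 0.05, sizeCap = 6,
                           rankPercentile = 0.5, seed = 1L) {
  stopifnot(distanceThreshold > 0, minFraction >= 0, minFraction <= 1,
            structureFraction >= 0, structureFraction <= 1,
            alphaAssociation >= 0, alphaAssociation <= 1,
            alphaModule >= 0, alphaModule <= 1,
            alphaPathway >= 0, alphaPathway <= 1, sizeCap >= 3,
            rankPercentile > 0, rankPercentile <= 1)
  cfg <- as.list(environment())
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected.
#'
#' @param path YAML file whose keys are the arguments of
#'   [pipelineConfig()].
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, y)
}

.readIdList <- function(path) {
  if (is.null(path)) return(character())
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}

#' Run the full pipeline
#'
#' Executes the six stages in order — (1) corpus mining to a thresholded
#' association list with typed relations, (2) GO annotation distance
#' validation and TF flagging, (3) structure-based interaction scoring,
#' (4) network assembly with topology and evidence tiers, (5) node
#' prioritization and hypergeometric TF associations, (6) module
#' extraction/ranking and pathway enrichment — writing each stage's
#' outputs before the next starts.  Re-running with identical inputs and
#' configuration is bit-identical.
#'
#' @param config a `PipelineConfig`.
#' @return the run manifest (invisibly also written as
#'   `manifest.json`), a list with `config`, `decisions`, `counts`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e),
           call. = FALSE))
  }
  requireFile <- function(path, what, stageName) {
    if (is.null(path) || !file.exists(path))
      stop("stage ", stageName, " failed: missing ", what, " file: ",
           if (is.null(path)) "<unset>" else path, call. = FALSE)
  }

  ## stage 1: corpus mining -------------------------------------------
  requireFile(config$corpus, "corpus", "1-mine")
  requireFile(config$geneThesaurus, "gene thesaurus", "1-mine")
  requireFile(config$relationThesaurus, "relation thesaurus", "1-mine")
  s1 <- stage("1-mine", {
    corpus <- readCorpus(config$corpus)
    thes <- readGeneThesaurus(config$geneThesaurus)
    rels <- readRelationThesaurus(config$relationThesaurus)
    tvs <- buildTermVectors(corpus, thes, logBase = config$logBase,
                            termFreq = config$termFreq)
    am <- computeAssociationMatrix(tvs)
    am <- thresholdAssociations(am, config$associationThreshold)
    retained <- retainedPairs(am)
    rel <- extractRelations(corpus, retained, thes, rels)
    retained$best_relation <- rel$best_relation
    retained$relation_score <- rel$relation_score
    .writeTSV(retained, file.path(config$outDir, "associations.tsv"))
    list(corpus = corpus, thes = thes, tvs = tvs, am = am,
         retained = retained)
  })
  .log(sprintf("stage 1: %d documents, %d entities mentioned, %d retained pairs (threshold %.6g)",
               nrow(s1$corpus), sum(s1$tvs@docFreq > 0),
               nrow(s1$retained), s1$am@threshold))

  ## stage 2: GO validation -------------------------------------------
  requireFile(config$annotations, "GO annotation", "2-go")
  s2 <- stage("2-go", {
    annotTab <- if (grepl("\\.gaf$", config$annotations, ignore.case = TRUE))
      readGAF(config$annotations)
    else readAnnotationTSV(config$annotations)
    annots <- goAnnotationSets(annotTab)
    goTab <- goDistanceTable(annots, s1$retained)
    flags <- classifyTF(annots, config$tfTerms)
    prot <- sort(unique(c(s1$retained$gene_a, s1$retained$gene_b)))
    miss <- setdiff(prot, flags$protein_id)
    if (length(miss))
      flags <- rbind(flags,
                     data.frame(protein_id = miss, is_tf = FALSE,
                                matched_functionalities = "",
                                stringsAsFactors = FALSE))
    .writeTSV(goTab, file.path(config$outDir, "go_distances.tsv"))
    .writeTSV(flags, file.path(config$outDir, "tf_flags.tsv"))
    list(goTab = goTab, flags = flags)
  })
  .log(sprintf("stage 2: %d/%d pairs pass the GO distance rule, %d TFs flagged",
               sum(s2$goTab$interacting, na.rm = TRUE), nrow(s2$goTab),
               sum(s2$flags$is_tf)))

  ## stage 3: structure validation ------------------------------------
  s3 <- if (is.null(config$structureMap)) {
    .log("stage 3: no structure map supplied; structural scores omitted")
    NULL
  } else {
    requireFile(config$structureMap, "structure map", "3-structures")
    stage("3-structures", {
      smap <- readStructureMap(config$structureMap)
      res <- scoreStructurePairs(
        s1$retained, smap,
        distanceThreshold = config$distanceThreshold,
        minFraction = config$minFraction,
        structureFractionThreshold = config$structureFraction)
      if (!is.null(res$structurePairs))
        .writeTSV(res$structurePairs,
                  file.path(config$outDir, "structure_pairs.tsv"))
      .writeTSV(res$calls, file.path(config$outDir, "structure_calls.tsv"))
      res
    })
  }
  if (!is.null(s3))
    .log(sprintf("stage 3: %d pairs structurally scored",
                 sum(s3$calls$status == "scored")))

  ## stage 4: network assembly ----------------------------------------
  s4 <- stage("4-network", {
    net <- buildNetwork(s1$retained, s2$goTab,
                        structureCalls = if (is.null(s3)) NULL
                                         else s3$calls,
                        tfFlags = s2$flags)
    net <- computeTopology(net)
    net <- tierEvidence(net,
                        colonList = .readIdList(config$highList),
                        cancerList = .readIdList(config$mediumList),
                        otherList = .readIdList(config$lowList))
    .writeTSV(nodeTable(net), file.path(config$outDir, "nodes.tsv"))
    .writeTSV(edgeTable(net), file.path(config$outDir, "edges.tsv"))
    writeNetworkGraphML(net, file.path(config$outDir, "network.graphml"))
    net
  })
  .log(sprintf("stage 4: network with %d nodes, %d GO-validated edges",
               igraph::vcount(s4@graph), igraph::ecount(s4@graph)))

  ## stage 5: prioritization ------------------------------------------
  s5 <- stage("5-prioritize", {
    ranking <- rankNodes(s4, scheme = config$scheme)
    assoc <- tfAssociations(s4, alpha = config$alphaAssociation)
    .writeTSV(ranking, file.path(config$outDir, "node_ranking.tsv"))
    .writeTSV(assoc, file.path(config$outDir, "tf_associations.tsv"),
              pcols = c("p_value", "q_value"))
    list(ranking = ranking, assoc = assoc)
  })
  .log(sprintf("stage 5: %d nodes ranked (%s scheme), %d significant TF associations",
               nrow(s5$ranking), config$scheme,
               sum(s5$assoc$significant)))

  ## stage 6: modules and enrichment ----------------------------------
  requireFile(config$pathways, "pathway GMT", "6-modules-enrich")
  s6 <- stage("6-modules-enrich", {
    mods <- extractModules(s4, s5$ranking, sizeCap = config$sizeCap,
                           rankPercentile = config$rankPercentile)
    mr <- rankModules(mods, s4, s5$ranking, alpha = config$alphaModule,
                      binding = config$binding)
    .writeTSV(mr$table, file.path(config$outDir, "modules.tsv"),
              pcols = "p_value")
    .writeTSV(mr$ranked, file.path(config$outDir, "modules_ranked.tsv"),
              pcols = "p_value")
    .writeTSV(mr$sizeSummary,
              file.path(config$outDir, "module_size_summary.tsv"))
    pwys <- readGMT(config$pathways)
    grp <- if (is.null(config$groups)) NULL
           else readGroupLabels(config$groups)
    userList <- igraph::V(s4@graph)$name
    enr <- enrichPathways(userList, pwys, alpha = config$alphaPathway,
                          groups = grp)
    fg <- classifyFunctionalGroups(enr)
    .writeTSV(enr, file.path(config$outDir, "enrichment.tsv"),
              pcols = c("p_value", "q_value"))
    .writeTSV(fg, file.path(config$outDir, "functional_groups.tsv"))
    list(modules = mods, moduleRanking = mr, enrichment = enr,
         groups = fg)
  })
  .log(sprintf("stage 6: %d modules, %d significant pathways",
               length(s6$modules@modules), sum(s6$enrichment$significant)))

  ## manifest ----------------------------------------------------------
  ssCount <- sum(!is.na(igraph::edge_attr(s4@graph, "structural_score")))
  counts <- list(
    documents = nrow(s1$corpus),
    thesaurus_terms = s1$tvs@docFreq |> length(),
    entities_mentioned = sum(s1$tvs@docFreq > 0),
    nonzero_association_pairs =
      sum(s1$am@scores[upper.tri(s1$am@scores)] > 0),
    retained_associations = nrow(s1$retained),
    go_validated_edges = igraph::ecount(s4@graph),
    structurally_scored_edges = ssCount,
    network_nodes = igraph::vcount(s4@graph),
    network_tfs = sum(igraph::V(s4@graph)$is_tf),
    modules = length(s6$modules@modules),
    significant_modules = nrow(s6$moduleRanking$ranked),
    significant_tf_associations = sum(s5$assoc$significant),
    significant_pathways = sum(s6$enrichment$significant))
  if (!(counts$structurally_scored_edges <= counts$go_validated_edges &&
        counts$go_validated_edges <= counts$retained_associations))
    stop("manifest invariant violated: expected structurally scored <= ",
         "GO-validated <= retained associations")
  manifest <- list(
    config = lapply(unclass(config), function(x)
      if (is.null(x)) NA else x),
    decisions = list(
      log_base = config$logBase,
      term_frequency = config$termFreq,
      association_threshold_used = s1$am@threshold,
      go_edge_rule = "overall Czekanowski-Dice distance < 1",
      eq5_denominator = "union of predicted residues on both chains",
      threshold_comparisons = "inclusive (>=)",
      betweenness_normalization = "(n-1)(n-2)/2 per component",
      strength_scheme = config$scheme,
      module_pvalue_binding = config$binding,
      tie_break = "lexicographic protein id"),
    counts = counts,
    versions = list(
      tfnetminer = as.character(utils::packageVersion("tfnetminer")),
      igraph = as.character(utils::packageVersion("igraph"))))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(manifest)
}
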