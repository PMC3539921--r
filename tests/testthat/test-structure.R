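mkChain <- function(xyz, resid = NULL, resno = NULL) {
  n <- nrow(xyz)
  data.frame(resno = resno %||% seq_len(n),
             resid = resid %||% rep("ALA", n),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the default interface predictor is deterministic and rule-driven", {
  # single hydrophobic residue: table value at maximum, exposure proxy 1
  one <- mkChain(matrix(c(0, 0, 0), 1), resid = "ILE")
  expect_identical(predictInterfaceResidues(one), 1L)
  # single least-hydrophobic residue scores 0.5 (exposure alone): at cutoff
  oneArg <- mkChain(matrix(c(0, 0, 0), 1), resid = "ARG")
  expect_identical(predictInterfaceResidues(oneArg), 1L)
  expect_identical(
    predictInterfaceResidues(oneArg,
                             interfacePredictorConfig(cutoff = 0.6)),
    integer())
  # empty chain: empty prediction
  expect_identical(predictInterfaceResidues(mkChain(matrix(0, 0, 3))),
                   integer())
  # determinism
  set.seed(1)
  xyz <- matrix(rnorm(60, sd = 5), ncol = 3)
  ch <- mkChain(xyz, resid = sample(names(hydrophobicityTable()), 20,
                                    replace = TRUE))
  expect_identical(predictInterfaceResidues(ch),
                   predictInterfaceResidues(ch))
  # "all" predictor keeps everything
  expect_identical(predictInterfaceResidues(ch, predictor = "all"),
                   ch$resno)
})

test_that("structure pair score counts cross-chain contacts within 6 angstroms", {
  # 3 predicted residues per chain, exactly one on each side within 6 A
  A <- mkChain(rbind(c(0, 0, 0), c(100, 0, 0), c(200, 0, 0)))
  B <- mkChain(rbind(c(3, 0, 0), c(300, 0, 0), c(400, 0, 0)))
  r <- structurePairScore(A, 1:3, B, 1:3)
  expect_identical(r$interacting_count, 2L)
  expect_identical(r$probable_count, 6L)
  expect_equal(r$interaction_score, 2 / 6)
  expect_true(r$satisfies)  # 1/3 >= 10%
  # all distances > 6 A: score 0, not satisfying
  Bfar <- mkChain(rbind(c(50, 0, 0), c(300, 0, 0), c(400, 0, 0)))
  r0 <- structurePairScore(A, 1:3, Bfar, 1:3)
  expect_equal(r0$interaction_score, 0)
  expect_false(r0$satisfies)
  # superposed chains: every residue has a partner within 6 A
  r1 <- structurePairScore(A, 1:3, A, 1:3)
  expect_equal(r1$interaction_score, 1)
  # no predicted residues: undefined, flagged, not satisfying
  rna <- structurePairScore(A, integer(), B, integer())
  expect_true(is.na(rna$interaction_score))
  expect_false(rna$satisfies)
  expect_true(rna$flagged)
})

test_that("pair scores equal the brute-force all-pairs distance oracle and are symmetric", {
  set.seed(7)
  for (i in 1:20) {
    A <- mkChain(matrix(rnorm(30, sd = 6), ncol = 3))
    B <- mkChain(matrix(rnorm(30, sd = 6), ncol = 3))
    pa <- sort(sample(1:10, sample(0:10, 1)))
    pb <- sort(sample(1:10, sample(0:10, 1)))
    r <- structurePairScore(A, pa, B, pb)
    o <- bruteStructureScore(A, pa, B, pb, 6)
    if (is.na(o)) expect_true(is.na(r$interaction_score))
    else expect_equal(r$interaction_score, o)
    rSwap <- structurePairScore(B, pb, A, pa)
    expect_identical(r$interaction_score, rSwap$interaction_score)
  }
})

test_that("rigidly translating one chain far away drives the score to zero", {
  set.seed(9)
  for (i in 1:5) {
    A <- mkChain(matrix(rnorm(45, sd = 4), ncol = 3))
    B <- A
    B$x <- B$x + 60
    r <- structurePairScore(A, A$resno, B, B$resno)
    expect_equal(r$interaction_score, 0)
  }
})

test_that("protein pair calls use the inclusive 30% structure fraction", {
  expect_false(pairInteractionCall(rep(FALSE, 10))$is_interacting)
  expect_true(pairInteractionCall(rep(TRUE, 10))$is_interacting)
  cc <- pairInteractionCall(c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_equal(cc$structure_fraction, 0.30)
  expect_true(cc$is_interacting)  # threshold inclusive
  none <- pairInteractionCall(logical())
  expect_identical(none$status, "no_structural_evidence")
  expect_true(is.na(none$is_interacting))
})

test_that("fixture dimers are interacting and decoys are not, end to end", {
  dir <- withr::local_tempdir()
  cfg <- fixtureConfig(seed = 5)
  st <- generateStructures(cfg, dir)
  pairs <- rbind(st$truth$interactingPairs,
                 data.frame(gene_a = st$truth$decoyPair[1],
                            gene_b = st$truth$decoyPair[2]))
  res <- scoreStructurePairs(pairs, st$map)
  calls <- res$calls
  planted <- calls[seq_len(nrow(st$truth$interactingPairs)), ]
  expect_true(all(planted$is_interacting))
  decoy <- calls[nrow(calls), ]
  expect_false(decoy$is_interacting)
  # geometry: planted min cross-chain distance below 6 A, decoy above
  ch1 <- readChainStructure(st$map$pdb_file[1], chain = "A")
  ch2 <- readChainStructure(st$map$pdb_file[1], chain = "B")
  d <- as.matrix(dist(rbind(as.matrix(ch1[, c("x", "y", "z")]),
                            as.matrix(ch2[, c("x", "y", "z")]))))
  cross <- d[seq_len(nrow(ch1)), nrow(ch1) + seq_len(nrow(ch2))]
  expect_lt(min(cross), 6)
  dec <- st$map[grepl("decoy", st$map$pdb_file), ]
  dh1 <- readChainStructure(dec$pdb_file[1], chain = "A")
  dh2 <- readChainStructure(dec$pdb_file[1], chain = "B")
  dd <- as.matrix(dist(rbind(as.matrix(dh1[, c("x", "y", "z")]),
                             as.matrix(dh2[, c("x", "y", "z")]))))
  crossD <- dd[seq_len(nrow(dh1)), nrow(dh1) + seq_len(nrow(dh2))]
  expect_gt(min(crossD), 6)
})

test_that("PDB fixtures round-trip through the structure reader", {
  dir <- withr::local_tempdir()
  cfg <- fixtureConfig(seed = 2)
  st <- generateStructures(cfg, dir)
  ch <- readChainStructure(st$map$pdb_file[1], chain = "A")
  expect_identical(nrow(ch), as.integer(cfg$nResidues))
  expect_equal(ch$resno, seq_len(cfg$nResidues))
  # coordinates match the helix template to PDB format precision
  t <- seq_len(cfg$nResidues)
  expect_equal(ch$z, 1.5 * t, tolerance = 1e-3)
  expect_equal(ch$x, 2.3 * cos(t * 100 * pi / 180), tolerance = 1e-3)
  expect_equal(attr(ch, "coverage"), 1)
})
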