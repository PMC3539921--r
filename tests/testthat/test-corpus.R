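thes <- geneThesaurus(list(GENEA = "gena", GENEB = "genb", GENEC = "genc",
                           GENED = character()))
rels <- relationThesaurus(list(activation = c("activates", "stimulates"),
                               inhibition = "inhibits"))

mkCorpus <- function(texts)
  data.frame(doc_id = sprintf("D%02d", seq_along(texts)), text = texts,
             stringsAsFactors = FALSE)

test_that("tf*idf weights follow the frequency * log(N/n_k) rule", {
  corpus <- mkCorpus(c("GENEA binds GENEA here.", "Nothing relevant.",
                       "GENEB only.", "Still nothing."))
  tv <- buildTermVectors(corpus, thes, logBase = 10)
  W <- termWeights(tv)
  # N=4, GENEA occurs twice in exactly one document: W = 2*log10(4/1)
  expect_equal(W["D01", "GENEA"], 2 * log10(4), tolerance = 1e-12)
  expect_equal(unname(W[, "GENED"]), rep(0, 4))  # absent term: zero column
  # absent from a document => weight zero
  expect_equal(W["D02", "GENEA"], 0)
})

test_that("a term present in every document carries zero weight", {
  corpus <- mkCorpus(c("GENEA one.", "GENEA two.", "GENEA and GENEB."))
  tv <- buildTermVectors(corpus, thes)
  expect_equal(unname(termWeights(tv)[, "GENEA"]), rep(0, 3))
  expect_gt(termWeights(tv)["D03", "GENEB"], 0)
})

test_that("synonym matching is case-insensitive, token-bounded and non-overlapping", {
  th <- geneThesaurus(list(LONG = "tumor necrosis factor",
                           TNF = c("tnf", "necrosis")))
  tv <- buildTermVectors(mkCorpus(
    c("Tumor Necrosis Factor and TNF differ.",  # long match masks 'necrosis'
      "The gene tnfx is not tnf.")), th)
  tf <- tv@termFreq
  expect_equal(unname(tf["D01", ]), c(1, 1))   # LONG once, TNF once
  expect_equal(unname(tf["D02", "TNF"]), 1)    # tnfx must not match
})

test_that("empty corpora and synonym collisions are load errors", {
  expect_error(buildTermVectors(mkCorpus(character()), thes), "empty")
  expect_error(geneThesaurus(list(A = "shared", B = "shared")), "collision")
})

test_that("association matrix equals the brute-force double loop", {
  set.seed(11)
  for (rep in 1:5) {
    texts <- replicate(8, paste(
      sample(c("GENEA", "GENEB", "GENEC", "filler", "noise"),
             sample(3:10, 1), replace = TRUE), collapse = " "))
    tv <- buildTermVectors(mkCorpus(texts), thes)
    am <- computeAssociationMatrix(tv)
    expect_equal(associationScores(am), bruteAssociation(termWeights(tv)),
                 tolerance = 1e-12)
    expect_true(isSymmetric(associationScores(am)))
  }
})

test_that("association of a hand-built two-document case is the dot product", {
  tv <- new("TermVectorSet",
            weights = matrix(c(1.2, 0, 0.6, 0.9), nrow = 2,
                             dimnames = list(c("d1", "d2"), c("k", "l"))),
            termFreq = matrix(c(1, 0, 1, 1), nrow = 2,
                              dimnames = list(c("d1", "d2"), c("k", "l"))),
            docFreq = c(k = 1L, l = 2L), nDocs = 2L, logBase = 10)
  am <- computeAssociationMatrix(tv)
  expect_equal(associationScores(am)["k", "l"], 1.2 * 0.6)
})

test_that("thresholding retains exactly the pairs at or above the cutoff", {
  s <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  s["a", "b"] <- s["b", "a"] <- 0.72
  s["a", "c"] <- s["c", "a"] <- 0.10
  am <- new("AssociationMatrix", scores = s, threshold = NA_real_,
            retainedPairs = data.frame())
  th <- thresholdAssociations(am, 0.5)
  expect_identical(nrow(retainedPairs(th)), 1L)
  expect_identical(retainedPairs(th)$gene_a, "a")
  # zero-score pairs are never retained, even at threshold 0
  th0 <- thresholdAssociations(am, 0)
  expect_identical(nrow(retainedPairs(th0)), 2L)
  # threshold above the maximum retains nothing
  expect_identical(nrow(retainedPairs(thresholdAssociations(am, 1))), 0L)
  # monotone: raising the threshold never adds pairs
  for (t2 in c(0.05, 0.2, 0.8))
    expect_lte(nrow(retainedPairs(thresholdAssociations(am, t2))),
               nrow(retainedPairs(thresholdAssociations(am, t2 / 2))))
  expect_error(thresholdAssociations(am, -1), "non-negative")
})

test_that("relation extraction counts sentences with both genes and a trigger", {
  corpus <- mkCorpus(c(
    "GENEA activates GENEB. GENEA inhibits GENEB. Unrelated text here.",
    "GENEA stimulates GENEB strongly. GENEB alone now.",
    "GENEA activates GENEC."))
  pairs <- data.frame(gene_a = c("GENEA", "GENEA", "GENEB"),
                      gene_b = c("GENEB", "GENEC", "GENEC"))
  out <- extractRelations(corpus, pairs, thes, rels)
  counts <- attr(out, "counts")
  # activation seen in 2 sentences, inhibition in 1 -> activation wins
  expect_equal(unname(counts[1, ]), c(2L, 1L))
  expect_identical(out$best_relation[1], "activation")
  expect_identical(out$relation_score[1], 2L)
  expect_identical(out$best_relation[2], "activation")
  # no shared sentence -> no relation
  expect_true(is.na(out$best_relation[3]))
  expect_identical(out$relation_score[3], 0L)
})

test_that("relation counts are invariant to sentence order and ties break lexicographically", {
  c1 <- mkCorpus("GENEA activates GENEB. GENEA inhibits GENEB.")
  c2 <- mkCorpus("GENEA inhibits GENEB. GENEA activates GENEB.")
  pr <- data.frame(gene_a = "GENEA", gene_b = "GENEB")
  o1 <- extractRelations(c1, pr, thes, rels)
  o2 <- extractRelations(c2, pr, thes, rels)
  expect_equal(attr(o1, "counts"), attr(o2, "counts"))
  # 1-1 tie: lexicographically smallest label
  expect_identical(o1$best_relation, "activation")
})

test_that("corpus readers round-trip JSONL and directory formats", {
  dir <- withr::local_tempdir()
  jl <- file.path(dir, "c.jsonl")
  writeLines(c('{"id":"x1","text":"GENEA here."}',
               '{"id":"x2","text":"GENEB there."}'), jl)
  docs <- readCorpus(jl)
  expect_identical(docs$doc_id, c("x1", "x2"))
  td <- file.path(dir, "txt"); dir.create(td)
  writeLines("GENEA here.", file.path(td, "a1.txt"))
  writeLines("GENEB there.", file.path(td, "a2.txt"))
  docs2 <- readCorpus(td)
  expect_identical(docs2$doc_id, c("a1", "a2"))
  expect_match(docs2$text[1], "GENEA")
})
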