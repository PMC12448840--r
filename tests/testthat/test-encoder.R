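test_that("graph construction drops featureless endpoints and sorts nodes", {
  feats <- matrix(rnorm(6), 2, 3, dimnames = list(c("B", "A"), NULL))
  e <- PPIEdges("A", "B")
  g <- buildGraph(e, feats)
  expect_identical(graphNodes(g), c("A", "B"))
  expect_identical(edgeCount(g), 1L)

  e2 <- PPIEdges(c("A", "B"), c("B", "C"))
  expect_warning(g2 <- buildGraph(e2, feats), "C")
  expect_identical(edgeCount(g2), 1L)

  expect_error(suppressWarnings(buildGraph(PPIEdges("C", "D"), feats)),
               "no usable edges")

  # SBM fixture: node count preserved when all nodes are featured
  edges <- generateSBMGraph(30, 3, 0.6, 0.05, seed = 2)
  feats30 <- compositionFeatures(generateSequences(30, seed = 3))
  g3 <- buildGraph(edges, feats30)
  expect_identical(length(graphNodes(g3)),
                   length(unique(as.vector(graphEdges(g3)))))
})

test_that("edge splits are disjoint, exhaustive, sized and reproducible", {
  edges <- generateSBMGraph(30, 3, 0.6, 0.05, seed = 2)
  g <- buildGraph(edges, compositionFeatures(generateSequences(30, seed = 3)))
  nE <- edgeCount(g)
  sp <- splitEdges(g, 0.8, seed = 5)
  expect_identical(length(sp$train), as.integer(round(0.8 * nE)))
  expect_identical(sort(c(sp$train, sp$test)), seq_len(nE))
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_identical(splitEdges(g, 0.8, seed = 5), sp)
  expect_false(identical(splitEdges(g, 0.8, seed = 6), sp))
})

test_that("training is seed-deterministic end to end", {
  g <- sbmTestGraph()
  cfg <- encoderConfig(embeddingDim = 16, epochs = 20, seed = 4)
  m1 <- trainEncoder(g, cfg)
  m2 <- trainEncoder(g, cfg)
  expect_equal(trainingHistory(m1)$loss, trainingHistory(m2)$loss,
               tolerance = 1e-6)
  e1 <- embeddingMatrix(encodeProteins(m1, g))
  e2 <- embeddingMatrix(encodeProteins(m2, g))
  expect_lt(max(abs(e1 - e2)), 1e-6)
  expect_identical(dim(e1), c(120L, 16L))
})

test_that("strong community structure yields above-chance held-out link AUC", {
  g <- sbmTestGraph()
  m <- trainEncoder(g, encoderConfig(epochs = 150, seed = 11))
  expect_gt(validationAUC(m, g, seed = 99), 0.7)
})

test_that("embeddings separate communities: within-block correlation exceeds cross", {
  g <- sbmTestGraph()
  blocks <- attr(g, "blocks")
  m <- trainEncoder(g, encoderConfig(epochs = 150, seed = 21))
  Z <- embeddingMatrix(encodeProteins(m, g))
  C <- cor(t(Z))
  same <- outer(blocks, blocks, "==")
  ut <- upper.tri(C)
  expect_gt(mean(C[same & ut]), mean(C[!same & ut]))
})

test_that("an untrained model on a structureless graph scores at chance", {
  seqs <- generateSequences(100, seed = 31)
  feats <- compositionFeatures(seqs)
  aucs <- vapply(1:4, function(s) {
    er <- generateSBMGraph(100, 1, 0.08, 0.08, seed = s)
    g <- buildGraph(er, feats)
    m0 <- trainEncoder(g, encoderConfig(epochs = 0, seed = s))
    expect_identical(nrow(trainingHistory(m0)), 0L)
    validationAUC(m0, g, seed = s + 50)
  }, 0)
  expect_true(all(aucs > 0.35 & aucs < 0.65))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)
})

test_that("training aborts cleanly when the loss turns non-finite", {
  feats <- matrix(rnorm(6 * 4), 6, 4,
                  dimnames = list(sprintf("N%d", 1:6), NULL))
  feats[1, 1] <- Inf  # poisoned input feature
  g <- buildGraph(PPIEdges(c("N1", "N2", "N3", "N4", "N1", "N2"),
                           c("N2", "N3", "N4", "N5", "N6", "N5")),
                  feats)
  expect_error(trainEncoder(g, encoderConfig(epochs = 3, seed = 1)),
               "non-finite")
})

test_that("embedding tables have constant dimension and named rows", {
  g <- sbmTestGraph()
  m <- trainEncoder(g, encoderConfig(embeddingDim = 8, epochs = 10, seed = 2))
  emb <- encodeProteins(m, g)
  expect_identical(embeddingDim(emb), 8L)
  expect_identical(proteinIds(emb), graphNodes(g))
  # feature-dimension mismatch is rejected
  g2 <- buildGraph(PPIEdges(c("A", "B", "A", "C", "B"),
                            c("B", "C", "C", "D", "D")),
                   matrix(rnorm(4 * 5), 4, 5,
                          dimnames = list(c("A", "B", "C", "D"), NULL)))
  expect_error(encodeProteins(m, g2), "mismatch")
})

test_that("dimension tuning returns a candidate and prefers smaller ties", {
  g <- sbmTestGraph()
  cfg <- encoderConfig(epochs = 5, seed = 3)
  one <- tuneEmbeddingDim(g, 64, cfg)
  expect_identical(one$embeddingDim, 64L)
  pick <- tuneEmbeddingDim(g, c(8, 16), cfg)
  expect_true(pick$embeddingDim %in% c(8L, 16L))
  # with zero epochs every candidate ties at the initialization baseline
  tie <- tuneEmbeddingDim(g, c(8, 16), encoderConfig(epochs = 0, seed = 3))
  expect_identical(tie$embeddingDim, 8L)
})
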