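test_that("SBM generation matches closed-form edge counts", {
  # p_in = 1, p_out = 0, two communities of 3: exactly two triangles
  full <- generateSBMGraph(6, 2, 1, 0, seed = 1)
  expect_identical(edgeCount(full), 6L)
  blocks <- attr(full, "blocks")
  tab <- edgeTable(full)
  expect_true(all(blocks[tab$protein1] == blocks[tab$protein2]))

  empty <- generateSBMGraph(6, 2, 0, 0, seed = 1)
  expect_identical(edgeCount(empty), 0L)

  expect_error(generateSBMGraph(10, 2, 0.1, 0.5, seed = 1), "pOut <= pIn")
})

test_that("SBM edge counts concentrate around the binomial expectation", {
  nIn <- 4 * choose(30, 2)
  nOut <- choose(120, 2) - nIn
  expectation <- nIn * 0.3 + nOut * 0.01
  varSum <- nIn * 0.3 * 0.7 + nOut * 0.01 * 0.99
  counts <- vapply(1:20, function(s) {
    edgeCount(generateSBMGraph(120, 4, 0.3, 0.01, seed = s))
  }, 0L)
  se <- sqrt(varSum / 20)
  expect_lt(abs(mean(counts) - expectation), 3 * se)
})

test_that("generated sequences have the declared ids, lengths and composition", {
  s <- generateSequences(3, seed = 2)
  expect_identical(names(s), c("P0001", "P0002", "P0003"))
  expect_identical(generateSequences(3, seed = 2), s)

  fixed <- generateSequences(10, 50, 50, seed = 3)
  expect_true(all(nchar(fixed) == 50L))

  many <- generateSequences(400, 80, 120, seed = 4)
  freq <- table(factor(unlist(strsplit(paste(many, collapse = ""), "")),
                       levels = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  freq <- freq / sum(freq)
  expect_true(all(abs(freq - 0.05) < 0.01))
})

test_that("planted embeddings hit the requested within-block correlation", {
  blocks <- communityBlocks(60, 3)
  indep <- generatePlantedEmbeddings(blocks, dim = 64, rho = 0, seed = 5)
  C0 <- cor(t(embeddingMatrix(indep)))
  same <- outer(blocks, blocks, "==") & upper.tri(C0)
  expect_lt(abs(mean(C0[same])), 0.1)

  withins <- vapply(1:5, function(s) {
    emb <- generatePlantedEmbeddings(blocks, dim = 128, rho = 0.95, seed = s)
    C <- cor(t(embeddingMatrix(emb)))
    mean(C[same])
  }, 0)
  expect_true(all(withins > 0.90 & withins < 0.99))

  expect_identical(embeddingDim(indep), 64L)
  expect_identical(proteinIds(indep), names(blocks))
})

test_that("scenario collections realize their overlap contracts", {
  blocks <- communityBlocks(120, 4)
  scen <- generateScenarioCollection(blocks, querySize = 10,
                                     pathwaySize = 10, shareFraction = 0.5,
                                     seed = 6)
  mem <- pathwayMembers(scen$collection)
  q <- queryIds(scen$query)
  expect_identical(length(intersect(q, mem$overlap_rich)), 5L)
  expect_identical(length(intersect(q, mem$overlap_free_linked)), 0L)
  expect_identical(length(intersect(q, mem$unrelated)), 0L)
  expect_true(all(blocks[mem$overlap_free_linked] == 1L))
  expect_true(all(blocks[mem$unrelated] != 1L))
  expect_true(all(blocks[q] == 1L))
  # pure function of seed
  scen2 <- generateScenarioCollection(blocks, seed = 6)
  expect_identical(pathwayMembers(scen2$collection), mem)
})

test_that("interaction-linked pathways outscore unrelated ones under planted signal", {
  blocks <- communityBlocks(120, 4)
  wins <- vapply(1:25, function(s) {
    emb <- generatePlantedEmbeddings(blocks, dim = 128, rho = 0.95, seed = s)
    scen <- generateScenarioCollection(blocks, seed = s + 1000)
    res <- as.data.frame(enrich(scen$query, scen$collection, emb,
                                scoringConfig(beta = 1)))
    res$score[res$pathway_id == "overlap_free_linked"] >
      res$score[res$pathway_id == "unrelated"]
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})
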