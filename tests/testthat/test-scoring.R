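test_that("pearson correlation matches hand evaluation and conventions", {
  expect_equal(pearsonCor(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(pearsonCor(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearsonCor(c(1, 2, 3), c(1, 1, 2)), sqrt(3) / 2,
               tolerance = 1e-12)
  expect_identical(pearsonCor(c(1, 2, 3), c(5, 5, 5)), 0)
  expect_error(pearsonCor(1:3, 1:4), "equal length")
  expect_error(pearsonCor(1:2, 2:1), "at least 3")
})

test_that("correlation matrix equals the entrywise brute-force loop", {
  set.seed(14)
  for (rep in 1:5) {
    q <- matrix(rnorm(3 * 7), 3, 7)
    p <- matrix(rnorm(4 * 7), 4, 7)
    C <- correlationMatrix(q, p)
    for (k in 1:3) for (l in 1:4) {
      expect_equal(C[k, l], oraclePearson(q[k, ], p[l, ]),
                   tolerance = 1e-12)
    }
  }
  # identity: same proteins on both axes give a unit diagonal
  C2 <- correlationMatrix(q[1:2, ], q[1:2, ])
  expect_equal(diag(C2), c(1, 1), tolerance = 1e-12)
  expect_error(correlationMatrix(q, p[, 1:5]), "mismatch")
})

test_that("filtration is strict at the threshold", {
  expect_equal(filterCorrelations(matrix(c(0.95, 0.5), 1)),
               matrix(c(0.95, 0), 1))
  expect_equal(filterCorrelations(matrix(0.9, 1, 1), 0.9), matrix(0, 1, 1))
  expect_equal(filterCorrelations(matrix(-abs(rnorm(6)), 2, 3)),
               matrix(0, 2, 3))
})

test_that("overlap masking pins matched entries to 1 and zeroes their columns", {
  filt <- matrix(c(0.97, 0.93, 0.95, 0.92), 2, 2)
  mk <- maskOverlaps(filt, c("A", "X"), c("A", "Y"))
  expect_equal(mk$matrix, matrix(c(1, 0, 0.95, 0.92), 2, 2))
  expect_identical(unname(mk$overlapPairs[, 1]), "A")

  none <- maskOverlaps(filt, c("Q1", "Q2"), c("P1", "P2"))
  expect_identical(none$matrix, filt)
  expect_identical(nrow(none$overlapPairs), 0L)

  # full self-overlap gives the identity pattern
  self <- maskOverlaps(matrix(0.99, 2, 2), c("A", "B"), c("A", "B"))
  expect_equal(self$matrix, diag(2))
})

test_that("every overlap column has exactly one nonzero entry after masking", {
  set.seed(5)
  for (rep in 1:20) {
    N <- sample(2:6, 1)
    M <- sample(2:6, 1)
    qids <- sprintf("G%02d", sample(12, N))
    pids <- sprintf("G%02d", sample(12, M))
    filt <- matrix(runif(N * M, 0.9, 1), N, M)
    mk <- maskOverlaps(filt, qids, pids)
    for (l in which(pids %in% qids)) {
      expect_identical(sum(mk$matrix[, l] != 0), 1L)
      expect_identical(mk$matrix[match(pids[l], qids), l], 1)
    }
  }
})

test_that("decomposition reconstructs the masked matrix entrywise", {
  masked <- matrix(c(1, 0, 0.95, 0.92), 2, 2)
  pairs <- matrix(c("A", "A"), 1, 2)
  parts <- decomposeCorrelations(masked, c("A", "B"), c("A", "C"), pairs)
  expect_equal(parts$overlap, matrix(c(1, 0, 0, 0), 2, 2))
  expect_equal(parts$interaction, matrix(c(0, 0, 0.95, 0.92), 2, 2))
  expect_equal(parts$overlap + parts$interaction, masked)

  z <- matrix(0, 2, 2)
  zp <- decomposeCorrelations(z, c("A", "B"), c("C", "D"),
                              matrix(character(), 0, 2))
  expect_equal(zp$overlap, z)
  expect_equal(zp$interaction, z)
})

test_that("weighted score follows the hand-worked arithmetic", {
  ov <- matrix(c(1, 0, 0, 0), 2, 2)
  it <- matrix(c(0, 0, 0.95, 0.92), 2, 2)
  w10 <- weightedScore(ov, it, beta = 10)
  expect_equal(w10$maxC, c(10, 0.92))
  expect_equal(w10$score, 5.46)
  w1 <- weightedScore(ov, it, beta = 1)
  expect_equal(w1$maxC, c(1, 0.92))
  expect_equal(w1$score, 0.96)
  expect_equal(weightedScore(diag(2), matrix(0, 2, 2), beta = 1)$score, 1)
  expect_equal(weightedScore(matrix(0, 2, 2), matrix(0, 2, 2), 5)$score, 0)
  w0 <- weightedScore(matrix(0, 2, 0), matrix(0, 2, 0), 5)
  expect_true(w0$empty)
  expect_identical(w0$score, 0)
})

test_that("interaction counting enumerates qualifying unordered pairs", {
  e <- PPIEdges(c("A", "A", "B"), c("B", "C", "C"))
  expect_identical(countInteractions("A", "B", PPIEdges("A", "B")), 1L)
  expect_identical(countInteractions("A", "B", PPIEdges("C", "D")), 0L)
  expect_identical(countInteractions(c("A", "B"), c("B", "C"), e), 3L)
})

test_that("pipeline score equals the brute-force oracle on random instances", {
  set.seed(77)
  ids <- sprintf("G%03d", 1:30)
  for (rep in 1:40) {
    d <- sample(3:16, 1)
    emb <- correlatedEmbeddings(ids[1:12], d = d, rho = runif(1, 0.8, 0.99),
                                seed = rep, extraIds = ids[13:30])
    qids <- sample(ids, sample(2:8, 1))
    pids <- sample(ids, sample(2:8, 1))
    beta <- sample(c(1, 2, 10, 40), 1)
    bd <- scoreQueryAgainstPathway(emb, qids, pids,
                                   scoringConfig(beta = beta))
    expect_equal(enrichmentScore(bd),
                 oracleScore(embeddingMatrix(emb), qids, pids, beta, 0.9),
                 tolerance = 1e-12)
  }
})

test_that("scores are bounded, beta-monotone and reach the overlap limit", {
  set.seed(99)
  ids <- sprintf("G%03d", 1:20)
  betas <- c(1, 2, 5, 10, 40, 100)
  for (rep in 1:15) {
    emb <- correlatedEmbeddings(ids[1:10], d = 12, rho = 0.96,
                                seed = rep + 100, extraIds = ids[11:20])
    qids <- sample(ids, 6)
    pids <- sample(ids, 7)
    scores <- vapply(betas, function(b) {
      enrichmentScore(scoreQueryAgainstPathway(emb, qids, pids,
                                               scoringConfig(beta = b)))
    }, 0)
    expect_true(all(diff(scores) >= -1e-12))           # monotone in beta
    expect_true(all(scores >= 0 & scores <= betas + 1e-12))
    if (length(intersect(qids, pids)) == 0L) {
      expect_true(all(scores <= 1 + 1e-12))            # no overlap: <= 1
    }
    # closed-form overlap-dominance limit at large beta
    bd <- scoreQueryAgainstPathway(emb, qids, pids, scoringConfig(beta = 1))
    ovRows <- which(rowSums(bd@overlap) > 0)
    intMax <- apply(bd@interaction, 1, function(r) max(c(r, 0)))
    B <- 1000
    expected <- (B * length(ovRows) +
                 sum(intMax[setdiff(seq_along(intMax), ovRows)])) /
      nrow(bd@overlap)
    got <- enrichmentScore(scoreQueryAgainstPathway(
      emb, qids, pids, scoringConfig(beta = B)))
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("scores are invariant to affine rescaling of the embeddings", {
  ids <- sprintf("G%03d", 1:16)
  emb <- correlatedEmbeddings(ids[1:8], d = 10, rho = 0.95, seed = 8,
                              extraIds = ids[9:16])
  qids <- ids[c(1:4, 9, 10)]
  pids <- ids[c(3:8, 11)]
  base <- enrichmentScore(scoreQueryAgainstPathway(emb, qids, pids,
                                                   scoringConfig(beta = 5)))
  m2 <- 3.7 * embeddingMatrix(emb) + 11
  s2 <- enrichmentScore(scoreQueryAgainstPathway(ProteinEmbeddings(m2),
                                                 qids, pids,
                                                 scoringConfig(beta = 5)))
  expect_equal(base, s2, tolerance = 1e-12)
})

test_that("enrichment handles self-match, unrelated and planted pathways", {
  blocks <- communityBlocks(60, 3)
  emb <- generatePlantedEmbeddings(blocks, dim = 64, rho = 0.95, seed = 6)
  scen <- generateScenarioCollection(blocks, querySize = 8, pathwaySize = 8,
                                     seed = 7)
  q <- scen$query

  # a pathway identical to the query scores exactly 1 at beta = 1
  self <- PathwayCollection("self", "SELF", list(queryIds(q)))
  expect_equal(as.data.frame(enrich(q, self, emb,
                                    scoringConfig(beta = 1)))$score, 1)

  res <- as.data.frame(enrich(q, scen$collection, emb,
                              scoringConfig(beta = 1)))
  # the block-linked pathway outranks everything else at beta = 1
  expect_identical(res$pathway_id[which.max(res$score)],
                   "overlap_free_linked")
  expect_equal(res$score[res$pathway_id == "unrelated"], 0)

  # a pathway with no encodable member is skipped with score 0
  ghost <- PathwayCollection("g", c("REAL", "GHOST"),
                             list(queryIds(q)[1:2], c("NOPE1", "NOPE2")))
  expect_warning(rg <- enrich(q, ghost, emb, scoringConfig(beta = 1)),
                 "skipped")
  tg <- as.data.frame(rg)
  expect_true(tg$skipped[tg$pathway_id == "GHOST"])
  expect_identical(tg$score[tg$pathway_id == "GHOST"], 0)

  # a query with no embeddings at all is an error
  alien <- GeneQuery(c("Z1", "Z2"))
  expect_error(suppressWarnings(enrich(alien, self, emb)), "no query")
})

test_that("missing query genes can count as zero rows via missingAsZero", {
  ids <- sprintf("G%03d", 1:10)
  emb <- correlatedEmbeddings(ids[1:6], d = 8, rho = 0.95, seed = 3,
                              extraIds = ids[7:10])
  qids <- c(ids[1:4], "ABSENT1", "ABSENT2")
  bdDrop <- suppressWarnings(scoreQueryAgainstPathway(
    emb, qids, ids[1:4], scoringConfig(beta = 1)))
  bdZero <- suppressWarnings(scoreQueryAgainstPathway(
    emb, qids, ids[1:4], scoringConfig(beta = 1, missingAsZero = TRUE)))
  expect_equal(enrichmentScore(bdZero),
               enrichmentScore(bdDrop) * 4 / 6, tolerance = 1e-12)
})
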