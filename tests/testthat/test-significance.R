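test_that("empirical p-values implement the add-one exceedance estimator", {
  # zero exceedances among 100000 nulls: exactly the minimal p of 1e-5
  expect_identical(empiricalPvalue(0.5, numeric(1e5)), 1e-5)
  # every null at least as large: clamp at 1
  expect_identical(empiricalPvalue(0, c(0.1, 0.2)), 1)
  # hand count: one of three nulls >= 0.25
  expect_equal(empiricalPvalue(0.25, c(0.1, 0.2, 0.3)), 2 / 3)
  expect_error(empiricalPvalue(1, numeric(0)), "non-empty")
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(0.04, 5)), rep(0.04, 5))
  set.seed(3)
  for (rep in 1:10) {
    p <- runif(sample(2:30, 1))^2
    p[p == 0] <- 1e-8
    adj <- bhAdjust(p)
    expect_equal(adj, oracleBH(p), tolerance = 1e-12)
    expect_true(all(adj >= p))                 # BH never decreases p
    expect_true(all(diff(adj[order(p)]) >= -1e-12))  # rank order preserved
  }
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("null query sampling is uniform, sized and reproducible", {
  u <- sprintf("U%02d", 1:10)
  l1 <- sampleNullQueries(u, 3, 50, seed = 9)
  l2 <- sampleNullQueries(u, 3, 50, seed = 9)
  expect_identical(l1, l2)
  expect_true(all(lengths(l1) == 3L))
  expect_true(all(vapply(l1, function(x) !anyDuplicated(x), TRUE)))

  # size equal to the universe: every draw is a permutation
  perms <- sampleNullQueries(u[1:5], 5, 20, seed = 2)
  expect_true(all(vapply(perms, function(x) setequal(x, u[1:5]), TRUE)))

  expect_error(sampleNullQueries(u, 11, 5), "exceeds")

  # binomial inclusion check: 10000 draws of size 2 from 10
  draws <- sampleNullQueries(u, 2, 10000, seed = 4)
  freq <- table(factor(unlist(draws), levels = u)) / 10000
  expect_true(all(abs(freq - 0.2) < 0.02))
})

test_that("assessment fills calibrated p-values and respects the config", {
  blocks <- communityBlocks(60, 3)
  emb <- generatePlantedEmbeddings(blocks, dim = 64, rho = 0.95, seed = 16)
  scen <- generateScenarioCollection(blocks, querySize = 8, pathwaySize = 8,
                                     seed = 17)
  coll <- PathwayCollection(
    "mix", c(pathwayIds(scen$collection), "SELF"),
    c(pathwayMembers(scen$collection), list(queryIds(scen$query))))
  sc <- scoringConfig(beta = 1)
  nc <- nullConfig(nPermutations = 500, seed = 18)
  res <- enrich(scen$query, coll, emb, sc)
  out <- assessSignificance(res, coll, emb, sc, nc)
  tab <- as.data.frame(out)

  # the self-matching pathway is as significant as 500 permutations allow
  expect_equal(tab$pvalue[tab$pathway_id == "SELF"], 1 / 500)
  # a zero score can never beat the null
  expect_identical(tab$pvalue[tab$pathway_id == "unrelated"], 1)
  expect_true(all(tab$bh >= tab$pvalue, na.rm = TRUE))
  expect_true(all(tab$pvalue >= 1 / 500 & tab$pvalue <= 1, na.rm = TRUE))

  # deterministic under a fixed seed
  out2 <- assessSignificance(res, coll, emb, sc, nc)
  expect_identical(as.data.frame(out2)$pvalue, tab$pvalue)

  # beta mismatch between scores and the null is rejected
  expect_error(assessSignificance(res, coll, emb, scoringConfig(beta = 2),
                                  nc),
               "beta mismatch")
})

test_that("the fast permutation scorer agrees with the staged pipeline", {
  blocks <- communityBlocks(40, 2)
  emb <- generatePlantedEmbeddings(blocks, dim = 16, rho = 0.9, seed = 21)
  ids <- proteinIds(emb)
  mem <- ids[c(3, 9, 15, 22, 30)]
  coll <- PathwayCollection("one", "PW", list(mem))
  query <- GeneQuery(ids[c(1, 5, 11, 25)])
  sc <- scoringConfig(beta = 7)
  nc <- nullConfig(nPermutations = 60, seed = 5)
  res <- enrich(query, coll, emb, sc)
  out <- assessSignificance(res, coll, emb, sc, nc)

  # recompute the null by brute force through the staged scorer
  lists <- sampleNullQueries(ids, 4, 60, seed = 5)
  nullScores <- vapply(lists, function(l) {
    enrichmentScore(scoreQueryAgainstPathway(emb, l, mem, sc))
  }, 0)
  expect_equal(as.data.frame(out)$pvalue,
               empiricalPvalue(as.data.frame(res)$score, nullScores),
               tolerance = 1e-12)
})

test_that("skipped pathways are excluded from the BH family", {
  ids <- sprintf("G%03d", 1:12)
  emb <- correlatedEmbeddings(ids[1:6], d = 8, rho = 0.95, seed = 2,
                              extraIds = ids[7:12])
  coll <- PathwayCollection("c", c("OK1", "GHOST", "OK2"),
                            list(ids[1:3], c("NO1", "NO2"), ids[4:6]))
  q <- GeneQuery(ids[c(1, 4, 8)])
  sc <- scoringConfig(beta = 1)
  res <- suppressWarnings(enrich(q, coll, emb, sc))
  out <- as.data.frame(assessSignificance(res, coll, emb, sc,
                                          nullConfig(100, seed = 1)))
  expect_true(is.na(out$pvalue[out$pathway_id == "GHOST"]))
  expect_true(is.na(out$bh[out$pathway_id == "GHOST"]))
  expect_false(anyNA(out$bh[out$pathway_id != "GHOST"]))
})
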