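refCohort <- function(seed = 101) makeReferenceDescriptors(seed = seed)

test_that("aggregates are two-point statistics on a minimal cohort", {
  rec <- data.frame(id = c("a", "b"), HBD = c(2, 4), HBA = c(4, 4),
                    MW = c(200, 300), logP = c(1, 3), MR = c(50, 70),
                    AtX = c(15, 25), RB = c(2, 6), PSA = c(50, 90),
                    LD50 = c(900, 1300), ames = c(0.1, 0.2), SA = c(40, 60))
  agg <- buildReferenceAggregates(rec)
  st <- aggregateStats(agg)
  expect_equal(st$mean[st$property == "HBD"], 3)
  expect_equal(st$sd[st$property == "HBD"], sqrt(2))
  # identical records have zero spread
  agg0 <- buildReferenceAggregates(rec[c(1, 1, 1), ])
  expect_true(all(aggregateStats(agg0)$sd == 0))
  expect_error(buildReferenceAggregates(rec[1, ]), "insufficient")
  rec$MW[2] <- NA
  expect_error(buildReferenceAggregates(rec), "compound b lacks property MW")
})

test_that("generated cohort recovers its generating means within sampling error", {
  rec <- makeReferenceDescriptors(n = 54, seed = 7)
  agg <- aggregateStats(buildReferenceAggregates(rec))
  gm <- c(MW = 320, logP = 2.5, MR = 90, PSA = 75)
  for (p in names(gm)) {
    i <- match(p, agg$property)
    se <- agg$sd[i] / sqrt(54)
    expect_lt(abs(agg$mean[i] - gm[p]), 4 * se)
  }
  expect_lt(abs(agg$mean[agg$property == "LD50"] - 1142.87),
            3 * agg$sd[agg$property == "LD50"] / sqrt(54))
})

test_that("reference set scored against itself has mean S_S exactly 1", {
  rec <- refCohort()
  agg <- buildReferenceAggregates(rec)
  sc <- selectionScore(rec, agg)
  expect_equal(mean(sc$S_S), 1.0, tolerance = 1e-14)
})

test_that("a molecule at the reference property means scores close to 1", {
  rec <- refCohort()
  agg <- buildReferenceAggregates(rec)
  st <- aggregateStats(agg)
  centroid <- as.data.frame(as.list(setNames(st$mean, st$property)))
  centroid$id <- "centroid"
  sc <- selectionScore(centroid, agg)
  # not an exact fixed point: desirabilities are nonlinear, so the score of
  # the mean differs from the mean of the scores
  expect_equal(sc$S_S, 1.0, tolerance = 0.1)
})

test_that("improving a desirability-oriented property never lowers S_S", {
  rec <- refCohort()
  agg <- buildReferenceAggregates(rec)
  base <- rec[3, ]
  better_ld50 <- transform(base, LD50 = 2000)
  worse_ld50 <- transform(base, LD50 = 500)
  s <- selectionScore(rbind(better_ld50, base, worse_ld50), agg)$S_S
  expect_true(s[1] > s[2] && s[2] > s[3])
  # moving an out-of-rule MW toward compliance raises the score
  far <- transform(base, MW = 700)
  near <- transform(base, MW = 550)
  inwin <- transform(base, MW = 400)
  s2 <- selectionScore(rbind(far, near, inwin), agg)$S_S
  expect_true(s2[1] < s2[2] && s2[2] <= s2[3])
})

test_that("elimination score counts deviations beyond the z threshold", {
  rec <- refCohort()
  agg <- buildReferenceAggregates(rec)
  st <- aggregateStats(agg)
  centroid <- as.data.frame(as.list(setNames(st$mean, st$property)))
  centroid$id <- "c0"
  e0 <- eliminationScore(centroid, agg)
  expect_equal(e0$scores$S_E, 0L)
  expect_equal(nrow(e0$flags), 0L)
  # one property pushed to mean + 3 sd trips exactly one flag
  dev <- centroid
  dev$PSA <- st$mean[st$property == "PSA"] + 3 * st$sd[st$property == "PSA"]
  e1 <- eliminationScore(dev, agg, zThreshold = 2)
  expect_equal(e1$scores$S_E, 1L)
  expect_equal(e1$flags$property, "PSA")
  expect_equal(e1$flags$direction, "above")
  expect_false(e1$flags$benign)
  # a high LD50 deviation is flagged but benign
  tox <- centroid
  tox$LD50 <- st$mean[st$property == "LD50"] + 5 * st$sd[st$property == "LD50"]
  e2 <- eliminationScore(tox, agg)
  expect_true(e2$flags$benign[e2$flags$property == "LD50"])
})

test_that("z-scores, S_E and S_S are invariant under a consistent unit change", {
  rec <- refCohort()
  agg <- buildReferenceAggregates(rec)
  probe <- rec[5, ]; probe$MW <- 700  # out of window so the window term matters
  s1 <- selectionScore(probe, agg)$S_S
  e1 <- eliminationScore(probe, agg)$scores$S_E
  # express MW in centigrams/mol everywhere, windows included
  rec2 <- transform(rec, MW = MW * 100)
  probe2 <- transform(probe, MW = MW * 100)
  win2 <- propertyWindows(); win2$MW <- win2$MW * 100
  agg2 <- buildReferenceAggregates(rec2)
  expect_equal(selectionScore(probe2, agg2, windows = win2)$S_S, s1,
               tolerance = 1e-12)
  expect_equal(eliminationScore(probe2, agg2)$scores$S_E, e1)
})

test_that("candidate selection is a strict double-threshold filter", {
  sc <- data.frame(id = c("a", "b", "c"), S_S = c(1.02, 1.05, 1.03))
  sel <- selectCandidates(sc, c(reference = 1.0, parent = 1.03))
  expect_equal(sel$id, "b")
  expect_equal(nrow(selectCandidates(sc[0, ], c(reference = 1, parent = 1))), 0L)
  # selection equals a brute-force filter and is sorted with stable id ties
  rec <- refCohort()
  agg <- buildReferenceAggregates(rec)
  scores <- selectionScore(rec, agg)
  thr <- c(reference = 1.0, parent = 1.01)
  sel2 <- selectCandidates(scores, thr)
  brute <- scores[scores$S_S > max(thr), ]
  expect_setequal(sel2$id, brute$id)
  expect_true(all(diff(sel2$S_S) <= 0))
  tie <- data.frame(id = c("z", "a"), S_S = c(1.2, 1.2))
  expect_equal(selectCandidates(tie, c(reference = 1, parent = 1))$id,
               c("a", "z"))
})

test_that("missing external fields error when their term is weighted", {
  rec <- refCohort()
  agg <- buildReferenceAggregates(rec)
  noLD <- rec[1, ]; noLD$LD50 <- NA
  expect_error(selectionScore(noLD, agg), "LD50")
  expect_silent(selectionScore(noLD, agg, weights = scoreWeights(tox = 0, sa = 0)))
})
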