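test_that("volcano statistics implement the fold-change / significance gate", {
  set.seed(1)
  base <- matrix(rnorm(40, 10, 1), 8, 5)
  d <- mvDataset(rbind(base, base), rep(c("g0", "g1"), each = 8))
  v <- volcanoStats(d, "g0", "g1")
  expect_equal(v$log2FoldChange, rep(0, 5))
  expect_equal(v$pValue, rep(1, 5))
  expect_false(any(v$significant))

  # one variable with means 1 vs 4 and tiny variance: log2FC = 2, p << 0.01
  set.seed(2)
  X <- cbind(marker = c(rnorm(10, 1, 0.01), rnorm(10, 4, 0.01)),
             flat = rnorm(20, 5, 1))
  d2 <- mvDataset(X, rep(c("g0", "g1"), each = 10))
  v2 <- volcanoStats(d2, "g0", "g1")
  expect_equal(v2$log2FoldChange[1], 2, tolerance = 0.05)
  expect_lt(v2$pValue[1], 1e-6)
  expect_true(v2$significant[1])
  expect_false(v2$significant[2])
  expect_identical(v2$direction[1], "high in right")

  # default gate: needs both p < 0.01 AND > 2-fold
  X3 <- cbind(strongButFlat = c(rnorm(30, 10, 0.1), rnorm(30, 11, 0.1)))
  d3 <- mvDataset(X3, rep(c("g0", "g1"), each = 30))
  v3 <- volcanoStats(d3, "g0", "g1")
  expect_lt(v3$pValue[1], 0.01)
  expect_false(v3$significant[1])      # 1.1-fold only

  # nonpositive mean: excluded, never significant
  X4 <- cbind(neg = c(rnorm(10, -5, 0.1), rnorm(10, 5, 0.1)))
  d4 <- mvDataset(X4, rep(c("g0", "g1"), each = 10))
  v4 <- volcanoStats(d4, "g0", "g1")
  expect_true(v4$excluded[1])
  expect_true(is.na(v4$log2FoldChange[1]))
  expect_false(v4$significant[1])
})

test_that("volcano p-values are invariant to positive rescaling; fold changes are too", {
  set.seed(9)
  X <- matrix(rnorm(40, 20, 3), 10, 4)
  d <- mvDataset(X, rep(c("g0", "g1"), each = 5))
  v1 <- volcanoStats(d, "g0", "g1")
  k <- c(2, 10, 0.5, 7)
  d2 <- mvDataset(sweep(X, 2, k, "*"), datasetLabels(d))
  v2 <- volcanoStats(d2, "g0", "g1")
  expect_equal(v2$pValue, v1$pValue, tolerance = 1e-10)
  expect_equal(v2$log2FoldChange, v1$log2FoldChange, tolerance = 1e-10)
})

test_that("null variables trip the 1% gate at about the nominal rate", {
  set.seed(17)
  X <- matrix(rnorm(60 * 500), 60)
  d <- mvDataset(X, rep(c("g0", "g1"), each = 30))
  v <- volcanoStats(d, "g0", "g1")
  expect_lt(abs(mean(v$pValue < 0.01) - 0.01), 0.01)
})

# minimal HdaNode wrapping a given CvResult, for score-table tests
fakeNode <- function(cv, y) {
  d <- twoCloudDataset(max(4, length(y) / 2), seed = 99)
  model <- fitOplsDa(datasetValues(d), datasetLabels(d), "a", "b")
  model@dummy <- new("DummyResponse", y = y, class0 = "left", class1 = "right")
  new("HdaNode", splitId = 1L, leftClasses = "left", rightClasses = "right",
      model = model, cv = cv, threshold = 0.5)
}

test_that("cv-score tables carry Hotelling ellipses with the closed-form radius", {
  gen <- makeHierarchical(classSizes = 30, seed = 21)
  m <- buildHda(subsetClasses(gen$data, c("A1", "B1")))
  node <- hdaNodes(m)[[1]]
  tab <- cvScoreTable(node)
  expect_equal(nrow(tab$scores), 60)
  # separable fixture: group means on opposite sides of 0
  mt <- tapply(tab$scores$tCv, tab$scores$group, mean)
  expect_lt(min(mt) * max(mt), 0)

  # isotropic closed-form check on synthetic 2-D scores: semi-axes equal and
  # scale with the F-based Hotelling radius
  set.seed(3)
  n <- 400; s <- 1.7
  y <- rep(c(0, 1), each = n / 2)
  cv <- new("CvResult", yCv = y, tCv = rnorm(n, 0, s), tOrthCv = rnorm(n, 0, s),
            pressByA = c("0" = 1, "1" = 0.5), q2ByA = c("0" = 0, "1" = 0.5),
            chosenA = 1L, foldAssignment = rep(1:4, n / 4))
  tab2 <- cvScoreTable(fakeNode(cv, y))
  e <- tab2$ellipses
  for (g in seq_len(nrow(e))) {
    ng <- sum(tab2$scores$group == e$group[g])
    crit <- 2 * (ng - 1) / (ng - 2) * qf(0.95, 2, ng - 2)
    expect_equal(e$semiAxis1[g], e$semiAxis2[g], tolerance = 0.25)
    expect_equal(e$semiAxis1[g], s * sqrt(crit), tolerance = 0.15)
  }
})

test_that("a node with no orthogonal component degenerates to a 1-D t-interval", {
  set.seed(4)
  n <- 40
  y <- rep(c(0, 1), each = n / 2)
  cv <- new("CvResult", yCv = y, tCv = rnorm(n, 2 * y - 1, 0.3),
            tOrthCv = rep(NA_real_, n),
            pressByA = c("0" = 1), q2ByA = c("0" = 0.5),
            chosenA = 0L, foldAssignment = rep(1:4, n / 4))
  tab <- cvScoreTable(fakeNode(cv, y))
  expect_true(all(is.na(tab$scores$tOrthCv)))
  expect_true(all(is.na(tab$ellipses$semiAxis2)))
  for (g in seq_len(nrow(tab$ellipses))) {
    idx <- tab$scores$group == tab$ellipses$group[g]
    ng <- sum(idx)
    expect_equal(tab$ellipses$semiAxis1[g],
                 sd(tab$scores$tCv[idx]) * sqrt(qf(0.95, 1, ng - 1)),
                 tolerance = 1e-10)
  }
})
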