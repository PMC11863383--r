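test_that("three collinear classes produce the expected two-split tree", {
  d <- makeIrisLike(seed = 1, nPerClass = 30)
  m <- buildHda(d)
  expect_length(hdaNodes(m), 2)
  top <- hdaNodes(m)[[1]]
  # split 1 peels off the compact outlying class
  expect_true(setequal(c(top@leftClasses, top@rightClasses),
                       c("setosa", "versicolor", "virginica")))
  expect_true("setosa" %in% c(top@leftClasses, top@rightClasses)[
    c(length(top@leftClasses), length(top@rightClasses)) == 1])
  # split 2 separates the adjacent pair
  expect_setequal(c(hdaNodes(m)[[2]]@leftClasses, hdaNodes(m)[[2]]@rightClasses),
                  c("versicolor", "virginica"))

  # decision regions: on a dense grid restricted to well-separated areas the
  # tree agrees with the nearest-class-mean rule (both evaluated in the
  # variance-scaled metric the models operate in)
  grid <- as.matrix(expand.grid(seq(0.5, 7, length.out = 60),
                                seq(0, 2.6, length.out = 40)))
  centers <- rbind(setosa = c(1.46, 0.25),
                   versicolor = c(1.46, 0.25) + 0.65 * c(5.55 - 1.46, 2.03 - 0.25),
                   virginica = c(5.55, 2.03))
  sds <- apply(datasetValues(d), 2, sd)
  gs <- sweep(grid, 2, sds, "/")
  cs <- sweep(centers, 2, sds, "/")
  dist2 <- vapply(1:3, function(k)
    rowSums(sweep(gs, 2, cs[k, ])^2), numeric(nrow(gs)))
  nearest <- rownames(centers)[max.col(-dist2)]
  margin <- apply(dist2, 1, function(z) sqrt(sort(z)[2]) - sqrt(sort(z)[1]))
  sep <- margin > 0.5        # points clearly closer to one mean
  agree <- mean(predict(m, grid[sep, ])$labels == nearest[sep])
  expect_gte(agree, 0.95)
})

test_that("a two-class HDA model reduces exactly to thresholded OPLS-DA", {
  d <- subsetClasses(makeIrisLike(seed = 2, nPerClass = 15),
                     c("setosa", "virginica"))
  m <- buildHda(d)
  expect_length(hdaNodes(m), 1)
  node <- hdaNodes(m)[[1]]
  prd <- predict(m, datasetValues(d))
  yhat <- predict(node@model, datasetValues(d))$yHat
  manual <- ifelse(yhat < node@threshold,
                   node@leftClasses[1], node@rightClasses[1])
  expect_identical(prd$labels, unname(manual))
  expect_identical(node@model@dummy@class0, node@leftClasses)
  expect_identical(node@model@dummy@class1, node@rightClasses)
})

test_that("12 synthetic classes give 11 splits and full structural invariants", {
  gen <- makeHierarchical(classSizes = 8, nNoiseVariables = 0, seed = 6)
  m <- buildHda(gen$data)
  expect_length(hdaNodes(m), 11)
  expect_length(pairRecords(pairwiseDistanceMatrix(gen$data)), 66)
  # split ids ordered by decreasing dendrogram height
  heights <- vapply(hdaNodes(m), function(nd) {
    members <- c(nd@leftClasses, nd@rightClasses)
    hs <- vapply(dendNodes(m@dendrogram), function(x)
      if (setequal(x$members, members)) x$height else NA_real_, 0)
    hs[!is.na(hs)][1]
  }, 0)
  expect_true(all(diff(heights) <= 1e-12))
  # every class reachable by exactly one root-to-leaf path: the class means
  # themselves land on 12 distinct leaves
  prd <- predict(m, gen$means)
  expect_setequal(prd$labels, rownames(gen$means))
  # thresholds sit strictly between the group mean fitted predictions
  for (nd in hdaNodes(m)) {
    fitted <- nd@model@q * nd@model@tPred + nd@model@yMean
    y <- nd@model@dummy@y
    expect_gt(nd@threshold, mean(fitted[y == 0]))
    expect_lt(nd@threshold, mean(fitted[y == 1]))
  }
})

test_that("training samples of a well-separated fixture route to their own leaves", {
  # betweenScale 16 with decay 0.5 puts even sibling classes ~11 SD apart
  gen <- makeHierarchical(classSizes = 10, betweenScale = 16, seed = 3)
  m <- buildHda(gen$data)
  prd <- predict(m, datasetValues(gen$data))
  expect_gte(mean(prd$labels == datasetLabels(gen$data)), 0.99)
  # path records audit every decision and end at the predicted leaf
  expect_lte(max(vapply(prd$paths, nrow, 0L)), 11)
  i <- 1
  path <- prd$paths[[i]]
  lastNode <- hdaNodes(m)[[path$splitId[nrow(path)]]]
  leaf <- if (path$direction[nrow(path)] == "left")
    lastNode@leftClasses else lastNode@rightClasses
  expect_identical(prd$labels[i], leaf)
})

test_that("a sample exactly at the threshold routes right", {
  d <- subsetClasses(makeIrisLike(seed = 7, nPerClass = 10),
                     c("setosa", "virginica"))
  m <- buildHda(d)
  node <- hdaNodes(m)[[1]]
  # construct a point whose prediction equals the threshold by solving along
  # the predictive direction in raw space
  pre <- node@model@preprocessor
  base <- colMeans(datasetValues(d))
  dirRaw <- node@model@wPred * pre@columnScales
  f <- function(alpha) predict(node@model, rbind(base + alpha * dirRaw))$yHat - node@threshold
  alpha <- uniroot(f, c(-50, 50), tol = 1e-15)$root
  x <- rbind(base + alpha * dirRaw)
  prd <- predict(m, x)
  yhat <- predict(node@model, x)$yHat
  expect_lt(abs(yhat - node@threshold), 1e-10)
  if (yhat >= node@threshold)
    expect_identical(prd$paths[[1]]$direction, "right")
})

test_that("confusion matrix counts and accuracy follow the actual/predicted layout", {
  cm <- confusionMatrix(c("a", "b", "c"), c("a", "b", "c"))
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(attr(cm, "accuracy"), 1)

  cm2 <- confusionMatrix(c("a", "b", "c", "a"), rep("b", 4))
  expect_equal(sum(cm2[, "b"]), 4)
  expect_equal(sum(cm2[, c("a", "c")]), 0)

  truth <- c(rep("A", 3), rep("B", 3))
  pred <- c("A", "A", "B", "B", "B", "B")        # one known swap
  cm3 <- confusionMatrix(truth, pred)
  expect_equal(cm3["A", "B"], 1)
  expect_equal(attr(cm3, "accuracy"), 5 / 6)
  expect_error(confusionMatrix("a", "z", classOrder = c("a", "b")), "outside")
})

test_that("identical data and config give identical serialized models", {
  d <- makeIrisLike(seed = 10, nPerClass = 12)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  saveHdaModel(buildHda(d), f1)
  saveHdaModel(buildHda(d), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("HDA model JSON round-trip reproduces predictions bitwise", {
  d <- makeIrisLike(seed = 11, nPerClass = 10)
  m <- buildHda(d)
  path <- withr::local_tempfile(fileext = ".json")
  saveHdaModel(m, path)
  m2 <- readHdaModel(path)
  Xnew <- datasetValues(makeIrisLike(seed = 12, nPerClass = 5))
  expect_identical(predict(m2, Xnew)$labels, predict(m, Xnew)$labels)
  p1 <- predict(m, Xnew)$paths[[1]]; p2 <- predict(m2, Xnew)$paths[[1]]
  expect_identical(p1$yHat, p2$yHat)
})
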