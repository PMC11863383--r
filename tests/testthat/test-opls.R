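test_that("a single perfectly predictive column is recovered with zero residual", {
  y <- c(-2, -1, 0, 1, 2)
  X <- cbind(y)
  m <- fitOpls(X, y, 0)
  expect_equal(abs(cor(m@tPred, y)), 1, tolerance = 1e-12)
  expect_equal(m@residualY, rep(0, 5), tolerance = 1e-12)
})

test_that("model invariants hold on random fits: reconstruction and orthogonality", {
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(8:25, 1); p <- sample(4:30, 1)
    nOrth <- sample(0:2, 1)
    X <- matrix(rnorm(n * p), n)
    y <- rnorm(n)
    X <- scale(X, scale = FALSE); y <- y - mean(y)
    m <- fitOpls(X, y, nOrth)
    recon <- tcrossprod(m@tPred, m@pPred) + m@TOrth %*% t(m@POrth) + m@residualX
    expect_lt(norm(recon - X, "F") / norm(X, "F"), 1e-8)
    expect_equal(m@q * m@tPred + m@residualY, y, tolerance = 1e-8)
    for (a in seq_len(nOrth)) {
      expect_lt(abs(sum(m@tPred * m@TOrth[, a])) /
                  (sqrt(sum(m@tPred^2)) * sqrt(sum(m@TOrth[, a]^2))), 1e-8)
      expect_lt(abs(sum(m@wPred * m@WOrth[, a])), 1e-8)
    }
    expect_equal(sum(m@wPred^2), 1, tolerance = 1e-12)
  }
})

test_that("OPLS with a orthogonal components predicts identically to (a+1)-component PLS", {
  set.seed(33)
  for (rep in 1:10) {
    n <- sample(10:40, 1); p <- sample(3:60, 1)
    X <- scale(matrix(rnorm(n * p), n), scale = FALSE)
    y <- rnorm(n); y <- y - mean(y)
    Xnew <- matrix(rnorm(4 * p), 4)
    for (a in 0:2) {
      m <- fitOpls(X, y, a)
      expect_equal(predict(m, Xnew)$yHat,
                   as.numeric(Xnew %*% oraclePlsCoef(X, y, a + 1)),
                   tolerance = 1e-8)
    }
  }
})

test_that("a constructed y-orthogonal component is recovered", {
  y <- c(-1, -1, -1, 1, 1, 1)
  to <- c(1, -1, 0, 1, -1, 0)            # orthogonal to y by construction
  # the orthogonal loading must overlap the predictive direction, otherwise
  # that variation never enters the predictive score and there is nothing
  # for the orthogonal filter to remove
  pPred <- c(1, 0, 0); pOrth <- c(1, 2, 1)
  X <- tcrossprod(y, pPred) + tcrossprod(to, pOrth)
  m <- fitOpls(X, y, 1)
  # recovered orthogonal score spans to: cosine of angle ~ 1
  cosang <- abs(sum(m@TOrth[, 1] * to)) /
    (sqrt(sum(m@TOrth[, 1]^2)) * sqrt(sum(to^2)))
  expect_gt(cosang, 1 - 1e-6)
})

test_that("prediction is consistent with training and invariant to absorbed shifts", {
  d <- twoCloudDataset(8)
  m <- fitOplsDa(datasetValues(d), datasetLabels(d), "a", "b", nOrth = 1)
  prd <- predict(m, datasetValues(d))
  expect_equal(prd$yHat, m@q * m@tPred + m@yMean, tolerance = 1e-10)

  one <- datasetValues(d)[3, , drop = FALSE]
  three <- one[rep(1, 3), ]
  expect_equal(predict(m, three)$yHat, rep(predict(m, one)$yHat, 3))

  # manual-centring oracle: preprocessing absorbs the training means, so
  # predicting pre-centred data with a mean-free model gives the same yHat
  pre <- m@preprocessor
  Xc <- applyPreprocessor(pre, datasetValues(d))
  mShift <- m
  mShift@preprocessor <- new("Preprocessor",
                             columnMeans = rep(0, nVariables(d)),
                             columnScales = rep(1, nVariables(d)), mode = "none")
  expect_equal(predict(mShift, Xc)$yHat, predict(m, datasetValues(d))$yHat,
               tolerance = 1e-10)
})

test_that("degenerate inputs raise informative errors", {
  X <- matrix(rnorm(20), 5)
  expect_error(fitOpls(X, rep(1, 5), 0), "constant")
  expect_error(fitOpls(X, rnorm(5), 50), "bound")
  m <- fitOpls(scale(X, scale = FALSE), c(-1, -1, 0, 1, 1), 0)
  expect_error(predict(m, matrix(rnorm(10), 2, 5)), "columns")
})

test_that("identical inputs give bitwise-identical fits (deterministic, no RNG)", {
  set.seed(77)
  X <- scale(matrix(rnorm(80), 10), scale = FALSE)
  y <- rnorm(10); y <- y - mean(y)
  m1 <- fitOpls(X, y, 2); m2 <- fitOpls(X, y, 2)
  expect_identical(m1@wPred, m2@wPred)
  expect_identical(m1@TOrth, m2@TOrth)
  expect_identical(m1@q, m2@q)
})

test_that("OPLS model JSON round-trip reproduces predictions bitwise", {
  d <- twoCloudDataset(6)
  m <- fitOplsDa(datasetValues(d), datasetLabels(d), "a", "b", nOrth = 1)
  path <- withr::local_tempfile(fileext = ".json")
  saveOplsModel(m, path)
  m2 <- readOplsModel(path)
  Xnew <- datasetValues(d) + 0.1
  expect_identical(predict(m2, Xnew)$yHat, predict(m, Xnew)$yHat)
})
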