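#' Stratified fold assignment
#'
#' Deterministic given `(labels, k, seed)`: within each class (processed in
#' sorted order) the sample indices are shuffled under the seeded RNG and
#' dealt round-robin over folds 1..k, so fold sizes differ by at most one
#' within every class and a class with fewer samples than folds is spread
#' over distinct folds — no training fold can ever lose a class entirely.
#'
#' @param labels character class labels.
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return integer fold index per sample.
#' @export
assignFolds <- function(labels, k, seed = 0L) {
  if (k < 2) stopf("k must be >= 2 (got %s)", k)
  n <- length(labels)
  folds <- integer(n)
  withSeed(seed, {
    offset <- 0L
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      # continue the round-robin across classes so all k folds are used even
      # when individual classes are smaller than k (e.g. leave-one-out)
      folds[idx] <- ((offset + seq_along(idx) - 1L) %% as.integer(k)) + 1L
      offset <- offset + length(idx)
    }
  })
  folds
}

#' k-fold cross-validation of a two-class OPLS-DA model
#'
#' For each fold, the preprocessor and the OPLS model are refitted on the
#' in-fold samples only (no leakage into the held-out predictions) and the
#' held-out samples are predicted. Results are returned in the original
#' sample order.
#'
#' @param data an [MvDataset-class] restricted to the samples being modelled.
#' @param dummy a [DummyResponse-class] for those samples.
#' @param nOrth orthogonal component count.
#' @param k folds.
#' @param seed fold-assignment seed.
#' @param mode scaling mode.
#' @param folds optional precomputed fold assignment (overrides `k`/`seed`).
#' @return list with `yCv`, `tCv`, `tOrthCv` (NA column when nOrth = 0),
#'   `press`, `q2`, `folds`.
#' @export
crossValidate <- function(data, dummy, nOrth = 0L, k = 7L, seed = 0L,
                          mode = "uv", folds = NULL) {
  y <- dummy@y
  n <- nSamples(data)
  if (length(y) != n) stopf("dummy length does not match dataset")
  if (is.null(folds)) folds <- assignFolds(data@labels, k, seed)
  yCv <- numeric(n); tCv <- numeric(n)
  tOrthCv <- rep(NA_real_, n)
  for (fold in sort(unique(folds))) {
    test <- folds == fold
    train <- !test
    ytr <- y[train]
    if (sd(ytr) < 1e-14)
      stopf("fold %d leaves the training set with a single class", fold)
    pre <- fitPreprocessor(data@values[train, , drop = FALSE], mode)
    ym <- mean(ytr)
    fit <- fitOpls(applyPreprocessor(pre, data@values[train, , drop = FALSE]),
                   ytr - ym, nOrth, preprocessor = pre, dummy = dummy, yMean = ym)
    prd <- predict(fit, data@values[test, , drop = FALSE])
    yCv[test] <- prd$yHat
    tCv[test] <- prd$tPred
    if (nOrth > 0) tOrthCv[test] <- prd$TOrth[, 1]
  }
  press <- sum((y - yCv)^2)
  ssy <- sum((y - mean(y))^2)
  list(yCv = yCv, tCv = tCv, tOrthCv = tOrthCv, press = press,
       q2 = 1 - press / ssy, folds = folds)
}

#' Select the number of orthogonal components by cross-validated prediction error
#'
#' Evaluates A = 0, 1, 2, ... orthogonal components sequentially, keeping
#' A + 1 over A only when the cross-validated Q2 improves by more than
#' `q2GainThreshold`; stops at the first failure, at `maxOrth`, or when the
#' data cannot support another component. The chosen model's cross-validated
#' predictions are what downstream Cohen's d distances are computed from.
#'
#' @param data an [MvDataset-class].
#' @param dummy a [DummyResponse-class].
#' @param k folds (default 7).
#' @param seed fold seed (default 0).
#' @param maxOrth largest orthogonal count considered (default 5).
#' @param q2GainThreshold minimal Q2 gain to keep an extra component
#'   (default 0.01).
#' @param mode scaling mode.
#' @return a [CvResult-class] for the chosen component count, carrying the
#'   full PRESS/Q2 trace over every evaluated count.
#' @export
selectNOrth <- function(data, dummy, k = 7L, seed = 0L, maxOrth = 5L,
                        q2GainThreshold = 0.01, mode = "uv") {
  if (maxOrth < 0) stopf("maxOrth must be >= 0")
  folds <- assignFolds(data@labels, k, seed)
  runs <- list()
  press <- numeric(0); q2 <- numeric(0)
  runs[["0"]] <- crossValidate(data, dummy, 0L, mode = mode, folds = folds)
  press["0"] <- runs[["0"]]$press
  q2["0"] <- runs[["0"]]$q2
  chosen <- 0L
  A <- 0L
  while (A < maxOrth) {
    A <- A + 1L
    run <- tryCatch(crossValidate(data, dummy, A, mode = mode, folds = folds),
                    error = function(e) NULL)
    if (is.null(run)) break                    # rank exhausted in some fold
    key <- as.character(A)
    runs[[key]] <- run
    press[key] <- run$press
    q2[key] <- run$q2
    if (q2[key] - q2[as.character(chosen)] > q2GainThreshold) chosen <- A else break
  }
  best <- runs[[as.character(chosen)]]
  new("CvResult", yCv = best$yCv, tCv = best$tCv, tOrthCv = best$tOrthCv,
      pressByA = press, q2ByA = q2, chosenA = chosen,
      foldAssignment = as.integer(folds))
}

#' @describeIn selectNOrth Q2 of the chosen component count
#' @param cv a [CvResult-class].
#' @export
cvQ2 <- function(cv) unname(cv@q2ByA[as.character(cv@chosenA)])

#' @describeIn selectNOrth PRESS of the chosen component count
#' @export
cvPress <- function(cv) unname(cv@pressByA[as.character(cv@chosenA)])

#' Tabulate a cross-validation result
#'
#' One row per sample: fold index, cross-validated prediction and
#' cross-validated predictive score, suitable for CSV export.
#' @param cv a [CvResult-class].
#' @param sampleIds optional sample identifiers.
#' @return data.frame with sampleId, fold, yCv, tCv.
#' @export
cvResultTable <- function(cv, sampleIds = NULL) {
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_along(cv@yCv))
  data.frame(sampleId = sampleIds, fold = cv@foldAssignment,
             yCv = cv@yCv, tCv = cv@tCv, stringsAsFactors = FALSE)
}

setMethod("show", "CvResult", function(object) {
  cat("CvResult:", length(object@yCv), "samples, chosen A =", object@chosenA,
      sprintf("(Q2 = %.3f)\n", cvQ2(object)))
})
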