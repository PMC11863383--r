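#' Fit a two-class OPLS(-DA) model
#'
#' Implements the classic O-PLS extraction for a single response: the model
#' splits predictor variation into one predictive component (the direction
#' used to model the response — between-class variation in the discriminant
#' setting) and `nOrth` orthogonal components (systematic variation in X
#' uncorrelated with the response — within-class variation).
#'
#' With a single response the PLS weight has the closed form
#' `w = X'y / ||X'y||`, so no iterative NIPALS loop is needed and the fit is
#' fully deterministic. For each orthogonal component the y-orthogonal part
#' of the current loading is split off (`wOrth = p - (w'p) w`), its scores
#' and loadings computed, and X deflated; the single predictive component is
#' extracted from the fully deflated matrix. Because orthogonal scores are
#' orthogonal to y, the predictive weight is unchanged by the deflations.
#'
#' `X` is expected already preprocessed (see [fitPreprocessor()]) and `y`
#' centred; `preprocessor`, `dummy` and `yMean` are carried in the returned
#' model so that [predict()] can be applied to raw data and report on the
#' original 0/1 dummy scale.
#'
#' @param X preprocessed numeric matrix (n x p), n >= 2, p >= 1.
#' @param y centred response vector with nonzero variance.
#' @param nOrth number of orthogonal components (>= 0).
#' @param preprocessor the [Preprocessor-class] that produced `X`.
#' @param dummy optional [DummyResponse-class] behind `y`.
#' @param yMean training mean of the uncentred response (added back at
#'   prediction time).
#' @return an [OplsModel-class].
#' @export
fitOpls <- function(X, y, nOrth = 0L,
                    preprocessor = new("Preprocessor",
                                       columnMeans = rep(0, ncol(X)),
                                       columnScales = rep(1, ncol(X)),
                                       mode = "none"),
                    dummy = new("DummyResponse", y = numeric(),
                                class0 = character(), class1 = character()),
                    yMean = 0) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2 || p < 1) stopf("X must have >= 2 rows and >= 1 column")
  if (length(y) != n) stopf("length(y) != nrow(X)")
  nOrth <- as.integer(nOrth)
  if (nOrth < 0) stopf("nOrth must be >= 0")
  if (sd(y) < 1e-14) stopf("degenerate response: y is constant")
  bound <- min(n - 1L, p) - 1L
  if (nOrth > max(bound, 0L))
    stopf("nOrth = %d exceeds the extractable bound %d for a %d x %d matrix",
          nOrth, max(bound, 0L), n, p)

  Xd <- X
  xy <- crossprod(Xd, y)            # invariant under the orthogonal deflations
  nxy <- sqrt(sum(xy^2))
  if (nxy < 1e-14) stopf("X carries no covariance with y; nothing to extract")
  w <- as.numeric(xy) / nxy

  WOrth <- matrix(0, p, nOrth)
  POrth <- matrix(0, p, nOrth)
  TOrth <- matrix(0, n, nOrth)
  totX <- sum(Xd^2)
  for (a in seq_len(nOrth)) {
    tt <- as.numeric(Xd %*% w)
    pp <- as.numeric(crossprod(Xd, tt)) / sum(tt^2)
    wo <- pp - sum(w * pp) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo^2 < 1e-12 * sum(pp^2) || nwo < 1e-14)
      stopf("rank exhausted: no orthogonal variation left for component %d", a)
    wo <- wo / nwo
    to <- as.numeric(Xd %*% wo)
    if (sum(to^2) < 1e-12 * totX)
      stopf("rank exhausted: orthogonal component %d has ~zero variance", a)
    po <- as.numeric(crossprod(Xd, to)) / sum(to^2)
    Xd <- Xd - tcrossprod(to, po)
    WOrth[, a] <- wo; POrth[, a] <- po; TOrth[, a] <- to
  }
  tp <- as.numeric(Xd %*% w)
  pp <- as.numeric(crossprod(Xd, tp)) / sum(tp^2)
  q <- sum(y * tp) / sum(tp^2)
  E <- Xd - tcrossprod(tp, pp)
  f <- y - q * tp

  new("OplsModel", wPred = w, pPred = pp, tPred = tp, q = q,
      WOrth = WOrth, POrth = POrth, TOrth = TOrth, nOrth = nOrth,
      preprocessor = preprocessor, dummy = dummy, yMean = as.numeric(yMean),
      residualX = E, residualY = f)
}

#' Fit an OPLS-DA model from raw data
#'
#' Convenience wrapper: fits the preprocessor on the given samples, encodes
#' the dummy response, centres it, and calls [fitOpls()].
#'
#' @param values raw numeric matrix (samples x variables).
#' @param labels class labels, one per row.
#' @param class0,class1 class-name sets for the two sides.
#' @param nOrth orthogonal component count.
#' @param mode scaling mode, see [fitPreprocessor()].
#' @return an [OplsModel-class].
#' @export
fitOplsDa <- function(values, labels, class0, class1, nOrth = 0L, mode = "uv") {
  pre <- fitPreprocessor(values, mode)
  dummy <- encodeDummy(labels, class0, class1)
  ym <- mean(dummy@y)
  fitOpls(applyPreprocessor(pre, values), dummy@y - ym, nOrth,
          preprocessor = pre, dummy = dummy, yMean = ym)
}

#' Predict from a fitted OPLS model
#'
#' Applies the stored preprocessor to the raw matrix, removes the orthogonal
#' variation component by component, projects onto the predictive weight and
#' returns predictions on the original dummy scale
#' (`yHat = q * tPredNew + yMean`). Deterministic.
#'
#' @param object an [OplsModel-class].
#' @param newdata raw numeric matrix with the training column count.
#' @return list with `yHat` (numeric), `tPred` (numeric predictive scores)
#'   and `TOrth` (matrix of orthogonal scores, 0 columns when nOrth = 0).
#' @export
setMethod("predict", "OplsModel", function(object, newdata) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object@wPred))
    stopf("newdata has %d columns; model expects %d", ncol(X), length(object@wPred))
  Xc <- applyPreprocessor(object@preprocessor, X)
  TOrthNew <- matrix(0, nrow(Xc), object@nOrth)
  for (a in seq_len(object@nOrth)) {
    to <- as.numeric(Xc %*% object@WOrth[, a])
    Xc <- Xc - tcrossprod(to, object@POrth[, a])
    TOrthNew[, a] <- to
  }
  tNew <- as.numeric(Xc %*% object@wPred)
  list(yHat = object@q * tNew + object@yMean, tPred = tNew, TOrth = TOrthNew)
})

setMethod("show", "OplsModel", function(object) {
  cat("OplsModel: 1 predictive +", object@nOrth, "orthogonal component(s),",
      length(object@wPred), "variables,", length(object@tPred), "training samples\n")
  if (length(object@dummy@class0))
    cat("  0 =", paste(object@dummy@class0, collapse = "+"),
        " vs  1 =", paste(object@dummy@class1, collapse = "+"), "\n")
})
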