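#' Cohen's d between two groups of cross-validated predictions
#'
#' Standardized mean difference `|m1 - m0| / s_p` with the pooled standard
#' deviation `s_p = sqrt((ss0 + ss1) / (n0 + n1 - 2))`, where each `ss` is a
#' group's sum of squared deviations from its own mean. Large when a
#' two-class model pushes each class's predictions tightly toward its 0/1
#' target; near zero when predictions of both classes collapse around the
#' response mean. The absolute value makes it a dissimilarity; a zero pooled
#' SD with distinct means (perfect noiseless separation) is capped at 1e6 so
#' downstream linkage stays finite.
#'
#' @param yhat0,yhat1 prediction vectors of the two groups (length >= 2 each).
#' @return nonnegative scalar.
#' @examples
#' cohensD(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9))  # 6
#' @export
cohensD <- function(yhat0, yhat1) {
  n0 <- length(yhat0); n1 <- length(yhat1)
  if (n0 < 2 || n1 < 2)
    stopf("each group needs >= 2 samples (got %d and %d)", n0, n1)
  m0 <- mean(yhat0); m1 <- mean(yhat1)
  ss0 <- sum((yhat0 - m0)^2); ss1 <- sum((yhat1 - m1)^2)
  sp <- sqrt((ss0 + ss1) / (n0 + n1 - 2))
  if (sp == 0) return(if (m0 == m1) 0 else 1e6)
  min(abs(m1 - m0) / sp, 1e6)
}

#' All pairwise one-vs-one OPLS-DA models and the Cohen's d distance matrix
#'
#' For every unordered pair of classes (lexicographic iteration order) the
#' dataset is restricted to the two classes, the orthogonal component count
#' is selected by cross-validation ([selectNOrth()]), and Cohen's d is
#' computed from the chosen model's cross-validated predictions. N classes
#' yield N(N-1)/2 models; the distances fill a symmetric matrix with zero
#' diagonal whose rows/columns are ordered lexicographically by class name.
#'
#' @param data an [MvDataset-class] with >= 2 classes.
#' @param control build parameters from [hdaControl()].
#' @param verbose print one line per pair.
#' @return a [ClassDistanceMatrix-class]; per-pair records (chosen component
#'   count, Q2, Cohen's d, the CvResult) are in `records(x)`.
#' @export
pairwiseDistanceMatrix <- function(data, control = hdaControl(), verbose = FALSE) {
  cls <- classNames(data)
  N <- length(cls)
  if (N < 2) stopf("need >= 2 classes, found %d", N)
  d <- matrix(0, N, N, dimnames = list(cls, cls))
  records <- vector("list", N * (N - 1) / 2)
  r <- 0L
  for (i in seq_len(N - 1)) for (j in seq.int(i + 1, N)) {
    a <- cls[i]; b <- cls[j]
    sub <- subsetClasses(data, c(a, b))
    dummy <- encodeDummy(sub@labels, a, b)
    cv <- selectNOrth(sub, dummy, k = control$cvFolds, seed = control$cvSeed,
                      maxOrth = control$maxOrth,
                      q2GainThreshold = control$q2GainThreshold,
                      mode = control$scaling)
    dd <- cohensD(cv@yCv[sub@labels == a], cv@yCv[sub@labels == b])
    d[i, j] <- d[j, i] <- dd
    r <- r + 1L
    records[[r]] <- list(classA = a, classB = b, chosenA = cv@chosenA,
                         q2 = cvQ2(cv), cohensD = dd, cv = cv)
    if (verbose)
      message(sprintf("pair %s vs %s: A = %d, Q2 = %.3f, d = %.3f",
                      a, b, cv@chosenA, cvQ2(cv), dd))
  }
  new("ClassDistanceMatrix", classNames = cls, d = d, records = records)
}

#' @describeIn pairwiseDistanceMatrix per-pair model records
#' @param x a [ClassDistanceMatrix-class].
#' @export
pairRecords <- function(x) x@records

#' @describeIn pairwiseDistanceMatrix the distance matrix itself
#' @export
distanceMatrix <- function(x) x@d

#' Per-pair summary table
#' @param x a [ClassDistanceMatrix-class].
#' @return data.frame with classA, classB, chosenA, q2, cohensD.
#' @export
pairSummary <- function(x) {
  do.call(rbind, lapply(x@records, function(r)
    data.frame(classA = r$classA, classB = r$classB, chosenA = r$chosenA,
               q2 = r$q2, cohensD = r$cohensD, stringsAsFactors = FALSE)))
}

setMethod("show", "ClassDistanceMatrix", function(object) {
  cat("ClassDistanceMatrix over", length(object@classNames), "classes (",
      length(object@records), "pairwise models )\n")
  print(round(object@d, 3))
})
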