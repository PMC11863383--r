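#' Build configuration for an OPLS-HDA model
#'
#' Central validated list of every tunable. Defaults: unit-variance scaling
#' (the chemometrics convention), 7-fold cross-validation with seed 0, up to
#' 5 orthogonal components kept only when each adds more than 0.01 of Q2,
#' average linkage, and the volcano gate P < 0.01 with a > 2-fold difference.
#'
#' @param scaling "uv", "center", "pareto" or "none".
#' @param cvFolds number of cross-validation folds (>= 2).
#' @param cvSeed integer seed for fold assignment.
#' @param maxOrth maximum orthogonal components per two-class model.
#' @param q2GainThreshold minimum Q2 gain to keep an extra component.
#' @param linkage "average", "single", "complete" or "ward".
#' @param alpha volcano significance level.
#' @param foldThreshold volcano fold-change gate (ratio scale).
#' @return named list of validated parameters.
#' @export
hdaControl <- function(scaling = "uv", cvFolds = 7L, cvSeed = 0L,
                       maxOrth = 5L, q2GainThreshold = 0.01,
                       linkage = "average", alpha = 0.01, foldThreshold = 2) {
  scaling <- match.arg(scaling, c("uv", "center", "pareto", "none"))
  linkage <- match.arg(linkage, c("average", "single", "complete", "ward"))
  cvFolds <- as.integer(cvFolds)
  if (is.na(cvFolds) || cvFolds < 2) stopf("cvFolds must be an integer >= 2")
  maxOrth <- as.integer(maxOrth)
  if (is.na(maxOrth) || maxOrth < 0) stopf("maxOrth must be an integer >= 0")
  if (!is.finite(q2GainThreshold)) stopf("q2GainThreshold must be finite")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  if (!is.finite(foldThreshold) || foldThreshold < 1)
    stopf("foldThreshold must be >= 1 (ratio scale)")
  list(scaling = scaling, cvFolds = cvFolds, cvSeed = as.integer(cvSeed),
       maxOrth = maxOrth, q2GainThreshold = q2GainThreshold,
       linkage = linkage, alpha = alpha, foldThreshold = foldThreshold)
}
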