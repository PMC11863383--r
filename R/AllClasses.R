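#' @import methods
#' @importFrom stats predict sd var qf pf p.adjust t.test rnorm runif hclust as.dist cov setNames
#' @importFrom tools md5sum
NULL

#' Multivariate dataset with class labels
#'
#' Container for a samples x variables numeric matrix plus one categorical
#' class label per sample, the universal input of the OPLS-HDA workflow.
#' Row/column identity is carried by `sampleIds` and `variableNames`;
#' every class must contain at least two samples (required for the pooled
#' standard deviation underlying Cohen's d).
#'
#' @slot values numeric matrix, samples in rows, variables in columns.
#' @slot sampleIds character vector of unique sample identifiers.
#' @slot variableNames character vector of unique variable names.
#' @slot labels character vector of class names, one per sample.
#'
#' @seealso [mvDataset()], [readDataset()]
#' @export
setClass("MvDataset", representation(
  values = "matrix",
  sampleIds = "character",
  variableNames = "character",
  labels = "character"
))

setValidity("MvDataset", function(object) {
  v <- object@values
  msgs <- character()
  if (!is.numeric(v)) msgs <- c(msgs, "values must be a numeric matrix")
  if (nrow(v) != length(object@sampleIds))
    msgs <- c(msgs, "row count of values must equal length of sampleIds")
  if (nrow(v) != length(object@labels))
    msgs <- c(msgs, "row count of values must equal length of labels")
  if (ncol(v) != length(object@variableNames))
    msgs <- c(msgs, "column count of values must equal length of variableNames")
  if (anyDuplicated(object@sampleIds))
    msgs <- c(msgs, "duplicate sample id")
  if (anyDuplicated(object@variableNames))
    msgs <- c(msgs, "duplicate variable name")
  if (length(v) && anyNA(v))
    msgs <- c(msgs, "values contains missing entries; impute or drop before construction")
  if (length(object@labels)) {
    tab <- table(object@labels)
    if (any(tab < 2))
      msgs <- c(msgs, paste0("every class needs >= 2 samples; offending: ",
                             paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

#' Column centering/scaling state
#'
#' Stores per-variable means and scales fitted on a training matrix so that
#' exactly the same transformation can be applied to held-out data. Modes:
#' `"center"` (mean centring only), `"uv"` (unit variance: centre and divide
#' by the sample standard deviation), `"pareto"` (divide by the square root
#' of the standard deviation), `"none"`. Scales are floored at 1e-12 so
#' constant columns map to (numerically) zero rather than NaN.
#'
#' @slot columnMeans numeric vector of per-variable training means.
#' @slot columnScales numeric vector of strictly positive per-variable scales.
#' @slot mode character, one of "center", "uv", "pareto", "none".
#' @export
setClass("Preprocessor", representation(
  columnMeans = "numeric",
  columnScales = "numeric",
  mode = "character"
))

setValidity("Preprocessor", function(object) {
  msgs <- character()
  if (length(object@columnMeans) != length(object@columnScales))
    msgs <- c(msgs, "columnMeans and columnScales must have equal length")
  if (any(object@columnScales <= 0))
    msgs <- c(msgs, "columnScales must be strictly positive")
  if (!object@mode %in% c("center", "uv", "pareto", "none"))
    msgs <- c(msgs, "mode must be one of center, uv, pareto, none")
  if (length(msgs)) msgs else TRUE
})

#' 0/1 dummy response for a two-group discriminant model
#'
#' Encodes class membership as the OPLS-DA response vector: samples whose
#' class is in `class0` get 0, those in `class1` get 1. For a balanced
#' two-class set the mean of `y` is exactly 0.5.
#'
#' @slot y numeric 0/1 vector, one entry per sample.
#' @slot class0 character set of class names mapped to 0.
#' @slot class1 character set of class names mapped to 1.
#' @export
setClass("DummyResponse", representation(
  y = "numeric",
  class0 = "character",
  class1 = "character"
))

setValidity("DummyResponse", function(object) {
  msgs <- character()
  if (!all(object@y %in% c(0, 1))) msgs <- c(msgs, "y must contain only 0 and 1")
  if (length(intersect(object@class0, object@class1)))
    msgs <- c(msgs, "class0 and class1 must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' Fitted two-class OPLS(-DA) model
#'
#' One predictive component plus `nOrth` orthogonal components extracted by
#' the classic O-PLS algorithm. The preprocessed training matrix decomposes
#' as `tPred %*% t(pPred) + TOrth %*% t(POrth) + E`, and the centred response
#' as `q * tPred + f`. The predictive weight is orthogonal to every
#' orthogonal weight, and the predictive score to every orthogonal score.
#'
#' @slot wPred unit-norm predictive weight vector (length p).
#' @slot pPred predictive loading vector (length p).
#' @slot tPred predictive score vector (length n train).
#' @slot q scalar regression coefficient of the centred response on tPred.
#' @slot WOrth p x A matrix of unit-norm orthogonal weights.
#' @slot POrth p x A matrix of orthogonal loadings.
#' @slot TOrth n x A matrix of orthogonal scores.
#' @slot nOrth integer count A of orthogonal components.
#' @slot preprocessor the [Preprocessor-class] fitted on the training samples.
#' @slot dummy the [DummyResponse-class] used as response (empty for plain
#'   regression use).
#' @slot yMean scalar training mean of the 0/1 response; predictions are
#'   returned on the original dummy scale by adding it back.
#' @slot residualX training residual matrix E.
#' @slot residualY training residual vector f.
#' @export
setClass("OplsModel", representation(
  wPred = "numeric",
  pPred = "numeric",
  tPred = "numeric",
  q = "numeric",
  WOrth = "matrix",
  POrth = "matrix",
  TOrth = "matrix",
  nOrth = "integer",
  preprocessor = "Preprocessor",
  dummy = "DummyResponse",
  yMean = "numeric",
  residualX = "matrix",
  residualY = "numeric"
))

#' Cross-validation result for a two-class OPLS-DA model
#'
#' Per-sample cross-validated predictions (each sample predicted by the fold
#' model that excluded it), cross-validated predictive and first orthogonal
#' scores, the PRESS/Q2 trace over candidate orthogonal-component counts, and
#' the count chosen by the sequential Q2-gain rule.
#'
#' @slot yCv cross-validated predictions on the 0/1 dummy scale.
#' @slot tCv cross-validated predictive scores.
#' @slot tOrthCv cross-validated first orthogonal scores (NA when chosenA = 0).
#' @slot pressByA named numeric, PRESS per evaluated orthogonal count.
#' @slot q2ByA named numeric, Q2 = 1 - PRESS/SSy per evaluated count.
#' @slot chosenA integer, selected number of orthogonal components.
#' @slot foldAssignment integer fold index per sample.
#' @export
setClass("CvResult", representation(
  yCv = "numeric",
  tCv = "numeric",
  tOrthCv = "numeric",
  pressByA = "numeric",
  q2ByA = "numeric",
  chosenA = "integer",
  foldAssignment = "integer"
))

setValidity("CvResult", function(object) {
  msgs <- character()
  if (any(object@q2ByA > 1 + 1e-12)) msgs <- c(msgs, "Q2 cannot exceed 1")
  if (length(msgs)) msgs else TRUE
})

#' Symmetric Cohen's d distance matrix over classes
#'
#' Entry (i, j) is the Cohen's d computed from the cross-validated
#' predictions of the one-vs-one OPLS-DA model for classes i and j.
#' `records` keeps one [list] entry per unordered pair (class names, chosen
#' orthogonal count, Q2, Cohen's d, the CvResult).
#'
#' @slot classNames ordered (lexicographic) class names.
#' @slot d N x N symmetric nonnegative matrix with zero diagonal.
#' @slot records list of per-pair model records.
#' @export
setClass("ClassDistanceMatrix", representation(
  classNames = "character",
  d = "matrix",
  records = "list"
))

setValidity("ClassDistanceMatrix", function(object) {
  d <- object@d
  msgs <- character()
  if (nrow(d) != ncol(d) || nrow(d) != length(object@classNames))
    msgs <- c(msgs, "d must be square with one row per class")
  else {
    if (max(abs(d - t(d))) > 1e-12) msgs <- c(msgs, "d must be symmetric")
    if (any(diag(d) != 0)) msgs <- c(msgs, "diagonal must be exactly 0")
    if (any(!is.finite(d))) msgs <- c(msgs, "all entries must be finite")
    if (any(d < 0)) msgs <- c(msgs, "distances must be nonnegative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Class dendrogram from agglomerative clustering
#'
#' Binary merge tree over classes with merge heights on the Cohen's d scale.
#' `nodes` lists 2N-1 nodes: leaves 1..N (height 0, one class each) then
#' internal nodes N+1..2N-1 in merge order, each with `left`, `right`
#' child ids, `height`, and `members` (the class-name set).
#'
#' @slot classNames leaf class names, in distance-matrix order.
#' @slot merge (N-1) x 2 matrix of merged node ids.
#' @slot heights numeric merge heights.
#' @slot linkage linkage rule used ("single", "complete", "average", "ward").
#' @slot nodes list of node records.
#' @export
setClass("Dendrogram", representation(
  classNames = "character",
  merge = "matrix",
  heights = "numeric",
  linkage = "character",
  nodes = "list"
))

#' One split of an OPLS-HDA decision tree
#'
#' An internal dendrogram node fitted with a two-class OPLS-DA model that
#' discriminates the pooled left classes (dummy 0) from the pooled right
#' classes (dummy 1). The decision threshold is the midpoint of the two
#' training-group mean fitted predictions; at prediction time a sample goes
#' left when its prediction is below the threshold, right otherwise.
#'
#' @slot splitId integer; 1 is the top (highest) split.
#' @slot leftClasses,rightClasses disjoint class-name sets.
#' @slot model the fitted [OplsModel-class].
#' @slot cv the [CvResult-class] that selected the component count.
#' @slot threshold decision cut on the predicted dummy response.
#' @export
setClass("HdaNode", representation(
  splitId = "integer",
  leftClasses = "character",
  rightClasses = "character",
  model = "OplsModel",
  cv = "CvResult",
  threshold = "numeric"
))

#' Fitted OPLS-HDA model
#'
#' The class dendrogram plus one fitted [HdaNode-class] per internal
#' dendrogram node (N - 1 of them for N classes) and the full build
#' configuration. Classification proceeds top-down from split 1.
#'
#' @slot dendrogram the [Dendrogram-class] defining the tree topology.
#' @slot nodes list of [HdaNode-class], ordered by splitId.
#' @slot classNames the full class set.
#' @slot config list of build parameters and seeds (see [hdaControl()]).
#' @export
setClass("HdaModel", representation(
  dendrogram = "Dendrogram",
  nodes = "list",
  classNames = "character",
  config = "list"
))

setValidity("HdaModel", function(object) {
  msgs <- character()
  if (length(object@nodes) != length(object@classNames) - 1L)
    msgs <- c(msgs, "an HDA model needs exactly N - 1 split nodes")
  if (length(msgs)) msgs else TRUE
})
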