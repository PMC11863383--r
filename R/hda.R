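#' Build an OPLS-HDA model
#'
#' The full data-driven pipeline: (1) fit all N(N-1)/2 one-vs-one OPLS-DA
#' models and assemble the Cohen's d class-distance matrix; (2) cluster the
#' classes agglomeratively into a dendrogram; (3) populate every internal
#' dendrogram node with a two-class OPLS-DA model that discriminates the
#' pooled left classes (dummy 0) from the pooled right classes (dummy 1),
#' selecting each node's orthogonal component count by cross-validation on
#' the node's own samples. The dendrogram plus the fitted split models
#' constitute the decision tree.
#'
#' Splits are numbered 1..N-1 by decreasing dendrogram height, split 1 being
#' the top split. Each node's decision threshold is the midpoint of the two
#' training-group mean fitted predictions (not a fixed 0.5, which is only
#' principled for balanced groups).
#'
#' @param data an [MvDataset-class] with >= 2 classes, each with >= 2 samples.
#' @param control build parameters from [hdaControl()].
#' @param verbose log one line per pairwise model and per split.
#' @return an [HdaModel-class].
#' @export
buildHda <- function(data, control = hdaControl(), verbose = FALSE) {
  dmat <- pairwiseDistanceMatrix(data, control, verbose = verbose)
  dend <- agglomerate(dmat, control$linkage)
  N <- length(dend@classNames)
  internal <- dend@nodes[seq.int(N + 1, 2 * N - 1)]
  ord <- order(vapply(internal, `[[`, 0, "height"), decreasing = TRUE)
  nodes <- vector("list", N - 1)
  for (s in seq_along(ord)) {
    node <- internal[[ord[s]]]
    kids <- c(node$left, node$right)
    kids <- kids[order(vapply(kids, function(k) dend@nodes[[k]]$members[1], ""))]
    leftClasses <- dend@nodes[[kids[1]]]$members
    rightClasses <- dend@nodes[[kids[2]]]$members
    sub <- subsetClasses(data, c(leftClasses, rightClasses))
    nLeft <- sum(sub@labels %in% leftClasses)
    nRight <- sum(sub@labels %in% rightClasses)
    if (nLeft < 2 || nRight < 2)
      stopf("split %d ({%s} vs {%s}) has a side with < 2 samples", s,
            paste(leftClasses, collapse = ","), paste(rightClasses, collapse = ","))
    dummy <- encodeDummy(sub@labels, leftClasses, rightClasses)
    cv <- selectNOrth(sub, dummy, k = control$cvFolds, seed = control$cvSeed,
                      maxOrth = control$maxOrth,
                      q2GainThreshold = control$q2GainThreshold,
                      mode = control$scaling)
    model <- fitOplsDa(sub@values, sub@labels, leftClasses, rightClasses,
                       nOrth = cv@chosenA, mode = control$scaling)
    fitted <- model@q * model@tPred + model@yMean
    threshold <- (mean(fitted[dummy@y == 0]) + mean(fitted[dummy@y == 1])) / 2
    nodes[[s]] <- new("HdaNode", splitId = as.integer(s),
                      leftClasses = leftClasses, rightClasses = rightClasses,
                      model = model, cv = cv, threshold = threshold)
    if (verbose)
      message(sprintf("split %d: {%s} vs {%s}, A = %d, Q2 = %.3f", s,
                      paste(leftClasses, collapse = ","),
                      paste(rightClasses, collapse = ","),
                      cv@chosenA, cvQ2(cv)))
  }
  new("HdaModel", dendrogram = dend, nodes = nodes,
      classNames = dend@classNames, config = control)
}

# split node whose class sets match the given child sets, or NULL
findSplit <- function(model, leftClasses, rightClasses) {
  for (node in model@nodes)
    if (setequal(node@leftClasses, leftClasses) &&
        setequal(node@rightClasses, rightClasses)) return(node)
  NULL
}

#' @describeIn buildHda split nodes, ordered by splitId (1 = top)
#' @param model an [HdaModel-class].
#' @export
hdaNodes <- function(model) model@nodes

#' Classify samples with an OPLS-HDA model
#'
#' Each sample starts at the top split and moves down the tree: at every
#' node the node's OPLS-DA model predicts the dummy response, and the sample
#' goes to the left (dummy 0) side when the prediction is below the node
#' threshold, to the right side otherwise (ties route right). It ends at a
#' leaf, whose class is returned. Path records expose every decision for
#' auditing.
#'
#' @param object an [HdaModel-class].
#' @param newdata raw numeric matrix with the training column count.
#' @return list with `labels` (character) and `paths` (list, per sample, of
#'   data.frames with splitId, yHat, direction).
#' @export
setMethod("predict", "HdaModel", function(object, newdata) {
  X <- as.matrix(newdata)
  p <- length(object@nodes[[1]]@model@wPred)
  if (ncol(X) != p) stopf("newdata has %d columns; model expects %d", ncol(X), p)
  n <- nrow(X)
  labels <- character(n)
  paths <- replicate(n, list(splitId = integer(), yHat = numeric(),
                             direction = character()), simplify = FALSE)
  route <- function(idx, classes) {
    if (length(classes) == 1) { labels[idx] <<- classes; return(invisible()) }
    # locate the split that partitions exactly this class set
    node <- NULL
    for (cand in object@nodes)
      if (setequal(c(cand@leftClasses, cand@rightClasses), classes)) { node <- cand; break }
    if (is.null(node)) stopf("no split found for class set {%s}",
                             paste(classes, collapse = ","))
    prd <- predict(node@model, X[idx, , drop = FALSE])
    goLeft <- prd$yHat < node@threshold
    for (ii in seq_along(idx)) {
      i <- idx[ii]
      paths[[i]]$splitId <<- c(paths[[i]]$splitId, node@splitId)
      paths[[i]]$yHat <<- c(paths[[i]]$yHat, prd$yHat[ii])
      paths[[i]]$direction <<- c(paths[[i]]$direction,
                                 if (goLeft[ii]) "left" else "right")
    }
    if (any(goLeft)) route(idx[goLeft], node@leftClasses)
    if (any(!goLeft)) route(idx[!goLeft], node@rightClasses)
  }
  route(seq_len(n), sort(object@classNames))
  paths <- lapply(paths, function(pp)
    data.frame(splitId = pp$splitId, yHat = pp$yHat, direction = pp$direction,
               stringsAsFactors = FALSE))
  list(labels = labels, paths = paths)
})

#' Confusion matrix and accuracy
#'
#' Rows are actual classes, columns predicted classes; accuracy is the trace
#' divided by the total and is attached as attribute `"accuracy"`.
#'
#' @param trueLabels actual class labels.
#' @param predicted predicted class labels (same length).
#' @param classOrder row/column order; defaults to sorted union.
#' @return integer matrix of counts with attribute `accuracy`.
#' @export
confusionMatrix <- function(trueLabels, predicted, classOrder = NULL) {
  if (length(trueLabels) != length(predicted))
    stopf("label vectors differ in length")
  if (is.null(classOrder)) classOrder <- sort(unique(c(trueLabels, predicted)))
  unknown <- setdiff(unique(c(trueLabels, predicted)), classOrder)
  if (length(unknown))
    stopf("labels outside classOrder: %s", paste(unknown, collapse = ", "))
  m <- table(factor(trueLabels, levels = classOrder),
             factor(predicted, levels = classOrder))
  m <- unclass(as.matrix(m))
  names(dimnames(m)) <- c("actual", "predicted")
  attr(m, "accuracy") <- sum(diag(m)) / sum(m)
  m
}

#' One-vs-rest OPLS-DA baseline classifier
#'
#' Fits one two-class OPLS-DA model per class (that class against the pooled
#' rest) and classifies by the largest predicted dummy response. This is the
#' conventional multiclass reduction that OPLS-HDA improves upon: each
#' one-vs-rest model is anchored on the global data centre, which misplaces
#' boundaries when classes lie along a common direction at different scales.
#'
#' @param data an [MvDataset-class].
#' @param control build parameters from [hdaControl()].
#' @return list of per-class models (class "ovrOpls").
#' @export
oneVsRestOpls <- function(data, control = hdaControl()) {
  cls <- classNames(data)
  models <- lapply(cls, function(cl) {
    rest <- setdiff(cls, cl)
    dummy <- encodeDummy(data@labels, rest, cl)
    cv <- selectNOrth(data, dummy, k = control$cvFolds, seed = control$cvSeed,
                      maxOrth = control$maxOrth,
                      q2GainThreshold = control$q2GainThreshold,
                      mode = control$scaling)
    fitOplsDa(data@values, data@labels, rest, cl,
              nOrth = cv@chosenA, mode = control$scaling)
  })
  names(models) <- cls
  structure(list(models = models, classNames = cls), class = "ovrOpls")
}

#' @describeIn oneVsRestOpls classify by argmax over the per-class models
#' @param fit an object from [oneVsRestOpls()].
#' @param newdata raw numeric matrix.
#' @export
predictOneVsRest <- function(fit, newdata) {
  scores <- vapply(fit$models, function(m) predict(m, newdata)$yHat,
                   numeric(nrow(newdata)))
  scores <- matrix(scores, nrow = nrow(newdata))
  fit$classNames[max.col(scores, ties.method = "first")]
}

setMethod("show", "HdaModel", function(object) {
  cat("HdaModel:", length(object@classNames), "classes,",
      length(object@nodes), "splits, linkage =", object@dendrogram@linkage, "\n")
  for (node in object@nodes)
    cat(sprintf("  split %d: {%s} | {%s}  (A = %d, Q2 = %.3f)\n",
                node@splitId, paste(node@leftClasses, collapse = ","),
                paste(node@rightClasses, collapse = ","),
                node@model@nOrth, cvQ2(node@cv)))
})

setMethod("show", "HdaNode", function(object) {
  cat(sprintf("HdaNode split %d: {%s} vs {%s}, threshold %.4f\n",
              object@splitId, paste(object@leftClasses, collapse = ","),
              paste(object@rightClasses, collapse = ","), object@threshold))
})
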