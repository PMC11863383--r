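# JSON (de)serialization. Numbers are written with 17 significant digits,
# which round-trips IEEE doubles exactly, so a reloaded model reproduces
# predictions bitwise.

oplsToList <- function(m) {
  list(wPred = m@wPred, pPred = m@pPred, tPred = m@tPred, q = m@q,
       WOrth = m@WOrth, POrth = m@POrth, TOrth = m@TOrth, nOrth = m@nOrth,
       yMean = m@yMean,
       preprocessor = list(columnMeans = m@preprocessor@columnMeans,
                           columnScales = m@preprocessor@columnScales,
                           mode = m@preprocessor@mode),
       dummy = list(y = m@dummy@y, class0 = m@dummy@class0,
                    class1 = m@dummy@class1),
       residualX = m@residualX, residualY = m@residualY)
}

asMat <- function(x, nrowHint = NULL) {
  m <- if (is.list(x)) do.call(rbind, lapply(x, unlist)) else as.matrix(x)
  if (length(m) == 0) m <- matrix(0, if (is.null(nrowHint)) 0 else nrowHint, 0)
  storage.mode(m) <- "double"
  m
}

listToOpls <- function(l) {
  p <- length(l$wPred); n <- length(l$tPred)
  new("OplsModel", wPred = as.numeric(l$wPred), pPred = as.numeric(l$pPred),
      tPred = as.numeric(l$tPred), q = as.numeric(l$q),
      WOrth = asMat(l$WOrth, p), POrth = asMat(l$POrth, p),
      TOrth = asMat(l$TOrth, n), nOrth = as.integer(l$nOrth),
      preprocessor = new("Preprocessor",
                         columnMeans = as.numeric(l$preprocessor$columnMeans),
                         columnScales = as.numeric(l$preprocessor$columnScales),
                         mode = l$preprocessor$mode),
      dummy = new("DummyResponse", y = as.numeric(l$dummy$y),
                  class0 = as.character(unlist(l$dummy$class0)),
                  class1 = as.character(unlist(l$dummy$class1))),
      yMean = as.numeric(l$yMean),
      residualX = asMat(l$residualX, n), residualY = as.numeric(l$residualY))
}

cvToList <- function(cv) {
  list(yCv = cv@yCv, tCv = cv@tCv, tOrthCv = cv@tOrthCv,
       pressByA = as.list(cv@pressByA), q2ByA = as.list(cv@q2ByA),
       chosenA = cv@chosenA, foldAssignment = cv@foldAssignment)
}

listToCv <- function(l) {
  new("CvResult", yCv = as.numeric(l$yCv), tCv = as.numeric(l$tCv),
      tOrthCv = as.numeric(l$tOrthCv),
      pressByA = unlist(l$pressByA), q2ByA = unlist(l$q2ByA),
      chosenA = as.integer(l$chosenA),
      foldAssignment = as.integer(l$foldAssignment))
}

#' Save / load a fitted OPLS model as JSON
#'
#' All vectors and matrices are stored as nested arrays at full double
#' precision; reloading reproduces predictions bitwise.
#'
#' @param model an [OplsModel-class].
#' @param path output JSON path.
#' @export
saveOplsModel <- function(model, path) {
  json <- jsonlite::toJSON(oplsToList(model), digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @describeIn saveOplsModel load the model back
#' @export
readOplsModel <- function(path) {
  listToOpls(jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyMatrix = TRUE))
}

#' Save / load a fitted OPLS-HDA model as JSON
#'
#' Serializes the dendrogram, every split node (class sets, threshold,
#' OPLS model, cross-validation record) and the build configuration.
#'
#' @param model an [HdaModel-class].
#' @param path output JSON path.
#' @export
saveHdaModel <- function(model, path) {
  dend <- model@dendrogram
  obj <- list(
    format = "oplshda-model", version = 1L,
    config = model@config,
    classNames = model@classNames,
    dendrogram = list(classNames = dend@classNames, merge = dend@merge,
                      heights = dend@heights, linkage = dend@linkage),
    nodes = lapply(model@nodes, function(nd)
      list(splitId = nd@splitId, leftClasses = nd@leftClasses,
           rightClasses = nd@rightClasses, threshold = nd@threshold,
           model = oplsToList(nd@model), cv = cvToList(nd@cv))))
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @describeIn saveHdaModel load the model back
#' @export
readHdaModel <- function(path) {
  l <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                          simplifyMatrix = TRUE, simplifyDataFrame = FALSE)
  dm <- asMat(l$dendrogram$merge)
  storage.mode(dm) <- "integer"
  cls <- as.character(unlist(l$dendrogram$classNames))
  N <- length(cls)
  nodes <- vector("list", 2 * N - 1)
  for (i in seq_len(N))
    nodes[[i]] <- list(id = i, left = NA_integer_, right = NA_integer_,
                       height = 0, members = cls[i])
  toId <- function(code) if (code < 0) -code else N + code
  heights <- as.numeric(unlist(l$dendrogram$heights))
  for (m in seq_len(N - 1)) {
    li <- toId(dm[m, 1]); ri <- toId(dm[m, 2])
    nodes[[N + m]] <- list(id = N + m, left = li, right = ri,
                           height = heights[m],
                           members = sort(c(nodes[[li]]$members, nodes[[ri]]$members)))
  }
  dend <- new("Dendrogram", classNames = cls, merge = dm, heights = heights,
              linkage = l$dendrogram$linkage, nodes = nodes)
  hnodes <- lapply(l$nodes, function(nd)
    new("HdaNode", splitId = as.integer(nd$splitId),
        leftClasses = as.character(unlist(nd$leftClasses)),
        rightClasses = as.character(unlist(nd$rightClasses)),
        model = listToOpls(nd$model), cv = listToCv(nd$cv),
        threshold = as.numeric(nd$threshold)))
  cfg <- l$config
  cfg$cvFolds <- as.integer(cfg$cvFolds)
  cfg$cvSeed <- as.integer(cfg$cvSeed)
  cfg$maxOrth <- as.integer(cfg$maxOrth)
  new("HdaModel", dendrogram = dend, nodes = hnodes,
      classNames = as.character(unlist(l$classNames)), config = cfg)
}
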