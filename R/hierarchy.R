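#' Agglomerative clustering of a class-distance matrix
#'
#' Standard bottom-up hierarchical clustering: every class starts as its own
#' cluster and the two clusters at minimal inter-cluster distance under the
#' chosen linkage are merged successively (Lance-Williams updates, via
#' [stats::hclust()]). Heights stay on the Cohen's d scale — no rescaling —
#' so the dendrogram's y-axis reads directly as class separability. `"ward"`
#' maps to the squared-distance Ward form (`ward.D2`); it is offered but
#' average linkage is the default since the Cohen's d matrix is not a
#' Euclidean distance.
#'
#' @param dist a [ClassDistanceMatrix-class] (or plain symmetric matrix with
#'   dimnames).
#' @param linkage one of "average", "single", "complete", "ward".
#' @return a [Dendrogram-class].
#' @export
agglomerate <- function(dist, linkage = c("average", "single", "complete", "ward")) {
  linkage <- match.arg(linkage)
  if (is(dist, "ClassDistanceMatrix")) {
    d <- dist@d; cls <- dist@classNames
  } else {
    d <- as.matrix(dist)
    cls <- rownames(d)
    if (is.null(cls)) cls <- paste0("c", seq_len(nrow(d)))
  }
  if (nrow(d) < 2) stopf("need >= 2 classes to cluster")
  method <- c(average = "average", single = "single",
              complete = "complete", ward = "ward.D2")[[linkage]]
  hc <- hclust(as.dist(d), method = method)
  N <- length(cls)
  nodes <- vector("list", 2 * N - 1)
  for (i in seq_len(N))
    nodes[[i]] <- list(id = i, left = NA_integer_, right = NA_integer_,
                       height = 0, members = cls[i])
  toId <- function(code) if (code < 0) -code else N + code
  for (m in seq_len(N - 1)) {
    l <- toId(hc$merge[m, 1]); r <- toId(hc$merge[m, 2])
    nodes[[N + m]] <- list(id = N + m, left = l, right = r,
                           height = hc$height[m],
                           members = sort(c(nodes[[l]]$members, nodes[[r]]$members)))
  }
  new("Dendrogram", classNames = cls, merge = hc$merge, heights = hc$height,
      linkage = linkage, nodes = nodes)
}

#' @describeIn agglomerate node list (leaves first, then merges in order)
#' @param dend a [Dendrogram-class].
#' @export
dendNodes <- function(dend) dend@nodes

#' @describeIn agglomerate id of the root node
#' @export
dendRoot <- function(dend) length(dend@nodes)

#' @describeIn agglomerate member-class sets of all internal nodes
#' @export
dendClades <- function(dend) {
  N <- length(dend@classNames)
  lapply(dend@nodes[seq.int(N + 1, 2 * N - 1)], `[[`, "members")
}

#' Newick serialization of a class dendrogram
#'
#' Branch lengths are parent height minus child height (leaves sit at height
#' 0, so the tree is ultrametric on the Cohen's d scale). Children are
#' emitted in deterministic order: the child whose lexicographically smallest
#' member class comes first. Names containing Newick-reserved characters are
#' single-quoted.
#'
#' @param dend a [Dendrogram-class].
#' @return a Newick string terminated by ";".
#' @export
toNewick <- function(dend) {
  quoteName <- function(x) {
    if (grepl("[][ ,:;()']", x))
      paste0("'", gsub("'", "''", x), "'") else x
  }
  rec <- function(id, parentHeight) {
    node <- dend@nodes[[id]]
    bl <- parentHeight - node$height
    if (is.na(node$left))
      return(sprintf("%s:%.10g", quoteName(node$members), bl))
    kids <- c(node$left, node$right)
    kids <- kids[order(vapply(kids, function(k) dend@nodes[[k]]$members[1], ""))]
    inner <- paste(vapply(kids, rec, "", parentHeight = node$height), collapse = ",")
    if (id == dendRoot(dend)) sprintf("(%s);", inner)
    else sprintf("(%s):%.10g", inner, bl)
  }
  rec(dendRoot(dend), dend@nodes[[dendRoot(dend)]]$height)
}

#' Write dendrogram artifacts
#'
#' @param dend a [Dendrogram-class].
#' @param path output file path.
#' @export
writeNewick <- function(dend, path) {
  writeLines(toNewick(dend), path)
  invisible(path)
}

#' @describeIn writeNewick 4-column linkage/merge table (left id, right id,
#'   height, cluster size), node ids as in `dendNodes`.
#' @export
linkageTable <- function(dend) {
  N <- length(dend@classNames)
  do.call(rbind, lapply(seq_len(N - 1), function(m) {
    node <- dend@nodes[[N + m]]
    data.frame(left = node$left, right = node$right, height = node$height,
               size = length(node$members))
  }))
}

setMethod("show", "Dendrogram", function(object) {
  cat("Dendrogram over", length(object@classNames), "classes, linkage =",
      object@linkage, "\n ", toNewick(object), "\n")
})
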