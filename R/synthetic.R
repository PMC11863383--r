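#' Three collinear Gaussian classes in two dimensions
#'
#' Seeded generator of the geometry that defeats one-vs-rest OPLS-DA: three
#' classes whose means lie exactly on one line (petal-style measurements),
#' with one compact outlying class and two adjacent classes further along
#' the same direction. Because every one-vs-rest boundary passes near the
#' common data centre, the middle class is squeezed; a hierarchical model
#' places both boundaries where the gaps actually are.
#'
#' Class means: `setosa` (1.46, 0.25), `virginica` (5.55, 2.03), and
#' `versicolor` exactly 65% of the way between them; per-class standard
#' deviations echo the classic petal measurements.
#'
#' @param seed integer RNG seed.
#' @param nPerClass samples per class (>= 4).
#' @return an [MvDataset-class] with `3 * nPerClass` samples and 2 variables
#'   (`petal_length`, `petal_width`).
#' @export
makeIrisLike <- function(seed = 0L, nPerClass = 50L) {
  if (nPerClass < 4) stopf("nPerClass must be >= 4")
  mA <- c(1.46, 0.25)
  mC <- c(5.55, 2.03)
  mB <- mA + 0.65 * (mC - mA)               # exactly collinear
  sds <- list(setosa = c(0.17, 0.11), versicolor = c(0.47, 0.20),
              virginica = c(0.55, 0.27))
  means <- list(setosa = mA, versicolor = mB, virginica = mC)
  withSeed(seed, {
    rows <- lapply(names(means), function(cl) {
      cbind(rnorm(nPerClass, means[[cl]][1], sds[[cl]][1]),
            rnorm(nPerClass, means[[cl]][2], sds[[cl]][2]))
    })
  })
  values <- do.call(rbind, rows)
  colnames(values) <- c("petal_length", "petal_width")
  mvDataset(values, rep(names(means), each = nPerClass))
}

#' Default two-level class hierarchy: 4 groups x 3 subclasses
#'
#' Mirrors a two-factor class structure (e.g. species crossed with
#' processing state) where one factor dominates: 12 classes arranged as four
#' groups of three. The generative clades are the four groups; recovering
#' them means all within-group merges happen before any cross-group merge.
#' @return nested list of class names usable as `tree` in
#'   [makeHierarchical()].
#' @export
defaultHierarchyTree <- function() {
  lapply(c("A", "B", "C", "D"), function(g) as.list(paste0(g, 1:3)))
}

#' Hierarchically structured Gaussian multiclass data
#'
#' Class mean vectors are generated by walking a nested grouping tree: at
#' depth `l` (root = 0) each child's mean is its parent's mean plus an
#' offset of fixed magnitude `betweenScale * levelDecay^l` along a seeded
#' random direction. Directions are drawn mutually orthogonal (each new
#' direction is Gram-Schmidt orthogonalized against every offset generated
#' before it), so realized separations equal their nominal values exactly:
#' two classes whose paths diverge at a set of edges are separated by the
#' root sum of squares of those edges' magnitudes. Sibling subclasses under
#' the default settings are `sqrt(2) * betweenScale * levelDecay` apart and
#' classes in different top-level groups at least `sqrt(2) * betweenScale` —
#' the declared between/within separation holds deterministically, not just
#' in expectation. This requires `nVariables >=` the number of tree edges.
#'
#' Samples are the class mean plus isotropic Gaussian noise of SD
#' `withinSd`; optional pure-noise variables (standard normal, independent
#' of class) are appended to exercise scaling and orthogonal-component
#' selection.
#'
#' @param tree nested list of class names (default [defaultHierarchyTree()]).
#' @param classSizes samples per class — a single number or a named vector
#'   (default 40; every class needs >= 4).
#' @param nVariables informative dimensions (default 16, the edge count of
#'   the default tree).
#' @param betweenScale offset magnitude at the root level (default 4).
#' @param withinSd within-class SD (default 1).
#' @param nNoiseVariables appended noise variables (default 5).
#' @param levelDecay multiplicative offset shrink per level (default 0.5).
#' @param seed integer RNG seed.
#' @return list with `data` (an [MvDataset-class]), `tree` (the generative
#'   topology), `means` (class-mean matrix), and `clades` (member sets of
#'   every internal generative node).
#' @export
makeHierarchical <- function(tree = defaultHierarchyTree(), classSizes = 40L,
                             nVariables = 16L, betweenScale = 4,
                             withinSd = 1, nNoiseVariables = 5L,
                             levelDecay = 0.5, seed = 0L) {
  if (betweenScale <= 0 || withinSd <= 0)
    stopf("betweenScale and withinSd must be > 0")
  leaves <- unlist(tree)
  if (anyDuplicated(leaves)) stopf("duplicate class names in tree")
  countEdges <- function(node)
    if (!is.list(node)) 0L else length(node) + sum(vapply(node, countEdges, 0L))
  nEdges <- countEdges(tree)
  if (nVariables < nEdges)
    stopf("nVariables (%d) must be >= the tree's edge count (%d) for orthogonal offsets",
          nVariables, nEdges)
  sizes <- if (length(classSizes) == 1)
    stats::setNames(rep(as.integer(classSizes), length(leaves)), leaves)
  else classSizes[leaves]
  if (any(sizes < 4)) stopf("every class size must be >= 4")

  means <- matrix(0, length(leaves), nVariables, dimnames = list(leaves, NULL))
  clades <- list()
  usedDirs <- matrix(0, nVariables, 0)
  withSeed(seed, {
    newDir <- function() {
      # random direction orthogonal to every offset drawn so far
      repeat {
        v <- rnorm(nVariables)
        if (ncol(usedDirs)) v <- v - usedDirs %*% crossprod(usedDirs, v)
        nv <- sqrt(sum(v^2))
        if (nv > 1e-8) break
      }
      v <- as.numeric(v) / nv
      usedDirs <<- cbind(usedDirs, v)
      v
    }
    walk <- function(node, mean, depth) {
      if (!is.list(node)) { means[node, ] <<- mean; return(node) }
      members <- lapply(node, function(child)
        walk(child, mean + betweenScale * levelDecay^depth * newDir(), depth + 1))
      members <- sort(unlist(members))
      if (depth > 0) clades[[length(clades) + 1]] <<- members
      members
    }
    walk(tree, rep(0, nVariables), 0)
    X <- do.call(rbind, lapply(leaves, function(cl) {
      matrix(rnorm(sizes[cl] * nVariables, 0, withinSd), sizes[cl], nVariables) +
        matrix(means[cl, ], sizes[cl], nVariables, byrow = TRUE)
    }))
    if (nNoiseVariables > 0)
      X <- cbind(X, matrix(rnorm(nrow(X) * nNoiseVariables), nrow(X)))
  })
  colnames(X) <- c(paste0("signal_", seq_len(nVariables)),
                   if (nNoiseVariables > 0) paste0("noise_", seq_len(nNoiseVariables)))
  labels <- rep(leaves, times = sizes)
  clades <- unique(clades[order(vapply(clades, length, 0L))])
  list(data = mvDataset(X, labels), tree = tree, means = means, clades = clades)
}
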