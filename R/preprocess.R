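#' Fit a column centering/scaling preprocessor
#'
#' Learns per-variable means and scales on training data only. Scales:
#' `"center"` all 1; `"uv"` the per-column sample standard deviation;
#' `"pareto"` its square root; `"none"` no centring or scaling. Scales are
#' floored at 1e-12, so a constant column transforms to (numerically) zero
#' instead of producing NaN — columns are never dropped, keeping variable
#' names in sync.
#'
#' @param X numeric matrix or [MvDataset-class] (training samples only).
#' @param mode one of "center", "uv", "pareto", "none".
#' @return a [Preprocessor-class].
#' @export
fitPreprocessor <- function(X, mode = c("uv", "center", "pareto", "none")) {
  mode <- match.arg(mode)
  if (is(X, "MvDataset")) X <- X@values
  if (nrow(X) < 2) stopf("fitting a preprocessor needs >= 2 samples")
  m <- colMeans(X)
  s <- rep(1, ncol(X))
  if (mode %in% c("uv", "pareto")) {
    sds <- apply(X, 2, sd)
    s <- if (mode == "uv") sds else sqrt(sds)
  }
  if (mode == "none") m <- rep(0, ncol(X))
  s <- pmax(s, EPS_SCALE)
  new("Preprocessor", columnMeans = unname(m), columnScales = unname(s), mode = mode)
}

#' Apply a fitted preprocessor
#' @param pre a [Preprocessor-class].
#' @param X numeric matrix with the training column count.
#' @return transformed matrix `(X - means) / scales`.
#' @export
applyPreprocessor <- function(pre, X) {
  if (ncol(X) != length(pre@columnMeans))
    stopf("column count %d does not match preprocessor (%d variables)",
          ncol(X), length(pre@columnMeans))
  sweep(sweep(X, 2, pre@columnMeans, "-"), 2, pre@columnScales, "/")
}

#' Invert a fitted preprocessor
#' @param pre a [Preprocessor-class].
#' @param X transformed matrix.
#' @return matrix on the original scale, `X * scales + means`.
#' @export
invertPreprocessor <- function(pre, X) {
  sweep(sweep(X, 2, pre@columnScales, "*"), 2, pre@columnMeans, "+")
}

#' Encode class membership as a 0/1 dummy response
#'
#' Samples whose label is in `class0` map to 0, those in `class1` to 1.
#' For a balanced two-class set `mean(y)` is exactly 0.5; in general it is
#' the class-1 fraction.
#'
#' @param labels character class labels.
#' @param class0 class names mapped to 0.
#' @param class1 class names mapped to 1.
#' @return a [DummyResponse-class].
#' @export
encodeDummy <- function(labels, class0, class1) {
  if (length(intersect(class0, class1)))
    stopf("class0 and class1 overlap: %s",
          paste(intersect(class0, class1), collapse = ", "))
  outside <- setdiff(unique(labels), c(class0, class1))
  if (length(outside))
    stopf("labels outside both groups: %s", paste(outside, collapse = ", "))
  new("DummyResponse", y = as.numeric(labels %in% class1),
      class0 = sort(unique(as.character(class0))),
      class1 = sort(unique(as.character(class1))))
}

setMethod("show", "Preprocessor", function(object) {
  cat("Preprocessor (mode =", object@mode, "),",
      length(object@columnMeans), "variables\n")
})
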