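#' Volcano statistics for a two-group comparison
#'
#' Per variable, on the original (unscaled) data: the fold change
#' `mean(group1) / mean(group0)` reported as log2, and a two-sided Welch
#' t-test p-value. A variable is significant when `p < alpha` AND the fold
#' difference exceeds `foldThreshold` in either direction (the default gate
#' is P < 0.01 with a > 2-fold difference). Variables with a nonpositive
#' group mean get `NA` fold change, are flagged `excluded`, and are never
#' significant. A Benjamini-Hochberg adjusted p-value column is included for
#' users who want multiplicity control; the significance gate itself uses
#' raw p-values.
#'
#' @param data an [MvDataset-class].
#' @param group0,group1 class-name sets ("left" and "right" of a split).
#' @param alpha significance level (default 0.01).
#' @param foldThreshold fold-change gate on the ratio scale (default 2).
#' @return data.frame with variable, log2FoldChange, pValue, pAdjBH,
#'   significant, excluded, direction ("high in right" when group1 mean is
#'   larger).
#' @export
volcanoStats <- function(data, group0, group1, alpha = 0.01, foldThreshold = 2) {
  i0 <- data@labels %in% group0
  i1 <- data@labels %in% group1
  if (sum(i0) < 2 || sum(i1) < 2)
    stopf("both groups need >= 2 samples (got %d and %d)", sum(i0), sum(i1))
  X0 <- data@values[i0, , drop = FALSE]
  X1 <- data@values[i1, , drop = FALSE]
  m0 <- colMeans(X0); m1 <- colMeans(X1)
  p <- vapply(seq_len(ncol(X0)), function(j) {
    if (sd(X0[, j]) == 0 && sd(X1[, j]) == 0)
      return(if (m0[j] == m1[j]) 1 else 0)
    t.test(X1[, j], X0[, j], var.equal = FALSE)$p.value
  }, 0)
  excluded <- m0 <= 0 | m1 <= 0
  l2fc <- rep(NA_real_, length(m0))
  l2fc[!excluded] <- log2(m1[!excluded] / m0[!excluded])
  sig <- !excluded & p < alpha & abs(l2fc) > log2(foldThreshold)
  data.frame(variable = data@variableNames,
             log2FoldChange = unname(l2fc),
             pValue = unname(p),
             pAdjBH = unname(p.adjust(p, "BH")),
             significant = unname(sig),
             excluded = unname(excluded),
             direction = ifelse(is.na(l2fc), NA_character_,
                                ifelse(l2fc >= 0, "high in right", "high in left")),
             stringsAsFactors = FALSE)
}

#' Cross-validated score table with Hotelling's T2 ellipses for a split
#'
#' Per-sample cross-validated predictive score (and first orthogonal score
#' when the node kept at least one orthogonal component), plus a 95%
#' Hotelling's T2 confidence region per class computed from the class's
#' score covariance: semi-axes `sqrt(lambda_j * p (n-1) / (n-p) * F_{0.95}(p, n-p))`
#' along the covariance eigenvectors. With no orthogonal score the region
#' degenerates to the 1-D interval (which reduces to a t-interval).
#'
#' @param node an [HdaNode-class] (from [buildHda()]).
#' @param labels class labels of the node's training samples; defaults to
#'   reconstructing group membership from the dummy encoding.
#' @param confidence confidence level, default 0.95.
#' @return list with `scores` (data.frame: sampleIndex, group, tCv, tOrthCv)
#'   and `ellipses` (data.frame per class-group: center/semi-axis/angle
#'   parameters, or interval bounds in the 1-D case).
#' @export
cvScoreTable <- function(node, labels = NULL, confidence = 0.95) {
  cv <- node@cv
  y <- node@model@dummy@y
  group <- ifelse(y == 0, paste(node@leftClasses, collapse = "+"),
                  paste(node@rightClasses, collapse = "+"))
  has2d <- cv@chosenA >= 1 && !all(is.na(cv@tOrthCv))
  scores <- data.frame(sampleIndex = seq_along(cv@yCv), group = group,
                       tCv = cv@tCv,
                       tOrthCv = if (has2d) cv@tOrthCv else NA_real_,
                       stringsAsFactors = FALSE)
  ellipses <- do.call(rbind, lapply(unique(group), function(g) {
    idx <- group == g
    n <- sum(idx)
    if (has2d) {
      S <- cov(cbind(cv@tCv[idx], cv@tOrthCv[idx]))
      pdim <- 2
      crit <- pdim * (n - 1) / (n - pdim) * qf(confidence, pdim, n - pdim)
      eig <- eigen(S, symmetric = TRUE)
      data.frame(group = g, centerT = mean(cv@tCv[idx]),
                 centerTOrth = mean(cv@tOrthCv[idx]),
                 semiAxis1 = sqrt(max(eig$values[1], 0) * crit),
                 semiAxis2 = sqrt(max(eig$values[2], 0) * crit),
                 angle = atan2(eig$vectors[2, 1], eig$vectors[1, 1]),
                 confidence = confidence, stringsAsFactors = FALSE)
    } else {
      v <- var(cv@tCv[idx])
      crit <- (n - 1) / (n - 1) * qf(confidence, 1, n - 1)
      half <- sqrt(max(v, 0) * crit)
      data.frame(group = g, centerT = mean(cv@tCv[idx]),
                 centerTOrth = NA_real_, semiAxis1 = half, semiAxis2 = NA_real_,
                 angle = 0, confidence = confidence, stringsAsFactors = FALSE)
    }
  }))
  list(scores = scores, ellipses = ellipses)
}
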