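# Independent oracles, deliberately written against the textbook algorithms
# rather than the package's code paths.

# NIPALS PLS1 regression coefficients (X, y already centred).
oraclePlsCoef <- function(X, y, ncomp) {
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  Xd <- X; yd <- y
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)
    w <- w / sqrt(sum(w^2))
    t <- as.numeric(Xd %*% w)
    pl <- as.numeric(crossprod(Xd, t)) / sum(t^2)
    q <- sum(yd * t) / sum(t^2)
    Xd <- Xd - tcrossprod(t, pl)
    yd <- yd - q * t
    W[, a] <- w; P[, a] <- pl; qv[a] <- q
  }
  W %*% solve(crossprod(P, W), qv)
}

# Brute-force O(N^3) agglomerator: recomputes every cluster-cluster distance
# from the original matrix at every step (no Lance-Williams updates).
oracleAgglomerate <- function(d, linkage) {
  stopifnot(linkage %in% c("single", "complete", "average"))
  n <- nrow(d)
  clusters <- as.list(seq_len(n))      # member leaf indices
  active <- seq_along(clusters)
  merges <- list()
  linkFun <- switch(linkage, single = min, complete = max, average = mean)
  while (length(active) > 1) {
    best <- NULL
    for (ii in seq_along(active)) for (jj in seq_len(ii - 1)) {
      a <- active[ii]; b <- active[jj]
      dd <- linkFun(d[clusters[[a]], clusters[[b]], drop = FALSE])
      if (is.null(best) || dd < best$d) best <- list(a = a, b = b, d = dd)
    }
    clusters[[length(clusters) + 1]] <- sort(c(clusters[[best$a]], clusters[[best$b]]))
    merges[[length(merges) + 1]] <- list(members = clusters[[length(clusters)]],
                                         height = best$d)
    active <- c(setdiff(active, c(best$a, best$b)), length(clusters))
  }
  merges
}

randomDistanceMatrix <- function(n) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- runif(n * (n - 1) / 2, 0.1, 10)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- paste0("k", seq_len(n))
  d
}

# clades of a Dendrogram as a set, for topology comparison
cladeSet <- function(dend) {
  lapply(dendClades(dend), sort)
}

hasClade <- function(dend, members) {
  any(vapply(dendClades(dend), function(g) setequal(g, members), TRUE))
}

# seeded stratified split; returns test indices
stratifiedHoldout <- function(labels, fraction, seed) {
  set.seed(seed)
  unlist(lapply(unique(labels), function(cl) {
    idx <- which(labels == cl)
    sample(idx, max(1, round(length(idx) * fraction)))
  }))
}

# small deterministic two-class dataset: one informative variable + noise
twoCloudDataset <- function(n = 10, sep = 6, seed = 1) {
  set.seed(seed)
  x1 <- c(rnorm(n, 0, 0.5), rnorm(n, sep, 0.5))
  noise <- matrix(rnorm(2 * n * 2), 2 * n, 2,
                  dimnames = list(NULL, c("noise1", "noise2")))
  mvDataset(cbind(info = x1, noise), rep(c("a", "b"), each = n))
}
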