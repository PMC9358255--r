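# Independent oracles used to freeze expected values: deliberately naive
# implementations (enumeration, double loops, textbook formulas) that share
# no code with the package internals.

# textbook Pearson correlation, sum formula
pearsonRef <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force discrete convolution of a rectangle with a unit-area
# Gaussian, central truncation, rescaled to max 1
taperRef <- function(len, sigma) {
  half <- max(1, ceiling(6 * sigma))
  g <- exp(-((-half):half)^2 / (2 * sigma^2))
  g <- g / sum(g)
  rect <- rep(1, len)
  full <- rep(0, len + 2 * half)
  for (i in seq_len(len)) {
    for (j in seq_along(g)) {
      full[i + j - 1] <- full[i + j - 1] + rect[i] * g[j]
    }
  }
  w <- full[(half + 1):(half + len)]
  w / max(w)
}

# exhaustive-partition k-means optimum: minimum WCSS over every labeling
bruteKmeansInertia <- function(X, k) {
  X <- as.matrix(X)
  N <- nrow(X)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), N))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < k) next
    wcss <- 0
    for (j in unique(lab)) {
      rows <- X[lab == j, , drop = FALSE]
      mu <- colMeans(rows)
      wcss <- wcss + sum(sweep(rows, 2, mu)^2)
    }
    best <- min(best, wcss)
  }
  best
}

# brute-force nearest-centroid scan with lowest-index tie-breaking
bruteNearest <- function(X, cent) {
  apply(X, 1, function(x) {
    d <- apply(cent, 1, function(c) sum((x - c)^2))
    which(d == min(d))[1]
  })
}

# all permutations of 1..n (small n)
permsRef <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in permsRef(n - 1)) {
    for (pos in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = pos)
    }
  }
  out
}

# exhaustive optimal assignment maximizing summed correlation (K <= 4):
# returns the best total over injections of the smaller index set
bruteAssignmentMax <- function(corM) {
  nA <- nrow(corM)
  nB <- ncol(corM)
  if (nA <= nB) {
    best <- -Inf
    for (p in permsRef(nB)) {
      tot <- sum(corM[cbind(seq_len(nA), p[seq_len(nA)])])
      best <- max(best, tot)
    }
  } else {
    best <- bruteAssignmentMax(t(corM))
  }
  best
}

# Eq-style distance-ratio double loop
distanceRatioRef <- function(X, cent, labels) {
  ratios <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    dc <- sqrt(sum((X[i, ] - cent[labels[i], ])^2))
    dsc <- 0
    for (j in seq_len(nrow(cent))) {
      if (j != labels[i]) dsc <- dsc + sqrt(sum((X[i, ] - cent[j, ])^2))
    }
    ratios[i] <- dsc / max(dc, 1e-12)
  }
  ratios
}

# wrap a bare matrix (windows x features) as a DFNCTensor; ncol must be
# C(C-1)/2 for the implied C. Declared fisherZ so toy values need not lie
# in [-1, 1].
makeTensor <- function(X, id = "s1") {
  F <- ncol(X)
  C <- (1 + sqrt(1 + 8 * F)) / 2
  stopifnot(C == round(C))
  new("DFNCTensor", subjectId = id, data = X,
      windowStarts = seq_len(nrow(X)), featureIndex = featurePairs(C),
      fisherZ = TRUE)
}

# small state model around given centroids (elbow curve is synthetic)
makeModel <- function(cent, tag = "conventional") {
  k <- nrow(cent)
  elbow <- new("ElbowCurve", kValues = seq.int(k, k + 2L),
               criterion = c(3, 2, 1), selectedK = as.integer(k),
               methodTag = "curvature")
  new("StateModel", kOpt = as.integer(k), centroids = cent, elbow = elbow,
      pipelineTag = tag, config = list())
}
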