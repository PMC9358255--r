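## k-means optimizer and elbow model-order criterion shared by both the
## conventional and the two-step pipelines. Written in-package because the
## pipeline contracts (k-means++ seeding, deterministic seeds, empty-cluster
## repair at the farthest point, lowest-index tie-breaking, optional sample
## weights for the size-weighted second step) are part of the method.

## Pairwise dissimilarity between rows of X and rows of Cn.
## euclidean -> squared Euclidean distance; manhattan -> L1 distance.
.pdist <- function(X, Cn, distance = "euclidean") {
  if (distance == "euclidean") {
    D <- matrix(rowSums(X^2), nrow(X), nrow(Cn)) +
      matrix(rowSums(Cn^2), nrow(X), nrow(Cn), byrow = TRUE) -
      2 * tcrossprod(X, Cn)
    pmax(D, 0)
  } else {
    D <- matrix(NA_real_, nrow(X), nrow(Cn))
    for (j in seq_len(nrow(Cn))) {
      D[, j] <- rowSums(abs(sweep(X, 2L, Cn[j, ], check.margin = FALSE)))
    }
    D
  }
}

## k-means++ seeding: first center uniform (weight-proportional when
## weighted), later centers with probability proportional to w * D(x)^2.
.kmeansppInit <- function(X, k, distance, w) {
  N <- nrow(X)
  ids <- integer(k)
  ids[1L] <- sample.int(N, 1L, prob = w)
  if (k > 1L) {
    d2 <- .pdist(X, X[ids[1L], , drop = FALSE], distance)[, 1L]
    for (j in 2L:k) {
      p <- w * if (distance == "euclidean") d2 else d2^2
      if (sum(p) <= 0) {
        ids[j] <- sample.int(N, 1L, prob = w)
      } else {
        ids[j] <- sample.int(N, 1L, prob = p)
      }
      d2 <- pmin(d2, .pdist(X, X[ids[j], , drop = FALSE], distance)[, 1L])
    }
  }
  X[ids, , drop = FALSE]
}

.weightedColMedian <- function(X, w) {
  apply(X, 2L, function(col) {
    o <- order(col)
    cw <- cumsum(w[o]) / sum(w)
    col[o][which(cw >= 0.5)[1L]]
  })
}

## One Lloyd run from a given initialization. Returns labels consistent
## with the returned centroids (final assignment is never stale).
.lloyd <- function(X, centers, maxIter, tol, distance, w) {
  N <- nrow(X)
  k <- nrow(centers)
  prev <- Inf
  trace <- numeric(0)
  lab <- integer(N)
  for (it in seq_len(maxIter)) {
    D <- .pdist(X, centers, distance)
    lab <- max.col(-D, ties.method = "first")
    counts <- tabulate(lab, k)
    repairs <- 0L
    while (any(counts == 0L) && repairs < k) {
      ## empty-cluster repair: re-seed at the point farthest from its centroid
      repairs <- repairs + 1L
      j <- which(counts == 0L)[1L]
      dOwn <- D[cbind(seq_len(N), lab)]
      far <- which.max(dOwn)
      centers[j, ] <- X[far, ]
      D[, j] <- .pdist(X, centers[j, , drop = FALSE], distance)[, 1L]
      lab <- max.col(-D, ties.method = "first")
      counts <- tabulate(lab, k)
    }
    inert <- sum(w * D[cbind(seq_len(N), lab)])
    trace <- c(trace, inert)
    if (inert == 0 ||
        (is.finite(prev) &&
         abs(prev - inert) <= tol * max(inert, .Machine$double.eps))) {
      return(list(centers = centers, labels = lab, inertia = inert,
                  nIter = it, trace = trace))
    }
    prev <- inert
    for (j in seq_len(k)) {
      rows <- lab == j
      centers[j, ] <- if (distance == "euclidean") {
        colSums(X[rows, , drop = FALSE] * w[rows]) / sum(w[rows])
      } else {
        .weightedColMedian(X[rows, , drop = FALSE], w[rows])
      }
    }
  }
  ## maxIter reached: refresh the assignment so labels match the centroids
  D <- .pdist(X, centers, distance)
  lab <- max.col(-D, ties.method = "first")
  inert <- sum(w * D[cbind(seq_len(N), lab)])
  list(centers = centers, labels = lab, inertia = inert,
       nIter = maxIter, trace = c(trace, inert))
}

#' Fit k-means by Lloyd's algorithm with k-means++ restarts
#'
#' Minimizes the within-cluster sum of squared Euclidean distances (the
#' within-cluster sum-of-squares criterion; an L1/city-block variant is
#' available via \code{distance}). Runs \code{nInit} k-means++-seeded
#' restarts and keeps the best by inertia. Deterministic given
#' \code{seed}; assignment ties go to the lowest centroid index; empty
#' clusters are re-seeded at the point farthest from its centroid.
#'
#' @param X N x F numeric matrix of observations.
#' @param k number of clusters (1 <= k <= N).
#' @param seed optional seed (NULL = current RNG stream).
#' @param nInit number of restarts (default 10).
#' @param maxIter Lloyd iteration cap per restart (default 300).
#' @param tol relative inertia-change convergence tolerance (default 1e-4).
#' @param distance "euclidean" (default, squared-Euclidean objective) or
#'   "manhattan" (L1 objective with medians).
#' @param weights optional positive observation weights (used by the
#'   size-weighted second clustering step).
#' @return a \linkS4class{KMeansResult}.
#' @export
kmeansFit <- function(X, k, seed = NULL, nInit = 10L, maxIter = 300L,
                      tol = 1e-4, distance = c("euclidean", "manhattan"),
                      weights = NULL) {
  X <- .assertFiniteMatrix(as.matrix(X), "X")
  k <- .assertCount(k, "k")
  nInit <- .assertCount(nInit, "nInit")
  maxIter <- .assertCount(maxIter, "maxIter")
  distance <- match.arg(distance)
  N <- nrow(X)
  if (N < k) stop(sprintf("cannot fit k = %d clusters to %d observations", k, N),
                  call. = FALSE)
  w <- if (is.null(weights)) rep(1, N) else as.numeric(weights)
  if (length(w) != N || any(!is.finite(w)) || any(w <= 0)) {
    stop("weights must be positive and finite, one per observation", call. = FALSE)
  }
  withSeed(seed, {
    best <- NULL
    for (i in seq_len(nInit)) {
      fit <- .lloyd(X, .kmeansppInit(X, k, distance, w), maxIter, tol, distance, w)
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
    new("KMeansResult", k = k, centroids = best$centers,
        labels = as.integer(best$labels), inertia = best$inertia,
        nIter = as.integer(best$nIter), inertiaTrace = best$trace,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  })
}

#' Elbow of a criterion curve by maximum chord distance
#'
#' Normalizes the (k, criterion) points to the unit square and returns the
#' k whose point lies farthest (perpendicular distance) from the chord
#' joining the first and last points. Ties go to the smallest k. Endpoints
#' have zero chord distance by construction, so a curve must contain at
#' least one interior point (>= 3 values).
#'
#' @param kValues ascending candidate k values (length >= 3).
#' @param criterion criterion value at each k.
#' @return the selected k.
#' @export
chordElbow <- function(kValues, criterion) {
  if (length(kValues) < 3L || length(criterion) != length(kValues)) {
    stop("chord-distance elbow needs >= 3 (k, criterion) points", call. = FALSE)
  }
  x <- (kValues - kValues[1L]) / max(kValues[length(kValues)] - kValues[1L], 1)
  rng <- diff(range(criterion))
  y <- if (rng == 0) rep(0, length(criterion)) else (criterion - min(criterion)) / rng
  ## perpendicular distance to the line through (x1,y1) and (xn,yn)
  dx <- x[length(x)] - x[1L]
  dy <- y[length(y)] - y[1L]
  d <- abs(dy * (x - x[1L]) - dx * (y - y[1L])) / sqrt(dx^2 + dy^2)
  kValues[which.max(d)]
}

#' Select the number of clusters by the elbow criterion
#'
#' Fits \code{\link{kmeansFit}} for every k in \code{[kMin, kMax]} and
#' locates the bend of the criterion curve. Both inertia-based methods
#' anchor the curve at the closed-form k = 1 point (the total sum of
#' squares); the anchor is what makes an elbow at \code{kMin} itself
#' detectable. Selection is restricted to the requested range.
#'
#' Method \code{"curvature"} (default) selects the k with the largest
#' second difference of the anchored inertia curve — the sharpest bend.
#' It is robust on curves with a dominant first drop followed by a
#' secondary one, where the chord construction is nearly indifferent
#' between adjacent k (see the methods vignette).
#'
#' Method \code{"chord_distance"} applies \code{\link{chordElbow}} to the
#' anchored inertia curve: the k farthest from the chord joining the
#' curve's endpoints after normalization to the unit square.
#'
#' Method \code{"wcss_ratio"} uses the ratio of the mean within-cluster
#' distance to the mean between-centroid distance — the criterion
#' conventional in dynamic-connectivity toolchains — and locates its bend
#' with the chord geometry (needs >= 3 candidate k values; no k = 1
#' anchor, the ratio being undefined there).
#'
#' @param X N x F numeric matrix.
#' @param kMin,kMax inclusive search range (kMax >= kMin >= 2).
#' @param seed optional seed (NULL = current RNG stream).
#' @param method "curvature", "chord_distance" or "wcss_ratio".
#' @param nInit,maxIter,tol,distance,weights passed to \code{\link{kmeansFit}}.
#' @return an \linkS4class{ElbowCurve}.
#' @export
elbowSelect <- function(X, kMin = 2L, kMax = 10L, seed = NULL,
                        method = c("curvature", "chord_distance", "wcss_ratio"),
                        nInit = 10L, maxIter = 300L, tol = 1e-4,
                        distance = "euclidean", weights = NULL) {
  X <- .assertFiniteMatrix(as.matrix(X), "X")
  kMin <- .assertCount(kMin, "kMin", min = 2L)
  kMax <- .assertCount(kMax, "kMax", min = 2L)
  method <- match.arg(method)
  if (kMax < kMin) stop("kMax must be >= kMin", call. = FALSE)
  if (nrow(X) < kMax) {
    stop(sprintf("need at least kMax = %d observations, got %d", kMax, nrow(X)),
         call. = FALSE)
  }
  ks <- kMin:kMax
  if (method %in% c("curvature", "chord_distance") && length(ks) < 2L) {
    stop(sprintf("%s needs at least 2 candidate k values (plus the k = 1 anchor)",
                 method), call. = FALSE)
  }
  if (method == "wcss_ratio" && length(ks) < 3L) {
    stop("wcss_ratio needs at least 3 candidate k values", call. = FALSE)
  }
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(weights)
  withSeed(seed, {
    fits <- lapply(ks, function(k) {
      kmeansFit(X, k, seed = NULL, nInit = nInit, maxIter = maxIter,
                tol = tol, distance = distance, weights = weights)
    })
    if (method %in% c("curvature", "chord_distance")) {
      crit <- vapply(fits, inertia, numeric(1))
      ## closed-form k = 1 anchor: weighted total sum of squares
      mu <- colSums(X * w) / sum(w)
      anchor <- if (distance == "euclidean") {
        sum(w * .pdist(X, matrix(mu, 1L), "euclidean")[, 1L])
      } else {
        med <- .weightedColMedian(X, w)
        sum(w * .pdist(X, matrix(med, 1L), "manhattan")[, 1L])
      }
      kx <- c(1L, ks)
      cx <- c(anchor, crit)
      if (method == "curvature") {
        ## sharpest bend of the log-inertia curve: the k where the drop
        ## RATIO I[k-1]/I[k] most exceeds I[k]/I[k+1]. Log scale makes the
        ## selection invariant to the overall inertia scale; interior
        ## points only, ties to the smallest k.
        lx <- log(pmax(cx, max(cx) * 1e-12))
        curv <- diff(diff(lx))  # l[k-1] - 2 l[k] + l[k+1] at interior k
        cand <- kx[2L:(length(kx) - 1L)]
        full <- cand[which.max(curv)]
      } else {
        full <- chordElbow(kx, cx)
      }
      sel <- if (full %in% ks) full else ks[1L]
    } else {
      crit <- vapply(seq_along(ks), function(i) {
        fit <- fits[[i]]
        D <- .pdist(X, centroids(fit), distance)
        within <- mean(sqrt(D[cbind(seq_len(nrow(X)), clusterLabels(fit))]))
        cd <- .pdist(centroids(fit), centroids(fit), distance)
        between <- mean(sqrt(cd[upper.tri(cd)]))
        within / between
      }, numeric(1))
      sel <- chordElbow(ks, crit)
    }
    new("ElbowCurve", kValues = ks, criterion = crit,
        selectedK = as.integer(sel), methodTag = method)
  })
}
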