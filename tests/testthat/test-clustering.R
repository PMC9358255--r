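test_that("k-means finds exact optima on closed-form instances", {
  # k distinct points each repeated 5x: zero inertia, centroids = points
  pts <- matrix(c(0, 0, 10, 0, 0, 10), 3, 2, byrow = TRUE)
  X <- pts[rep(1:3, each = 5), ]
  fit <- kmeansFit(X, 3, seed = 1)
  expect_equal(inertia(fit), 0)
  expect_equal(centroids(fit)[order(centroids(fit)[, 1], centroids(fit)[, 2]), ],
               pts[order(pts[, 1], pts[, 2]), ], ignore_attr = TRUE)

  # {0,1,9,10} in 1-D, k = 2: centroids {0.5, 9.5}, inertia 1.0
  X <- matrix(c(0, 1, 9, 10), 4, 1)
  fit <- kmeansFit(X, 2, seed = 1)
  expect_equal(sort(centroids(fit)[, 1]), c(0.5, 9.5))
  expect_equal(inertia(fit), 1.0)

  # k = 1: column means and total sum of squared deviations
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3)
  fit <- kmeansFit(X, 1, seed = 1)
  expect_equal(centroids(fit)[1, ], colMeans(X), ignore_attr = TRUE)
  expect_equal(inertia(fit), sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-12)

  expect_error(kmeansFit(X, 21), "21 clusters")
  expect_error(kmeansFit(matrix(c(1, NA), 2, 1), 1), "non-finite")
})

test_that("best-of-restarts inertia equals the exhaustive-partition optimum", {
  set.seed(10)
  cases <- list(
    list(N = 7, F = 1, k = 2), list(N = 8, F = 2, k = 3),
    list(N = 10, F = 1, k = 3), list(N = 9, F = 3, k = 2))
  for (cs in cases) {
    X <- matrix(rnorm(cs$N * cs$F), cs$N, cs$F)
    fit <- kmeansFit(X, cs$k, seed = 99, nInit = 50)
    expect_equal(inertia(fit), bruteKmeansInertia(X, cs$k), tolerance = 1e-9)
  }
})

test_that("k-means agrees with an independent optimizer on a planted mixture", {
  set.seed(21)
  X <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 6), 100, 2))
  fit <- kmeansFit(X, 2, seed = 5)
  sk <- kmeans(X, 2, nstart = 20, iter.max = 100)
  expect_equal(inertia(fit), sk$tot.withinss, tolerance = 1e-8)
})

test_that("Lloyd inertia is non-increasing and labels satisfy the nearest-centroid invariant", {
  set.seed(2)
  X <- matrix(rnorm(400), 100, 4)
  fit <- kmeansFit(X, 4, seed = 3)
  expect_true(all(diff(fit@inertiaTrace) <= 1e-9))
  # every point is at least as close to its own centroid as to any other
  lab <- clusterLabels(fit)
  cent <- centroids(fit)
  for (i in sample(100, 20)) {
    dOwn <- sum((X[i, ] - cent[lab[i], ])^2)
    for (j in seq_len(4)) {
      expect_lte(dOwn, sum((X[i, ] - cent[j, ])^2) + 1e-9)
    }
  }
  # inertia recomputes from its definition
  expect_equal(inertia(fit),
               sum((X - cent[lab, ])^2), tolerance = 1e-6)
})

test_that("k-means is deterministic under a seed and equivariant to row permutation", {
  set.seed(6)
  X <- matrix(rnorm(300), 75, 4)
  f1 <- kmeansFit(X, 3, seed = 11)
  f2 <- kmeansFit(X, 3, seed = 11)
  expect_identical(centroids(f1), centroids(f2))
  expect_identical(clusterLabels(f1), clusterLabels(f2))
  expect_identical(inertia(f1), inertia(f2))

  # row permutation: same optimum (up to centroid reindexing) on a
  # well-separated instance where the best partition is unambiguous
  Xs <- rbind(matrix(rnorm(60, 0, 0.3), 30, 2),
              matrix(rnorm(60, 4, 0.3), 30, 2),
              matrix(rnorm(60, c(8, 0), 0.3), 30, 2))
  perm <- sample(90)
  f0 <- kmeansFit(Xs, 3, seed = 11, nInit = 20)
  fp <- kmeansFit(Xs[perm, ], 3, seed = 11, nInit = 20)
  expect_equal(inertia(fp), inertia(f0), tolerance = 1e-8)
  # labels permute with the rows (up to a bijective relabeling)
  lab0 <- clusterLabels(f0)
  labp <- clusterLabels(fp)
  expect_equal(length(unique(paste(lab0[perm], labp))), 3L)
})

test_that("the chord elbow reproduces hand geometry and planted separations", {
  # hand geometry: [100, 20, 18, 17, 16] at k = 2..6 bends at 3
  expect_equal(chordElbow(2:6, c(100, 20, 18, 17, 16)), 3L)
  expect_error(chordElbow(2:3, c(3, 2)), ">= 3")

  # three tight, far-separated masses: selected k = 3 over 2..6
  set.seed(12)
  X <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
             matrix(rnorm(60, 5, 0.1), 30, 2),
             matrix(rnorm(60, c(10, 0), 0.1), 30, 2))
  e <- elbowSelect(X, 2, 6, seed = 1, method = "curvature")
  expect_equal(selectedK(e), 3L)
  # inertia is non-increasing in k up to optimizer noise
  expect_true(all(diff(e@criterion) <= 1e-6 * e@criterion[1]))
  ew <- elbowSelect(X, 2, 6, seed = 1, method = "wcss_ratio")
  expect_equal(selectedK(ew), 3L)
  # the chord variant runs and lands on an adjacent order at worst (its
  # unit-square geometry is nearly indifferent between the first bends)
  ec <- elbowSelect(X, 2, 6, seed = 1, method = "chord_distance")
  expect_true(selectedK(ec) %in% 2:3)
})

test_that("elbow selection recovers the planted two-state order in feature space", {
  fx <- defaultFixture(nSubjects = 6, seed = 2)
  tensors <- computeDfncTensors(fx$timecourses)
  pooled <- do.call(rbind, lapply(tensors, dataMatrix))
  e <- elbowSelect(pooled, 2, 6, seed = 1)
  expect_equal(selectedK(e), 2L)
})

test_that("manhattan distance is available as a clustering metric", {
  X <- matrix(c(0, 1, 9, 10), 4, 1)
  fit <- kmeansFit(X, 2, seed = 1, distance = "manhattan")
  expect_equal(sort(centroids(fit)[, 1]), c(0.5, 9.5), tolerance = 1)
  expect_equal(length(clusterLabels(fit)), 4L)
})
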