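test_that("the distance ratio reproduces hand arithmetic on the 1-D toy", {
  cent <- matrix(c(0, 10), 2, 1)
  model <- makeModel(cent)
  tn <- makeTensor(matrix(c(1, 9), 2, 1))
  q <- distanceRatio(tn, model)
  expect_equal(q@ratios, c(9, 9))
  expect_equal(meanDistanceRatio(q), 9)
  expect_length(q@flooredWindows, 0L)
})

test_that("zero own-centroid distances are floored and logged", {
  cent <- matrix(c(0, 5), 2, 1)
  model <- makeModel(cent)
  tn <- makeTensor(matrix(c(0), 1, 1))  # window exactly at centroid 1
  expect_message(q <- distanceRatio(tn, model), "floored")
  expect_equal(q@flooredWindows, 1L)
  expect_equal(q@ratios, 5 / 1e-12)
})

test_that("the distance ratio matches a brute-force double loop and is relabel-invariant", {
  set.seed(3)
  X <- matrix(rnorm(30 * 4), 30, 4)
  X6 <- cbind(X, X[, 1:2])  # F = 6 -> C = 4
  cent <- matrix(rnorm(3 * 6), 3, 6)
  model <- makeModel(cent)
  tn <- makeTensor(X6)
  sv <- assignStates(model, tn)
  q <- distanceRatio(tn, model, sv)
  expect_equal(q@ratios, distanceRatioRef(X6, cent, clusterLabels(sv)),
               tolerance = 1e-12)
  expect_equal(meanDistanceRatio(q), mean(q@ratios), tolerance = 1e-12)
  # permuting the states leaves every ratio unchanged
  perm <- c(3L, 1L, 2L)
  modelP <- makeModel(cent[perm, ])
  svP <- stateVector(match(clusterLabels(sv), perm), 3, subjectId(sv))
  qP <- distanceRatio(tn, modelP, svP)
  expect_equal(sort(qP@ratios), sort(q@ratios), tolerance = 1e-12)
  expect_equal(meanDistanceRatio(qP), meanDistanceRatio(q), tolerance = 1e-12)
})

test_that("moving the other centroids farther away strictly increases the ratio", {
  model1 <- makeModel(matrix(c(0, 10), 2, 1))
  model2 <- makeModel(matrix(c(0, 100), 2, 1))
  tn <- makeTensor(matrix(c(1, 2), 2, 1))
  expect_gt(meanDistanceRatio(distanceRatio(tn, model2)),
            meanDistanceRatio(distanceRatio(tn, model1)))
  # a single-state model is rejected
  single <- new("StateModel", kOpt = 1L, centroids = matrix(0, 1, 1),
                elbow = new("ElbowCurve", kValues = 1:3, criterion = c(3, 2, 1),
                            selectedK = 1L, methodTag = "curvature"),
                pipelineTag = "conventional", config = list())
  expect_error(distanceRatio(tn, single), "single-state")
})

test_that("state matching recovers identity, permutations, and the assignment optimum", {
  set.seed(8)
  A <- matrix(rnorm(4 * 10), 4, 10)
  m <- matchStates(A, A)
  expect_equal(matchedPairs(m)[, "A"], matchedPairs(m)[, "B"])
  expect_equal(matchedCorrelations(m), rep(1, 4), tolerance = 1e-12)

  perm <- c(3L, 1L, 4L, 2L)
  m2 <- matchStates(A, A[perm, ])
  expect_equal(matchedPairs(m2)[, "B"][order(matchedPairs(m2)[, "A"])],
               match(1:4, perm)[order(1:4)])
  expect_equal(matchedCorrelations(m2), rep(1, 4), tolerance = 1e-12)

  # noisy copy still matches like the clean permutation
  m3 <- matchStates(A, A[perm, ] + matrix(rnorm(40, sd = 0.05), 4, 10))
  expect_equal(matchedPairs(m3), matchedPairs(m2))
  expect_gt(minMatchedCor(m3), 0.95)

  # optimal assignment equals exhaustive enumeration for K <= 4
  for (i in 1:10) {
    KA <- sample(2:4, 1)
    KB <- sample(2:4, 1)
    A <- matrix(rnorm(KA * 8), KA, 8)
    B <- matrix(rnorm(KB * 8), KB, 8)
    m <- matchStates(A, B)
    expect_equal(sum(matchedCorrelations(m)),
                 bruteAssignmentMax(cor(t(A), t(B))), tolerance = 1e-10)
    expect_equal(nrow(matchedPairs(m)), min(KA, KB))
  }
  expect_error(matchStates(matrix(rnorm(8), 2, 4), matrix(rnorm(9), 3, 3)),
               "feature widths")
})

test_that("surplus states are reported unmatched", {
  set.seed(20)
  A <- matrix(rnorm(2 * 6), 2, 6)
  B <- rbind(A, matrix(rnorm(6), 1, 6))
  m <- matchStates(A, B)
  expect_equal(nrow(matchedPairs(m)), 2L)
  expect_length(m@unmatchedB, 1L)
  expect_length(m@unmatchedA, 0L)
})

test_that("feature similarity is plain Pearson with degenerate guards", {
  x <- c(1, 3, 2, 5, 4)
  expect_equal(featureSimilarity(x, x), 1)
  expect_equal(featureSimilarity(x, -x), -1)
  set.seed(2)
  a <- rnorm(10)
  b <- rnorm(10)
  expect_equal(featureSimilarity(a, b), windowedCorrelation(a, b),
               tolerance = 1e-12)
  expect_error(featureSimilarity(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(featureSimilarity(1:2, 1:2), "at least 3")
})

test_that("the quality comparison reproduces the closed-form t statistic", {
  a <- c(4.1, 4.5, 3.9, 4.3)
  expect_equal(compareQuality(a, a)$statistic, 0)
  expect_equal(compareQuality(a, a)$pValue, 1)
  # constant shift with equal variances: pooled formula in closed form
  b <- a + 0.8
  res <- compareQuality(b, a, varEqual = TRUE)
  sp2 <- (var(a) + var(b)) / 2
  tRef <- 0.8 / sqrt(sp2 * (2 / 4))
  expect_equal(res$statistic, tRef, tolerance = 1e-12)
  expect_equal(res$direction, 1)
  # Welch variant reports its tag and a sensible direction
  res2 <- compareQuality(a, b)
  expect_equal(res2$test, "welch")
  expect_equal(res2$direction, -1)
})
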