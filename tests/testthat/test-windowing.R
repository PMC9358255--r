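test_that("taper weights reduce to a rectangle at sigma 0 and match the convolution oracle", {
  expect_equal(taperWeights(5, 0), rep(1, 5))
  # symmetry for arbitrary sigma
  for (sig in c(0.5, 1, 3, 7)) {
    w <- taperWeights(9, sig)
    expect_equal(w, rev(w))
    expect_equal(max(w), 1)
    expect_true(all(w > 0))
  }
  # brute-force convolution oracle
  expect_equal(taperWeights(5, 1), taperRef(5, 1), tolerance = 1e-12)
  expect_equal(taperWeights(30, 3), taperRef(30, 3), tolerance = 1e-12)
  # center of a long window is untapered
  expect_equal(taperWeights(30, 3)[15], 1)
  expect_error(taperWeights(1, 1), "length")
})

test_that("windowed correlation reproduces the textbook formula", {
  expect_equal(windowedCorrelation(1:5, 2 * (1:5) + 1), 1.0)
  expect_equal(windowedCorrelation(1:5, -(1:5)), -1.0)
  # hand evaluation: r = 3 / sqrt(2 * 42/9)
  expect_equal(windowedCorrelation(c(1, 2, 3), c(1, 2, 4)),
               3 / sqrt(2 * 42 / 9), tolerance = 1e-12)
  expect_equal(windowedCorrelation(c(1, 2, 3), c(1, 2, 4)), 0.98198,
               tolerance = 1e-5)
  # oracle equivalence on random vectors with unit weights
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(17)
    y <- rnorm(17)
    expect_equal(windowedCorrelation(x, y), pearsonRef(x, y),
                 tolerance = 1e-12)
    expect_equal(windowedCorrelation(x, y), cor(x, y), tolerance = 1e-12)
  }
  expect_error(windowedCorrelation(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("tapered correlation weights the window as intended", {
  # hand-computed weighted correlation on a length-3 window
  w <- c(0.5, 1, 0.5)
  x <- c(1, 2, 4)
  y <- c(3, 1, 2)
  sw <- sum(w)
  mx <- sum(w * x) / sw
  my <- sum(w * y) / sw
  ref <- sum(w * (x - mx) * (y - my)) /
    sqrt(sum(w * (x - mx)^2) * sum(w * (y - my)^2))
  expect_equal(windowedCorrelation(x, y, w), ref, tolerance = 1e-14)
})

test_that("tensors have the documented geometry", {
  expect_equal(nrow(featurePairs(53)), 1378L)
  expect_equal(nrow(featurePairs(2)), 1L)
  # feature order is row-major over pairs i < j
  expect_equal(featurePairs(4)[, "i"], c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(featurePairs(4)[, "j"], c(2L, 3L, 4L, 3L, 4L, 4L))

  set.seed(1)
  tc <- componentTimeCourses(matrix(rnorm(100 * 2), 100, 2), "a")
  tn <- computeDfncTensor(tc, windowSpec(length = 30, step = 1, taperSigma = 0))
  expect_equal(dim(dataMatrix(tn)), c(71L, 1L))
  expect_equal(windowStarts(tn), 1:71)
  # window count for a strided window
  tn5 <- computeDfncTensor(tc, windowSpec(length = 30, step = 5, taperSigma = 0))
  expect_equal(nrow(dataMatrix(tn5)), floor((100 - 30) / 5) + 1)
  # first row equals the direct pairwise correlation of the first window
  X <- dataMatrix(tc)
  expect_equal(dataMatrix(tn)[1, 1], cor(X[1:30, 1], X[1:30, 2]),
               tolerance = 1e-12)
})

test_that("tensor rows rebuild symmetric unit-diagonal matrices and entries stay in [-1,1]", {
  set.seed(7)
  tc <- componentTimeCourses(matrix(rnorm(80 * 6), 80, 6), "a")
  tn <- computeDfncTensor(tc)
  X <- dataMatrix(tn)
  expect_true(all(X >= -1 & X <= 1))
  for (r in c(1, 17, nrow(X))) {
    M <- unvectorizeConnectivity(X[r, ], 6)
    expect_equal(M, t(M))
    expect_equal(diag(M), rep(1, 6))
  }
})

test_that("the tensor is invariant to shifting or positively scaling a component", {
  set.seed(3)
  base <- matrix(rnorm(60 * 4), 60, 4)
  shifted <- base
  shifted[, 2] <- shifted[, 2] + 100
  scaled <- base
  scaled[, 3] <- scaled[, 3] * 0.001
  t0 <- dataMatrix(computeDfncTensor(componentTimeCourses(base, "a")))
  t1 <- dataMatrix(computeDfncTensor(componentTimeCourses(shifted, "a")))
  t2 <- dataMatrix(computeDfncTensor(componentTimeCourses(scaled, "a")))
  expect_equal(t0, t1, tolerance = 1e-10)
  expect_equal(t0, t2, tolerance = 1e-10)
})

test_that("single-state data recovers the planted pair correlation on average", {
  Sigma <- diag(1, 3)
  Sigma[1, 2] <- Sigma[2, 1] <- 0.5
  cfg <- simulationConfig(nSubjects = 1, C = 3, tTotal = 1500,
                          states = list(stateSpec(0, Sigma)),
                          transitionMatrix = matrix(1, 1, 1), seed = 2)
  tc <- generateTimecourses(cfg)$timecourses[[1]]
  tn <- computeDfncTensor(tc)
  vals <- dataMatrix(tn)[, 1]  # feature (1,2)
  # windows overlap heavily, so use the dispersion of the window estimates
  # themselves as the scale for the tolerance band
  se <- sd(vals) / sqrt(sum(!duplicated(windowStarts(tn) %/% 30)))
  expect_lt(abs(mean(vals) - 0.5), max(3 * se, 0.05))
})

test_that("degenerate windows raise a located error and Fisher z is honored", {
  X <- matrix(rnorm(200), 50, 4)
  X[10:45, 2] <- 7  # constant stretch covering whole windows
  tc <- componentTimeCourses(X, "subj-x")
  expect_error(computeDfncTensor(tc, windowSpec(length = 30, step = 1, taperSigma = 0)),
               "subj-x.*component 2")
  set.seed(8)
  tc2 <- componentTimeCourses(matrix(rnorm(200), 50, 4), "a")
  tz <- computeDfncTensor(tc2, fisherZ = TRUE)
  tr <- computeDfncTensor(tc2, fisherZ = FALSE)
  expect_equal(dataMatrix(tz), atanh(dataMatrix(tr)), tolerance = 1e-12)
})
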