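test_that("state sequences honor absorbing, alternating and dwell-floor regimes", {
  # identity chain: never leaves the initial state
  lab <- generateStateSequence(50, diag(2), minDwell = 1, seed = 3)
  expect_equal(length(unique(lab)), 1L)
  expect_length(lab, 50L)

  # deterministic alternation with a dwell floor of 5: runs of exactly 5
  P <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE)
  lab <- generateStateSequence(20, P, minDwell = 5, seed = 1)
  runs <- rle(lab)
  expect_true(all(runs$lengths == 5L))
  expect_true(all(abs(diff(runs$values)) == 1L))

  # non-stochastic matrix rejected
  expect_error(generateStateSequence(10, matrix(c(0.5, 0.4, 0.1, 0.9), 2, 2)),
               "row-stochastic")
  expect_error(generateStateSequence(4, diag(2), minDwell = 5), "minDwell")
})

test_that("dwell times beyond the floor follow the geometric law of the chain", {
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2, byrow = TRUE)
  lab <- generateStateSequence(10000, P, minDwell = 5, seed = 11)
  runs <- rle(lab)$lengths
  complete <- runs[-length(runs)]  # final run may be truncated
  expect_true(all(complete >= 5L))
  extra <- complete - 5L
  # extra dwell ~ geometric(leave prob 0.1): mean 9, sd ~ 9.49
  mu <- 0.9 / 0.1
  se <- sqrt(0.9) / 0.1 / sqrt(length(extra))
  expect_lt(abs(mean(extra) - mu), 4 * se)
  # empirical leave probability at the first post-floor step
  expect_lt(abs(mean(extra == 0) - 0.1), 4 * sqrt(0.1 * 0.9 / length(extra)))
})

test_that("generated segments carry the planted covariance and are reproducible", {
  # single state with one pair correlated at 0.8
  Sigma <- diag(1, 4)
  Sigma[1, 2] <- Sigma[2, 1] <- 0.8
  cfg <- simulationConfig(nSubjects = 1, C = 4, tTotal = 2000,
                          states = list(stateSpec(0, Sigma)),
                          transitionMatrix = matrix(1, 1, 1), seed = 5)
  out <- generateTimecourses(cfg)
  X <- dataMatrix(out$timecourses[[1]])
  expect_equal(dim(X), c(2000L, 4L))
  # Fisher-z standard error of r at n = 2000 is ~0.022; 0.8 +/- ~2 se
  expect_gt(cor(X[, 1], X[, 2]), 0.76)
  expect_lt(cor(X[, 1], X[, 2]), 0.84)
  # uncorrelated pairs near zero (3/sqrt(T) band)
  expect_lt(max(abs(cor(X)[cbind(c(1, 2, 3), c(3, 4, 4))])), 3 / sqrt(2000))

  # determinism: identical config, identical draws
  out2 <- generateTimecourses(cfg)
  expect_identical(dataMatrix(out$timecourses[[1]]),
                   dataMatrix(out2$timecourses[[1]]))

  # non-positive-definite covariance named in the error
  bad <- matrix(0.99, 3, 3); bad[1, 2] <- bad[2, 1] <- -0.99; diag(bad) <- 1
  expect_error(stateSpec(7, bad), "state 7.*positive definite")
})

test_that("segment draws use exactly the covariance of their hidden label", {
  # two near-degenerate states with opposite-sign correlation make mixing
  # across segment boundaries visible immediately
  s1 <- diag(1, 2); s1[1, 2] <- s1[2, 1] <- 0.95
  s2 <- diag(1, 2); s2[1, 2] <- s2[2, 1] <- -0.95
  cfg <- simulationConfig(nSubjects = 1, C = 2, tTotal = 600,
                          states = list(stateSpec(0, s1), stateSpec(1, s2)),
                          transitionMatrix = matrix(0.5, 2, 2),
                          minDwell = 50, seed = 9)
  out <- generateTimecourses(cfg)
  X <- dataMatrix(out$timecourses[[1]])
  lab <- out$truth$timepointLabels[[1]]
  for (v in unique(lab)) {
    r <- cor(X[lab == v, 1], X[lab == v, 2])
    expect_gt(r * c(1, -1)[v], 0.9)
  }
})

test_that("the default fixture has the documented shape and separation", {
  fx <- defaultFixture(nSubjects = 5, seed = 1)
  expect_length(fx$timecourses, 5L)
  for (tc in fx$timecourses) {
    expect_equal(dim(dataMatrix(tc)), c(400L, 10L))
  }
  # planted centroids in feature space are close to orthogonal
  pc <- fx$truth$plantedCentroids
  expect_equal(dim(pc), c(2L, 45L))
  expect_lt(abs(cor(pc[1, ], pc[2, ])), 0.3)
  # reproducibility of the full fixture
  fx2 <- defaultFixture(nSubjects = 5, seed = 1)
  expect_identical(dataMatrix(fx$timecourses[[3]]),
                   dataMatrix(fx2$timecourses[[3]]))
})

test_that("window-level majority labels cover both states in nearly all seeds", {
  # chain-level Monte Carlo at the default fixture's dynamics (stay 0.98,
  # dwell floor 40, T = 400, 30-sample windows)
  P <- matrix(c(0.98, 0.02, 0.02, 0.98), 2, 2, byrow = TRUE)
  spec <- windowSpec()
  nSubj <- 5
  covered <- vapply(seq_len(200), function(s) {
    all(vapply(seq_len(nSubj), function(i) {
      lab <- generateStateSequence(400, P, minDwell = 40,
                                   seed = s * 1000 + i)
      length(unique(majorityWindowLabels(lab, spec))) == 2L
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("majority window labels break ties toward the earlier-entered state", {
  spec <- windowSpec(length = 4, step = 1, taperSigma = 0)
  # window [2,2,1,1]: tie between 1 and 2; 2 entered first
  expect_identical(majorityWindowLabels(c(2L, 2L, 1L, 1L), spec), 2L)
  expect_identical(majorityWindowLabels(c(1L, 2L, 2L, 1L), spec), 1L)
})
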