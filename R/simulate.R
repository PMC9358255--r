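## Synthetic multi-subject component time courses with planted,
## time-switching covariance states: the statistical structure the
## state-clustering pipeline assumes, with ground truth attached so every
## downstream stage is testable without imaging data.

#' Declare a planted connectivity state
#'
#' A state is a multivariate-normal regime: while the hidden chain sits in
#' the state, timepoints are i.i.d. draws from \code{N(mean, covariance)}.
#'
#' @param stateId integer identifier (>= 0).
#' @param covariance C x C symmetric positive-definite matrix; when given
#'   in correlation form its diagonal must be 1.
#' @param mean length-C mean vector (default all zero; correlations are
#'   location-invariant so nonzero means add nothing).
#' @return a validated list of class \code{StateSpec}.
#' @export
stateSpec <- function(stateId, covariance, mean = NULL) {
  stateId <- .assertCount(stateId, "stateId", min = 0L)
  covariance <- as.matrix(covariance)
  C <- nrow(covariance)
  if (ncol(covariance) != C) {
    stop(sprintf("state %d: covariance must be square", stateId), call. = FALSE)
  }
  if (max(abs(covariance - t(covariance))) > 1e-10) {
    stop(sprintf("state %d: covariance is not symmetric", stateId), call. = FALSE)
  }
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop(sprintf("state %d: covariance is not positive definite (min eigenvalue %.3g)",
                 stateId, min(ev)), call. = FALSE)
  }
  if (is.null(mean)) mean <- numeric(C)
  if (length(mean) != C) {
    stop(sprintf("state %d: mean must have length %d", stateId, C), call. = FALSE)
  }
  structure(list(stateId = stateId, covariance = covariance, mean = as.numeric(mean)),
            class = "StateSpec")
}

#' Configure a multi-subject simulation
#'
#' @param nSubjects number of subjects.
#' @param C number of components.
#' @param tTotal timepoints per subject.
#' @param states list of \code{\link{stateSpec}} regimes.
#' @param transitionMatrix K x K row-stochastic matrix of the hidden state
#'   chain (rows must sum to 1 within 1e-12).
#' @param minDwell minimum consecutive timepoints per state visit.
#' @param seed integer seed governing the whole simulation.
#' @param windowLength optional downstream window length; a \code{minDwell}
#'   below it triggers a warning (windows then straddle state changes).
#' @return a validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nSubjects, C, tTotal, states, transitionMatrix,
                             minDwell = 1L, seed = 1L, windowLength = NULL) {
  nSubjects <- .assertCount(nSubjects, "nSubjects")
  C <- .assertCount(C, "C", min = 2L)
  tTotal <- .assertCount(tTotal, "tTotal", min = 2L)
  minDwell <- .assertCount(minDwell, "minDwell")
  if (tTotal < minDwell) stop("tTotal must be >= minDwell", call. = FALSE)
  if (!length(states)) stop("need at least one state", call. = FALSE)
  for (s in states) {
    if (!inherits(s, "StateSpec")) stop("states must be built with stateSpec()", call. = FALSE)
    if (nrow(s$covariance) != C) {
      stop(sprintf("state %d covariance is %dx%d but C = %d", s$stateId,
                   nrow(s$covariance), ncol(s$covariance), C), call. = FALSE)
    }
  }
  P <- .validateTransitionMatrix(transitionMatrix, length(states))
  if (!is.null(windowLength) && minDwell < windowLength) {
    warning(sprintf("minDwell (%d) is below the window length (%d): windows will straddle state changes",
                    minDwell, as.integer(windowLength)), call. = FALSE)
  }
  structure(list(nSubjects = nSubjects, C = C, tTotal = tTotal, states = states,
                 transitionMatrix = P, minDwell = minDwell,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

.validateTransitionMatrix <- function(P, K = NULL) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square", call. = FALSE)
  if (!is.null(K) && nrow(P) != K) {
    stop(sprintf("transition matrix is %dx%d but there are %d states",
                 nrow(P), ncol(P), K), call. = FALSE)
  }
  if (any(P < 0) || max(abs(rowSums(P) - 1)) > 1e-12) {
    stop("transition matrix must be row-stochastic (rows summing to 1)", call. = FALSE)
  }
  P
}

#' Sample a hidden state-label sequence
#'
#' Samples the hidden chain with a dwell-time floor: each entered state
#' persists \code{minDwell} timepoints before the next transition draw, so
#' every maximal run has length >= \code{minDwell} (the final run may be
#' truncated at \code{tTotal}). The resulting extra dwell beyond the floor
#' is geometric with the state's leave probability.
#'
#' @param tTotal sequence length.
#' @param transitionMatrix K x K row-stochastic matrix.
#' @param minDwell minimum run length (default 1 = plain Markov chain).
#' @param seed optional seed (NULL = use the current RNG stream).
#' @return integer vector of length \code{tTotal} with labels in 1..K.
#' @export
generateStateSequence <- function(tTotal, transitionMatrix, minDwell = 1L,
                                  seed = NULL) {
  tTotal <- .assertCount(tTotal, "tTotal")
  minDwell <- .assertCount(minDwell, "minDwell")
  if (tTotal < minDwell) stop("tTotal must be >= minDwell", call. = FALSE)
  P <- .validateTransitionMatrix(transitionMatrix)
  K <- nrow(P)
  withSeed(seed, {
    labels <- integer(tTotal)
    s <- sample.int(K, 1L)
    t <- 0L
    while (t < tTotal) {
      run <- min(minDwell, tTotal - t)
      labels[(t + 1L):(t + run)] <- s
      t <- t + run
      while (t < tTotal) {
        nxt <- sample.int(K, 1L, prob = P[s, ])
        if (nxt != s) {
          s <- nxt
          break
        }
        t <- t + 1L
        labels[t] <- s
      }
    }
    labels
  })
}

#' Generate multi-subject component time courses with ground truth
#'
#' For each subject, samples a hidden state sequence and draws each
#' constant-label segment i.i.d. from that state's multivariate normal.
#' Identical configurations (including the seed) give bit-identical output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{timecourses} (list of
#'   \linkS4class{ComponentTimeCourses}) and \code{truth} (list with
#'   per-subject \code{timepointLabels}, the planted state centroids in
#'   connectivity-feature space, and \code{stateIds}).
#' @export
generateTimecourses <- function(config) {
  if (!inherits(config, "SimulationConfig")) {
    stop("config must be built with simulationConfig()", call. = FALSE)
  }
  K <- length(config$states)
  C <- config$C
  fp <- featurePairs(C)
  planted <- t(vapply(config$states, function(s) {
    R <- stats::cov2cor(s$covariance)
    R[fp]
  }, numeric(nrow(fp))))
  withSeed(config$seed, {
    tcs <- vector("list", config$nSubjects)
    labs <- vector("list", config$nSubjects)
    for (i in seq_len(config$nSubjects)) {
      lab <- generateStateSequence(config$tTotal, config$transitionMatrix,
                                   config$minDwell, seed = NULL)
      X <- matrix(NA_real_, config$tTotal, C)
      runs <- rle(lab)
      pos <- 0L
      for (r in seq_along(runs$lengths)) {
        len <- runs$lengths[r]
        st <- config$states[[runs$values[r]]]
        seg <- MASS::mvrnorm(n = len, mu = st$mean, Sigma = st$covariance)
        X[(pos + 1L):(pos + len), ] <- if (len == 1L) matrix(seg, 1L) else seg
        pos <- pos + len
      }
      tcs[[i]] <- componentTimeCourses(X, subjectId = sprintf("sub-%02d", i))
      labs[[i]] <- lab
    }
    names(labs) <- vapply(tcs, subjectId, character(1))
    list(timecourses = tcs,
         truth = list(timepointLabels = labs,
                      plantedCentroids = planted,
                      stateIds = vapply(config$states, function(s) s$stateId,
                                        integer(1))))
  })
}

#' Window-level majority ground-truth labels
#'
#' Reduces timepoint-level hidden-state labels to one label per sliding
#' window by majority vote; ties are broken toward the state entered
#' earlier within the window.
#'
#' @param labels integer timepoint labels for one subject.
#' @param spec a \code{\link{windowSpec}}.
#' @return integer vector with one majority label per window.
#' @export
majorityWindowLabels <- function(labels, spec) {
  stopifnot(is(spec, "WindowSpec"))
  Tt <- length(labels)
  if (Tt < spec@length) stop("label sequence shorter than the window", call. = FALSE)
  starts <- seq.int(1L, Tt - spec@length + 1L, by = spec@step)
  vapply(starts, function(s) {
    win <- labels[s:(s + spec@length - 1L)]
    cnt <- table(win)
    top <- as.integer(names(cnt)[cnt == max(cnt)])
    if (length(top) == 1L) return(top)
    first <- vapply(top, function(v) which(win == v)[1L], integer(1))
    top[which.min(first)]
  }, integer(1))
}

#' Default planted-state specifications
#'
#' Two well-separated connectivity regimes over C = 10 components:
#' state 1 has one 5-component block at r = 0.6 (components 1-5, rest
#' uncorrelated); state 2 has the complementary block (components 6-10)
#' at r = 0.6 with cross-block correlation -0.3. Their vectorized
#' correlation patterns are nearly orthogonal (pairwise r < 0.3).
#'
#' @return list of two \code{\link{stateSpec}} objects.
#' @export
defaultStateSpecs <- function() {
  C <- 10L
  SigmaA <- diag(1, C)
  SigmaA[1:5, 1:5] <- 0.6
  diag(SigmaA) <- 1
  SigmaB <- diag(1, C)
  SigmaB[6:10, 6:10] <- 0.6
  SigmaB[1:5, 6:10] <- -0.3
  SigmaB[6:10, 1:5] <- -0.3
  diag(SigmaB) <- 1
  list(stateSpec(0L, SigmaA), stateSpec(1L, SigmaB))
}

#' Default simulation configuration
#'
#' The study conditions used throughout the package's tests: C = 10
#' components, 400 timepoints, the two \code{\link{defaultStateSpecs}}
#' regimes, a symmetric chain with stay probability 0.98, and a dwell
#' floor of 40 timepoints (above the default 30-sample window, so windows
#' are dominated by single states).
#'
#' @param nSubjects number of subjects (>= 2).
#' @param seed integer seed.
#' @return a \code{\link{simulationConfig}}.
#' @export
defaultSimulationConfig <- function(nSubjects = 20L, seed = 1L) {
  nSubjects <- .assertCount(nSubjects, "nSubjects", min = 2L)
  simulationConfig(nSubjects = nSubjects, C = 10L, tTotal = 400L,
                   states = defaultStateSpecs(),
                   transitionMatrix = matrix(c(0.98, 0.02, 0.02, 0.98), 2L, 2L,
                                             byrow = TRUE),
                   minDwell = 40L, seed = seed)
}

#' Generate the default synthetic fixture
#'
#' Convenience wrapper: \code{\link{generateTimecourses}} under
#' \code{\link{defaultSimulationConfig}}.
#'
#' @inheritParams defaultSimulationConfig
#' @return list with \code{timecourses}, \code{truth} and \code{config}.
#' @export
defaultFixture <- function(nSubjects = 20L, seed = 1L) {
  config <- defaultSimulationConfig(nSubjects, seed)
  out <- generateTimecourses(config)
  out$config <- config
  out
}
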