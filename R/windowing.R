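## Tapered sliding-window connectivity: component time courses ->
## per-subject T x F tensors of vectorized windowed Pearson correlation.

#' Tapered sliding-window weights
#'
#' Discrete convolution of a rectangular window of \code{length} samples
#' with a unit-area Gaussian of standard deviation \code{taperSigma}
#' samples, truncated to \code{length} samples and rescaled to maximum 1.
#' \code{taperSigma = 0} returns the rectangular (all-ones) window.
#'
#' @param length window length in samples (>= 2).
#' @param taperSigma Gaussian standard deviation in samples (>= 0).
#' @return numeric weight vector of the given length.
#' @export
taperWeights <- function(length, taperSigma) {
  length <- .assertCount(length, "length", min = 2L)
  if (!is.numeric(taperSigma) || length(taperSigma) != 1L || taperSigma < 0) {
    stop("'taperSigma' must be a single nonnegative number", call. = FALSE)
  }
  if (taperSigma == 0) {
    return(rep(1, length))
  }
  half <- max(1L, ceiling(6 * taperSigma))
  offs <- (-half):half
  g <- exp(-offs^2 / (2 * taperSigma^2))
  g <- g / sum(g)
  ## central `length` samples of the full convolution with the rectangle:
  ## w[t] = sum_u g[u] * 1{1 <= t - u <= length}
  w <- vapply(seq_len(length), function(t) {
    keep <- (t - offs) >= 1L & (t - offs) <= length
    sum(g[keep])
  }, numeric(1))
  w / max(w)
}

#' Weighted Pearson correlation over one window
#'
#' Pearson correlation of two equal-length sample vectors using taper
#' weights in the means, variances and covariance; with unit weights this
#' is exactly the textbook sample correlation. The result is clamped to
#' [-1, 1] against floating-point rounding.
#'
#' @param x1,x2 numeric vectors of equal length >= 2.
#' @param weights positive weight vector of the same length (default unit
#'   weights).
#' @return correlation in [-1, 1].
#' @export
windowedCorrelation <- function(x1, x2, weights = rep(1, length(x1))) {
  n <- length(x1)
  if (n < 2L || length(x2) != n || length(weights) != n) {
    stop("x1, x2 and weights must share a common length >= 2", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  sw <- sum(weights)
  m1 <- sum(weights * x1) / sw
  m2 <- sum(weights * x2) / sw
  c1 <- x1 - m1
  c2 <- x2 - m2
  v1 <- sum(weights * c1^2)
  v2 <- sum(weights * c2^2)
  if (v1 <= 0 || v2 <= 0 || diff(range(x1)) == 0 || diff(range(x2)) == 0) {
    stop("degenerate window: zero weighted variance", call. = FALSE)
  }
  r <- sum(weights * c1 * c2) / sqrt(v1 * v2)
  min(1, max(-1, r))
}

#' Compute the dynamic connectivity tensor of one subject
#'
#' Slides the tapered window over the component time courses and stores,
#' per window, the strict upper triangle (row-major over pairs i < j) of
#' the C x C weighted-correlation matrix.
#'
#' @param tc a \linkS4class{ComponentTimeCourses}.
#' @param spec a \code{\link{windowSpec}} (default: length 30, step 1,
#'   Gaussian taper sigma 3).
#' @param fisherZ apply the Fisher z-transform (atanh) to the
#'   correlations (off by default).
#' @return a \linkS4class{DFNCTensor} with \code{T = floor((T_total -
#'   length)/step) + 1} rows and \code{F = C(C-1)/2} columns.
#' @export
computeDfncTensor <- function(tc, spec = windowSpec(), fisherZ = FALSE) {
  stopifnot(is(tc, "ComponentTimeCourses"), is(spec, "WindowSpec"))
  X <- dataMatrix(tc)
  Tt <- nrow(X)
  C <- ncol(X)
  L <- spec@length
  if (Tt < L) {
    stop(sprintf("subject '%s': %d timepoints is shorter than the %d-sample window",
                 subjectId(tc), Tt, L), call. = FALSE)
  }
  w <- spec@weights
  sw <- sum(w)
  fp <- featurePairs(C)
  starts <- seq.int(1L, Tt - L + 1L, by = spec@step)
  out <- matrix(NA_real_, length(starts), nrow(fp))
  for (t in seq_along(starts)) {
    S <- X[starts[t]:(starts[t] + L - 1L), , drop = FALSE]
    flat <- which(apply(S, 2L, function(col) diff(range(col))) == 0)
    if (length(flat)) {
      stop(sprintf("subject '%s', window %d (start %d): component %d is constant within the window",
                   subjectId(tc), t, starts[t], flat[1L]), call. = FALSE)
    }
    mu <- colSums(w * S) / sw
    Cc <- sweep(S, 2L, mu, check.margin = FALSE)
    M <- crossprod(Cc, w * Cc)
    v <- diag(M)
    R <- M / sqrt(outer(v, v))
    r <- pmin(1, pmax(-1, R[fp]))
    out[t, ] <- if (fisherZ) atanh(pmin(1 - 1e-15, pmax(-1 + 1e-15, r))) else r
  }
  new("DFNCTensor", subjectId = subjectId(tc), data = out,
      windowStarts = as.integer(starts), featureIndex = fp,
      fisherZ = isTRUE(fisherZ))
}

#' Compute tensors for a list of subjects
#'
#' @param tcs list of \linkS4class{ComponentTimeCourses}.
#' @inheritParams computeDfncTensor
#' @return list of \linkS4class{DFNCTensor}, one per subject.
#' @export
computeDfncTensors <- function(tcs, spec = windowSpec(), fisherZ = FALSE) {
  lapply(tcs, computeDfncTensor, spec = spec, fisherZ = fisherZ)
}
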