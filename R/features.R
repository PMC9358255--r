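## Temporal features of the state vector: occupancy rate (fraction of
## windows spent in each state) and number of between-state transitions.

#' Occupancy rate of a state vector
#'
#' Fraction of the subject's windows spent in each state; states never
#' visited get 0 and the vector sums to 1.
#'
#' @param sv a \linkS4class{StateVector}, or an integer label vector.
#' @param kOpt number of states (defaults to the state vector's own).
#' @return numeric vector of length \code{kOpt}.
#' @export
occupancyRate <- function(sv, kOpt = NULL) {
  labels <- if (is(sv, "StateVector")) clusterLabels(sv) else as.integer(sv)
  if (is.null(kOpt)) {
    if (!is(sv, "StateVector")) stop("kOpt is required for a bare label vector",
                                     call. = FALSE)
    kOpt <- kOpt(sv)
  }
  kOpt <- .assertCount(kOpt, "kOpt")
  if (!length(labels)) stop("empty state vector", call. = FALSE)
  if (min(labels) < 1L || max(labels) > kOpt) {
    stop(sprintf("labels outside 1..%d", kOpt), call. = FALSE)
  }
  tabulate(labels, kOpt) / length(labels)
}

#' Number of between-state transitions
#'
#' Counts the indices t with \code{labels[t] != labels[t-1]}; a constant
#' vector has 0 transitions and a length-T vector at most T - 1.
#'
#' @param sv a \linkS4class{StateVector}, or an integer label vector.
#' @return integer transition count.
#' @export
transitionCount <- function(sv) {
  labels <- if (is(sv, "StateVector")) clusterLabels(sv) else as.integer(sv)
  if (!length(labels)) stop("empty state vector", call. = FALSE)
  sum(labels[-1L] != labels[-length(labels)])
}

#' Temporal features of one subject
#'
#' @param sv a \linkS4class{StateVector}.
#' @param kOpt number of states (defaults to the state vector's own).
#' @return a \linkS4class{TemporalFeatures}.
#' @export
temporalFeatures <- function(sv, kOpt = NULL) {
  stopifnot(is(sv, "StateVector"))
  if (is.null(kOpt)) kOpt <- kOpt(sv)
  new("TemporalFeatures", subjectId = subjectId(sv),
      ocr = occupancyRate(sv, kOpt),
      nTransitions = as.integer(transitionCount(sv)))
}
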