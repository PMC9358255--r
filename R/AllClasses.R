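## S4 containers for the dFNC state pipeline. Validity methods encode the
## contracts the rest of the package relies on; use the constructor
## functions rather than new() directly.

#' Component time courses for one subject
#'
#' Holds a \code{T_total x C} matrix of component (network) activity over
#' time for a single subject — the raw input of the connectivity pipeline.
#'
#' @slot subjectId single subject identifier.
#' @slot data numeric matrix, rows = timepoints, columns = components.
#' @slot tr repetition time in seconds (\code{NA} if unknown; metadata only).
#' @exportClass ComponentTimeCourses
setClass("ComponentTimeCourses",
  representation(subjectId = "character", data = "matrix", tr = "numeric"))

setValidity("ComponentTimeCourses", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-empty string")
  if (!is.numeric(object@data))
    msg <- c(msg, "data must be numeric")
  else if (!all(is.finite(object@data)))
    msg <- c(msg, "data contains missing or non-finite values")
  if (ncol(object@data) < 2L)
    msg <- c(msg, "need at least 2 components")
  if (length(object@tr) != 1L)
    msg <- c(msg, "tr must be a single number (or NA)")
  if (length(msg)) msg else TRUE
})

#' @param data numeric matrix (timepoints x components).
#' @param subjectId subject identifier.
#' @param tr optional repetition time in seconds.
#' @rdname ComponentTimeCourses-class
#' @export
componentTimeCourses <- function(data, subjectId = "subject", tr = NA_real_) {
  new("ComponentTimeCourses", subjectId = as.character(subjectId),
      data = as.matrix(data), tr = as.numeric(tr))
}

#' Sliding-window specification
#'
#' Describes the tapered sliding window used for dynamic connectivity:
#' a rectangle of \code{length} samples convolved with a unit-area
#' Gaussian of standard deviation \code{taperSigma} samples (0 gives a
#' plain rectangular window), advanced by \code{step} samples.
#'
#' @slot length window length in samples.
#' @slot step window step in samples.
#' @slot taperSigma Gaussian taper standard deviation in samples.
#' @slot weights derived taper weights (max 1, symmetric, all positive).
#' @exportClass WindowSpec
setClass("WindowSpec",
  representation(length = "integer", step = "integer",
                 taperSigma = "numeric", weights = "numeric"))

setValidity("WindowSpec", function(object) {
  msg <- character()
  if (object@length < 2L) msg <- c(msg, "window length must be >= 2")
  if (object@step < 1L) msg <- c(msg, "step must be >= 1")
  if (object@taperSigma < 0) msg <- c(msg, "taperSigma must be >= 0")
  w <- object@weights
  if (length(w) != object@length)
    msg <- c(msg, "weights must have one entry per window sample")
  else {
    if (any(w <= 0)) msg <- c(msg, "all weights must be positive")
    if (abs(max(w) - 1) > 1e-12) msg <- c(msg, "max(weights) must equal 1")
    if (max(abs(w - rev(w))) > 1e-12)
      msg <- c(msg, "weights must be symmetric about the window midpoint")
  }
  if (length(msg)) msg else TRUE
})

#' @param length window length in samples (default 30).
#' @param step window step in samples (default 1).
#' @param taperSigma Gaussian taper sd in samples (default 3; 0 = rectangular).
#' @rdname WindowSpec-class
#' @export
windowSpec <- function(length = 30L, step = 1L, taperSigma = 3) {
  length <- .assertCount(length, "length", min = 2L)
  step <- .assertCount(step, "step", min = 1L)
  new("WindowSpec", length = length, step = step,
      taperSigma = as.numeric(taperSigma),
      weights = taperWeights(length, taperSigma))
}

#' Per-subject dynamic connectivity tensor
#'
#' A \code{T x F} matrix of vectorized windowed connectivity, where
#' \code{F = C(C-1)/2} enumerates component pairs in row-major strict
#' upper-triangle order (see \code{\link{featurePairs}}).
#'
#' @slot subjectId subject identifier.
#' @slot data numeric matrix, rows = windows, columns = connectivity features.
#' @slot windowStarts first-sample index of each window.
#' @slot featureIndex F x 2 integer matrix of component pairs (i < j).
#' @slot fisherZ whether entries are Fisher z-transformed correlations.
#' @exportClass DFNCTensor
setClass("DFNCTensor",
  representation(subjectId = "character", data = "matrix",
                 windowStarts = "integer", featureIndex = "matrix",
                 fisherZ = "logical"))

setValidity("DFNCTensor", function(object) {
  msg <- character()
  if (length(object@subjectId) != 1L || !nzchar(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-empty string")
  if (!all(is.finite(object@data)))
    msg <- c(msg, "tensor contains non-finite values")
  fi <- object@featureIndex
  if (ncol(fi) != 2L) {
    msg <- c(msg, "featureIndex must have two columns (i, j)")
  } else {
    C <- max(fi)
    if (nrow(fi) != C * (C - 1L) / 2L)
      msg <- c(msg, "featureIndex must enumerate all C(C-1)/2 pairs")
    if (any(fi[, 1L] >= fi[, 2L]))
      msg <- c(msg, "featureIndex pairs must satisfy i < j")
    if (ncol(object@data) != nrow(fi))
      msg <- c(msg, "ncol(data) must equal nrow(featureIndex)")
  }
  if (length(object@windowStarts) != nrow(object@data))
    msg <- c(msg, "windowStarts must have one entry per window")
  if (!object@fisherZ && nrow(object@data) > 0 &&
      (min(object@data) < -1 - 1e-9 || max(object@data) > 1 + 1e-9))
    msg <- c(msg, "correlation entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Aggregated first-step centroids
#'
#' The reduced dataset of the two-step pipeline: first-step cluster
#' centroids from all batches stacked row-wise, with per-row provenance
#' (batch of origin, k of the sweep, within-k cluster index, source
#' cluster size).
#'
#' @slot data M x F numeric matrix of stacked centroids.
#' @slot provenance data.frame with columns batch, k, cluster, size.
#' @exportClass AggregatedCentroids
setClass("AggregatedCentroids",
  representation(data = "matrix", provenance = "data.frame"))

setValidity("AggregatedCentroids", function(object) {
  msg <- character()
  if (!all(is.finite(object@data)))
    msg <- c(msg, "aggregated centroids contain non-finite values")
  if (nrow(object@provenance) != nrow(object@data))
    msg <- c(msg, "provenance must have one row per centroid")
  need <- c("batch", "k", "cluster", "size")
  if (!all(need %in% names(object@provenance)))
    msg <- c(msg, "provenance must have columns batch, k, cluster, size")
  if (length(msg)) msg else TRUE
})

#' k-means fit result
#'
#' @slot k number of clusters.
#' @slot centroids k x F matrix.
#' @slot labels 1-based cluster assignment per row of the input.
#' @slot inertia within-cluster sum of dissimilarities (squared Euclidean
#'   by default).
#' @slot nIter Lloyd iterations of the winning restart.
#' @slot inertiaTrace per-iteration inertia of the winning restart
#'   (non-increasing).
#' @slot seed seed used, or NA when run inside an outer seeded scope.
#' @exportClass KMeansResult
setClass("KMeansResult",
  representation(k = "integer", centroids = "matrix", labels = "integer",
                 inertia = "numeric", nIter = "integer",
                 inertiaTrace = "numeric", seed = "integer"))

setValidity("KMeansResult", function(object) {
  msg <- character()
  if (nrow(object@centroids) != object@k)
    msg <- c(msg, "centroids must have k rows")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (object@inertia < 0) msg <- c(msg, "inertia must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Elbow curve and selected model order
#'
#' @slot kValues ascending candidate cluster counts.
#' @slot criterion per-k criterion values (inertia for chord_distance,
#'   within/between distance ratio for wcss_ratio).
#' @slot selectedK the elbow-selected k.
#' @slot methodTag "curvature", "chord_distance" or "wcss_ratio".
#' @exportClass ElbowCurve
setClass("ElbowCurve",
  representation(kValues = "integer", criterion = "numeric",
                 selectedK = "integer", methodTag = "character"))

setValidity("ElbowCurve", function(object) {
  msg <- character()
  if (length(object@kValues) != length(object@criterion))
    msg <- c(msg, "kValues and criterion must have equal length")
  if (is.unsorted(object@kValues, strictly = TRUE))
    msg <- c(msg, "kValues must be strictly ascending")
  if (!(object@selectedK %in% object@kValues))
    msg <- c(msg, "selectedK must be one of kValues")
  if (!object@methodTag %in% c("curvature", "chord_distance", "wcss_ratio"))
    msg <- c(msg, "methodTag must be curvature, chord_distance or wcss_ratio")
  if (length(msg)) msg else TRUE
})

#' Group connectivity-state model
#'
#' The final set of dFNC states (cluster centroids in connectivity-feature
#' space), the elbow curve that selected the model order, and a snapshot of
#' the configuration that produced them. States are indexed in descending
#' group occupancy.
#'
#' @slot kOpt number of states.
#' @slot centroids kOpt x F matrix of state centroids.
#' @slot elbow the \linkS4class{ElbowCurve} that chose kOpt.
#' @slot pipelineTag "two_step" or "conventional".
#' @slot config list snapshot of the run configuration.
#' @exportClass StateModel
setClass("StateModel",
  representation(kOpt = "integer", centroids = "matrix", elbow = "ElbowCurve",
                 pipelineTag = "character", config = "list"))

setValidity("StateModel", function(object) {
  msg <- character()
  if (!all(is.finite(object@centroids)))
    msg <- c(msg, "state centroids must be finite")
  if (nrow(object@centroids) != object@kOpt)
    msg <- c(msg, "centroids must have kOpt rows")
  if (object@kOpt != object@elbow@selectedK)
    msg <- c(msg, "kOpt must equal elbow@selectedK")
  if (!object@pipelineTag %in% c("two_step", "conventional"))
    msg <- c(msg, "pipelineTag must be two_step or conventional")
  if (length(msg)) msg else TRUE
})

#' Per-subject state vector
#'
#' Window-by-window assignment of one subject's connectivity to the
#' nearest group state (1-based labels).
#'
#' @slot subjectId subject identifier.
#' @slot labels integer labels in 1..kOpt, one per window.
#' @slot kOpt number of states in the model that produced the labels.
#' @exportClass StateVector
setClass("StateVector",
  representation(subjectId = "character", labels = "integer", kOpt = "integer"))

setValidity("StateVector", function(object) {
  msg <- character()
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > object@kOpt))
    msg <- c(msg, "labels must lie in 1..kOpt")
  if (length(msg)) msg else TRUE
})

#' @param labels integer window labels (1-based).
#' @param kOpt number of states.
#' @param subjectId subject identifier.
#' @rdname StateVector-class
#' @export
stateVector <- function(labels, kOpt, subjectId = "subject") {
  new("StateVector", subjectId = as.character(subjectId),
      labels = as.integer(labels), kOpt = .assertCount(kOpt, "kOpt"))
}

#' Temporal state features for one subject
#'
#' @slot subjectId subject identifier.
#' @slot ocr occupancy rate: fraction of windows spent in each state
#'   (sums to 1).
#' @slot nTransitions number of adjacent-window state changes.
#' @exportClass TemporalFeatures
setClass("TemporalFeatures",
  representation(subjectId = "character", ocr = "numeric",
                 nTransitions = "integer"))

setValidity("TemporalFeatures", function(object) {
  msg <- character()
  if (abs(sum(object@ocr) - 1) > 1e-12)
    msg <- c(msg, "occupancy rates must sum to 1")
  if (any(object@ocr < 0 | object@ocr > 1))
    msg <- c(msg, "occupancy rates must lie in [0, 1]")
  if (object@nTransitions < 0L)
    msg <- c(msg, "transition count must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Clustering-quality report for one subject
#'
#' Per-window distance ratios (summed Euclidean distance to the other
#' centroids over distance to the own centroid) and their subject-level
#' mean; higher means crisper clustering.
#'
#' @slot subjectId subject identifier.
#' @slot Rp mean distance ratio over the subject's windows.
#' @slot ratios per-window distance ratios.
#' @slot flooredWindows indices of windows whose own-centroid distance was
#'   floored at 1e-12 to avoid division by zero.
#' @exportClass QualityReport
setClass("QualityReport",
  representation(subjectId = "character", Rp = "numeric", ratios = "numeric",
                 flooredWindows = "integer"))

setValidity("QualityReport", function(object) {
  msg <- character()
  if (any(object@ratios < 0)) msg <- c(msg, "ratios must be nonnegative")
  if (length(object@ratios) &&
      abs(object@Rp - mean(object@ratios)) > 1e-12 * max(1, abs(object@Rp)))
    msg <- c(msg, "Rp must equal the mean of the per-window ratios")
  if (length(msg)) msg else TRUE
})

#' Matched-state similarity between two state models
#'
#' One-to-one assignment between two centroid sets maximizing the summed
#' Pearson correlation of paired centroids.
#'
#' @slot pairs n x 2 integer matrix of matched (index A, index B) pairs.
#' @slot correlations Pearson correlation of each matched pair.
#' @slot minCor minimum matched correlation.
#' @slot meanCor mean matched correlation.
#' @slot unmatchedA,unmatchedB surplus state indices left unmatched.
#' @exportClass StateMatching
setClass("StateMatching",
  representation(pairs = "matrix", correlations = "numeric",
                 minCor = "numeric", meanCor = "numeric",
                 unmatchedA = "integer", unmatchedB = "integer"))

setValidity("StateMatching", function(object) {
  msg <- character()
  if (ncol(object@pairs) != 2L) msg <- c(msg, "pairs must have two columns")
  if (anyDuplicated(object@pairs[, 1L]) || anyDuplicated(object@pairs[, 2L]))
    msg <- c(msg, "pairs must form a partial bijection (no index reused)")
  if (nrow(object@pairs) != length(object@correlations))
    msg <- c(msg, "one correlation per matched pair required")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "ComponentTimeCourses", function(object) {
  cat(sprintf("ComponentTimeCourses '%s': %d timepoints x %d components\n",
              object@subjectId, nrow(object@data), ncol(object@data)))
})

setMethod("show", "DFNCTensor", function(object) {
  cat(sprintf("DFNCTensor '%s': %d windows x %d features%s\n",
              object@subjectId, nrow(object@data), ncol(object@data),
              if (object@fisherZ) " (Fisher z)" else ""))
})

setMethod("show", "AggregatedCentroids", function(object) {
  cat(sprintf("AggregatedCentroids: %d centroids x %d features from %d batches\n",
              nrow(object@data), ncol(object@data),
              length(unique(object@provenance$batch))))
})

setMethod("show", "KMeansResult", function(object) {
  cat(sprintf("KMeansResult: k = %d, inertia = %.6g, %d iterations\n",
              object@k, object@inertia, object@nIter))
})

setMethod("show", "ElbowCurve", function(object) {
  cat(sprintf("ElbowCurve (%s): k in [%d, %d], selected k = %d\n",
              object@methodTag, min(object@kValues), max(object@kValues),
              object@selectedK))
})

setMethod("show", "StateModel", function(object) {
  cat(sprintf("StateModel (%s): %d states x %d features, elbow-selected\n",
              object@pipelineTag, object@kOpt, ncol(object@centroids)))
})

setMethod("show", "StateVector", function(object) {
  cat(sprintf("StateVector '%s': %d windows, %d states\n",
              object@subjectId, length(object@labels), object@kOpt))
})

setMethod("show", "TemporalFeatures", function(object) {
  cat(sprintf("TemporalFeatures '%s': ocr = [%s], %d transitions\n",
              object@subjectId,
              paste(sprintf("%.3f", object@ocr), collapse = ", "),
              object@nTransitions))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport '%s': mean distance ratio R_p = %.4g (%d windows)\n",
              object@subjectId, object@Rp, length(object@ratios)))
})

setMethod("show", "StateMatching", function(object) {
  cat(sprintf("StateMatching: %d matched pairs, min r = %.4f, mean r = %.4f\n",
              nrow(object@pairs), object@minCor, object@meanCor))
})
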