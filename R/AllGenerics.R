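## Accessor generics: use these rather than @ slot access.

#' Subject identifier of a per-subject object
#' @param x a per-subject object.
#' @return single character identifier.
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname subjectId
setMethod("subjectId", "ComponentTimeCourses", function(x) x@subjectId)
#' @rdname subjectId
setMethod("subjectId", "DFNCTensor", function(x) x@subjectId)
#' @rdname subjectId
setMethod("subjectId", "StateVector", function(x) x@subjectId)
#' @rdname subjectId
setMethod("subjectId", "TemporalFeatures", function(x) x@subjectId)
#' @rdname subjectId
setMethod("subjectId", "QualityReport", function(x) x@subjectId)

#' Underlying numeric matrix of a container
#' @param x a matrix-backed object.
#' @return the numeric matrix payload.
#' @export
setGeneric("dataMatrix", function(x) standardGeneric("dataMatrix"))

#' @rdname dataMatrix
setMethod("dataMatrix", "ComponentTimeCourses", function(x) x@data)
#' @rdname dataMatrix
setMethod("dataMatrix", "DFNCTensor", function(x) x@data)
#' @rdname dataMatrix
setMethod("dataMatrix", "AggregatedCentroids", function(x) x@data)

#' State or cluster centroids
#' @param x a \linkS4class{KMeansResult} or \linkS4class{StateModel}.
#' @return numeric matrix with one centroid per row.
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname centroids
setMethod("centroids", "KMeansResult", function(x) x@centroids)
#' @rdname centroids
setMethod("centroids", "StateModel", function(x) x@centroids)

#' Cluster or state labels
#' @param x a \linkS4class{KMeansResult} or \linkS4class{StateVector}.
#' @return integer vector of 1-based labels.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
setMethod("clusterLabels", "KMeansResult", function(x) x@labels)
#' @rdname clusterLabels
setMethod("clusterLabels", "StateVector", function(x) x@labels)

#' Number of states of a model or state vector
#' @param x a \linkS4class{StateModel} or \linkS4class{StateVector}.
#' @return integer count of states.
#' @export
setGeneric("kOpt", function(x) standardGeneric("kOpt"))

#' @rdname kOpt
setMethod("kOpt", "StateModel", function(x) x@kOpt)
#' @rdname kOpt
setMethod("kOpt", "StateVector", function(x) x@kOpt)

#' Elbow curve of a state model
#' @param x a \linkS4class{StateModel}.
#' @return the \linkS4class{ElbowCurve} used for model-order selection.
#' @export
setGeneric("elbowCurve", function(x) standardGeneric("elbowCurve"))

#' @rdname elbowCurve
setMethod("elbowCurve", "StateModel", function(x) x@elbow)

#' Window start indices of a connectivity tensor
#' @param x a \linkS4class{DFNCTensor}.
#' @return integer vector of first-sample window indices.
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))

#' @rdname windowStarts
setMethod("windowStarts", "DFNCTensor", function(x) x@windowStarts)

#' Component-pair feature index of a connectivity tensor
#' @param x a \linkS4class{DFNCTensor}.
#' @return F x 2 integer matrix of (i, j) component pairs, i < j.
#' @export
setGeneric("featureIndex", function(x) standardGeneric("featureIndex"))

#' @rdname featureIndex
setMethod("featureIndex", "DFNCTensor", function(x) x@featureIndex)

#' Within-cluster sum of dissimilarities
#' @param x a \linkS4class{KMeansResult}.
#' @return nonnegative inertia value.
#' @export
setGeneric("inertia", function(x) standardGeneric("inertia"))

#' @rdname inertia
setMethod("inertia", "KMeansResult", function(x) x@inertia)

#' Selected model order of an elbow curve
#' @param x an \linkS4class{ElbowCurve}.
#' @return the selected k.
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname selectedK
setMethod("selectedK", "ElbowCurve", function(x) x@selectedK)

#' Occupancy rates of a feature object
#' @param x a \linkS4class{TemporalFeatures}.
#' @return numeric vector of per-state occupancy fractions.
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname occupancy
setMethod("occupancy", "TemporalFeatures", function(x) x@ocr)

#' Number of between-state transitions of a feature object
#' @param x a \linkS4class{TemporalFeatures}.
#' @return integer transition count.
#' @export
setGeneric("nTransitions", function(x) standardGeneric("nTransitions"))

#' @rdname nTransitions
setMethod("nTransitions", "TemporalFeatures", function(x) x@nTransitions)

#' Mean distance ratio of a quality report
#' @param x a \linkS4class{QualityReport}.
#' @return the subject-level mean distance ratio R_p.
#' @export
setGeneric("meanDistanceRatio", function(x) standardGeneric("meanDistanceRatio"))

#' @rdname meanDistanceRatio
setMethod("meanDistanceRatio", "QualityReport", function(x) x@Rp)

#' Matched state pairs of a state matching
#' @param x a \linkS4class{StateMatching}.
#' @return n x 2 integer matrix of matched (A, B) indices.
#' @export
setGeneric("matchedPairs", function(x) standardGeneric("matchedPairs"))

#' @rdname matchedPairs
setMethod("matchedPairs", "StateMatching", function(x) x@pairs)

#' Per-pair correlations of a state matching
#' @param x a \linkS4class{StateMatching}.
#' @return numeric vector, one Pearson correlation per matched pair.
#' @export
setGeneric("matchedCorrelations", function(x) standardGeneric("matchedCorrelations"))

#' @rdname matchedCorrelations
setMethod("matchedCorrelations", "StateMatching", function(x) x@correlations)

#' Minimum matched-state correlation
#' @param x a \linkS4class{StateMatching}.
#' @return the minimum Pearson correlation across matched pairs.
#' @export
setGeneric("minMatchedCor", function(x) standardGeneric("minMatchedCor"))

#' @rdname minMatchedCor
setMethod("minMatchedCor", "StateMatching", function(x) x@minCor)
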