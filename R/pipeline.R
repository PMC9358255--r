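## Orchestration of the two clustering pipelines over a collection of
## per-subject connectivity tensors:
##   conventional — pool every subject's windows, elbow-select k, one
##     k-means over everything;
##   two-step     — per-batch k-means sweeps (k = 2..L) over disjoint
##     subject subsamples, then elbow selection and a second k-means on
##     the aggregated first-step centroids. Only one batch of tensors is
##     materialized at a time, which is the point of the method.

#' Two-step pipeline configuration
#'
#' @param m subjects per first-step batch (m = 1 is the finest
#'   granularity; m = n collapses the two-step scheme onto a single batch).
#' @param L upper end of the first-step k sweep (k = 2..L); each full
#'   batch contributes L(L+1)/2 - 1 centroids.
#' @param kRange length-2 elbow search range for the model order.
#' @param seed integer seed governing the whole run.
#' @param shuffle randomize subject order before batching (default TRUE).
#' @param elbowMethod "curvature", "chord_distance" or "wcss_ratio".
#' @param nInit,maxIter,tol,distance passed to \code{\link{kmeansFit}}.
#' @param weightBySize weight second-step observations by their source
#'   cluster size (default FALSE: every centroid counts once).
#' @return list of class \code{TwoStepConfig}.
#' @export
twoStepConfig <- function(m, L = 6L, kRange = c(2L, 10L), seed = 1L,
                          shuffle = TRUE, elbowMethod = "curvature",
                          nInit = 10L, maxIter = 300L, tol = 1e-4,
                          distance = "euclidean", weightBySize = FALSE) {
  m <- .assertCount(m, "m")
  L <- .assertCount(L, "L", min = 2L)
  if (length(kRange) != 2L) stop("kRange must be c(kMin, kMax)", call. = FALSE)
  structure(list(m = m, L = L, kRange = as.integer(kRange),
                 seed = as.integer(seed), shuffle = isTRUE(shuffle),
                 elbowMethod = elbowMethod, nInit = as.integer(nInit),
                 maxIter = as.integer(maxIter), tol = tol,
                 distance = distance, weightBySize = isTRUE(weightBySize)),
            class = "TwoStepConfig")
}

#' Partition subjects into disjoint batches
#'
#' Splits the subject list into consecutive batches of \code{m}; when n is
#' not divisible by m, the remainder subjects are appended to the final
#' batch so no subject is dropped.
#'
#' @param subjectIds character vector of unique subject identifiers.
#' @param m batch size (1 <= m <= n).
#' @param seed optional seed for the shuffle (NULL = current RNG stream).
#' @param shuffle randomize order before batching.
#' @return list of character vectors forming a partition of
#'   \code{subjectIds}.
#' @export
partitionSubjects <- function(subjectIds, m, seed = NULL, shuffle = TRUE) {
  subjectIds <- as.character(subjectIds)
  if (anyDuplicated(subjectIds)) {
    stop("duplicate subject ids in the partition request", call. = FALSE)
  }
  n <- length(subjectIds)
  m <- .assertCount(m, "m")
  if (m > n) stop(sprintf("m = %d exceeds the %d available subjects", m, n),
                  call. = FALSE)
  ids <- withSeed(seed, if (shuffle) sample(subjectIds) else subjectIds)
  r <- n %/% m
  batches <- split(ids[seq_len(r * m)], rep(seq_len(r), each = m))
  if (r * m < n) {
    batches[[r]] <- c(batches[[r]], ids[(r * m + 1L):n])
  }
  unname(batches)
}

## Normalize the many accepted tensor sources to a (loader, ids) pair.
## The loader materializes one subject at a time, so a directory-backed
## source never loads the whole collection.
.resolveTensorSource <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    return(list(loader = dfncStoreLoader(x), ids = dfncStoreSubjects(x)))
  }
  if (is.function(x)) {
    stop("a bare loader function has no subject list; pass list(loader=, subjectIds=)",
         call. = FALSE)
  }
  if (is.list(x) && !is.null(x$loader) && !is.null(x$subjectIds)) {
    return(list(loader = x$loader, ids = as.character(x$subjectIds)))
  }
  if (is.list(x) && all(vapply(x, is, logical(1), "DFNCTensor"))) {
    ids <- vapply(x, subjectId, character(1))
    if (anyDuplicated(ids)) stop("duplicate subject ids among tensors", call. = FALSE)
    names(x) <- ids
    return(list(loader = function(id) x[[id]], ids = ids))
  }
  stop("tensors must be a list of DFNCTensor, a dFNC store directory, or list(loader=, subjectIds=)",
       call. = FALSE)
}

#' First-step subsample k-means sweep
#'
#' For each batch, pools its subjects' tensor rows, runs
#' \code{\link{kmeansFit}} for every k in 2..L, and stacks all resulting
#' centroids with provenance. Each full batch contributes exactly
#' \code{L(L+1)/2 - 1} rows. Batches are materialized one at a time via
#' the loader.
#'
#' @param source tensors (see \code{\link{runTwoStep}}).
#' @param batches list of subject-id batches from
#'   \code{\link{partitionSubjects}}.
#' @param L sweep upper end (k = 2..L).
#' @param seed optional seed (NULL = current RNG stream).
#' @param nInit,maxIter,tol,distance passed to \code{\link{kmeansFit}}.
#' @return an \linkS4class{AggregatedCentroids}.
#' @export
firstStepSweep <- function(source, batches, L, seed = NULL, nInit = 10L,
                           maxIter = 300L, tol = 1e-4, distance = "euclidean") {
  src <- .resolveTensorSource(source)
  L <- .assertCount(L, "L", min = 2L)
  withSeed(seed, {
    rows <- list()
    prov <- list()
    for (b in seq_along(batches)) {
      pooled <- do.call(rbind, lapply(batches[[b]], function(id) {
        dataMatrix(src$loader(id))
      }))
      if (nrow(pooled) < L) {
        stop(sprintf("batch %d has %d pooled windows; need at least L = %d",
                     b, nrow(pooled), L), call. = FALSE)
      }
      for (k in 2L:L) {
        fit <- kmeansFit(pooled, k, seed = NULL, nInit = nInit,
                         maxIter = maxIter, tol = tol, distance = distance)
        rows[[length(rows) + 1L]] <- centroids(fit)
        prov[[length(prov) + 1L]] <- data.frame(
          batch = b, k = k, cluster = seq_len(k),
          size = tabulate(clusterLabels(fit), k))
      }
    }
    new("AggregatedCentroids", data = do.call(rbind, rows),
        provenance = do.call(rbind, prov))
  })
}

## Reindex states by descending total occupancy across all subjects
## (ties to the lower original index) and remap the state vectors.
.reindexByOccupancy <- function(cent, svs, kOpt) {
  counts <- Reduce(`+`, lapply(svs, function(sv) tabulate(sv@labels, kOpt)))
  ord <- order(-counts, seq_len(kOpt))
  remap <- match(seq_len(kOpt), ord)
  svs <- lapply(svs, function(sv) {
    stateVector(remap[sv@labels], kOpt, subjectId(sv))
  })
  list(centroids = cent[ord, , drop = FALSE], stateVectors = svs)
}

.finishModel <- function(cent, elbow, tag, config, src) {
  kOpt <- selectedK(elbow)
  model0 <- new("StateModel", kOpt = kOpt, centroids = cent, elbow = elbow,
                pipelineTag = tag, config = config)
  svs <- lapply(src$ids, function(id) assignStates(model0, src$loader(id)))
  re <- .reindexByOccupancy(centroids(model0), svs, kOpt)
  model <- new("StateModel", kOpt = kOpt, centroids = re$centroids,
               elbow = elbow, pipelineTag = tag, config = config)
  names(re$stateVectors) <- src$ids
  list(model = model, stateVectors = re$stateVectors)
}

#' Run the two-step state-clustering pipeline
#'
#' Partitions subjects into disjoint batches, runs the first-step k sweep
#' per batch, elbow-selects the model order on the aggregated centroids,
#' fits the final k-means on the aggregated centroids, and assigns every
#' subject's windows to the nearest final state. States are indexed in
#' descending group occupancy.
#'
#' @param tensors a list of \linkS4class{DFNCTensor}, the path of a dFNC
#'   store directory (loaded lazily, one subject at a time), or
#'   \code{list(loader = function(id) ..., subjectIds = ...)}.
#' @param config a \code{\link{twoStepConfig}}.
#' @return list with \code{model} (a \linkS4class{StateModel}) and
#'   \code{stateVectors} (named list of \linkS4class{StateVector}).
#' @export
runTwoStep <- function(tensors, config) {
  if (!inherits(config, "TwoStepConfig")) {
    stop("config must be built with twoStepConfig()", call. = FALSE)
  }
  src <- .resolveTensorSource(tensors)
  withSeed(config$seed, {
    batches <- partitionSubjects(src$ids, config$m, seed = NULL,
                                 shuffle = config$shuffle)
    agg <- firstStepSweep(tensors, batches, config$L, seed = NULL,
                          nInit = config$nInit, maxIter = config$maxIter,
                          tol = config$tol, distance = config$distance)
    w <- if (config$weightBySize) pmax(agg@provenance$size, 1) else NULL
    elbow <- elbowSelect(dataMatrix(agg), config$kRange[1L], config$kRange[2L],
                         seed = NULL, method = config$elbowMethod,
                         nInit = config$nInit, maxIter = config$maxIter,
                         tol = config$tol, distance = config$distance,
                         weights = w)
    fit <- kmeansFit(dataMatrix(agg), selectedK(elbow), seed = NULL,
                     nInit = config$nInit, maxIter = config$maxIter,
                     tol = config$tol, distance = config$distance, weights = w)
    .finishModel(centroids(fit), elbow, "two_step", unclass(config), src)
  })
}

#' Run the conventional single-pass pipeline
#'
#' Pools every subject's tensor rows, elbow-selects the model order on the
#' pooled windows, fits one k-means at the selected order, and assigns
#' labels. Same state-indexing convention as \code{\link{runTwoStep}}.
#'
#' @param tensors as in \code{\link{runTwoStep}}.
#' @param kRange length-2 elbow search range.
#' @param seed integer seed.
#' @param elbowMethod,nInit,maxIter,tol,distance as in
#'   \code{\link{twoStepConfig}}.
#' @return list with \code{model} and \code{stateVectors}.
#' @export
runConventional <- function(tensors, kRange = c(2L, 10L), seed = 1L,
                            elbowMethod = "curvature", nInit = 10L,
                            maxIter = 300L, tol = 1e-4,
                            distance = "euclidean") {
  src <- .resolveTensorSource(tensors)
  if (length(kRange) != 2L) stop("kRange must be c(kMin, kMax)", call. = FALSE)
  withSeed(seed, {
    pooled <- do.call(rbind, lapply(src$ids, function(id) {
      Xi <- dataMatrix(src$loader(id))
      Xi
    }))
    elbow <- elbowSelect(pooled, kRange[1L], kRange[2L], seed = NULL,
                         method = elbowMethod, nInit = nInit,
                         maxIter = maxIter, tol = tol, distance = distance)
    fit <- kmeansFit(pooled, selectedK(elbow), seed = NULL, nInit = nInit,
                     maxIter = maxIter, tol = tol, distance = distance)
    cfg <- list(kRange = as.integer(kRange), seed = as.integer(seed),
                elbowMethod = elbowMethod, nInit = nInit, maxIter = maxIter,
                tol = tol, distance = distance)
    .finishModel(centroids(fit), elbow, "conventional", cfg, src)
  })
}

#' Assign a subject's windows to the nearest states
#'
#' Labels every tensor row with the index of the nearest model centroid
#' (squared Euclidean; ties to the lowest index).
#'
#' @param model a \linkS4class{StateModel}.
#' @param tensor a \linkS4class{DFNCTensor} with the model's feature width.
#' @return a \linkS4class{StateVector}.
#' @export
assignStates <- function(model, tensor) {
  stopifnot(is(model, "StateModel"), is(tensor, "DFNCTensor"))
  X <- dataMatrix(tensor)
  if (ncol(X) != ncol(centroids(model))) {
    stop(sprintf("tensor has %d features but the model expects %d",
                 ncol(X), ncol(centroids(model))), call. = FALSE)
  }
  D <- .pdist(X, centroids(model), "euclidean")
  stateVector(max.col(-D, ties.method = "first"), kOpt(model),
              subjectId(tensor))
}
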