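## Clustering quality (distance ratio), matched-state similarity between
## two state models, feature-level similarity, and the two-sample quality
## comparison.

#' Per-subject clustering-quality distance ratio
#'
#' For every window, the ratio of the summed Euclidean distance to the
#' other \code{K - 1} centroids over the Euclidean distance to the
#' window's own centroid; the subject-level quality \code{R_p} is the mean
#' over windows. Higher means crisper clustering. Own-centroid distances
#' below 1e-12 are floored at 1e-12 and the affected windows recorded.
#' Note the ratio sums over the other centroids, so it scales with
#' \code{K - 1}: compare only models with equal K.
#'
#' @param tensor a \linkS4class{DFNCTensor}.
#' @param model a \linkS4class{StateModel} with kOpt >= 2.
#' @param sv optional \linkS4class{StateVector} (computed by
#'   \code{\link{assignStates}} when omitted).
#' @return a \linkS4class{QualityReport}.
#' @export
distanceRatio <- function(tensor, model, sv = NULL) {
  stopifnot(is(tensor, "DFNCTensor"), is(model, "StateModel"))
  if (kOpt(model) < 2L) {
    stop("distance ratio is undefined for a single-state model", call. = FALSE)
  }
  if (is.null(sv)) sv <- assignStates(model, tensor)
  labels <- clusterLabels(sv)
  D <- sqrt(.pdist(dataMatrix(tensor), centroids(model), "euclidean"))
  dOwn <- D[cbind(seq_along(labels), labels)]
  dOthers <- rowSums(D) - dOwn
  floored <- which(dOwn < 1e-12)
  if (length(floored)) {
    message(sprintf("distanceRatio: floored %d zero own-centroid distance(s) at 1e-12 for subject '%s'",
                    length(floored), subjectId(tensor)))
    dOwn[floored] <- 1e-12
  }
  ratios <- dOthers / dOwn
  new("QualityReport", subjectId = subjectId(tensor), Rp = mean(ratios),
      ratios = ratios, flooredWindows = as.integer(floored))
}

## Hungarian algorithm (potentials / shortest augmenting path, O(n^3))
## for the square min-cost assignment problem. Returns, for each column,
## the assigned row.
.solveAssignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)   # p[j+1] = row matched to column j (0 = virtual col)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[j] <- p[j + 1L]
  assignment  # assignment[j] = row matched to column j
}

#' Match states between two centroid sets
#'
#' Finds the one-to-one assignment between the rows of two centroid
#' matrices that maximizes the summed Pearson correlation of paired
#' centroid vectors (optimal assignment); surplus states of the larger
#' set are reported unmatched.
#'
#' @param centroidsA K_A x F numeric matrix.
#' @param centroidsB K_B x F numeric matrix (same F).
#' @return a \linkS4class{StateMatching}.
#' @export
matchStates <- function(centroidsA, centroidsB) {
  A <- .assertFiniteMatrix(as.matrix(centroidsA), "centroidsA")
  B <- .assertFiniteMatrix(as.matrix(centroidsB), "centroidsB")
  if (ncol(A) != ncol(B)) {
    stop(sprintf("centroid sets have different feature widths (%d vs %d)",
                 ncol(A), ncol(B)), call. = FALSE)
  }
  if (ncol(A) < 2L) stop("need at least 2 features to correlate centroids",
                         call. = FALSE)
  corM <- stats::cor(t(A), t(B))
  if (any(!is.finite(corM))) {
    stop("undefined centroid correlation (zero-variance centroid)", call. = FALSE)
  }
  n <- max(nrow(A), nrow(B))
  ## pad to square with constant cost so real pairs drive the optimum
  cost <- matrix(0, n, n)
  cost[seq_len(nrow(A)), seq_len(nrow(B))] <- -corM
  rowOfCol <- .solveAssignment(cost)
  pairs <- cbind(A = rowOfCol, B = seq_len(n))
  keep <- pairs[, 1L] <= nrow(A) & pairs[, 2L] <= nrow(B)
  pairs <- pairs[keep, , drop = FALSE]
  pairs <- pairs[order(pairs[, 1L]), , drop = FALSE]
  cors <- corM[pairs]
  new("StateMatching", pairs = matrix(as.integer(pairs), ncol = 2L,
                                      dimnames = list(NULL, c("A", "B"))),
      correlations = as.numeric(cors),
      minCor = min(cors), meanCor = mean(cors),
      unmatchedA = setdiff(seq_len(nrow(A)), pairs[, 1L]),
      unmatchedB = setdiff(seq_len(nrow(B)), pairs[, 2L]))
}

#' Cross-pipeline similarity of a per-subject feature
#'
#' Plain Pearson correlation across subjects between the same feature
#' computed under two pipelines.
#'
#' @param valuesA,valuesB numeric vectors of equal length >= 3 with
#'   nonzero variance.
#' @return Pearson correlation.
#' @export
featureSimilarity <- function(valuesA, valuesB) {
  a <- as.numeric(valuesA)
  b <- as.numeric(valuesB)
  if (length(a) != length(b) || length(a) < 3L) {
    stop("need two equal-length vectors of at least 3 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("degenerate feature vector: zero variance", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Two-sample comparison of clustering quality
#'
#' Two-sample t-test between the per-subject distance ratios of two
#' pipelines (Welch by default; set \code{varEqual = TRUE} for the pooled
#' formulation).
#'
#' @param RpA,RpB numeric vectors of per-subject mean distance ratios.
#' @param varEqual use the pooled-variance t-test (default FALSE = Welch).
#' @return list with \code{statistic}, \code{pValue}, \code{direction}
#'   (sign of mean(A) - mean(B)) and \code{test}.
#' @export
compareQuality <- function(RpA, RpB, varEqual = FALSE) {
  a <- as.numeric(RpA)
  b <- as.numeric(RpB)
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    ## both groups constant: t.test() refuses; the limit is unambiguous
    d <- mean(a) - mean(b)
    return(list(statistic = if (d == 0) 0 else sign(d) * Inf,
                pValue = if (d == 0) 1 else 0,
                direction = sign(d),
                test = if (isTRUE(varEqual)) "pooled" else "welch"))
  }
  ht <- stats::t.test(a, b, var.equal = isTRUE(varEqual))
  list(statistic = unname(ht$statistic), pValue = ht$p.value,
       direction = sign(mean(a) - mean(b)),
       test = if (isTRUE(varEqual)) "pooled" else "welch")
}
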