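#' @import methods
#' @importFrom stats cor cov2cor sd t.test
#' @importFrom utils read.csv write.csv packageVersion
#' @importFrom MASS mvrnorm
#' @importFrom jsonlite read_json write_json
NULL

## Evaluate `code` under a temporary RNG state seeded with `seed`.
## seed = NULL means "use the current RNG stream" (callers that have
## already seeded an outer scope pass NULL down so one seed governs a
## whole pipeline run).
withSeed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

.assertCount <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

.assertFiniteMatrix <- function(X, name) {
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
  if (!all(is.finite(X))) {
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  }
  X
}

#' Row-major strict upper-triangle component pairs
#'
#' Enumerates the pairs (1,2),(1,3),...,(1,C),(2,3),... This fixed order
#' defines the connectivity-feature axis everywhere in the package
#' (\code{F = C(C-1)/2} features).
#'
#' @param C component count (>= 2).
#' @return F x 2 integer matrix with columns i and j, i < j.
#' @export
featurePairs <- function(C) {
  C <- .assertCount(C, "C", min = 2L)
  i <- rep(seq_len(C - 1L), times = (C - 1L):1L)
  j <- unlist(lapply(seq_len(C - 1L), function(a) (a + 1L):C), use.names = FALSE)
  cbind(i = i, j = as.integer(j))
}

#' Rebuild a connectivity matrix from one tensor row
#'
#' Inverse of the upper-triangle vectorization: returns the symmetric
#' C x C correlation matrix (unit diagonal) whose strict upper triangle,
#' read in \code{\link{featurePairs}} order, equals \code{v}.
#'
#' @param v feature vector of length C(C-1)/2.
#' @param C component count.
#' @return symmetric C x C matrix with unit diagonal.
#' @export
unvectorizeConnectivity <- function(v, C) {
  fp <- featurePairs(C)
  if (length(v) != nrow(fp)) {
    stop(sprintf("feature vector has length %d; expected C(C-1)/2 = %d",
                 length(v), nrow(fp)), call. = FALSE)
  }
  M <- diag(1, C)
  M[fp] <- v
  M[fp[, c(2L, 1L)]] <- v
  M
}

## Timestamped progress line used by the pipeline drivers and the CLI.
.logStage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- force(expr)
  dt <- proc.time()[["elapsed"]] - t0
  message(sprintf("[%s] %s (%.2fs)", format(Sys.time(), "%H:%M:%S"), stage, dt))
  res
}
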