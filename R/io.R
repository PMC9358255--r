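## File formats: delimited text for component time courses (one file per
## subject plus a manifest) and a directory-backed store for dFNC tensors
## (JSON metadata + one full-precision TSV per subject). The store
## supports lazy one-subject-at-a-time loading, which is what lets the
## two-step pipeline run without the whole collection in memory.

DFNC_STORE_SCHEMA <- 1L

.fmtRow <- function(x) paste(sprintf("%.17g", x), collapse = "\t")

.writeNumericTSV <- function(X, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(apply(X, 1L, .fmtRow), con)
  invisible(path)
}

.readNumericTSV <- function(path, what = "file") {
  lines <- readLines(path)
  if (!length(lines)) stop(sprintf("%s '%s' is empty", what, path), call. = FALSE)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1L])[1L]
    stop(sprintf("%s '%s': row %d has %d fields, expected %d",
                 what, path, bad, ncols[bad], ncols[1L]), call. = FALSE)
  }
  matrix(as.numeric(unlist(rows, use.names = FALSE)), nrow = length(rows),
         byrow = TRUE)
}

.sanitizeId <- function(id) gsub("[^A-Za-z0-9._-]", "_", id)

#' Read component time courses from a manifest
#'
#' The manifest is a CSV with columns \code{subject_id} and \code{path}
#' (relative paths resolved against the manifest's directory). Each
#' referenced file is a delimited matrix (TSV or CSV, optional header),
#' rows = timepoints, columns = components. All subjects must share the
#' same component count.
#'
#' @param manifest path to the manifest CSV.
#' @return list of \linkS4class{ComponentTimeCourses}.
#' @export
readTimecourses <- function(manifest) {
  if (!file.exists(manifest)) {
    stop(sprintf("manifest '%s' does not exist", manifest), call. = FALSE)
  }
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "path") %in% names(man))) {
    stop("manifest must have columns subject_id and path", call. = FALSE)
  }
  base <- dirname(normalizePath(manifest))
  tcs <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!grepl("^(/|[A-Za-z]:)", p)) p <- file.path(base, p)
    if (!file.exists(p)) {
      stop(sprintf("time-course file '%s' (subject '%s') does not exist",
                   p, man$subject_id[i]), call. = FALSE)
    }
    lines <- readLines(p)
    if (!length(lines)) stop(sprintf("file '%s' is empty", p), call. = FALSE)
    sep <- if (grepl("\t", lines[1L])) "\t" else ","
    rows <- strsplit(lines, sep, fixed = TRUE)
    first <- suppressWarnings(as.numeric(rows[[1L]]))
    if (anyNA(first)) rows <- rows[-1L]  # header row
    if (!length(rows)) stop(sprintf("file '%s' has no data rows", p), call. = FALSE)
    ncols <- lengths(rows)
    if (length(unique(ncols)) != 1L) {
      bad <- which(ncols != ncols[1L])[1L]
      stop(sprintf("file '%s': row %d has %d fields, expected %d",
                   p, bad, ncols[bad], ncols[1L]), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(unlist(rows, use.names = FALSE)))
    if (anyNA(vals)) {
      idx <- which(is.na(vals))[1L] - 1L
      stop(sprintf("file '%s': non-numeric value at row %d, column %d",
                   p, idx %/% ncols[1L] + 1L, idx %% ncols[1L] + 1L),
           call. = FALSE)
    }
    componentTimeCourses(matrix(vals, nrow = length(rows), byrow = TRUE),
                         subjectId = man$subject_id[i])
  })
  C <- vapply(tcs, function(tc) ncol(dataMatrix(tc)), integer(1))
  if (length(unique(C)) != 1L) {
    stop(sprintf("inconsistent component counts across subjects: %s",
                 paste(sprintf("%s=%d", man$subject_id, C), collapse = ", ")),
         call. = FALSE)
  }
  tcs
}

#' Write component time courses and a manifest
#'
#' Writes one full-precision TSV per subject plus \code{manifest.csv};
#' values round-trip float64 exactly through
#' \code{\link{readTimecourses}}.
#'
#' @param tcs list of \linkS4class{ComponentTimeCourses}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeTimecourses <- function(tcs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(tcs, subjectId, character(1))
  files <- paste0(.sanitizeId(ids), ".tsv")
  for (i in seq_along(tcs)) {
    .writeNumericTSV(dataMatrix(tcs[[i]]), file.path(dir, files[i]))
  }
  man <- data.frame(subject_id = ids, path = files)
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE, quote = FALSE)
  invisible(manPath)
}

#' Write dFNC tensors to a store directory
#'
#' Persists a collection of per-subject tensors as \code{meta.json}
#' (schema version, feature index, per-subject window starts) plus one
#' full-precision TSV per subject. Stored float64 values round-trip
#' exactly.
#'
#' @param tensors list of \linkS4class{DFNCTensor} sharing one feature
#'   index.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeDfncStore <- function(tensors, dir) {
  if (!length(tensors)) stop("no tensors to write", call. = FALSE)
  fi <- featureIndex(tensors[[1L]])
  for (tn in tensors) {
    if (!identical(featureIndex(tn), fi)) {
      stop(sprintf("subject '%s' has a different feature index", subjectId(tn)),
           call. = FALSE)
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(tensors, subjectId, character(1))
  if (anyDuplicated(ids)) stop("duplicate subject ids", call. = FALSE)
  files <- paste0(.sanitizeId(ids), ".tsv")
  subjects <- vector("list", length(tensors))
  for (i in seq_along(tensors)) {
    .writeNumericTSV(dataMatrix(tensors[[i]]), file.path(dir, files[i]))
    subjects[[i]] <- list(id = ids[i], file = files[i],
                          n_windows = nrow(dataMatrix(tensors[[i]])),
                          window_starts = windowStarts(tensors[[i]]))
  }
  meta <- list(schema_version = DFNC_STORE_SCHEMA,
               feature_index = unname(apply(fi, 1L, as.list)),
               fisher_z = tensors[[1L]]@fisherZ,
               subjects = subjects)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

.readStoreMeta <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) {
    stop(sprintf("'%s' is not a dFNC store (no meta.json)", dir), call. = FALSE)
  }
  meta <- jsonlite::read_json(metaPath)
  if (is.null(meta$schema_version) ||
      meta$schema_version != DFNC_STORE_SCHEMA) {
    stop(sprintf("dFNC store schema version mismatch: found %s, expected %d",
                 format(meta$schema_version), DFNC_STORE_SCHEMA), call. = FALSE)
  }
  if (is.null(meta$feature_index)) {
    stop("dFNC store is missing its feature_index", call. = FALSE)
  }
  meta
}

.metaFeatureIndex <- function(meta) {
  fi <- t(vapply(meta$feature_index, function(p) c(p[[1L]], p[[2L]]), numeric(2)))
  matrix(as.integer(fi), ncol = 2L, dimnames = list(NULL, c("i", "j")))
}

.loadStoreSubject <- function(dir, meta, id) {
  ids <- vapply(meta$subjects, function(s) s$id, character(1))
  hit <- which(ids == id)
  if (!length(hit)) {
    stop(sprintf("subject '%s' is not in the dFNC store", id), call. = FALSE)
  }
  s <- meta$subjects[[hit]]
  X <- .readNumericTSV(file.path(dir, s$file), "tensor file")
  new("DFNCTensor", subjectId = s$id, data = X,
      windowStarts = as.integer(unlist(s$window_starts)),
      featureIndex = .metaFeatureIndex(meta),
      fisherZ = isTRUE(meta$fisher_z))
}

#' Subject identifiers of a dFNC store
#'
#' @param dir store directory written by \code{\link{writeDfncStore}}.
#' @return character vector of subject ids.
#' @export
dfncStoreSubjects <- function(dir) {
  meta <- .readStoreMeta(dir)
  vapply(meta$subjects, function(s) s$id, character(1))
}

#' Lazy per-subject loader over a dFNC store
#'
#' Returns a function that materializes one subject's tensor on demand;
#' nothing else is read, which honors the pipeline's partial-loading
#' contract.
#'
#' @param dir store directory.
#' @return function(id) returning a \linkS4class{DFNCTensor}.
#' @export
dfncStoreLoader <- function(dir) {
  meta <- .readStoreMeta(dir)
  force(dir)
  function(id) .loadStoreSubject(dir, meta, id)
}

#' Read all tensors from a dFNC store
#'
#' @param dir store directory.
#' @param subjects optional subset of subject ids.
#' @return named list of \linkS4class{DFNCTensor}.
#' @export
readDfncStore <- function(dir, subjects = NULL) {
  meta <- .readStoreMeta(dir)
  ids <- vapply(meta$subjects, function(s) s$id, character(1))
  if (!is.null(subjects)) ids <- ids[ids %in% subjects]
  out <- lapply(ids, function(id) .loadStoreSubject(dir, meta, id))
  names(out) <- ids
  out
}
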