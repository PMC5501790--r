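#' Read and write ROI time-series matrices
#'
#' Time series are exchanged as plain delimited text (comma or tab,
#' auto-detected on read), rows = time points, columns = ROIs, with an
#' optional single header row of ROI labels. `writeTimeSeries()` prints
#' values with 10 significant digits, so `readTimeSeries(writeTimeSeries())`
#' round-trips to that precision.
#'
#' @param path file path.
#' @param ts a [SubjectTimeSeries-class].
#' @param subjectId subject label for the object read in; defaults to the
#'   file name without extension.
#' @param sep field separator for writing, `","` (default) or `"\t"`.
#' @return `readTimeSeries()` returns a [SubjectTimeSeries-class];
#'   `writeTimeSeries()` returns `path` invisibly.
#' @export
readTimeSeries <- function(path, subjectId = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  cells <- lapply(cells, trimws)

  first <- suppressWarnings(as.numeric(cells[[1L]]))
  hasHeader <- anyNA(first)
  labels <- NULL
  if (hasHeader) {
    labels <- cells[[1L]]
    cells <- cells[-1L]
  }
  if (length(cells) < 3L)
    stop("fewer than 3 time points in ", path, call. = FALSE)

  ncols <- length(cells[[1L]])
  widths <- lengths(cells)
  if (any(widths != ncols)) {
    bad <- which(widths != ncols)[1L]
    stop(sprintf("ragged row %d in %s: %d fields, expected %d",
                 bad + hasHeader, path, widths[bad], ncols), call. = FALSE)
  }
  vals <- suppressWarnings(vapply(cells, as.numeric, numeric(ncols)))
  vals <- if (ncols == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value at row %d, column %d of %s",
                 bad[["row"]] + hasHeader, bad[["col"]], path),
         call. = FALSE)
  }
  colnames(vals) <- if (hasHeader) labels else paste0("ROI", seq_len(ncols))
  new("SubjectTimeSeries", values = vals, subjectId = subjectId)
}

#' @rdname readTimeSeries
#' @export
writeTimeSeries <- function(ts, path, sep = ",") {
  stopifnot(is(ts, "SubjectTimeSeries"))
  v <- ts@values
  rows <- apply(v, 1L, function(r)
    paste(sprintf("%.10g", r), collapse = sep))
  writeLines(c(paste(colnames(v), collapse = sep), rows), path)
  invisible(path)
}

#' Read or write a cohort via a manifest file
#'
#' A cohort is a directory of one time-series file per subject plus a
#' manifest (`manifest.txt`) listing the subject file names in order, one
#' per line.
#'
#' @param manifestPath path to the manifest file; subject paths inside it
#'   are resolved relative to its directory.
#' @param cohort list of [SubjectTimeSeries-class].
#' @param dir output directory (created if needed).
#' @return `readCohort()`: a list of [SubjectTimeSeries-class];
#'   `writeCohort()`: the manifest path, invisibly.
#' @export
readCohort <- function(manifestPath) {
  files <- readLines(manifestPath)
  files <- files[nzchar(trimws(files))]
  if (!length(files)) stop("empty cohort manifest: ", manifestPath, call. = FALSE)
  base <- dirname(manifestPath)
  lapply(files, function(f) readTimeSeries(file.path(base, f)))
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort, function(ts) {
    f <- paste0(ts@subjectId, ".csv")
    writeTimeSeries(ts, file.path(dir, f))
    f
  }, character(1))
  manifest <- file.path(dir, "manifest.txt")
  writeLines(files, manifest)
  invisible(manifest)
}
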