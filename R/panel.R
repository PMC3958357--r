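#' Construct a time-series panel
#'
#' A panel bundles one multivariate time series per individual (rows =
#' scans, columns = ROIs) together with individual IDs and shared ROI
#' labels. Missing frames (e.g. motion-scrubbed scans) are `NA` placeholder
#' rows so that the temporal ordering of scans is retained.
#'
#' @param series list of numeric T x p matrices, one per individual. T may
#'   differ across individuals; p must not.
#' @param ids character vector of unique individual identifiers; defaults
#'   to names of `series` or `ind001`-style labels.
#' @param roi_labels character vector of length p naming the ROI columns.
#' @return An object of class `ts_panel`.
#' @export
ts_panel <- function(series, ids = NULL, roi_labels = NULL) {
  if (!is.list(series) || length(series) == 0L)
    stop("`series` must be a non-empty list of matrices")
  series <- lapply(series, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    m
  })
  p <- ncol(series[[1L]])
  ok <- vapply(series, ncol, 0L) == p
  if (!all(ok))
    stop("inconsistent ROI count across individuals: ",
         paste(which(!ok), collapse = ", "))
  if (is.null(ids)) ids <- names(series)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sprintf("ind%03d", seq_along(series))
  if (anyDuplicated(ids)) stop("individual IDs must be unique")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%02d", seq_len(p))
  if (length(roi_labels) != p)
    stop("`roi_labels` must have length ", p)
  names(series) <- ids
  structure(list(series = series, ids = ids, roi_labels = roi_labels,
                 p = p),
            class = "ts_panel")
}

#' @export
print.ts_panel <- function(x, ...) {
  tt <- vapply(x$series, nrow, 0L)
  cat("<ts_panel> ", length(x$ids), " individuals, ", x$p, " ROIs, T = ",
      min(tt), if (min(tt) != max(tt)) paste0("-", max(tt)), "\n", sep = "")
  invisible(x)
}

#' @export
length.ts_panel <- function(x) length(x$series)

#' Subset a panel by individual
#' @param x a `ts_panel`
#' @param i index or ID vector
#' @param ... unused
#' @export
`[.ts_panel` <- function(x, i, ...) {
  ts_panel(x$series[i], ids = x$ids[if (is.character(i)) match(i, x$ids) else i],
           roi_labels = x$roi_labels)
}
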