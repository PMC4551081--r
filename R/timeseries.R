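#' ROI time-series container
#'
#' Holds a p-variate region-of-interest (ROI) time series: p series
#' observed at T successive scans (repetition times).  Values are stored
#' internally as a p x T matrix.
#'
#' @param values numeric matrix of observations.  With
#'   \code{orientation = "time"} rows are time points (T x p); with
#'   \code{"roi"} rows are series (p x T).
#' @param labels optional character vector of p series labels; defaults
#'   to \code{ROI1..ROIp}.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param orientation which dimension of \code{values} indexes time.
#' @return an object of class \code{"roi_ts"} with elements
#'   \code{values} (p x T matrix), \code{labels}, \code{tr_seconds} and
#'   \code{centered}.
#' @export
roi_ts <- function(values, labels = NULL, tr_seconds = 2,
                   orientation = c("time", "roi")) {
  orientation <- match.arg(orientation)
  values <- as.matrix(values)
  if (orientation == "time") values <- t(values)
  p <- nrow(values); T <- ncol(values)
  if (p < 1) stop("need at least one series")
  if (T <= p) stop("series length T (", T, ") must exceed the number of series p (", p, ")")
  if (!all(is.finite(values))) stop("non-finite values in time series")
  if (!is.numeric(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be positive")
  if (is.null(labels)) labels <- paste0("ROI", seq_len(p))
  if (length(labels) != p) stop("length of labels (", length(labels),
                                ") does not match number of series (", p, ")")
  rownames(values) <- labels
  centered <- all(abs(rowMeans(values)) < 1e-10)
  structure(list(values = values, labels = labels,
                 tr_seconds = tr_seconds, centered = centered),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat("ROI time series: p =", nrow(x$values), "series, T =", ncol(x$values),
      "time points, TR =", x$tr_seconds, "s",
      if (x$centered) "(centered)" else "", "\n")
  cat("labels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @method as.matrix roi_ts
as.matrix.roi_ts <- function(x, ...) t(x$values)

#' @export
dim.roi_ts <- function(x) dim(x$values)

#' Center (and optionally standardize) each ROI series
#'
#' Removes the sample mean of every series so that the zero-mean moment
#' structure assumed by the models holds exactly.  Standardization to
#' unit variance is optional and off by default, since the models
#' constrain only the mean.
#'
#' @param ts an object to center.
#' @param standardize also divide each series by its standard deviation.
#' @param ... passed to methods.
#' @return the centered object, with its \code{centered} flag set.
#' @export
center <- function(ts, ...) UseMethod("center")

#' @rdname center
#' @export
center.roi_ts <- function(ts, standardize = FALSE, ...) {
  if (ts$centered && !standardize) return(ts)   # idempotent, bit-exact
  v <- ts$values - rowMeans(ts$values)
  if (standardize) {
    s <- apply(v, 1, sd)
    s[s == 0] <- 1
    v <- v / s
  }
  ts$values <- v
  ts$centered <- TRUE
  ts
}

#' @rdname center
#' @export
center.matrix <- function(ts, standardize = FALSE, ...) {
  v <- ts - rowMeans(ts)
  if (standardize) {
    s <- apply(v, 1, sd); s[s == 0] <- 1; v <- v / s
  }
  v
}

.detect_delim <- function(line) if (grepl("\t", line)) "\t" else ","

#' Read an ROI time series from a delimited text file
#'
#' Reads TSV or CSV exports of ROI time courses.  By default rows are
#' time points and an optional single header row supplies the labels;
#' the delimiter is auto-detected from tab or comma.
#'
#' @param path file to read.
#' @param orientation \code{"time"} (rows are time points, the default
#'   export layout) or \code{"roi"} (rows are series).
#' @param delimiter field separator; \code{NULL} auto-detects tab vs comma.
#' @param tr_seconds repetition time in seconds attached to the result.
#' @return a \code{\link{roi_ts}}.
#' @export
read_roi_ts <- function(path, orientation = c("time", "roi"),
                        delimiter = NULL, tr_seconds = 2) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path)
  if (is.null(delimiter)) delimiter <- .detect_delim(lines[[1]])
  rows <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1)
    stop("ragged rows in ", path, ": row widths ", paste(unique(widths), collapse = "/"))
  first <- trimws(rows[[1]])
  header <- any(is.na(suppressWarnings(as.numeric(first))))
  labels <- NULL
  if (header) {
    labels <- first
    rows <- rows[-1]
    if (!length(rows)) stop("no data rows in ", path)
  }
  num <- matrix(NA_real_, length(rows), widths[1])
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(trimws(rows[[i]])))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric cell at data row ", i, ", column ", j, " of ", path)
    }
    num[i, ] <- v
  }
  if (orientation == "roi") {
    # rows are series; header (if any) would have labelled columns = time
    roi_ts(t(num), labels = labels, tr_seconds = tr_seconds, orientation = "time")
  } else {
    roi_ts(num, labels = labels, tr_seconds = tr_seconds, orientation = "time")
  }
}

#' Write an ROI time series to a delimited text file
#'
#' Writes a T x p table with a header row of labels; the inverse of
#' \code{\link{read_roi_ts}}.
#'
#' @param ts a \code{\link{roi_ts}}.
#' @param path output file.
#' @param delimiter field separator (default tab).
#' @export
write_roi_ts <- function(ts, path, delimiter = "\t") {
  m <- t(ts$values)
  colnames(m) <- ts$labels
  write.table(format(m, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}
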