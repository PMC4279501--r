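#' Construct an accelerometer stream
#'
#' An `accel_stream` is a data frame with columns `time_s` (strictly
#' increasing timestamps in seconds, arbitrary origin) and `ax`, `ay`, `az`
#' (acceleration in m/s^2).  The axis convention follows a chest-mounted
#' phone: x lateral, y vertical, z horizontal.  Acceleration is specific
#' force, i.e. gravity-inclusive, so a resting sensor reads ay near 9.81.
#'
#' @param time_s Numeric vector of timestamps, strictly increasing.
#' @param ax,ay,az Numeric vectors of the same length as `time_s`.
#' @param meta Optional named list of provenance (device, nominal rate, ...).
#' @return An object of class `accel_stream` (a data frame).
#' @export
#' @examples
#' s <- accel_stream(c(0, 0.0125, 0.025), 0, c(9.81, 9.80, 9.82), 0)
#' nrow(s)
accel_stream <- function(time_s, ax, ay, az, meta = list()) {
  n <- length(time_s)
  df <- data.frame(time_s = as.numeric(time_s),
                   ax = rep_len(as.numeric(ax), n),
                   ay = rep_len(as.numeric(ay), n),
                   az = rep_len(as.numeric(az), n))
  structure(df, meta = meta, class = c("accel_stream", "data.frame"))
}

validate_stream <- function(stream, where = "stream") {
  need <- c("time_s", "ax", "ay", "az")
  if (!all(need %in% names(stream)))
    stop(where, ": missing column(s) ",
         paste(setdiff(need, names(stream)), collapse = ", "), call. = FALSE)
  for (col in need) {
    bad <- which(!is.finite(stream[[col]]))
    if (length(bad))
      stop(where, ": non-finite value in column '", col, "' at row ", bad[1],
           call. = FALSE)
  }
  t <- stream$time_s
  if (length(t) > 1L) {
    bad <- which(diff(t) <= 0)
    if (length(bad))
      stop(where, ": timestamps not strictly increasing at row ", bad[1] + 1L,
           call. = FALSE)
  }
  invisible(stream)
}

#' @export
print.accel_stream <- function(x, ...) {
  n <- nrow(x)
  dur <- if (n > 1) x$time_s[n] - x$time_s[1] else 0
  cat(sprintf("<accel_stream> %d samples over %.3f s", n, dur))
  if (n > 1) cat(sprintf(" (~%.1f Hz)", (n - 1) / dur))
  cat("\n")
  if (n) print.data.frame(utils::head(as.data.frame(x), 4))
  if (n > 4) cat("...\n")
  invisible(x)
}

#' Read / write accelerometer streams
#'
#' The stream CSV format has the exact header `time_s,ax,ay,az`, comma
#' separator, `.` decimal point.  The reader is tolerant of trailing
#' whitespace and CRLF line endings but strict about column names; it
#' validates monotone timestamps and rejects NaN/Inf cells.  Round-tripping
#' preserves values to better than 1e-9.
#'
#' @param path Path to a CSV file.
#' @return `read_stream` returns an [accel_stream()]; `write_stream`
#'   invisibly returns `path`.
#' @export
read_stream <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE, check.names = FALSE)
  names(df) <- trimws(names(df))
  need <- c("time_s", "ax", "ay", "az")
  if (!identical(sort(names(df)), sort(need)))
    stop("stream file ", path, ": expected columns ",
         paste(need, collapse = ","), ", found ",
         paste(names(df), collapse = ","), call. = FALSE)
  for (col in need) df[[col]] <- as.numeric(df[[col]])
  s <- accel_stream(df$time_s, df$ax, df$ay, df$az,
                    meta = list(source = path))
  validate_stream(s, where = path)
}

#' @param stream An [accel_stream()].
#' @rdname read_stream
#' @export
write_stream <- function(stream, path) {
  validate_stream(stream)
  df <- as.data.frame(stream)[c("time_s", "ax", "ay", "az")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gear label intervals
#'
#' Ground-truth gear annotations: half-open style intervals
#' `[start_s, end_s)` in seconds, each carrying one gear from
#' [gear_levels()].  Intervals within one set must be non-overlapping;
#' they are kept sorted by start time.  These stand in for the video gold
#' standard used to score the classifier.
#'
#' @param start_s,end_s Numeric vectors; `end_s > start_s` elementwise.
#' @param gear Character vector of gear labels.
#' @return An object of class `gear_labels` (a data frame with columns
#'   `start_s`, `end_s`, `gear`).
#' @export
#' @examples
#' gear_labels(c(0, 30), c(30, 60), c("G3", "G2L"))
gear_labels <- function(start_s, end_s, gear) {
  df <- data.frame(start_s = as.numeric(start_s),
                   end_s = as.numeric(end_s),
                   gear = as.character(gear))
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  out <- structure(df, class = c("gear_labels", "data.frame"))
  validate_labels(out)
}

validate_labels <- function(labels, where = "labels") {
  need <- c("start_s", "end_s", "gear")
  if (!all(need %in% names(labels)))
    stop(where, ": missing column(s) ",
         paste(setdiff(need, names(labels)), collapse = ", "), call. = FALSE)
  assert_gear(labels$gear)
  bad <- which(!(labels$end_s > labels$start_s))
  if (length(bad))
    stop(where, ": interval ", bad[1], " has end_s <= start_s", call. = FALSE)
  if (nrow(labels) > 1L) {
    ov <- which(labels$start_s[-1L] < labels$end_s[-nrow(labels)] - 1e-9)
    if (length(ov))
      stop(where, ": intervals ", ov[1], " and ", ov[1] + 1L, " overlap",
           call. = FALSE)
  }
  invisible(labels)
}

#' Read / write gear label intervals
#'
#' Label CSVs have the exact header `start_s,end_s,gear`.  Unknown gear
#' strings and overlapping intervals are rejected; intervals are returned
#' sorted by start time.
#'
#' @param path Path to a CSV file.
#' @return `read_labels` returns a [gear_labels()] data frame;
#'   `write_labels` invisibly returns `path`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE, check.names = FALSE,
                        colClasses = c("numeric", "numeric", "character"))
  names(df) <- trimws(names(df))
  need <- c("start_s", "end_s", "gear")
  if (!identical(sort(names(df)), sort(need)))
    stop("label file ", path, ": expected columns ",
         paste(need, collapse = ","), ", found ",
         paste(names(df), collapse = ","), call. = FALSE)
  gear_labels(df$start_s, df$end_s, trimws(df$gear))
}

#' @param labels A [gear_labels()] object.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  validate_labels(labels)
  utils::write.csv(as.data.frame(labels)[c("start_s", "end_s", "gear")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
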