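# Stream containers and CSV I/O.
#
# A device stream is a data.frame with numeric columns `t` (timestamp,
# minutes) and `x` (measurement value, e.g. bpm), timestamps strictly
# increasing, at least two rows. A collection of streams is a named list of
# such data.frames with class "ldp_streams"; names are device ids.

#' Construct a single device stream
#'
#' @param t numeric vector of timestamps (minutes); strictly increasing.
#' @param x numeric vector of measurements, same length as `t`.
#' @return A `data.frame` with columns `t` and `x`.
#' @examples
#' device_stream(1:5, c(70, 70, 72, 74, 73))
#' @export
device_stream <- function(t, x) {
  t <- as.numeric(t)
  x <- as.numeric(x)
  if (length(t) != length(x))
    stop("`t` and `x` must have the same length")
  if (length(t) < 2L)
    stop("a device stream needs at least 2 points")
  if (anyNA(t) || anyNA(x) || any(!is.finite(t)) || any(!is.finite(x)))
    stop("timestamps and values must be finite")
  if (any(diff(t) <= 0))
    stop("timestamps must be strictly increasing (no duplicates)")
  data.frame(t = t, x = x)
}

#' Assemble a stream collection from a long table
#'
#' Converts a long data frame with columns `device_id`, `timestamp`, `value`
#' into a named list of per-device streams (class `"ldp_streams"`), each
#' sorted by timestamp and validated.
#'
#' @param df data.frame with columns `device_id`, `timestamp`, `value`.
#' @return Named list of device streams, class `"ldp_streams"`.
#' @export
as_streams <- function(df) {
  need <- c("device_id", "timestamp", "value")
  if (!all(need %in% names(df)))
    stop("input must have columns device_id, timestamp, value")
  ids <- unique(as.character(df$device_id))
  out <- lapply(ids, function(id) {
    sub <- df[as.character(df$device_id) == id, , drop = FALSE]
    o <- order(sub$timestamp)
    tt <- as.numeric(sub$timestamp[o])
    if (anyDuplicated(tt))
      stop("duplicate timestamp in device '", id, "'")
    if (length(tt) < 2L)
      stop("device '", id, "' has fewer than 2 points")
    device_stream(tt, as.numeric(sub$value[o]))
  })
  names(out) <- ids
  structure(out, class = "ldp_streams")
}

#' Read device streams from CSV
#'
#' Expects a header `device_id,timestamp,value` with one observation per
#' row. Rows that do not parse as (label, number, number) raise an error
#' naming the offending line; duplicate timestamps within a device and
#' devices with fewer than two observations are rejected.
#'
#' @param path path to a CSV file.
#' @return Named list of device streams, class `"ldp_streams"`.
#' @seealso [write_streams()]
#' @export
read_streams <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  need <- c("device_id", "timestamp", "value")
  if (!identical(names(raw)[seq_along(need)], need))
    stop("expected CSV header 'device_id,timestamp,value' in ", path)
  ts <- suppressWarnings(as.numeric(raw$timestamp))
  vs <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(ts) | is.na(vs))
  if (length(bad))
    stop("cannot parse row at line ", bad[1] + 1L, " of ", path,
         ": '", paste(unlist(raw[bad[1], need]), collapse = ","), "'")
  as_streams(data.frame(device_id = raw$device_id, timestamp = ts,
                        value = vs, stringsAsFactors = FALSE))
}

#' Write device streams to CSV
#'
#' Inverse of [read_streams()]: numbers are written with enough digits that
#' reading the file back reproduces the collection exactly.
#'
#' @param streams an `"ldp_streams"` collection (or a single stream, which
#'   is written under device id `"d1"`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_streams <- function(streams, path) {
  if (is.data.frame(streams))
    streams <- structure(list(d1 = streams), class = "ldp_streams")
  rows <- lapply(names(streams), function(id) {
    s <- streams[[id]]
    data.frame(device_id = id,
               timestamp = sprintf("%.17g", s$t),
               value = sprintf("%.17g", s$x),
               stringsAsFactors = FALSE)
  })
  long <- if (length(rows)) do.call(rbind, rows) else
    data.frame(device_id = character(), timestamp = character(),
               value = character())
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Discrete derivative between two stream points
#'
#' Slope (x2 - x1) / (t2 - t1) between two consecutive observations; the
#' primitive behind salient-point identification. Vectorized.
#'
#' @param t1,x1 timestamp and value of the earlier point.
#' @param t2,x2 timestamp and value of the later point; `t2 > t1` required.
#' @return numeric slope(s).
#' @examples
#' derivative(1, 70, 3, 72)  # 1
#' @export
derivative <- function(t1, x1, t2, x2) {
  if (any(t2 <= t1))
    stop("derivative requires t2 > t1")
  (x2 - x1) / (t2 - t1)
}

# Per-point derivatives of a stream relative to the predecessor; first
# entry is NA (no predecessor).
stream_derivatives <- function(stream) {
  c(NA_real_, diff(stream$x) / diff(stream$t))
}

# All streams on one identical timestamp grid? Returns the grid or errors.
common_grid <- function(streams) {
  grid <- streams[[1]]$t
  for (s in streams)
    if (!isTRUE(all.equal(s$t, grid)))
      stop("all device streams must share an identical timestamp grid")
  grid
}

#' @export
print.ldp_streams <- function(x, ...) {
  n <- vapply(x, nrow, 1L)
  cat("Stream collection: ", length(x), " device(s), ",
      sum(n), " observations\n", sep = "")
  show <- utils::head(names(x), 8L)
  for (id in show)
    cat(sprintf("  %-12s n=%-5d t=[%g,%g] x=[%g,%g]\n", id, nrow(x[[id]]),
                min(x[[id]]$t), max(x[[id]]$t),
                min(x[[id]]$x), max(x[[id]]$x)))
  if (length(x) > 8L) cat("  ...\n")
  invisible(x)
}
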