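#' Read an epoch-level activity file
#'
#' Two plain-text CSV dialects are supported.
#'
#' * `"plain"` — the package's canonical interchange format: a header line
#'   `child_id,epoch_seconds,start_time`, one line of header values
#'   (timestamps ISO-8601, UTC), a column line `index,counts,steps`, then
#'   one row per epoch with a 0-based index.
#' * `"minimal"` — bare `timestamp,counts,steps` rows with a header; the
#'   epoch length is inferred from the (required uniform) spacing of the
#'   timestamps and the child id is taken from `child_id` or the file name.
#'
#' The reader validates rather than repairs: unparseable timestamps or
#' negative counts are rejected with an error, duplicated or non-monotone
#' timestamps are a data error naming the first offending row, and gaps
#' between recorded rows are an error (the monitor records contiguously),
#' so a loaded series is gap-free by construction.
#'
#' @param path Path to the CSV file.
#' @param dialect `"plain"` (default) or `"minimal"`.
#' @param child_id Identifier override for the `"minimal"` dialect;
#'   defaults to the file name without extension.
#' @return An [epoch_series()].
#' @export
read_epoch_file <- function(path, dialect = c("plain", "minimal"),
                            child_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "accel_format_error")
  }
  if (dialect == "plain") read_epoch_plain(path) else {
    read_epoch_minimal(path, child_id %||% sub("\\.[^.]*$", "", basename(path)))
  }
}

read_epoch_plain <- function(path) {
  lines <- readLines(path, n = 3L)
  if (length(lines) < 3L ||
      gsub("\\s", "", lines[1L]) != "child_id,epoch_seconds,start_time") {
    abort(sprintf("malformed header in %s: expected 'child_id,epoch_seconds,start_time'.",
                  path),
          class = "accel_format_error")
  }
  hdr <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  if (length(hdr) != 3L) {
    abort(sprintf("malformed header values in %s.", path),
          class = "accel_format_error")
  }
  epoch_seconds <- suppressWarnings(as.integer(hdr[2L]))
  start_time <- suppressWarnings(as.POSIXct(hdr[3L],
                                            tz = "UTC",
                                            tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                                           "%Y-%m-%d %H:%M:%S")))
  if (is.na(epoch_seconds) || is.na(start_time)) {
    abort(sprintf("malformed header values in %s (epoch_seconds or start_time).", path),
          class = "accel_format_error")
  }
  if (gsub("\\s", "", lines[3L]) != "index,counts,steps") {
    abort(sprintf("malformed column line in %s: expected 'index,counts,steps'.", path),
          class = "accel_format_error")
  }
  body <- read.csv(path, skip = 2L, header = TRUE, colClasses = "character")
  if (nrow(body) == 0L) {
    abort(sprintf("no epoch rows in %s.", path), class = "accel_data_error")
  }
  body$index <- suppressWarnings(as.numeric(body$index))
  body$counts <- suppressWarnings(as.numeric(body$counts))
  body$steps <- suppressWarnings(as.numeric(body$steps))
  if (any(is.na(body$index))) {
    abort(sprintf("unparseable epoch index at data row %d of %s.",
                  which(is.na(body$index))[1L], path),
          class = "accel_data_error")
  }
  d <- diff(body$index)
  if (any(d != 1)) {
    bad <- which(d != 1)[1L] + 1L
    what <- if (d[bad - 1L] <= 0) "non-monotone or duplicated" else "gapped"
    abort(sprintf("%s epoch index at data row %d of %s.", what, bad, path),
          class = "accel_data_error")
  }
  if (any(is.na(body$counts)) || any(is.na(body$steps)) ||
      any(body$counts < 0) || any(body$steps < 0)) {
    bad <- which(is.na(body$counts) | is.na(body$steps) |
                   body$counts < 0 | body$steps < 0)[1L]
    abort(sprintf("unparseable or negative counts/steps at data row %d of %s.",
                  bad, path),
          class = "accel_data_error")
  }
  epoch_series(hdr[1L], start_time + body$index[1L] * epoch_seconds,
               epoch_seconds, body$counts, body$steps)
}

read_epoch_minimal <- function(path, child_id) {
  body <- read.csv(path, header = TRUE, colClasses = "character")
  if (!identical(names(body), c("timestamp", "counts", "steps"))) {
    abort(sprintf("malformed header in %s: expected 'timestamp,counts,steps'.",
                  path),
          class = "accel_format_error")
  }
  ts <- as.POSIXct(body$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
  if (any(is.na(ts))) {
    abort(sprintf("unparseable timestamp at data row %d of %s.",
                  which(is.na(ts))[1L], path),
          class = "accel_data_error")
  }
  counts <- suppressWarnings(as.numeric(body$counts))
  steps <- suppressWarnings(as.numeric(body$steps))
  if (any(is.na(counts) | counts < 0 | is.na(steps) | steps < 0)) {
    bad <- which(is.na(counts) | counts < 0 | is.na(steps) | steps < 0)[1L]
    abort(sprintf("unparseable or negative counts/steps at data row %d of %s.",
                  bad, path),
          class = "accel_data_error")
  }
  d <- as.numeric(diff(ts), units = "secs")
  if (length(d) == 0L) {
    abort("minimal dialect needs at least two rows to infer the epoch length.",
          class = "accel_data_error")
  }
  if (any(d <= 0)) {
    abort(sprintf("non-monotone or duplicated timestamp at data row %d of %s.",
                  which(d <= 0)[1L] + 1L, path),
          class = "accel_data_error")
  }
  es <- d[1L]
  if (any(d != es)) {
    abort(sprintf("gap between recorded rows at data row %d of %s (monitor records contiguously).",
                  which(d != es)[1L] + 1L, path),
          class = "accel_data_error")
  }
  if (es <= 0 || 60 %% es != 0) {
    abort(sprintf("inferred epoch length %gs does not divide 60.", es),
          class = "accel_data_error")
  }
  epoch_series(child_id, ts[1L], es, counts, steps)
}

#' Write an epoch series to a CSV file
#'
#' Inverse of [read_epoch_file()]; round-tripping a well-formed series
#' through write/read is lossless in either dialect.
#'
#' @param series An [epoch_series()].
#' @param path Output path.
#' @param dialect `"plain"` (default) or `"minimal"`.
#' @return `path`, invisibly.
#' @export
write_epoch_file <- function(series, path, dialect = c("plain", "minimal")) {
  dialect <- match.arg(dialect)
  if (dialect == "plain") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("child_id,epoch_seconds,start_time",
                 paste(series$child_id[1L], epoch_length(series),
                       format(series$time[1L], "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                       sep = ",")),
               con)
    write.csv(data.frame(index = seq_len(nrow(series)) - 1L,
                         counts = series$counts, steps = series$steps),
              con, row.names = FALSE, quote = FALSE)
  } else {
    write.csv(data.frame(timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S",
                                            tz = "UTC"),
                         counts = series$counts, steps = series$steps),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
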