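#' Construct a raw accelerometer recording
#'
#' A `raw_recording` holds timestamped tri-axial samples before
#' standardization.  Timestamps are seconds relative to the first sample,
#' sorted, with exact duplicates collapsed (first occurrence kept).
#'
#' @param time numeric vector of timestamps in seconds (any origin).
#' @param xyz numeric matrix with one row per sample and columns x, y, z.
#' @param unit `"g"` or `"ms2"` (metres per second squared).
#' @param location sensor body location, one of `"thigh"`, `"waist"`,
#'   `"chest"`, `"arm"`, `"wrist"`, `"unspecified"`.
#' @param id opaque subject/session tag.
#' @return object of class `raw_recording` with elements `time` (seconds
#'   from first sample, strictly increasing), `xyz`, `unit`, `location`, `id`.
#' @export
raw_recording <- function(time, xyz, unit = c("g", "ms2"),
                          location = "unspecified", id = "recording") {
  unit <- match.arg(unit)
  location <- match.arg(location,
    c("unspecified", "thigh", "waist", "chest", "arm", "wrist"))
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("`xyz` must have exactly three columns")
  if (length(time) != nrow(xyz)) stop("`time` and `xyz` lengths differ")
  if (!all(is.finite(time)) || !all(is.finite(xyz)))
    stop("non-finite values in recording")
  ord <- order(time)
  time <- time[ord]; xyz <- xyz[ord, , drop = FALSE]
  keep <- !duplicated(time)
  time <- time[keep]; xyz <- xyz[keep, , drop = FALSE]
  structure(
    list(time = time - time[1L], xyz = unname(xyz), unit = unit,
         location = location, id = id),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s: %d samples over %.1f s, unit %s, location %s\n",
              x$id, length(x$time),
              if (length(x$time)) diff(range(x$time)) else 0,
              x$unit, x$location))
  invisible(x)
}

#' Read a tri-axial accelerometer CSV
#'
#' Expects a header row with a time column (numeric seconds or ISO-8601
#' timestamps) and three axis columns.  Rows are sorted by time and exact
#' duplicate timestamps dropped.
#'
#' @param path CSV file path.
#' @param unit declared unit of the axis columns, `"g"` or `"ms2"`.  No
#'   conversion is performed here; see [convert_to_g()].
#' @param columns named character vector mapping the roles `time`, `x`, `y`,
#'   `z` to column names in the file.
#' @param location,id metadata forwarded to [raw_recording()].
#' @return a [raw_recording()].
#' @export
read_accelerometer <- function(path, unit = c("g", "ms2"),
                               columns = c(time = "time", x = "x",
                                           y = "y", z = "z"),
                               location = "unspecified",
                               id = basename(path)) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty input file: ", path)
  missing_cols <- setdiff(unname(columns[c("time", "x", "y", "z")]), names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  tm <- df[[columns[["time"]]]]
  if (is.character(tm) || inherits(tm, "factor")) {
    parsed <- as.POSIXct(as.character(tm), tz = "UTC",
                         tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                        "%Y-%m-%d %H:%M:%OS"))
    if (anyNA(parsed))
      stop("unparseable timestamp at row ", which(is.na(parsed))[1L])
    tm <- as.numeric(parsed)
  }
  tm <- suppressWarnings(as.numeric(tm))
  if (anyNA(tm)) stop("non-numeric time value at row ", which(is.na(tm))[1L])
  ax <- lapply(c("x", "y", "z"), function(a) {
    v <- suppressWarnings(as.numeric(df[[columns[[a]]]]))
    if (anyNA(v))
      stop("non-numeric value in column '", columns[[a]], "' at row ",
           which(is.na(v))[1L])
    v
  })
  raw_recording(tm, cbind(ax[[1L]], ax[[2L]], ax[[3L]]), unit = unit,
                location = location, id = id)
}

# 1 g = 9.80665 m/s^2 (standard gravity)
STANDARD_GRAVITY <- 9.80665

#' Convert a recording to gravitational units
#'
#' Recordings in m/s\eqn{^2} are divided by the standard gravity
#' 9.80665 m/s\eqn{^2}; recordings already in g are returned unchanged.
#'
#' @param raw a [raw_recording()].
#' @return the recording with `unit == "g"`.
#' @export
convert_to_g <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  if (raw$unit == "g") return(raw)
  if (raw$unit != "ms2") stop("unknown unit tag: ", raw$unit)
  raw$xyz <- raw$xyz / STANDARD_GRAVITY
  raw$unit <- "g"
  raw
}

#' Resample a recording onto a uniform 10 Hz grid
#'
#' Each axis is linearly interpolated onto a 0.1 s grid anchored at the
#' first timestamp of each session.  The recording is split into sessions
#' wherever consecutive raw timestamps are more than `gap_threshold` apart;
#' no interpolation bridges a gap.  Sessions yielding fewer than 10 grid
#' samples (under one second) are dropped.
#'
#' @param raw a [raw_recording()] in g (see [convert_to_g()]).
#' @param gap_threshold seconds; default 1.
#' @return object of class `uniform_recording`: list with `sessions` (each a
#'   list with `start` time and `xyz` matrix on the exact 10 Hz grid), `fs`
#'   (10), `location`, `id`.
#' @export
resample_10hz <- function(raw, gap_threshold = 1) {
  stopifnot(inherits(raw, "raw_recording"))
  if (raw$unit != "g")
    stop("recording must be in g before resampling; see convert_to_g()")
  fs <- 10
  tm <- raw$time
  breaks <- which(diff(tm) > gap_threshold)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(tm))
  sessions <- list()
  for (k in seq_along(starts)) {
    idx <- starts[k]:ends[k]
    if (length(idx) < 2L) next
    t0 <- tm[idx[1L]]
    span <- tm[idx[length(idx)]] - t0
    grid <- t0 + seq(0, span, by = 1 / fs)
    if (length(grid) < fs) next   # under one second
    xyz <- vapply(1:3, function(a)
      approx(tm[idx], raw$xyz[idx, a], xout = grid)$y,
      numeric(length(grid)))
    sessions[[length(sessions) + 1L]] <- list(start = t0, xyz = xyz)
  }
  if (length(sessions) == 0L)
    warning("no session of at least one second; empty recording returned")
  structure(list(sessions = sessions, fs = fs, location = raw$location,
                 id = raw$id),
            class = "uniform_recording")
}

#' @export
print.uniform_recording <- function(x, ...) {
  n <- vapply(x$sessions, function(s) nrow(s$xyz), integer(1))
  cat(sprintf("<uniform_recording> %s: %d session(s), %.1f s total at %d Hz, location %s\n",
              x$id, length(n), sum(n) / x$fs, x$fs, x$location))
  invisible(x)
}

#' Vector-magnitude transform
#'
#' Reduces each tri-axial sample to \eqn{v = \sqrt{x_1^2+x_2^2+x_3^2} - 1},
#' removing static gravity and any dependence on device orientation, and
#' delimits consecutive non-overlapping one-second windows (10 samples; a
#' trailing partial window is dropped).
#'
#' @param u a `uniform_recording`.
#' @return object of class `magnitude_series`: list with `sessions` (each a
#'   list with `start`, `v`, and `n_sec` whole seconds), `fs`, `location`, `id`.
#' @export
vector_magnitude <- function(u) {
  stopifnot(inherits(u, "uniform_recording"))
  sessions <- lapply(u$sessions, function(s) {
    v <- sqrt(rowSums(s$xyz^2)) - 1
    list(start = s$start, v = v, n_sec = length(v) %/% u$fs)
  })
  structure(list(sessions = sessions, fs = u$fs, location = u$location,
                 id = u$id),
            class = "magnitude_series")
}

#' @export
print.magnitude_series <- function(x, ...) {
  cat(sprintf("<magnitude_series> %s: %d session(s), %d whole second(s)\n",
              x$id, length(x$sessions),
              sum(vapply(x$sessions, `[[`, integer(1), "n_sec"))))
  invisible(x)
}

# Per-second peak-to-peak amplitudes of one session's magnitude vector.
second_p2p <- function(v, fs = 10) {
  n_sec <- length(v) %/% fs
  if (n_sec == 0L) return(numeric(0))
  m <- matrix(v[seq_len(n_sec * fs)], nrow = fs)
  apply(m, 2L, function(w) max(w) - min(w))
}

# Per-second per-axis standard deviations for one session (fs x 3 windows).
second_axis_sd <- function(xyz, fs = 10) {
  n_sec <- nrow(xyz) %/% fs
  if (n_sec == 0L) return(matrix(numeric(0), ncol = 3L))
  out <- matrix(NA_real_, n_sec, 3L)
  for (k in seq_len(n_sec)) {
    idx <- ((k - 1L) * fs + 1L):(k * fs)
    out[k, ] <- apply(xyz[idx, , drop = FALSE], 2L, sd)
  }
  out
}
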