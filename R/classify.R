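#' Per-second amplitude screen
#'
#' A second is valid when the peak-to-peak amplitude of the magnitude
#' signal within its 10 samples is at least `A`; seconds below the
#' threshold are excluded from the wavelet stage.
#'
#' @param m a `magnitude_series` (see [vector_magnitude()]).
#' @param A amplitude threshold in g.
#' @return list with one element per session: list with `valid` (logical
#'   per-second mask) and `p2p` (per-second peak-to-peak amplitudes).
#' @export
amplitude_screen <- function(m, A) {
  stopifnot(inherits(m, "magnitude_series"), A > 0)
  lapply(m$sessions, function(s) {
    p2p <- second_p2p(s$v, m$fs)
    list(p2p = p2p, valid = p2p >= A)
  })
}

#' Harmonic-ratio walking test for one scalogram column
#'
#' A second passes (`w = 1`) when the in-band wavelet maximum dominates
#' both out-of-band maxima:
#' \deqn{\alpha \max_{f \in [f_{min}, f_{max}]} C(f) > \max_{f < f_{min}} C(f)
#'   \;\wedge\; \beta \max_{f \in [f_{min}, f_{max}]} C(f) >
#'   \max_{f > f_{max}} C(f),}
#' with strict inequalities and the maximum over an empty out-of-band set
#' defined as 0.
#'
#' @param column numeric vector of coefficient magnitudes on `freq`.
#' @param freq analysis frequency grid in Hz.
#' @param params a [walk_params()] object.
#' @return integer 0 or 1.
#' @export
harmonic_test <- function(column, freq, params) {
  b <- band_masks(freq, params$f_min, params$f_max)
  m_in <- if (any(b$inb)) max(column[b$inb]) else 0
  m_lo <- if (any(b$low)) max(column[b$low]) else 0
  m_hi <- if (any(b$high)) max(column[b$high]) else 0
  as.integer(params$alpha * m_in > m_lo && params$beta * m_in > m_hi)
}

# Frequency-band membership with a small tolerance against grid rounding.
band_masks <- function(freq, f_min, f_max, eps = 1e-9) {
  list(inb = freq >= f_min - eps & freq <= f_max + eps,
       low = freq < f_min - eps,
       high = freq > f_max + eps)
}

#' Minimum-duration filter
#'
#' A second is walking when it belongs to a maximal run of consecutive
#' `w = 1` seconds of length at least `T_min`; every second of a qualifying
#' run is labelled walking.
#'
#' @param w integer/logical per-second flags for one session.
#' @param T_min minimum run length in seconds.
#' @return logical walking mask of the same length.
#' @export
duration_filter <- function(w, T_min) {
  w <- as.integer(w) == 1L
  out <- rep(FALSE, length(w))
  runs <- true_runs(w)
  keep <- runs[runs$end - runs$start + 1L >= T_min, , drop = FALSE]
  for (i in seq_len(nrow(keep))) out[keep$start[i]:keep$end[i]] <- TRUE
  out
}

#' Classify walking seconds, cadence, bouts and steps
#'
#' Runs the full four-block pipeline on a standardized recording: vector
#' magnitude, per-second amplitude screen, Morse-wavelet scalogram over the
#' retained high-amplitude segments, the harmonic-ratio test per second,
#' and the minimum-duration filter.  For every walking second, cadence is
#' the in-band frequency of maximal wavelet magnitude (ties broken toward
#' the lower frequency); bouts are maximal walking runs and a bout's step
#' count is its cadence sum rounded half-up.
#'
#' @param recording a `uniform_recording` in g (see [resample_10hz()]).
#' @param params a [walk_params()] object, e.g. from [preset_params()].
#' @param freq_grid analysis frequencies; default [default_freq_grid()].
#' @param gamma,P2,pad_seconds Morse transform settings; see
#'   [build_morse_bank()].
#' @return object of class `walk_result`: list with `seconds` (data.frame:
#'   `session`, `second`, `time_start`, `p2p`, `valid`, `w`, `walking`,
#'   `cadence`), `bouts` (data.frame: `session`, `start`, `end`, `seconds`,
#'   `mean_cadence`, `steps`), `summary` (walking seconds, bouts, steps),
#'   and `params`.
#' @export
classify <- function(recording, params = preset_params("smartphone"),
                     freq_grid = default_freq_grid(),
                     gamma = 3, P2 = 60, pad_seconds = 5) {
  stopifnot(inherits(recording, "uniform_recording"),
            inherits(params, "walk_params"))
  fs <- recording$fs
  m <- vector_magnitude(recording)
  screens <- amplitude_screen(m, params$A)
  bank_cache <- new.env(parent = emptyenv())
  sec_rows <- list()
  bout_rows <- list()

  for (si in seq_along(m$sessions)) {
    s <- m$sessions[[si]]
    n_sec <- s$n_sec
    if (n_sec == 0L) next
    scr <- screens[[si]]
    w <- integer(n_sec)
    cadence <- rep(NA_real_, n_sec)
    segs <- true_runs(scr$valid)
    for (g in seq_len(nrow(segs))) {
      sec_lo <- segs$start[g]; sec_hi <- segs$end[g]
      samp <- ((sec_lo - 1L) * fs + 1L):(sec_hi * fs)
      key <- as.character(length(samp))
      if (is.null(bank_cache[[key]]))
        bank_cache[[key]] <- build_morse_bank(
          gamma = gamma, P2 = P2, freq_grid = freq_grid,
          segment_length = length(samp), sample_rate = fs,
          pad_seconds = pad_seconds)
      sg <- cwt_segment(s$v[samp], bank_cache[[key]])
      b <- band_masks(sg$freq, params$f_min, params$f_max)
      in_freq <- sg$freq[b$inb]
      for (k in seq_len(ncol(sg$coef))) {
        col <- sg$coef[, k]
        sec <- sec_lo + k - 1L
        w[sec] <- harmonic_test(col, sg$freq, params)
        cadence[sec] <- in_freq[which.max(col[b$inb])]
      }
    }
    walking <- duration_filter(w, params$T_min)
    cadence[!walking] <- NA_real_
    t_start <- recording$sessions[[si]]$start + (seq_len(n_sec) - 1L)
    sec_rows[[length(sec_rows) + 1L]] <- data.frame(
      session = si, second = seq_len(n_sec), time_start = t_start,
      p2p = scr$p2p, valid = scr$valid, w = w, walking = walking,
      cadence = cadence)
    bouts <- true_runs(walking)
    for (bi in seq_len(nrow(bouts))) {
      idx <- bouts$start[bi]:bouts$end[bi]
      cs <- cadence[idx]
      bout_rows[[length(bout_rows) + 1L]] <- data.frame(
        session = si,
        start = t_start[bouts$start[bi]],
        end = t_start[bouts$end[bi]] + 1,
        seconds = length(idx),
        mean_cadence = mean(cs),
        steps = floor(sum(cs) + 0.5))  # round half-up at bout level
    }
  }

  seconds <- if (length(sec_rows)) do.call(rbind, sec_rows) else
    data.frame(session = integer(0), second = integer(0),
               time_start = numeric(0), p2p = numeric(0),
               valid = logical(0), w = integer(0), walking = logical(0),
               cadence = numeric(0))
  bouts <- if (length(bout_rows)) do.call(rbind, bout_rows) else
    data.frame(session = integer(0), start = numeric(0), end = numeric(0),
               seconds = integer(0), mean_cadence = numeric(0),
               steps = numeric(0))
  structure(list(
    seconds = seconds, bouts = bouts,
    summary = list(total_seconds = nrow(seconds),
                   walking_seconds = sum(seconds$walking),
                   n_bouts = nrow(bouts),
                   total_steps = sum(bouts$steps)),
    params = params, id = recording$id, location = recording$location),
    class = "walk_result")
}

#' @export
print.walk_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<walk_result> %s [%s preset]\n", x$id, x$params$preset))
  cat(sprintf("  %d / %d seconds walking in %d bout(s); %d steps\n",
              s$walking_seconds, s$total_seconds, s$n_bouts, s$total_steps))
  invisible(x)
}

#' @export
summary.walk_result <- function(object, ...) {
  s <- object$summary
  cad <- object$seconds$cadence[object$seconds$walking]
  out <- list(
    id = object$id, preset = object$params$preset,
    total_seconds = s$total_seconds, walking_seconds = s$walking_seconds,
    walking_fraction = if (s$total_seconds) s$walking_seconds / s$total_seconds else NA,
    n_bouts = s$n_bouts, total_steps = s$total_steps,
    median_cadence = if (length(cad)) median(cad) else NA_real_,
    bouts = object$bouts)
  class(out) <- "summary.walk_result"
  out
}

#' @export
print.summary.walk_result <- function(x, ...) {
  cat(sprintf("Walking recognition summary for %s (%s preset)\n",
              x$id, x$preset))
  cat(sprintf("  walking: %d of %d s (%.1f%%), %d bout(s), %d steps\n",
              x$walking_seconds, x$total_seconds,
              100 * x$walking_fraction, x$n_bouts, x$total_steps))
  if (!is.na(x$median_cadence))
    cat(sprintf("  median cadence: %.2f steps/s\n", x$median_cadence))
  if (nrow(x$bouts)) {
    cat("  bouts:\n")
    print(x$bouts, row.names = FALSE)
  }
  invisible(x)
}

#' Plot per-second classification of a recording
#'
#' Shows the per-second peak-to-peak amplitude with detected walking
#' seconds shaded and per-second cadence overlaid on a secondary axis.
#'
#' @param x a `walk_result`.
#' @param session session index to plot; default 1.
#' @param ... passed to [plot()].
#' @export
plot.walk_result <- function(x, session = 1L, ...) {
  sec <- x$seconds[x$seconds$session == session, , drop = FALSE]
  if (!nrow(sec)) stop("no seconds in session ", session)
  t <- sec$time_start
  plot(t, sec$p2p, type = "h", col = "grey50",
       xlab = "time (s)", ylab = "peak-to-peak amplitude (g)",
       main = sprintf("%s: session %d", x$id, session), ...)
  abline(h = x$params$A, lty = 2)
  runs <- true_runs(sec$walking)
  for (i in seq_len(nrow(runs)))
    rect(t[runs$start[i]], 0, t[runs$end[i]] + 1, max(sec$p2p),
         col = adjustcolor("forestgreen", 0.2), border = NA)
  if (any(sec$walking)) {
    scale <- max(sec$p2p) / 4.5
    points(t + 0.5, sec$cadence * scale, pch = 16, cex = 0.4,
           col = "darkblue")
    axis(4, at = (1:4) * scale, labels = 1:4)
  }
  invisible(x)
}
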