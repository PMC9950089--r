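#' Generalized Morse wavelet filter bank
#'
#' Builds one frequency-domain kernel per analysis frequency for segments of
#' a given length.  The generalized Morse wavelet is the analytic family
#' \deqn{\Psi_{P,\gamma}(\omega) = U(\omega)\, a_{P,\gamma}\,
#'   \omega^{P^2/\gamma} e^{-\omega^\gamma},}
#' where \eqn{U(\omega)} is the unit step.  With \eqn{\gamma = 3} the
#' wavelet is close to symmetric around its peak in both time and frequency;
#' \eqn{P^2} is the time-bandwidth product.  The unscaled peak sits at
#' \eqn{\omega_p = (P^2/\gamma^2)^{1/\gamma}}; each kernel is the wavelet
#' evaluated at \eqn{\omega_p\, f/f_a} over the FFT bin frequencies
#' \eqn{f}, so its peak response lands at the analysis frequency \eqn{f_a}.
#' Kernels are peak-normalized (maximum response 1) so that a unit-amplitude
#' sinusoid yields a scalogram peak of 1 at every analysis frequency, which
#' keeps the harmonic-ratio thresholds scale-consistent.
#'
#' @param gamma symmetry parameter; default 3.
#' @param P2 time-bandwidth product \eqn{P^2}; default 60.
#' @param freq_grid strictly increasing analysis frequencies in Hz; default
#'   0.5 to 5.0 Hz in 0.05 Hz steps.
#' @param segment_length segment length in samples (before padding).
#' @param sample_rate sampling rate in Hz; default 10.
#' @param pad_seconds reflect padding applied on each side of a segment
#'   before the transform; default 5 s.
#' @return object of class `morse_bank`: kernels matrix (frequency x FFT
#'   bin) for the padded FFT length, plus the grid and geometry needed by
#'   [cwt_segment()].
#' @export
build_morse_bank <- function(gamma = 3, P2 = 60,
                             freq_grid = default_freq_grid(),
                             segment_length, sample_rate = 10,
                             pad_seconds = 5) {
  stopifnot(gamma > 0, P2 > 0, segment_length >= 1)
  if (is.unsorted(freq_grid, strictly = TRUE))
    stop("freq_grid must be strictly increasing")
  if (any(freq_grid <= 0) || any(freq_grid > sample_rate / 2))
    stop("analysis frequencies must lie in (0, sample_rate/2]")
  pad <- min(round(pad_seconds * sample_rate), segment_length - 1L)
  n_padded <- segment_length + 2L * pad
  nfft <- stats::nextn(n_padded, c(2L, 3L, 5L))
  # FFT bin frequencies; bins above Nyquist are negative frequencies and
  # receive zero response (analytic wavelet).
  k <- 0:(nfft - 1L)
  f_bins <- k * sample_rate / nfft
  f_bins[k > nfft / 2] <- -1  # negative-frequency half
  kernels <- t(vapply(freq_grid, function(fa)
    morse_kernel(f_bins, fa, gamma, P2), numeric(nfft)))
  structure(list(gamma = gamma, P2 = P2, freq_grid = freq_grid,
                 kernels = kernels, segment_length = segment_length,
                 sample_rate = sample_rate, pad = pad, nfft = nfft,
                 norm = "peak"),
            class = "morse_bank")
}

# Peak-normalized Morse response at bin frequencies f for analysis
# frequency fa.  Zero at and below zero frequency.
morse_kernel <- function(f, fa, gamma, P2) {
  wp <- morse_peak_omega(gamma, P2)
  x <- wp * f / fa
  out <- numeric(length(f))
  pos <- x > 0
  log_peak <- (P2 / gamma) * log(wp) - wp^gamma
  out[pos] <- exp((P2 / gamma) * log(x[pos]) - x[pos]^gamma - log_peak)
  out
}

#' Peak angular frequency of the unscaled Morse wavelet
#'
#' Solves \eqn{d/d\omega\,[\omega^{P^2/\gamma} e^{-\omega^\gamma}] = 0},
#' giving \eqn{\omega_p = (P^2/\gamma^2)^{1/\gamma}}.
#'
#' @param gamma,P2 Morse parameters.
#' @return peak angular frequency (rad/s) of the unscaled wavelet.
#' @export
morse_peak_omega <- function(gamma = 3, P2 = 60) (P2 / gamma^2)^(1 / gamma)

#' Default analysis frequency grid
#'
#' Linear grid from 0.5 to 5.0 Hz in 0.05 Hz steps (91 frequencies): spans
#' the stride sub-harmonic band, the walking band 1.4--2.3 Hz, and higher
#' harmonics up to the 5 Hz Nyquist limit of the 10 Hz grid, with
#' resolution fine enough to report cadence to one grid step (0.05 Hz).
#' Running the grid all the way to Nyquist matters for confounder
#' rejection: heel-strike harmonics of running (2 x step rate, 5--6.4 Hz)
#' alias into the 3.6--5 Hz range on the 10 Hz grid, and the
#' higher-harmonic gate can only veto them if the analysis grid covers
#' where they land.
#'
#' @return numeric vector of frequencies in Hz.
#' @export
default_freq_grid <- function() seq(0.5, 5.0, by = 0.05)

#' Continuous wavelet transform of a magnitude segment
#'
#' Computes coefficient magnitudes \eqn{|C(f, t)|} for every analysis
#' frequency by frequency-domain multiplication with the Morse kernels
#' after reflect-padding the segment on both sides, then reduces to one
#' column per second by taking, per frequency, the maximum magnitude over
#' that second's 10 samples.  The padding region is discarded.  Coefficients
#' carry a factor 2 so a sinusoid of amplitude \eqn{a} at an analysis
#' frequency peaks at \eqn{\approx a}.
#'
#' @param v numeric magnitude segment on the 10 Hz grid, at least one
#'   second (10 samples) long.
#' @param bank a [build_morse_bank()] built for `length(v)`.
#' @return object of class `scalogram`: list with `freq` (Hz) and `coef`
#'   (frequency x second matrix of non-negative magnitudes).
#' @export
cwt_segment <- function(v, bank) {
  stopifnot(inherits(bank, "morse_bank"))
  n <- length(v)
  fs <- bank$sample_rate
  if (n < fs) stop("segment shorter than one second")
  if (n != bank$segment_length)
    stop("bank was built for segment_length ", bank$segment_length,
         ", got ", n)
  pad <- bank$pad
  left <- if (pad > 0) v[seq(pad + 1L, 2L)] else numeric(0)
  right <- if (pad > 0) v[seq(n - 1L, n - pad)] else numeric(0)
  vp <- c(left, v, right, numeric(bank$nfft - n - 2L * pad))
  V <- fft(vp)
  n_sec <- n %/% fs
  coef <- matrix(0, length(bank$freq_grid), n_sec)
  sec_idx <- matrix(pad + seq_len(n_sec * fs), nrow = fs)
  for (i in seq_along(bank$freq_grid)) {
    ci <- 2 * Mod(fft(V * bank$kernels[i, ], inverse = TRUE)) / bank$nfft
    coef[i, ] <- apply(matrix(ci[sec_idx], nrow = fs), 2L, max)
  }
  structure(list(freq = bank$freq_grid, coef = coef), class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d frequencies (%.2f-%.2f Hz) x %d second(s)\n",
              length(x$freq), min(x$freq), max(x$freq), ncol(x$coef)))
  invisible(x)
}

#' @export
plot.scalogram <- function(x, ...) {
  image(x = seq_len(ncol(x$coef)) - 0.5, y = x$freq, z = t(x$coef),
        xlab = "time (s)", ylab = "frequency (Hz)",
        main = "Wavelet scalogram", ...)
  invisible(x)
}
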