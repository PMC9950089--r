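# Independent oracles and small builders shared across test files.

# Direct-evaluation CWT oracle: computes the time-domain filter for each
# analysis frequency by an explicit inverse-DFT sum and applies it by an
# explicit circular-convolution sum (O(N^2)); no fft() anywhere.  Mirrors
# the padding geometry of cwt_segment so results are comparable.
oracle_cwt_direct <- function(v, bank) {
  n <- length(v)
  fs <- bank$sample_rate
  pad <- bank$pad
  N <- bank$nfft
  left <- if (pad > 0) v[seq(pad + 1L, 2L)] else numeric(0)
  right <- if (pad > 0) v[seq(n - 1L, n - pad)] else numeric(0)
  vp <- c(left, v, right, numeric(N - n - 2L * pad))
  n_sec <- n %/% fs
  coef <- matrix(0, length(bank$freq_grid), n_sec)
  idx <- 0:(N - 1L)
  for (fi in seq_along(bank$freq_grid)) {
    H <- bank$kernels[fi, ]
    # h[m] = (1/N) sum_k H[k] exp(+2pi i k m / N), by direct summation
    h <- vapply(idx, function(m)
      sum(H * exp(2i * pi * idx * m / N)) / N, complex(1))
    conv <- vapply(idx, function(m)
      sum(vp * h[((m - idx) %% N) + 1L]), complex(1))
    mag <- 2 * Mod(conv)
    for (k in seq_len(n_sec)) {
      samp <- pad + (k - 1L) * fs + seq_len(fs)
      coef[fi, k] <- max(mag[samp])
    }
  }
  coef
}

# Literal second-by-second classifier oracle: re-evaluates the amplitude
# screen, the harmonic-ratio rule and the run-length rule with explicit
# loops.  Shares only the wavelet primitive (checked separately against the
# direct-convolution oracle).  Returns the walking mask for session 1.
oracle_classify_mask <- function(recording, params) {
  fs <- recording$fs
  xyz <- recording$sessions[[1L]]$xyz
  v <- sqrt(xyz[, 1]^2 + xyz[, 2]^2 + xyz[, 3]^2) - 1
  n_sec <- length(v) %/% fs
  valid <- logical(n_sec)
  for (k in seq_len(n_sec)) {
    w <- v[((k - 1L) * fs + 1L):(k * fs)]
    valid[k] <- (max(w) - min(w)) >= params$A
  }
  w_flag <- integer(n_sec)
  k <- 1L
  while (k <= n_sec) {
    if (!valid[k]) { k <- k + 1L; next }
    j <- k
    while (j < n_sec && valid[j + 1L]) j <- j + 1L
    samp <- ((k - 1L) * fs + 1L):(j * fs)
    bank <- build_morse_bank(segment_length = length(samp),
                             sample_rate = fs)
    sg <- cwt_segment(v[samp], bank)
    for (col in seq_len(ncol(sg$coef))) {
      cc <- sg$coef[, col]
      m_in <- m_lo <- m_hi <- 0
      for (fi in seq_along(sg$freq)) {
        f <- sg$freq[fi]
        if (f < params$f_min - 1e-9) m_lo <- max(m_lo, cc[fi])
        else if (f > params$f_max + 1e-9) m_hi <- max(m_hi, cc[fi])
        else m_in <- max(m_in, cc[fi])
      }
      if (params$alpha * m_in > m_lo && params$beta * m_in > m_hi)
        w_flag[k + col - 1L] <- 1L
    }
    k <- j + 1L
  }
  walking <- logical(n_sec)
  k <- 1L
  while (k <= n_sec) {
    if (w_flag[k] == 1L) {
      j <- k
      while (j < n_sec && w_flag[j + 1L] == 1L) j <- j + 1L
      if (j - k + 1L >= params$T_min) walking[k:j] <- TRUE
      k <- j + 1L
    } else k <- k + 1L
  }
  walking
}

# Uniform recording wrapped around a plain tri-axial matrix.
make_recording <- function(xyz, location = "unspecified", id = "test") {
  structure(list(sessions = list(list(start = 0, xyz = xyz)), fs = 10,
                 location = location, id = id),
            class = "uniform_recording")
}

# Random mixed-content 120 s recording used for oracle-equivalence checks:
# alternating blocks of gait-like oscillation, quiet noise, and
# high-frequency content, with randomized amplitudes so many seconds sit
# near the decision boundaries.
random_mixed_recording <- function(seed, duration = 120) {
  set.seed(seed)
  fs <- 10
  n <- duration * fs
  t <- (seq_len(n) - 1L) / fs
  v <- numeric(n)
  pos <- 1L
  while (pos < n) {
    len <- sample(5:20, 1) * fs
    idx <- pos:min(pos + len - 1L, n)
    kind <- sample(c("gait", "quiet", "fast", "slow"), 1)
    v[idx] <- switch(kind,
      gait = runif(1, 0.1, 0.6) *
        sin(2 * pi * runif(1, 1.2, 2.5) * t[idx] + runif(1, 0, 6)) +
        runif(1, 0, 0.3) * sin(2 * pi * runif(1, 0.6, 1.2) * t[idx]),
      quiet = rnorm(length(idx), 0, runif(1, 0.01, 0.08)),
      fast = runif(1, 0.2, 1) * sin(2 * pi * runif(1, 2.6, 4.5) * t[idx]),
      slow = runif(1, 0.1, 0.4) * sin(2 * pi * runif(1, 0.3, 0.9) * t[idx]))
    pos <- pos + len
  }
  v <- v + rnorm(n, 0, 0.01)
  make_recording(cbind(0, 0, 1 + v), id = paste0("mix-", seed))
}

# Random 3x3 rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

rotate_recording <- function(rec, R) {
  rec$sessions <- lapply(rec$sessions, function(s) {
    s$xyz <- s$xyz %*% t(R)
    s
  })
  rec
}
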