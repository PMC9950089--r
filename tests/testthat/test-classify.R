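test_that("walk_params validates its invariants", {
  expect_error(walk_params(A = 0), "A > 0")
  expect_error(walk_params(f_min = 2.5, f_max = 2.3))
  expect_error(walk_params(T_min = 0))
  p <- walk_params(A = 0.4, alpha = 2, T_min = 5.0)
  expect_identical(p$T_min, 5L)
})

test_that("amplitude screen applies the peak-to-peak threshold inclusively", {
  n <- 100
  t <- (seq_len(n) - 1) / 10
  const <- vector_magnitude(make_recording(cbind(0, 0, rep(1.37, n))))
  scr <- amplitude_screen(const, 0.3)
  expect_false(any(scr[[1]]$valid))

  # peak-to-peak 1.0 g sinusoid at 1.7 Hz: every window spans a full cycle
  osc <- make_recording(cbind(0, 0, 1 + 0.5 * sin(2 * pi * 1.7 * t)))
  scr2 <- amplitude_screen(vector_magnitude(osc), 0.3)
  expect_true(all(scr2[[1]]$valid))

  # boundary: p2p 0.29 < A; and exactly A passes (rule is >=)
  weak <- make_recording(cbind(0, 0, 1 + 0.145 * sin(2 * pi * 1.7 * t)))
  expect_false(any(amplitude_screen(vector_magnitude(weak), 0.3)[[1]]$valid))
  m <- vector_magnitude(osc)
  p2p_sec <- amplitude_screen(m, 0.01)[[1]]$p2p
  exact_A <- amplitude_screen(m, max(p2p_sec))
  expect_true(any(exact_A[[1]]$valid))
})

test_that("harmonic test implements the two strict ratio conditions", {
  freq <- default_freq_grid()
  col_at <- function(...) {
    spikes <- list(...)
    col <- numeric(length(freq))
    for (s in spikes) col[which.min(abs(freq - s[1]))] <- s[2]
    col
  }
  phone <- preset_params("smartphone")
  watch <- preset_params("smartwatch")

  # clean in-band dominance
  expect_equal(harmonic_test(col_at(c(1.8, 1), c(0.9, 0.01), c(3.6, 0.01)),
                             freq, phone), 1L)
  # running-like: strong content above the band
  expect_equal(harmonic_test(col_at(c(1.8, 1), c(2.9, 3)), freq, phone), 0L)
  # wrist-like: arm-swing sub-harmonic dominates; only the watch tolerates it
  wrist_col <- col_at(c(1.8, 1), c(0.9, 20))
  expect_equal(harmonic_test(wrist_col, freq, watch), 1L)
  expect_equal(harmonic_test(wrist_col, freq, phone), 0L)
  # all-zero column fails (0 > 0 is false)
  expect_equal(harmonic_test(numeric(length(freq)), freq, phone), 0L)
})

test_that("duration filter keeps only runs of at least T seconds", {
  for (T_min in c(2, 3, 6)) {
    expect_false(any(duration_filter(rep(1, T_min - 1), T_min)))
    expect_true(all(duration_filter(rep(1, T_min), T_min)))
  }
  expect_equal(duration_filter(c(1, 1, 0, 1, 1, 1), 3),
               c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(duration_filter(integer(0), 3), logical(0))
})

test_that("classify recovers simulated walking with cadence and steps", {
  ses <- simulate_walking(gait_model(cadence = 1.9, p2p = 0.8,
                                     duration = 60), seed = 1)
  res <- classify(ses$recording, preset_params("smartphone"))
  expect_gte(res$summary$walking_seconds, 54)
  expect_equal(median(res$seconds$cadence, na.rm = TRUE), 1.9,
               tolerance = 0.03)
  expect_equal(res$summary$n_bouts, 1L)
  expect_lt(abs(res$summary$total_steps - 114) / 114, 0.05)
  # invariants: walking => w = 1 => valid; cadence non-null iff walking
  sec <- res$seconds
  expect_true(all(sec$w[sec$walking] == 1L))
  expect_true(all(sec$valid[sec$w == 1L]))
  expect_identical(is.na(sec$cadence), !sec$walking)
  expect_true(all(res$bouts$seconds >= res$params$T_min))
})

test_that("classify rejects rest and fast running", {
  rest <- simulate_confounder("rest", 60, seed = 2)
  expect_equal(classify(rest$recording)$summary$walking_seconds, 0L)
  run <- simulate_walking(gait_model(cadence = 2.9, p2p = 2, sub_ratio = 0.2,
                                     high_ratio = 1.8, impact = TRUE,
                                     duration = 60), seed = 3)
  res <- classify(run$recording, preset_params("smartphone"))
  expect_lte(res$summary$walking_seconds, 3)
})

test_that("smartphone preset detects the mid-band but not the band edge", {
  # band-edge blindness: at 1.4-1.5 steps/s the fundamental leaks almost
  # fully into the sub-band grid and alpha = 0.6 cannot be satisfied
  for (cad in c(1.6, 1.9, 2.2)) {
    ses <- simulate_walking(gait_model(cadence = cad, p2p = 0.8,
                                       location = "waist", duration = 40),
                            seed = 50 + round(10 * cad))
    res <- classify(ses$recording, preset_params("smartphone"))
    expect_gte(mean(res$seconds$walking), 0.9)
  }
  slow <- simulate_walking(gait_model(cadence = 1.45, p2p = 0.8,
                                      location = "waist", duration = 40),
                           seed = 64)
  expect_lte(classify(slow$recording,
                      preset_params("smartphone"))$summary$walking_seconds, 2)
})

test_that("classify mask matches the literal step-by-step oracle", {
  phone <- preset_params("smartphone")
  for (seed in 1:3) {
    rec <- random_mixed_recording(seed, duration = 60)
    res <- classify(rec, phone)
    expect_identical(res$seconds$walking, oracle_classify_mask(rec, phone))
  }
})

test_that("classification is invariant under rigid rotations", {
  ses <- simulate_walking(gait_model(cadence = 1.8, p2p = 0.7,
                                     duration = 40), seed = 7)
  base <- classify(ses$recording, preset_params("smartphone"))
  set.seed(11)
  for (i in 1:3) {
    rot <- classify(rotate_recording(ses$recording, random_rotation()),
                    preset_params("smartphone"))
    expect_identical(rot$seconds$walking, base$seconds$walking)
    expect_equal(rot$seconds$cadence, base$seconds$cadence)
  }
})

test_that("classify handles empty and multi-session recordings", {
  empty <- structure(list(sessions = list(), fs = 10,
                          location = "unspecified", id = "none"),
                     class = "uniform_recording")
  res <- classify(empty)
  expect_equal(nrow(res$seconds), 0L)
  expect_equal(res$summary$walking_seconds, 0L)

  ses <- simulate_walking(gait_model(duration = 20), seed = 5)
  two <- ses$recording
  two$sessions <- c(two$sessions, lapply(two$sessions, function(s) {
    s$start <- 100; s
  }))
  res2 <- classify(two, preset_params("smartphone"))
  expect_setequal(unique(res2$seconds$session), c(1L, 2L))
  expect_equal(res2$summary$n_bouts, 2L)
})
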