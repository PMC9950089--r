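#' Parametric gait signal model
#'
#' Describes the quasi-periodic oscillation the walking classifier assumes:
#' a fundamental at the step frequency (cadence), a stride sub-harmonic at
#' half the cadence whose relative strength depends on body location (arm
#' swing makes it dominant at the wrist), a higher harmonic at twice the
#' cadence (heel-strike energy, strongest near the lower limbs), a constant
#' gravity component, slow cadence drift, and additive sensor noise.
#'
#' Location profiles set the harmonic ratios: `"thigh"` (sub 0.2, high
#' 0.8), `"waist"`/`"chest"`/`"arm"` (sub 0.3, high 0.4), `"wrist"` (sub
#' 2.5, high 0.2; the stride sub-harmonic dominates the step fundamental,
#' as arm swing does at the wrist), `"unspecified"` (sub 0.3, high 0.3).
#'
#' @param cadence step frequency in steps/s, in (0.5, 4).
#' @param p2p target one-second peak-to-peak amplitude of the magnitude
#'   signal, in g.
#' @param location body location; sets default harmonic ratios.
#' @param sub_ratio,high_ratio relative amplitudes of the stride
#'   sub-harmonic (cadence/2) and the higher harmonic (2 x cadence);
#'   override the location profile when given.
#' @param cadence_jitter SD of the slow per-second cadence drift (Hz).
#' @param noise_sd additive white-noise SD per axis (g).
#' @param impact if `TRUE`, the higher harmonic is phase-locked to the
#'   fundamental so that both crest together, producing the asymmetric
#'   upward spikes of impact-dominated activities (running, jumping)
#'   rather than a symmetric oscillation.  Default `FALSE`: harmonic
#'   phases are drawn independently once per session.
#' @param gravity_dir,osc_dir unit 3-vectors: gravity orientation and the
#'   axis of oscillation.  The default diagonal orientation reflects an
#'   arbitrarily oriented device, so motion projects onto all three axes
#'   (an axis-aligned device would trip the two-axes motion rule used for
#'   label adjustment).
#' @param duration session length in seconds.
#' @return object of class `gait_model`.
#' @export
gait_model <- function(cadence = 1.8, p2p = 1.0, location = "unspecified",
                       sub_ratio = NULL, high_ratio = NULL,
                       cadence_jitter = 0.02, noise_sd = 0.02,
                       impact = FALSE,
                       gravity_dir = c(1, 1, 1) / sqrt(3),
                       osc_dir = c(1, 1, 1) / sqrt(3),
                       duration = 60) {
  stopifnot(cadence > 0.5, cadence < 4, p2p > 0, duration >= 1,
            cadence_jitter >= 0, noise_sd >= 0)
  location <- match.arg(location,
    c("unspecified", "thigh", "waist", "chest", "arm", "wrist"))
  prof <- switch(location,
    thigh = c(0.2, 0.8),
    waist = , chest = , arm = c(0.3, 0.4),
    wrist = c(2.5, 0.2),
    unspecified = c(0.3, 0.3))
  if (is.null(sub_ratio)) sub_ratio <- prof[1L]
  if (is.null(high_ratio)) high_ratio <- prof[2L]
  stopifnot(sub_ratio >= 0, high_ratio >= 0)
  structure(list(cadence = cadence, p2p = p2p, location = location,
                 sub_ratio = sub_ratio, high_ratio = high_ratio,
                 cadence_jitter = cadence_jitter, noise_sd = noise_sd,
                 impact = isTRUE(impact),
                 gravity_dir = gravity_dir / sqrt(sum(gravity_dir^2)),
                 osc_dir = osc_dir / sqrt(sum(osc_dir^2)),
                 duration = duration),
            class = "gait_model")
}

# Deterministic oscillation s(t) for unit amplitude, given phases drawn
# from the seeded stream.  Returns list(s_unit, extras for reuse).
gait_oscillation <- function(model, n, fs) {
  # slow cadence drift: per-second Gaussian deviations, smoothed by a
  # 3-point moving average, linearly interpolated to the sample grid
  n_sec <- ceiling(n / fs)
  dev <- rnorm(n_sec + 2L, 0, model$cadence_jitter)
  dev <- stats::filter(dev, rep(1 / 3, 3), sides = 2)
  dev <- as.numeric(dev[2:(n_sec + 1L)])
  f_inst <- model$cadence +
    approx(seq_len(n_sec) - 0.5, dev, xout = (seq_len(n) - 0.5) / fs,
           rule = 2)$y
  phase <- 2 * pi * cumsum(f_inst) / fs
  ph0 <- runif(1, 0, 2 * pi)
  ph_sub <- runif(1, 0, 2 * pi)
  ph_high <- runif(1, 0, 2 * pi)
  if (model$impact) {
    # impact spike: harmonic crests with the fundamental
    cos(phase + ph0) + model$high_ratio * cos(2 * (phase + ph0)) +
      model$sub_ratio * sin((phase + ph0) / 2 + ph_sub)
  } else {
    sin(phase + ph0) +
      model$sub_ratio * sin(phase / 2 + ph_sub) +
      model$high_ratio * sin(2 * phase + ph_high)
  }
}

# Scaled oscillation with the free-fall floor: the total acceleration norm
# cannot go below zero, so dips saturate just above -1 g instead of folding.
scaled_oscillation <- function(a, s_unit) pmax(a * s_unit, -0.98)

# Median one-second peak-to-peak of the magnitude of gravity + a*s*osc_dir.
realized_p2p <- function(a, s_unit, model, fs) {
  xyz <- outer(scaled_oscillation(a, s_unit), model$osc_dir) +
    matrix(model$gravity_dir, length(s_unit), 3L, byrow = TRUE)
  median(second_p2p(sqrt(rowSums(xyz^2)) - 1, fs))
}

#' Simulate a walking session
#'
#' Generates a tri-axial recording `gravity + a * s(t) * osc_dir + noise`
#' on the 10 Hz grid, where `s(t)` sums the fundamental at the (slowly
#' jittered) cadence, the stride sub-harmonic and the higher harmonic.  The
#' oscillation amplitude `a` is solved numerically so that the magnitude
#' signal's median one-second peak-to-peak matches the requested `p2p`
#' despite the nonlinear norm (deterministic part; additive noise raises
#' the realized value slightly).  The whole session is labelled walking.
#'
#' @param model a [gait_model()].
#' @param seed integer seed; the full sample path is a pure function of
#'   `(model, seed)`.
#' @param id session tag.
#' @return object of class `sim_session`: list with `recording`
#'   (`uniform_recording`), `labels` ([activity_labels()]), `truth` (the
#'   generator parameters echoed for oracle checks), `id`.
#' @export
simulate_walking <- function(model = gait_model(), seed = 1L,
                             id = "sim-walking") {
  stopifnot(inherits(model, "gait_model"))
  fs <- 10
  n <- round(model$duration * fs)
  with_seed(seed, {
    s_unit <- gait_oscillation(model, n, fs)
    amp <- uniroot(function(a) realized_p2p(a, s_unit, model, fs) - model$p2p,
                   c(1e-4, 10 * model$p2p + 5), tol = 1e-5,
                   extendInt = "upX")$root
    xyz <- outer(scaled_oscillation(amp, s_unit), model$osc_dir) +
      matrix(model$gravity_dir, n, 3L, byrow = TRUE) +
      matrix(rnorm(3L * n, 0, model$noise_sd), n, 3L)
    rec <- structure(list(sessions = list(list(start = 0, xyz = xyz)),
                          fs = fs, location = model$location, id = id),
                     class = "uniform_recording")
    structure(list(recording = rec,
                   labels = activity_labels(0, model$duration, "walking"),
                   truth = list(kind = "walking", cadence = model$cadence,
                                p2p = model$p2p, amplitude = amp,
                                model = model, seed = seed),
                   id = id),
              class = "sim_session")
  })
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session> %s: %s, %.0f s\n", x$id, x$truth$kind,
              sum(vapply(x$recording$sessions,
                         function(s) nrow(s$xyz), integer(1))) /
                x$recording$fs))
  invisible(x)
}

#' Simulate a non-walking confounder activity
#'
#' Generates labelled sessions for the everyday activities the classifier
#' must reject (and one it knowingly does not):
#' \describe{
#'   \item{rest}{gravity plus white noise (SD at most 0.02 g).}
#'   \item{running}{the gait model at 2.5--3.2 steps/s with peak-to-peak
#'     1.5--3 g and weak stride sub-harmonics; the dominant frequency sits
#'     above the walking band, so the higher-harmonic gate rejects it.}
#'   \item{jumping}{continuous high-amplitude periodicity with fundamental
#'     1.5--2.5 Hz: a documented false-positive regime that overlaps the
#'     walking band in both amplitude and frequency.}
#'   \item{arm_task}{band-limited irregular motion 0.5--3 Hz with
#'     peak-to-peak 0.4--1 g (e.g. desk or household hand work).}
#'   \item{transport}{low-frequency (below 1 Hz) low-amplitude vibration,
#'     as in motorized transport; its amplitude is marginal against the
#'     screen.}
#' }
#'
#' @param kind one of `"rest"`, `"running"`, `"jumping"`, `"arm_task"`,
#'   `"transport"`.
#' @param duration session length in seconds; default 60.
#' @param seed integer seed.
#' @param location body location tag.
#' @param id session tag.
#' @return a `sim_session` whose labels carry `kind`.
#' @export
simulate_confounder <- function(kind = c("rest", "running", "jumping",
                                         "arm_task", "transport"),
                                duration = 60, seed = 1L,
                                location = "unspecified",
                                id = paste0("sim-", kind[1L])) {
  kind <- match.arg(kind)
  fs <- 10
  n <- round(duration * fs)
  if (kind == "running") {
    ses <- with_seed(seed, {
      cad <- runif(1, 2.5, 3.2); amp <- runif(1, 1.5, 3)
      list(cad = cad, amp = amp)
    })
    # impact-dominated spectrum: at lower-body sites the heel-strike
    # harmonic (2 x step rate) rivals or exceeds the fundamental
    model <- gait_model(cadence = ses$cad, p2p = ses$amp,
                        location = location, sub_ratio = 0.2,
                        high_ratio = 1.8, impact = TRUE,
                        duration = duration)
    out <- simulate_walking(model, seed = seed + 1L, id = id)
    out$labels <- activity_labels(0, duration, "running")
    out$truth$kind <- "running"
    return(out)
  }
  if (kind == "jumping") {
    ses <- with_seed(seed, list(f0 = runif(1, 1.5, 2.5),
                                amp = runif(1, 2.5, 4)))
    model <- gait_model(cadence = ses$f0, p2p = ses$amp,
                        location = location, sub_ratio = 0.1,
                        high_ratio = 0.5, cadence_jitter = 0.03,
                        impact = TRUE, duration = duration)
    out <- simulate_walking(model, seed = seed + 1L, id = id)
    out$labels <- activity_labels(0, duration, "jumping")
    out$truth$kind <- "jumping"
    return(out)
  }
  with_seed(seed, {
    t <- (seq_len(n) - 1L) / fs
    base <- switch(kind,
      rest = numeric(n),
      transport = {
        f <- runif(3, 0.25, 0.9); ph <- runif(3, 0, 2 * pi)
        a <- runif(3); a <- a / sum(a)
        s <- drop(sin(outer(2 * pi * t, f) +
                        matrix(ph, n, 3, byrow = TRUE)) %*% a)
        target <- runif(1, 0.15, 0.28)
        s * target / (max(s) - min(s)) * 1  # scale to target p2p
      },
      arm_task = {
        K <- 40
        f <- runif(K, 0.5, 3); ph <- runif(K, 0, 2 * pi)
        a <- abs(rnorm(K))
        s <- drop(sin(outer(2 * pi * t, f) +
                        matrix(ph, n, K, byrow = TRUE)) %*% a)
        target <- runif(1, 0.4, 1.0)
        s * target / median(second_p2p(s, fs))
      })
    noise_sd <- if (kind == "rest") 0.01 else 0.01
    xyz <- outer(base, c(0, 0, 1)) +
      matrix(c(0, 0, 1), n, 3L, byrow = TRUE) +
      matrix(rnorm(3L * n, 0, noise_sd), n, 3L)
    rec <- structure(list(sessions = list(list(start = 0, xyz = xyz)),
                          fs = fs, location = location, id = id),
                     class = "uniform_recording")
    structure(list(recording = rec,
                   labels = activity_labels(0, duration, kind),
                   truth = list(kind = kind, seed = seed),
                   id = id),
              class = "sim_session")
  })
}

#' Simulate a labelled benchmark cohort
#'
#' Builds a deterministic cohort of simulated subjects for tuning and
#' evaluation experiments.  Each subject walks at a cadence drawn uniformly
#' from `cadence_range` with a peak-to-peak amplitude from `p2p_range`, at
#' a body location drawn from `locations`, and additionally performs each
#' requested confounder activity.
#'
#' @param n_subjects number of subjects (at least 1).
#' @param seed master seed; all per-session seeds derive from it.
#' @param cadence_range,p2p_range uniform sampling ranges for the walking
#'   sessions.
#' @param locations candidate body locations.
#' @param activities confounder kinds generated per subject, in addition to
#'   walking.
#' @param duration per-session duration in seconds.
#' @param walking_trials walking sessions per subject.
#' @return list of `sim_session` objects; each carries a `subject` field.
#' @export
make_benchmark <- function(n_subjects = 20, seed = 11L,
                           cadence_range = c(1.5, 2.2),
                           p2p_range = c(0.5, 1.5),
                           locations = c("thigh", "waist", "chest", "arm"),
                           activities = c("rest", "running", "transport"),
                           duration = 60, walking_trials = 1L) {
  stopifnot(n_subjects >= 1)
  draws <- with_seed(seed, {
    list(cad = runif(n_subjects, cadence_range[1L], cadence_range[2L]),
         p2p = runif(n_subjects, p2p_range[1L], p2p_range[2L]),
         loc = sample(locations, n_subjects, replace = TRUE),
         seeds = matrix(sample.int(.Machine$integer.max - 1L,
                                   n_subjects * (walking_trials +
                                                   length(activities))),
                        nrow = n_subjects))
  })
  sessions <- list()
  for (i in seq_len(n_subjects)) {
    sc <- 0L
    for (tr in seq_len(walking_trials)) {
      sc <- sc + 1L
      ses <- simulate_walking(
        gait_model(cadence = draws$cad[i], p2p = draws$p2p[i],
                   location = draws$loc[i], duration = duration),
        seed = draws$seeds[i, sc],
        id = sprintf("s%02d-walk%d", i, tr))
      ses$subject <- i
      sessions[[length(sessions) + 1L]] <- ses
    }
    for (a in activities) {
      sc <- sc + 1L
      ses <- simulate_confounder(a, duration = duration,
                                 seed = draws$seeds[i, sc],
                                 location = draws$loc[i],
                                 id = sprintf("s%02d-%s", i, a))
      ses$subject <- i
      sessions[[length(sessions) + 1L]] <- ses
    }
  }
  sessions
}
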