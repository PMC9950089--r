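#' Classifier tuning parameters
#'
#' The walking classifier is controlled by six parameters: the one-second
#' peak-to-peak amplitude threshold `A` (g), the step-frequency band
#' `[f_min, f_max]` (Hz), the harmonic ratios `alpha` (sub-harmonic band,
#' below `f_min`) and `beta` (higher-harmonic band, above `f_max`), and the
#' minimum duration `T_min` in consecutive seconds.
#'
#' @param A amplitude threshold in g; must be positive.
#' @param f_min,f_max walking band bounds in Hz, `0 < f_min < f_max < 5`.
#' @param alpha,beta positive harmonic ratios.
#' @param T_min minimum walking duration in whole seconds, at least 1.
#' @param preset provenance tag: `"smartphone"`, `"smartwatch"`, or
#'   `"custom"`.
#' @return object of class `walk_params`.
#' @export
walk_params <- function(A = 0.3, f_min = 1.4, f_max = 2.3,
                        alpha = 0.6, beta = 2.5, T_min = 3L,
                        preset = "custom") {
  stopifnot(A > 0, f_min > 0, f_min < f_max, f_max < 5,
            alpha > 0, beta > 0, T_min >= 1)
  structure(list(A = A, f_min = f_min, f_max = f_max, alpha = alpha,
                 beta = beta, T_min = as.integer(round(T_min)),
                 preset = preset),
            class = "walk_params")
}

#' Device preset parameters
#'
#' Published parameter sets tuned for the two application scenarios.  Both
#' share the amplitude threshold `A = 0.3` g and the walking band
#' `[1.4, 2.3]` Hz; they differ in the harmonic ratios and minimum
#' duration.  The large smartwatch `alpha` tolerates the strong stride
#' sub-harmonics produced by arm swing at the wrist, while its tighter
#' `beta` and longer `T_min` compensate for the looser sub-harmonic gate.
#'
#' @param device `"smartphone"` (thigh, waist, chest, arm locations) or
#'   `"smartwatch"` (wrist).
#' @return a [walk_params()] object.
#' @export
preset_params <- function(device = c("smartphone", "smartwatch")) {
  device <- match.arg(device)
  switch(device,
    smartphone = walk_params(A = 0.3, f_min = 1.4, f_max = 2.3,
                             alpha = 0.6, beta = 2.5, T_min = 3L,
                             preset = "smartphone"),
    smartwatch = walk_params(A = 0.3, f_min = 1.4, f_max = 2.3,
                             alpha = 31.7, beta = 1.4, T_min = 6L,
                             preset = "smartwatch"))
}

#' @export
print.walk_params <- function(x, ...) {
  cat(sprintf(
    "<walk_params> [%s] A=%.2f g, f_w=[%.2f, %.2f] Hz, alpha=%.2f, beta=%.2f, T=%d s\n",
    x$preset, x$A, x$f_min, x$f_max, x$alpha, x$beta, x$T_min))
  invisible(x)
}
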