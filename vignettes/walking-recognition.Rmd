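---
title: "Walking recognition from tri-axial accelerometry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Walking recognition from tri-axial accelerometry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(walkbeat)
```

## The problem

Body-worn devices — smartphones, smartwatches, research accelerometers —
record tri-axial acceleration wherever they happen to be carried: in a
pocket, on a belt, strapped to the chest, on the wrist.  Walking is the most
informative everyday activity these devices can capture, but the raw signal
it produces differs enormously across body sites, devices and subjects.
`walkbeat` implements a device-agnostic walking recognizer built on the three
features walking always has, regardless of where the sensor sits:

* **intensity** — the acceleration magnitude oscillates with a peak-to-peak
  amplitude of roughly 0.4–2.5 g;
* **periodicity** — the oscillation is quasi-periodic at the step frequency
  (cadence), which for human walking lies in 1.4–2.3 Hz;
* **duration** — walking persists over multiple consecutive seconds.

## The pipeline

### Standardization

Input recordings (any sampling rate ≥ 10 Hz, possibly irregular, units g or
m/s²) are converted to g (1 g = 9.80665 m/s²) and linearly interpolated onto
an exact 10 Hz grid anchored at the first sample.  10 Hz is deliberate: it is
high enough to resolve the walking band and its neighbourhood and low enough
for multi-day battery-friendly collection.  Gaps longer than 1 s split the
recording into sessions — interpolating across a dropout would fabricate a
flat bridge that corrupts the amplitude screen.  Sessions shorter than one
second are dropped; duplicate timestamps keep their first value.

The three axes are collapsed to the vector magnitude
$v(t) = \sqrt{x_1^2 + x_2^2 + x_3^2} - 1$, which removes static gravity and
all dependence on device orientation (the classifier output is invariant
under any rigid rotation of the input — a tested property).

### Amplitude screen

$v(t)$ is cut into non-overlapping one-second windows (10 samples; a
trailing partial window is dropped).  A window is *valid* when its
peak-to-peak amplitude is at least the threshold $A$ (default 0.3 g;
the rule is $\geq A$, i.e. windows *below* the threshold are excluded).
One second is long enough to contain at least one step at any walking
cadence.  Besides rejecting sedentary data outright, the screen limits the
input to the wavelet stage, which dominates the computational cost
($O(N \log N)$).

### Time–frequency decomposition

Each maximal run of valid seconds is decomposed with a continuous wavelet
transform using the generalized Morse mother wavelet
$$\Psi_{P,\gamma}(\omega) = U(\omega)\, a_{P,\gamma}\,
\omega^{P^2/\gamma} e^{-\omega^\gamma}, \qquad \gamma = 3,\; P^2 = 60,$$
an analytic wavelet whose response at $\gamma = 3$ is nearly symmetric
around its peak in both time and frequency (the kernel's spectral skewness
is below 0.05, a tested property).  The unscaled peak sits at
$\omega_p = (P^2/\gamma^2)^{1/\gamma} \approx 1.8821$; each analysis kernel
is the wavelet evaluated at $\omega_p f/f_a$, so its response peaks exactly
at the analysis frequency $f_a$.

Numerical choices, each made once and fixed:

* **Frequency grid**: linear, 0.5–5.0 Hz in 0.05 Hz steps (91 frequencies).
  The resolution bounds the cadence quantization error at half a step
  (0.025 Hz).  The grid runs all the way to the 5 Hz Nyquist limit because
  the higher-harmonic veto must see where aliased harmonics land: running's
  heel-strike harmonic (twice the 2.5–3.2 Hz step rate) aliases into
  3.6–5.0 Hz on a 10 Hz grid, and capping the grid short of Nyquist blinds
  the veto to part of that range.
* **Normalization**: peak normalization (kernel maximum 1, coefficients
  scaled so a sinusoid of amplitude $a$ peaks at $\approx a$).  The walking
  test below uses only *ratios* of coefficients across frequencies, and peak
  normalization makes those ratios amplitude-consistent at every analysis
  frequency.
* **Per-second reduction**: one value per frequency per second, the maximum
  magnitude over the second's 10 samples — robust to sub-second phase.
* **Edge handling**: each segment is reflect-padded by 5 s per side before
  the transform and the padded columns are discarded, limiting
  cone-of-influence artifacts at bout edges.  FFTs run at the next
  2-3-5-smooth length.

### The walking test

For each valid second $\tau$, with $C(f, \tau)$ the scalogram column and
$f_w = [f_{\min}, f_{\max}]$ the walking band (default [1.4, 2.3] Hz):

$$w(\tau) = 1 \iff
\alpha \max_{f \in f_w} C > \max_{f < f_{\min}} C
\;\wedge\;
\beta \max_{f \in f_w} C > \max_{f > f_{\max}} C$$

with strict inequalities and an empty out-of-band maximum defined as 0.
$\alpha$ governs tolerance to stride sub-harmonics (arm swing at half the
cadence), $\beta$ tolerance to higher harmonics (heel-strike energy), and
both also prevent activities whose *global* peak lies outside the band from
sneaking in via in-band sub- or higher harmonics (e.g. the stride frequency
of running).  A second is finally labelled walking when it belongs to a run
of at least $T$ consecutive $w = 1$ seconds; the entire qualifying run is
labelled, so bout duration equals detected duration.  Seconds rejected by
the amplitude screen break runs — no gap bridging, since no principled
bridging rule presents itself at 1 s granularity.

Two device presets are shipped.  Smartphone-type locations (thigh, waist,
chest, arm): $A = 0.3$ g, $f_w = [1.4, 2.3]$ Hz, $\alpha = 0.6$,
$\beta = 2.5$, $T = 3$ s.  Wrist-worn devices: the same $A$ and $f_w$ but
$\alpha = 31.7$, $\beta = 1.4$, $T = 6$ s — the huge $\alpha$ tolerates
arm-swing sub-harmonics that routinely exceed the in-band peak, compensated
by a stricter $\beta$ and a longer minimum duration.

### Cadence, bouts, steps

Per walking second, cadence is the in-band argmax frequency of the column
(ties broken toward the lower frequency, deterministically).  Bouts are
maximal walking runs; a bout's step count is the sum of its per-second
cadences (steps/s × 1 s), rounded half-up once per bout so integer rounding
cannot accumulate.

```{r example}
ses <- simulate_walking(gait_model(cadence = 1.9, p2p = 0.8, duration = 60),
                        seed = 1)
summary(classify(ses$recording, preset_params("smartphone")))
```

## Label handling and evaluation

Activity labels are half-open intervals $[start, end)$; a second carries a
label when its midpoint falls inside.  Before scoring, walking labels are
restricted to seconds with actual motion (per-axis one-second moving SD
above 0.1 g on at least two of three axes); flatlined padding around a
labelled walking trial is relabelled to a reserved `adjusted_out` group and
excluded from scoring.  The adjustment never converts anything *to* walking.

`evaluate_walking()` scores sensitivity for walking groups and specificity
for all other groups, per subject: multiple trials of one activity are
averaged within subject first, then across subjects, reported with a
normal-approximation 95% CI (mean ± 1.96 SE).  The normal CI is a deliberate
fidelity choice — it can exceed [0, 1] for extreme means with few subjects,
which matches the convention of symmetric printed intervals in this
literature rather than statistical elegance.

## Threshold tuning

`tune_pipeline()` selects all six thresholds from a labelled dataset by
Youden-optimal ROC cutoffs on the one-vs-all task (walking seconds vs. all
non-walking seconds), sequentially, carrying earlier choices forward:

1. $A$ on the per-second peak-to-peak amplitude;
2. $f_w$ over candidate $(f_{\min}, f_{\max})$ pairs, scored by whether the
   scalogram's dominant frequency falls inside the candidate band.  (An
   in-band *energy fraction* was considered and rejected: a narrow band
   holds ~20 of 91 grid frequencies, so even clean gait rarely concentrates
   half its total coefficient mass in band; dominant-frequency membership is
   the statistic the walking test's band comparison actually constrains.)
3. $(\alpha, \beta)$ jointly — they share one ROC — over a 25 × 25
   logarithmic grid from 0.1 to 100;
4. $T$ on the length of the $w$-run each second belongs to.

Candidate grids: $A \in \{0.05, 0.10, \ldots, 1.00\}$ g, $f_{\min} \in
\{1.0, \ldots, 1.6\}$, $f_{\max} \in \{2.0, \ldots, 3.0\}$ (0.1 Hz steps),
$T \in \{1, \ldots, 10\}$ s.  Ties in the Youden index resolve to the
smallest candidate, making tuning deterministic.  For the two
multi-candidate stages, the reported AUC is the trapezoidal area under the
candidate operating points' envelope.  Tuning computes full-session
scalograms so every labelled second is visible to every stage;
classification itself transforms only the amplitude-valid segments.

## The synthetic-data generator

Every claim the test suite makes is exercised on simulated data, so the
generator's realism bounds what the tests demonstrate.  `gait_model()`
emulates:

* a fundamental at the cadence with slow Gaussian drift (SD 0.02 Hz,
  3-point smoothed), a stride sub-harmonic at half the cadence, and a
  higher harmonic at twice it, with location profiles: thigh (sub 0.2,
  high 0.8), waist/chest/arm (0.3, 0.4), wrist (2.5, 0.2 — the sub-harmonic
  *dominates* the fundamental, as arm swing does), unspecified (0.3, 0.3);
* a constant gravity component in a diagonal orientation, so motion
  projects onto all three axes as it does for an arbitrarily pocketed
  device (an axis-aligned device would trip the two-axes motion rule);
* an oscillation amplitude solved numerically (to ~1%) so the realized
  one-second peak-to-peak of the *magnitude* matches the requested value
  despite the nonlinear norm; dips saturate at −0.98 g, the free-fall
  floor, because an acceleration norm cannot be negative;
* additive white sensor noise (SD 0.02 g per axis).

Confounders: rest (noise only), running (cadence 2.5–3.2 steps/s,
peak-to-peak 1.5–3 g, impact mode: the heel-strike harmonic at 1.8× the
fundamental, phase-locked so the waveform is an asymmetric upward spike),
jumping (fundamental 1.5–2.5 Hz, peak-to-peak 2.5–4 g, impact mode),
arm_task (band-limited 0.5–3 Hz irregular motion, 0.4–1 g), transport
(sub-1 Hz vibration with marginal 0.15–0.28 g amplitude).  Jumping is
deliberately generated *inside* the walking band: it is the method's
documented false-positive regime, preserved rather than tuned away, and the
test suite asserts that it *is* misclassified.

What the generator does **not** emulate: biomechanical body-segment
dynamics, sensor saturation and quantization, surface/footwear effects,
postural transitions, or free-living label noise.  Green tests therefore
demonstrate internal correctness and the method's designed selectivity on
harmonic-structured signals — not field performance.

## Known limitations

* **Slow walking is invisible to the smartphone preset.**  A tone at the
  1.4 Hz band edge leaks ≈0.96 of its peak into the sub-band grid point at
  1.35 Hz (Morse $P^2 = 60$ bandwidth), so $\alpha = 0.6$ rejects cadences
  below ≈1.55 steps/s no matter how clean the data.  This is the method's
  real behaviour — it is why very slow treadmill walking scores near zero
  sensitivity at phone locations — and the full-band cadence-recovery test
  accordingly uses wrist-worn sessions under the smartwatch preset, whose
  $\alpha$ admits the band edge.
* **Slow running sits on a soft boundary.**  For step rates within
  ≈0.05 steps/s above the band edge (≈2.50–2.56), band-edge leakage times
  $\beta = 2.5$ can exceed the aliased harmonic peak and the second passes
  as walking.  Roughly 7% of random running draws fall there; the rest are
  rejected outright.
* **Jumping is systematically misclassified** (by design of the method, not
  the implementation).
* Cadence is quantized to the 0.05 Hz grid; step counts inherit that
  quantization.
* The tuner's per-second granularity means extremely unbalanced label mixes
  can starve a stage; each stage fails loudly when a class is missing.

## Problem sizes used in the shipped experiments

Simulated sessions are 60 s (300 s for confounder-rejection runs and
600–1200 s for the scaling measurement); tuning cohorts are 20 subjects ×
4 sessions with 8 held-out subjects; cadence recovery uses 10 seeds at each
of 10 cadences.  These sizes make the full experiment battery reproducible
in a few minutes on one core while keeping every Monte-Carlo margin (e.g.
detection ≥ 90%, MAE ≤ 0.05 steps/s) comfortably away from its threshold.
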