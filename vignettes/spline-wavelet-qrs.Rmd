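---
title: "Methods: spline-wavelet QRS detection and the ambulatory monitor model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spline-wavelet QRS detection and the ambulatory monitor model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgcwt)
```

`ecgcwt` reimplements, as desk-scale software, the computational core of a
three-lead ambulatory (Holter) ECG monitor: real-time QRS-complex detection
with a B-spline wavelet filter, beat-to-beat RR/heart-rate measurement, the
monitor's binary storage format, its device arithmetic and alarm logic, and
the statistics used to validate a detector. Everything is exercised on
synthetic ECG with known ground truth, so no recordings or hardware are
needed.

## The wavelet filter

At a fixed integer scale the continuous wavelet transform acts as a bandpass
filter. The mother wavelet here is the first derivative of a cubic-B-spline
smoothing kernel,

$$\psi(t) \;=\; \beta^3\!\left(t + \tfrac12\right) - \beta^3\!\left(t - \tfrac12\right)
\;=\; \frac{d}{dt}\,\bigl(\beta^3 * \mathrm{box}\bigr)(t),$$

where $\beta^3$ is the centered cubic B-spline. Realizing the derivative as a
unit-lag finite difference of the dilated spline is exactly what a
sample-by-sample recursion with running sums computes on a microcontroller,
and the composite is the derivative of a 4th-degree spline. The kernel at
integer scale $a$ is sampled analytically,
$h_a[k] = \tfrac1a\,\psi(k/a)$, giving a support of about $5a$ samples. It is
exactly antisymmetric and zero-mean, so it annihilates constants and turns
every sharp peak of the input into a positive/negative modulus pair with a
zero crossing at the peak — the signature the detector looks for.

Because dilation and sampling rate enter the response only through
$f \cdot a / F_m$, doubling the scale with the rate leaves the passband
fixed. `select_scale()` picks the integer scale whose band (computed by
`estimate_band()` from the discrete kernel on a dense grid, $-3$ dB
convention) is log-closest to the 14.4–48.6 Hz QRS target band; for 250, 500
and 1000 Hz this yields scales 2, 4 and 8:

```{r}
for (cfg in list(c(2, 250), c(4, 500), c(8, 1000))) {
  b <- estimate_band(spline_wavelet(cfg[1]), cfg[2])
  cat(sprintf("scale %d @ %4d Hz: %5.2f - %5.2f Hz\n",
              cfg[1], cfg[2], b$fc_min_hz, b$fc_max_hz))
}
```

That band suppresses baseline wander and P/T-wave energy from below and
50/60 Hz powerline interference from above.

**Cutoff convention.** The $-3$ dB amplitude convention on a dense grid
(8192 points to Nyquist, linear interpolation at the crossings) was fixed
once, because it reproduces the design band table of the monitor this models;
a $-6$ dB convention does not.

**Group delay.** The kernel's group delay equals its center of antisymmetry,
about $2.5a$ samples (19 at scale 8). Device-side figures quoted for such
detectors are often larger (the time from the R peak until the *decision*,
which adds the wait for the confirming second modulus and the detection
logic, roughly another $2$–$3.5a$ samples); `delay_samples` is deliberately
the filter delay, since that is what aligns the zero crossing with the ECG
time base. `detect_record()` compensates beat indices by exactly this value,
and on clean synthetic data the residual mean offset to the true R peaks is
well under 10 ms.

**Edges.** The first `delay_samples` outputs are computed against zero-padded
history; the detector's learning phase (below) covers this startup region, so
no beat is ever declared from edge transients.

## The streaming detector

Detection runs causally, one coefficient at a time (`process_sample()`), with
state:

* **Threshold memories.** Two running thresholds hold 75% of the modulus
  amplitudes: seeded during a learning phase (default 2 s) as 75% of the
  extreme positive/negative coefficients seen, then updated after each beat
  as $m \leftarrow (1-\alpha)\,m + \alpha\,0.75\,|P|$ with $\alpha = 0.25$,
  so the detector adapts over roughly four beats and a single ectopic
  amplitude cannot capture it.
* **Pairing.** A threshold excursion arms a candidate modulus (its running
  extremum and index). When an opposite-sign modulus follows within 120 ms —
  a QRS-width bound — the beat is declared at the zero crossing P1 between
  the two extrema (first integer sample at which the coefficient changes
  sign; no sub-sample interpolation). The pairing is order-agnostic:
  max-first and min-first pairs are both valid, so QRS polarity inversion
  changes `pair_order` but not a single beat index (a tested invariant).
* **Refractory period.** 200 ms after each accepted P1 no new modulus can be
  armed: the physiological minimum RR is about 300 ms, and 200 ms also
  blanks T-wave energy.
* **Dropout recovery.** If no beat arrives for 1.5 times the running mean RR
  the thresholds are halved (and again after each further such interval) — a
  streaming surrogate for search-back. A floor at 1% of the learning-phase
  maximum modulus (with a small absolute fallback for silent input) prevents
  collapse onto noise during flatline.

RR is the P1-to-P1 distance, heart rate $60000/\mathrm{RR}$ bpm, computed
independently per lead as on the device. Parameters not fixed by the modeled
design (update weight, refractory, pairing window, floor, decay rule) are
this package's own choices, set once to the values above on physiological
grounds.

## The record format and device model

Each sample is one 15-byte packet: per channel (DI, aVF, V2) a 3-byte
big-endian two's-complement 24-bit ADC code plus a 2-byte big-endian
heart-rate word. The HR word encoding is bpm × 10 fixed point with 0 meaning
"no beat yet" (the device leaves the 16-bit encoding unspecified; fixed
point preserves 0.1 bpm over the full physiological range). A record
directory `<subject>_<YYYYMMDD>_<HHMMSS>` holds `Record0000` (UTF-8
key–value metadata: subject data, rate, on-times, and the reference/gain so
raw codes remain interpretable) and up to 9999 data files of at most
$2^{16}$ packets (~65 s at 1000 Hz) each. Endianness and the per-file packet
count are this package's choices; the naming, packet layout and 15-byte
arithmetic are the modeled format. Storage therefore costs
$15 \cdot F_m \cdot t$ bytes — about 1.21 GiB per 24 h at 1000 Hz ("GB"
read as GiB, $2^{30}$, which matches the printed figure).

Device arithmetic is closed-form: full scale $\pm V_{ref}/G$ (±2.4 V at
unity gain), LSB resolution $2 V_{ref}/G/(2^{24}-1) \approx 286.10$ nV, and
battery life = battery energy / device power (67.27 h theoretical for
3000 mAh × 3.7 V against 50 mA × 3.3 V; 47.09 h at the 70% usable fraction
imposed by the low-voltage cutoff). The alarm engine mirrors the device:
electrode faults (from the per-electrode status bits reported with every
sample), SD disconnection during acquisition, SD full, and out-of-range
heart rate (outside 60–100 bpm) sound the buzzer; low battery is visual
only. The HR alarm is debounced over 3 consecutive beats — our choice, so a
single ectopic interval does not alarm.

## The synthetic generator

`generate_ecg()` renders each beat as five Gaussian waves (P, Q, R, S, T)
with a lead-II-like default template scaled per lead for DI/aVF/V2 —
the classic analytic-template approach, chosen over dynamical-system
generators because the R-peak positions are exact by construction. RR
intervals are drawn as $\max(300\,\mathrm{ms},\;
\mathcal N(60000/\mathrm{HR}, \sigma_{RR}))$, with the floor preventing
physiologically impossible overlap. Noise terms: white noise (specified
directly in mV or via a per-lead SNR computed from the clean signal power),
sinusoidal baseline wander, and 50/60 Hz powerline interference. QRS
polarity inversion negates Q/R/S; lead-off episodes saturate the leads
affected by the failing electrode (RA and LA fault DI and aVF, LL faults
aVF, V2 itself, RL everything) at the positive rail and set the ground-truth
mask. Everything is reproducible bit-for-bit from the seed, and the RR
sequence is drawn before any rate-dependent noise so the same seed gives the
same rhythm at every sampling rate.

Defaults describe the package's validation condition: 5 minutes, 70 ± 5 bpm,
20 dB SNR, mild wander (0.05 mV at 0.25 Hz) and powerline (0.02 mV at
60 Hz). What the generator does *not* emulate — muscle artifact, electrode
motion transients, ectopic morphologies, rhythm pathologies beyond jitter
and inversion — bounds what passing tests show: they validate the detector
logic and timing, not clinical performance on pathological recordings.

## Evaluation conventions

Beat matching is one-to-one within ±75 ms (a common beat-matching window;
the modeled validation does not state its own), accepting candidate pairs
globally by increasing time difference so that swapping the two lists
swaps sensitivity $Se = TP/(TP+FN)$ and positive predictivity
$P^+ = TP/(TP+FP)$ exactly. The detection error is $100(FP+FN)/(TP+FN)$.
Bland–Altman agreement reports the mean paired RR difference and ±2 SD
limits (sample SD, $n-1$). Waveform comparison maximizes cross-correlation
over integer lags and reports the Pearson correlation over the overlap at
the best lag, as a percentage.

## Problem sizes and numerical choices

The test suite and the acceptance script use: kernels at scales 1–10; CWT
oracle checks on random signals up to 2000 samples; detection runs of 20 s
to 7.5 min at 250–1000 Hz (up to ~500 beats per run, 5 seeds × 3 rates for
the error-rate study); $10^4$ randomized packet round-trips; and a $10^5$
sample Monte-Carlo for the Bland–Altman parameter recovery. Band estimation
uses 8192 grid points to Nyquist; all floating point is double precision
(the device's fixed-point scaling trick is unnecessary off-device).

## Known limitations

* The detector is a single-scale, single-pass streaming algorithm: no
  search-back re-examination of the raw buffer, no multi-lead fusion, and no
  ectopic/morphology classification (T-wave end and ST analysis are out of
  scope).
* Beats inside the learning phase are deliberately not detected; comparisons
  against ground truth should start after it.
* The group-delay figures quoted for the modeled device (48/24/12 samples)
  are not reproducible as the filter delay of any kernel consistent with the
  design band table (support $12a$ versus the $\approx 5a$ the band
  implies); see the discussion above. This package reports the true kernel
  delay (~2.5a) and treats the larger figures as decision latency.
* The synthetic generator's noise model is stationary; real ambulatory noise
  is not.
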