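---
title: "Methods: adaptive-threshold QRS detection and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive-threshold QRS detection and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrsdetect)
```

## The problem

Continuous single-lead ECG monitoring — smart garments, patch monitors,
telehealth devices — needs the R peak of every heartbeat located in real
time on hardware with little computational headroom. The classical
Pan–Tompkins detector solves the detection problem well but spends much of
its work on machinery (a second, parallel signal analysis and a second
RR-interval average) whose contribution to correctness is questionable on
ambulatory-quality signals. This package implements both that classical
detector and a streamlined variant that strips the parallel machinery out,
together with the scoring harness and a synthetic-signal generator needed
to quantify exactly what the simplification costs or buys.

## Signal conditioning

Both detectors share the classical conditioning chain, designed at 200 Hz
and applied causally with zero initial state:

* **Low-pass** $y_n = 2y_{n-1} - y_{n-2} + x_n - 2x_{n-6} + x_{n-12}$
  (DC gain 36, ~11 Hz corner).
* **High-pass** as all-pass minus low-pass,
  $y_n = y_{n-1} + 32x_{n-16} - 32x_{n-17} - x_n + x_{n-32}$ (DC gain 0,
  ~5 Hz corner). Note this is the *corrected* form: the difference equation
  as printed in the classical reference,
  $y_n = 32x_{n-16} - [y_{n-1} + x_n - x_{n-32}]$, is a well-known misprint —
  it has DC gain 16 and a marginally stable pole at $z = -1$, so it is not a
  high-pass filter at all. The corrected form is what every working
  implementation uses, and what the oracle tests here transcribe.
* **Five-point derivative** $y_n = (2x_n + x_{n-1} - x_{n-3} - 2x_{n-4})/8$.
* **Squaring**, then a **trailing moving-window mean** over
  $N = \mathrm{round}(0.150\,f_s)$ samples (30 at 200 Hz), which turns the
  squared slope signal into one energy hump per QRS complex.

In *native-rate* mode the 200 Hz coefficients run unchanged at the record's
own sampling rate — the band edges shift accordingly, which mirrors how the
chain is used in practice — while the integration window is always scaled to
150 ms. In *resampled* mode, records are first brought to 200 Hz by rational
polyphase resampling (zero-stuffing, a windowed-sinc FIR whose odd length
makes the group delay an integer that is removed exactly, then decimation),
so all records see identical cut-off frequencies. Annotation indices map by
$\mathrm{round}(i \cdot 200/f_s)$.

## The decision logic

Detection operates on the integrated signal's local maxima. Because the
integrated hump of a single QRS is ragged, strict local maxima are first
filtered by non-maximum suppression over a 200 ms radius (tallest wins, ties
to the earlier sample); without this, hump shoulders register as "noise
peaks" taller than the accepted signal peak and corrupt the noise estimate
on perfectly clean signals.

The streamlined detector keeps one pair of running estimates on the
integrated signal — for each candidate peak of height $PEAKF$:

$$SPKF \leftarrow 0.125\,PEAKF + 0.875\,SPKF \quad\text{(signal peaks)}$$
$$NPKF \leftarrow 0.125\,PEAKF + 0.875\,NPKF \quad\text{(noise peaks)}$$
$$T_1 = NPKF + 0.25\,(SPKF - NPKF), \qquad T_2 = 0.25\,T_1$$

A peak above $T_1$ is a QRS unless the T-wave rule rejects it; anything else
updates the noise estimate. Accepted beats feed a buffer of the eight most
recent RR intervals whose mean $\overline{RR}$ sets the missed-beat limit
$1.66\,\overline{RR}$: when the gap since the last beat exceeds it, the
interval is re-searched with the lowered threshold $T_2$, the tallest
qualifying peak wins (ties to the earlier), and — deliberately — the same
0.125/0.875 update is applied to search-back finds as to ordinary beats.

Retained physiological rules: a **200 ms refractory** period after each
accepted beat, and **T-wave discrimination** — a candidate within 360 ms of
the previous QRS whose maximal absolute derivative-stage slope is less than
half that of the previous QRS is a T wave, treated as noise. The slope is
measured over ±75 ms centred at the candidate's position *minus the
integration offset* ($\lfloor N/2\rfloor$ samples), because the integrated
peak lags the underlying slope energy by about half the integration window;
centred at the integrated peak itself the window misses the QRS slope
entirely.

The **original detector** differs in exactly two ways, both implemented
here: (1) the same signal/noise/threshold bookkeeping runs *in parallel on
the band-passed signal*, and a QRS is accepted only when the integrated and
band-passed peaks both clear their first thresholds within the
integration-window latency; (2) RR bookkeeping is doubled — a second
average over the last eight RR intervals that fell within 92–116% of its own
running mean defines lowered thresholds (halved while the rhythm is
irregular) and the missed-beat limit — and search-back finds update the
signal estimate with the steeper 0.25/0.75 coefficients. Both variants are
produced by one parameterised engine, so the claim that the streamlined
detector *is* the original minus these parts holds by construction and is
verified as program equivalence in the tests; the per-branch operation tally
(`op_count`: every estimate update, threshold recomputation and comparison)
gives a hardware-independent measure of the work each variant performs.
Wall-clock speedups are intentionally not reproduced — they depend on the
benchmark hardware and implementation language.

### Initialisation and warm-up

The source method is silent on initialisation; the choices here are
scale-free and conventional: $SPKF$ starts at 0.25 × the maximum and $NPKF$
at 0.5 × the mean of the integrated signal over the first 2 s, with the
first 0.5 s (filter transient) excluded from both learning and detection.
Before eight RR intervals exist the RR average uses what is available;
search-back needs at least two. Records shorter than the learning phase
yield an empty result with a warning. If noise drifts the estimates into
$NPKF > SPKF$, the threshold formulas are still applied literally — no
clamping — so pathological inputs degrade visibly rather than silently.

### Localization

Accepted peaks live in integrated-signal coordinates. They are mapped to raw
coordinates by subtracting the nominal chain delay (6 + 16 + 2 +
$\lfloor N/2 \rfloor$ samples), refining to the maximal absolute band-passed
amplitude within ±75 ms (searched at the exact 20-sample band-pass delay),
then snapping to the largest deviation of the raw signal from its local
median baseline (median over ±150 ms, search over ±25 ms). On clean
synthetic records this lands on the simulated R apex with zero-sample error
at all five standard rates; the band-passed argmax alone quantises to ±2
samples at 200 Hz. A 200 ms spacing is re-imposed after refinement so the
output contract (no two detections closer than the refractory period) is
unconditional.

Because candidate suppression looks up to 200 ms ahead and slope windows 75
ms around a peak, the detector's causality horizon is 275 ms: truncating a
record never changes detections earlier than that horizon before the cut.

## Evaluation

Beat-by-beat scoring pairs detections with annotations one-to-one inside a
150 ms window (the ANSI/AAMI convention): annotations in order, each taking
the nearest unmatched detection, ties to the earlier. Unmatched detections
are FP, unmatched annotations FN, and with $TB$ annotated beats:

$$\text{error rate} = \frac{FN + FP}{TB},\quad
  Se = \frac{TP}{TP + FN},\quad
  PPV = \frac{TP}{TP + FP},$$
$$\text{accuracy} = \frac{TP}{TP + FP + FN},\quad
  F_1 = \frac{2TP}{2TP + FP + FN},$$

all reported as percentages, with "failed detection" the count $FP + FN$.
Greedy nearest-neighbour pairing is the stated convention, not a
maximum-cardinality matching; contrived configurations exist where the two
differ, but on physiological beat spacings (inter-beat gaps well above twice
the tolerance) they coincide. Dataset-level aggregation is reported on two
bases — pooled counts, and the mean of per-record percentages — because
published summary tables do not always say which was used and the two can
differ materially on unbalanced data; `reference_counts()` ships one such
published table whose telehealth rows are internally inconsistent with their
own counts (flagged in the data), which is why only the count-consistent
rows feed the arithmetic checks.

## The synthetic generator

`simulate_ecg()` places a Gaussian-sum beat template (P, Q, R, S, T
deflections) on an RR point process, with optional per-beat gain modulation,
baseline wander, mains interference and white noise; `degrade_ecg()` adds a
calibrated white/wander/mains mixture to hit an exact broadband SNR. All
randomness flows from one integer seed through a protected RNG scope, so
records are bit-reproducible and the caller's RNG stream is untouched.
Regimes and their defaults:

* **sinus** — R amplitude 1, width σ = 12 ms, T/R ratio 0.25 at +300 ms;
  rates 128–500 Hz (the sampling rates of the public corpora this emulates).
* **irregular** — Gaussian RR jitter plus premature beats (default 10%):
  a ~55% RR followed by a ~145% compensatory pause, RR floor 200 ms.
* **paced** — a 4 ms high-amplitude stimulus spike 60 ms before a broad
  ~120 ms complex, the morphology on which threshold-based detectors
  historically struggle most.
* **tall_t** — a tall *peaked* T (T/R = 0.6, σ = 24 ms at +260 ms, the
  "tented T" pattern). This choice is deliberate: a broad 60 ms-wide T at
  normal amplitude ratios never crosses the adaptive threshold after
  derivative-squaring-integration, so it cannot probe the T-wave rule; the
  peaked variant crosses it at the 200 Hz design rate, making the
  discrimination rule's effect measurable (two orders of magnitude fewer
  false positives with the rule on).

What the generator does *not* emulate: real muscle-artifact spectra,
electrode motion transients, morphology drift within a record, multi-lead
redundancy, or true arrhythmia dynamics beyond premature-beat timing.
Passing tests on synthetic records therefore demonstrates the *logic* of the
detectors — thresholds, search-back, refractory, T-rejection, scale
invariance, determinism — not field performance on hospital or wearable
data; the optional external-database script exists for the latter.

## Problem sizes and numerical choices in the tests

The suite runs records of 30–300 s at 128–500 Hz (up to ~600 pooled beats
per check), chosen so the full suite completes in seconds while every
decision path (learning, search-back, T-rejection, refractory, resampling,
both detectors) is exercised. Filter oracles use 1000-sample random inputs
against literal scalar-loop transcriptions of the difference equations with
agreement demanded to 1e−9; RNG seeds are fixed in every stochastic test.
Degenerate inputs are tested explicitly: zero signals, records shorter than
the learning phase, empty RR buffers, zero-denominator metrics (reported as
`NA` with a warning, never silently 0 or 100).

## Limitations

Native-rate mode knowingly shifts the band edges away from their design
values at rates other than 200 Hz. The operation tally counts
decision-logic work only — the conditioning chain, identical for both
detectors, is excluded. The WFDB reader/writer covers headers, 16-bit and
212-format signals and beat annotations, not the full format family. No
statistical comparison between detectors (confidence intervals, McNemar) is
provided, matching the scope of the evaluation it reproduces.
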