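---
title: "Temporal QA of respiratory gating from treatment logs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal QA of respiratory gating from treatment logs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatelog)
```

# The measurement problem

A phase-gated linac delivers dose only while the respiratory phase of an
external surrogate lies inside a planned window, here 25%–75% of the cycle.
The gating chain — camera, phase predictor, beam trigger, beam servo — has
finite latency, and that latency is exactly what a temporal QA programme
must measure. The treatment log records everything needed: the surrogate
motion on three axes and the beam on/off flag, time-stamped on one clock.
`gatelog` turns one such log into per-cycle latency estimates
(`delta_on`, `delta_off`), window/trigger duration comparisons, aggregate
statistics, and tolerance verdicts, with an optional independent
cross-check from portal-imager (EPID) cine frames and an ion-chamber output
constancy comparison.

# The analysis model

## Signal conditioning

Only the anterior–posterior (AP) axis is analysed; it is the gating
surrogate axis by convention. The trace is min–max normalized,
`v' = (v - min v) / (max v - min v)`, so peak-detection parameters are
scale-free, then smoothed with a centred moving mean of **5 samples**
(window shrinking at the trace ends so output length equals input length).
Five samples at the 25 Hz logs we target spans 0.2 s — enough to suppress
sensor jitter without displacing peaks of multi-second breathing cycles.
Whether such a window should be counted in samples or in a resampled time
unit is genuinely open; samples was chosen because it keeps the operation
exact and rate-independent in definition, and the window is configurable.

A constant trace cannot be normalized; it returns all zeros with a
`degenerate` warning so segmentation can refuse it with a diagnostic rather
than an exception.

## Cycle segmentation

Cycles are anchored **peak-to-peak**: phase 0 is the end-inhale peak, which
makes the 25%–75% window the end-exhale half-cycle, matching the common
4D-CT phase convention. (Anchoring at troughs is available via
`anchor = "trough"`; which convention the gating vendor uses internally is
not observable from the log.) Peak detection is deliberately elementary and
fully specified, so it can be cross-checked against an exhaustive
local-maximum scan:

1. Candidate peaks are strict-rise/non-increase local maxima. A peak must
   be *right-confirmed* — followed by an observed non-increase. The first
   sample qualifies when the signal descends from it (a trace that starts
   exactly on a peak anchors its first cycle there); the last sample never
   does, because a trailing rise is a truncated ascent toward an unobserved
   peak. Partial leading/trailing cycles are discarded, not extrapolated.
2. Candidates must exceed a **topographic prominence of 0.2** (normalized
   units): height above the higher of the two minima separating the peak
   from its nearest higher neighbours. On a normalized trace this rejects
   noise wiggles while keeping any physiologically plausible breath.
3. A coarse period estimate — the lag of the autocorrelation maximum after
   its first local minimum — sets a minimum peak separation of **0.4 ×**
   that estimate; conflicts are resolved greedily by height, ties to the
   earlier sample.

Fewer than two surviving peaks yields an empty cycle table with a
`diagnostic` attribute: "no cycles" is a reportable QA outcome, not a
crash.

## Phase timing and pairing

Phase is **linear in time** within each cycle: the fraction-*f* point of a
cycle of period *T* is `t_start + f·T`, so the 25→75% window lasts exactly
`T/2`. The alternative (amplitude-proportional phase) is inconsistent with
the near-zero variance of window durations that a regular phantom produces,
and linear phase is what phase-gating systems compute prospectively.

Beam intervals come from flag transitions; an edge is stamped at the first
sample in the new state, a reproducible convention with bias below one
sample period. A trace that ends beam-on yields an incomplete interval
(excluded from duration statistics); one that *starts* beam-on has an
unseen rising edge and is flagged (demoted to incomplete under
`strict_edges`).

Each complete interval is assigned to the cycle whose planned window it
overlaps most — one-to-one, greedy by overlap, ties to the earlier cycle —
and unmatched cycles/intervals are reported in attributes, never silently
dropped. Per record,

- `delta_on = t_on − t25`, `delta_off = t_off − t75` (positive = late
  trigger),
- `delta_on − delta_off = window_duration − trigger_duration`, an algebraic
  identity asserted in the tests.

## Aggregation conventions

Summaries are mean, **population SD** (divisor *n*) and median. The 5–6
cycles of a session are the complete population of delivered cycles, and
recomputing published-style per-cycle tables confirms that convention:
`aggregate_stats(c(-0.01, 0.10, 0.04, 0.01, -0.02))` gives a population SD
of 0.043 (→ 0.04 at two decimals) where the sample SD would print 0.05.
`sd_type = "sample"` is available. All internal math is full precision;
rounding — 2 decimals, half *away from zero* — happens only in the
reporting layer. Missing cycles (a trial with 5 of 6 cycles) are excluded
before aggregation with `n` recorded per aggregate.

## EPID cine verification

The portal imager provides a log-independent timing check. Per frame, the
mean intensity of a square ROI — **5 × 5 cm defined at isocenter**,
projected onto the imager by the SID/SAD magnification (isocenter was
chosen because clinical ROI prescriptions are stated there; the plane is
switchable) — is normalized by the series maximum. A frame is beam-on iff
its normalized mean is **strictly above 0.5**: a frame exactly at threshold
counts as off, since ties are resolution artifacts. Contiguous runs become
segments and duration = frame count × frame period, so durations are
quantized to the frame period (0.04 s at 25 fps) and differ from truth by
at most one frame. An optional 3 × 3 median filter (off by default, so the
documented pipeline is the default) suppresses isolated hot pixels.

Input is a plain frame-stack directory — a JSON sidecar with frame period,
frame times and geometry plus a CSV of row-major flattened frames — the
format the simulator writes and `load_cine_frames()` reads; geometry
missing from the sidecar falls back to configured values with a message.

## Dose and reproducibility

Gated vs non-gated point doses are compared paired (per-measurement
differences, gated − reference) or unpaired (arm aggregates only); whether
a published "difference" is one or the other is often ambiguous, so both
modes exist. Multi-session trending tabulates each session's aggregates in
order and reports the maximum absolute drift of each metric's mean.

## Tolerances

Defaults: **0.10 s** on |mean delta| and the duration gap (the
TG-142-style 100 ms gating temporal-accuracy tolerance) and **0.5%** on the
dose difference relative to the reference mean. Boundary equality passes.
Every metric can be disabled, reporting "not evaluated" — a disabled check
is never silently counted as a pass.

# The synthetic phantom

The simulator emulates a rigid reflector block on a mechanical motion
stage: strictly periodic AP motion (`z(t) = A·cos(2πt/T)`, or a cos⁴ shape
with an end-exhale dwell), zero lateral motion, and analytic phase
`(t mod T)/T` with the peak at phase 0. Defaults: **period 5.32 s** (so the
planned window is 2.66 s), amplitude 1 cm, 25 Hz sampling, 6 cycles, and
**zero amplitude noise** — a mechanical phantom's surrogate trace is
essentially noiseless, which is also what near-zero window-duration
variance on real phantom sessions implies. Noise (`noise_sd`, as a fraction
of amplitude, seeded) is exercised explicitly in robustness tests at 0.05.

Beam flags are generated from the analytic window with configurable
latencies applied to the *event times before resampling* onto the log
clock, so sub-sample latencies are exercised; the true event table rides
along as an attribute for validation. EPID stacks render the whole panel
bright during (latency-shifted) beam-on over a dark-current background,
with optional exponential afterglow (first tail frame at 60% of the beam
level) and seeded Gaussian pixel noise.

What the simulator does **not** emulate — and what passing tests therefore
do not demonstrate — includes: irregular or drifting patient breathing,
predictive-filter behaviour, amplitude gating, beam hold-offs, dose-rate
ramp-up within an interval, EPID ghosting beyond the single afterglow term,
and the case where a trigger is logged but the beam fails to deliver (the
EPID comparison can flag that last case on real data; the simulator never
produces it).

Latency recovery is the simulator's core purpose: across on/off latencies
of 0–100 ms and ten seeds, the pipeline's mean deltas recover the injected
values within one log sample period (0.04 s). The quantization is one-sided
— a trigger edge is only observable at the next sample at or after the true
event — so recovered deltas carry a sub-sample positive bias, visible in
the worked example in the README.

# Numerical and degenerate-case choices

- Sampling gaps beyond 10% of the nominal period reject a log at read time;
  phase times rely on linear interpolation of the time axis, so mild jitter
  is benign and gross gaps are not.
- Times and amplitudes are written at 6 decimal places; write→read→write is
  byte-identical.
- Ties in peak separation filtering go to the earlier sample; ties in
  pairing overlap to the earlier cycle.
- Empty inputs raise classed errors (`gatelog_empty_input_error`) except
  where the contract says otherwise (all-off trace → empty interval table;
  flat signal → empty cycle table with diagnostic).
- Reports serialize with full-precision JSON; determinism is asserted by
  comparing serialized payloads of repeated runs (timestamp excluded).

# Problem sizes

The test suite and acceptance script run sessions of 6 cycles at 25 Hz
(≈800 samples), EPID stacks of ≈800 32 × 32 frames, oracle-equivalence
checks on 100 random instances per operation, and a 4 × 4 latency grid ×
10 seeds for recovery — sizes chosen so the complete validation runs in
about a minute on a laptop while every bound asserted (one sample period,
one frame period) is scale-independent.

# Known limitations

- The CSV log dialect is this package's own; converting a vendor's
  proprietary offline-review export into it is out of scope.
- DICOM RT IMAGE parsing is not implemented; EPID input uses the
  documented frame-stack directory format.
- Cycle anchors carry a small selection bias under heavy noise (peaks are
  found where noise pushed the smoothed trace up); the phase-0
  neighbourhood of the average periodic signal inherits it.
- A single boolean beam flag cannot distinguish beam hold-off from
  beam-off, and log analysis alone cannot detect a triggered-but-undelivered
  beam.
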