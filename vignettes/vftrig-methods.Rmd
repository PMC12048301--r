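---
title: "Models and methods behind vftrig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vftrig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

vftrig analyzes cardiac optical-mapping experiments in which a localized
region of shortened repolarization is created in perfused ventricular
tissue (a KATP-opener perfused through a terminal coronary branch), and
spontaneous premature ventricular complexes (PVCs) arising at the border
of that region trigger ventricular fibrillation (VF). The package has two
halves: an analysis chain (optical maps, repolarization gradients, border
geometry, pseudo-ECG events, phase maps) and a synthetic-preparation
generator that provides ground truth for every measurement the chain
makes. This vignette documents the models, the defaults and why they were
chosen, the numerical decisions, and what the synthetic validation does
and does not establish about real data.

## The tissue model

Electrical propagation is a two-variable monodomain reaction-diffusion
model (a Mitchell–Schaeffer-type excitable medium): a fast inward current
gated by a single recovery variable `h`, a linear outward current, and
isotropic diffusion,

$$\partial_t v = \frac{h\,v^2(1-v)}{\tau_{in}} - \frac{v}{\tau_{out}}
  + D\,\nabla^2 v + I_{stim},\qquad
\partial_t h = \begin{cases}
  (1-h)/\tau_{open} & v < v_{gate}\\
  -h/\tau_{close}(x,y) & v \ge v_{gate}.
\end{cases}$$

Two variables are sufficient because the scientific object here is a
*controllable* action potential duration (APD) field and the wave
phenomenology around it, not ionic mechanism. The gate-closing time
constant `tau_close` controls APD almost linearly, which is what the
lesion model manipulates per pixel.

Defaults: `tau_in` 0.3 ms, `tau_out` 6 ms, `tau_open` 120 ms,
`v_gate` 0.13, and `tau_close` 135.04 ms, the last calibrated so that a
single cell paced at a 500-ms cycle has an APD80 of 240 ms. Two defaults
deserve comment because they were genuinely open:

* **Baseline APD80 = 240 ms.** Porcine right-ventricular epicardium at a
  500-ms cycle is typically 210–250 ms. A longer baseline (270 ms) is
  also defensible, but it makes the shortest observed trigger couplings
  (down to 140 ms) physically unrealizable against a mean shortening of
  89 ms: a site cannot re-excite before its own repolarization plus gate
  recovery, and 270 − 89 plus conduction latency already exceeds 200 ms.
  The observed coupling range is only consistent with a baseline near
  240 ms combined with the reported spread of shortening across
  preparations.
* **D = 0.1 mm²/ms.** This gives a conduction velocity of ~0.29 mm/ms
  and an electrotonic space constant of ~0.8 mm, both physiological.
  Larger diffusivities (0.3) give a faster, prettier wave but flatten the
  realized border ramp to ~60 % of its target slope, because
  repolarization couples over sqrt(D·tau) — the tissue is then more
  strongly coupled than myocardium.

Integration is forward Euler on a 128×128 grid at the optical pixel pitch
(0.39 mm/px, ~50×50 mm of tissue), `dt` = 0.05 ms. The explicit
stability bound `dt < dx²/4D` (0.38 ms here) is checked; accuracy, not
stability, sets the default: halving `dt` moves activation times by
~0.3 ms (the convergence test asserts < 0.5 ms). The movie is sampled at
1-ms frames. No-flux boundaries mirror the cut edges of a tissue
preparation.

## The lesion and its calibration

The lesion is a disc (default radius 7.7 mm, ~7.5 % of tissue area,
matching the reported 5–10 %) in which the target APD80 is reduced by
89 ms, with a linear radial ramp of width 5.6 mm across the border — so
the ideal maximal gradient is 89/5.6 ≈ 15.9 ms/mm — superimposed on a
weak linear background gradient (1.5 ms/mm) in normal tissue. The target
APD map is converted to a per-pixel `tau_close` scaling by inverting a
calibration curve tabulated from single-cell runs at the pacing cycle;
the round trip (target → scaling → simulated single-cell APD80) is
accurate to < 3 ms over the full calibrated range (~75–296 ms).

Inside the core (tapered to zero across the inner 15 % of the ramp,
keeping the ramp and the measurement stencil around border sites
deterministic)
a smooth zero-mean heterogeneity field is added (sd 12 ms, correlation
2 mm): drug perfusion is not uniform, and a perfectly homogeneous core
repolarizes so synchronously that its T wave becomes an artificially
sharp deflection. The taper keeps the border ramp — where all gradient
measurements happen — deterministic. The amplitude is deliberately
moderate: much larger fields can cause the injected wave to surface at a
neighboring low-APD patch rather than the injected site, which would
decouple the generator's ground-truth origin from the observable one.

## Pacing, triggers, and what "injected" means

Pacing is a point stimulus train (500-ms cycle, i.e. 2 Hz, the boundary
of the "spontaneous" classification) from a site just outside the lesion
ring — ventricular pacing close to the substrate, as in the reference
experiments. An intrinsic-rhythm mode stimulates at ~667 ms (1.5 Hz) and
logs the events as intrinsic.

The trigger is, by default, *injected*: a prescribed point stimulus
0.5 mm inside the true border — on the short-APD side, where optical
traces in the reference experiments show triggers emerging, and at the
maximal-gradient point of the realized ramp, consistent with the
reported trigger-site gradients being the steep ones — at a random angle, timed so its coupling interval to the last
paced beat follows a truncated normal with mean 297 ms, sd 66 ms,
clipped to 140–460 ms. Injection rather than emergence is a deliberate
design choice: the phase-2-reexcitation mechanism is a hypothesis the
*analysis* observes; the generator's job is ground-truth control. If the
site is still refractory at the drawn time, delivery is retried in 1-ms
steps (up to 250 ms) and the realized time recorded; a capture check
requires a propagating wave (activation of ring pixels 4 px away), not
merely a stimulus artifact, and propagation may be unidirectional — block
toward the long-APD side is precisely the vulnerable pattern of interest.
Couplings below the local refractory floor (site activation time + local
APD + gate recovery) are therefore *censored upward*, exactly as in real
tissue, where a coupling below local refractoriness simply cannot be
observed.

Two consequences shaped the defaults:

* **Short couplings require deeply shortened preparations.** With the
  shortening fixed at its mean (−89 ms), the floor sits near 250 ms.
  The coupling study therefore draws each episode's preparation-level
  shortening from the reported across-preparation spread
  (−89.0 ± 48.4 ms, truncated to the calibrated range): 140–250-ms
  couplings are realizable only where the shortening is deep, exactly as
  across the reference preparations. The map-recovery study keeps the
  fixed mean shortening (its purpose is recovering that calibration).
* **The pseudo-ECG electrode sits over the mapped field at 8 mm.** A
  symmetric expanding wavelet has a nearly null far-field (its net dipole
  vanishes), so a distant electrode registers a growing PVC deflection
  only tens of ms after delivery, by a morphology-dependent amount. Over
  the lesion, every border-zone ectopic is in the near field and the
  measurement offset collapses to a constant (−12.0 ± 0.4 ms across
  episodes spanning the full range of shortenings). The pipeline applies
  no correction for that constant: it is the honest price of measuring
  couplings on an ECG, and it largely cancels against the refractory
  censoring in group means. The generator also implements the
  closed-loop alternative (`coupling_study(two_pass = TRUE)`): re-deliver
  with the measured lag as an advance so the ECG coupling matches the
  drawn value where refractoriness permits.

## Fibrillatory continuation

A single ectopic does not re-enter on this preparation: with
physiological conduction velocity and APDs, the reentrant wavelength
(CV × APD ≈ 95 mm) exceeds any available path on a 50-mm sheet. The
reference experiments show early VF as *repeated focal breakthroughs
contiguous to the trigger origin* with rotors appearing later; the
generator reproduces that phenomenology directly: `vf_mode = "scripted"`
appends a train of focal stimuli at sites 1–4.5 mm inside the border
near the origin, with irregular cycle lengths drawn from 170–245 ms
(refractory-deferred, so realized cycles respect local restitution).
Episode duration is set explicitly, which is how sustained (≥ 8 s) and
nonsustained episodes are constructed deliberately. This mode makes no
claim of an emergent reentry mechanism — it is a phenomenological
continuation for testing the ECG and phase stages. Rotor-specific tests
use spiral-wave phase fields constructed analytically.

## The acquisition model

Fluorescence = voltage after: Gaussian blur (σ 0.75 px — tandem-lens
optics plus dye diffusion), min–max normalization, multiplicative
rundown (5 %/min — photobleaching under the continuous illumination such
long recordings require), additive white noise (sd 0.02 of the AP
amplitude, a good-quality signal-to-noise ratio of ~50), and 1 % dead
pixels. The pseudo-ECG is the standard infinite-volume-conductor forward
model, Σ ∇V·∇(1/r) dA over pixels, computed from the *voltage* movie
(the experimental pseudo-ECG is an electrical recording, not an optical
one).

## The measurement chain

**Conditioning.** Baseline drift is removed by sliding-percentile
subtraction (10th percentile over 500-ms half-overlapping chunks),
polarity corrected, and each beat window renormalized to [0, 1] using its
own diastolic baseline (median of the first 50 ms) and peak. A pixel is
valid when amplitude / high-frequency noise sd ≥ 5 (mirroring the
"noisy pixels excluded" convention of published maps), and a beat window
is valid only when its amplitude reaches half the trace's overall AP
amplitude — a window catching only the falling tail of the previous beat
must not be renormalized into noise.

**Activation.** AT is the time of maximum positive dF/dt (the dominant
optical-mapping convention; a 50 %-upstroke alternative is a switch),
refined by parabolic interpolation of the derivative peak. Candidates
are derivative local maxima above 30 % of the window maximum that rise
by ≥ 0.4 (normalized) within 30 ms of the candidate itself; the earliest
qualifying candidate wins, which implements the stated tie-break for
double upstrokes and rejects noise blips ahead of the true upstroke. A
light Savitzky–Golay filter (7 ms, cubic) precedes differentiation by
default; oracle tests on noiseless data disable it.

**APD80 and RT.** APD80 is the first fall, after the AP peak, to 20 % of
the beat amplitude above baseline (linear interpolation); RT = AT +
APD80 exactly, pixel-wise. Maps for "regular activity preceding VF" are
taken from the last beat whose repolarization completes everywhere
before the trigger, so the measurement is uncontaminated.

**Gradients.** Central differences (1-px step) after a σ = 1 px Gaussian
pre-smooth applied by normalized convolution (masked pixels do not bleed
in); magnitude divided by the pixel pitch gives ms/mm. Pixels whose
1-px stencil touches an invalid pixel are masked, as is a boundary ring
the width of the smoothing support, so the estimator is exact (< 1 %) on
linear ramps of any orientation over the retained pixels. The gradient
scale is configuration-exposed because reported ms/mm values depend on
it; the default is the finest unbiased estimator at this pitch.

**Border delineation.** The valid-pixel APD distribution is first
detrended by a robustly fitted plane (three iterations, down-weighting
the short-APD tail): without this, the background gradient broadens the
normal mode until it swallows the core–normal valley, and a centered
lesion even carves a spurious notch inside the normal mode by removing
the mid-range pixels. On the residual, the threshold is the deepest
valley between the lowest density mode and any higher mode; if no
substantial dip exists, Otsu's threshold is the fallback, and a
distribution with < 20 ms of contrast is an error instructing manual
mode. The largest connected component below threshold is the lesion;
its sub-pixel contour (marching at level 0.5) yields a signed distance
map. The border-zone predicate is distance ≤ 3.5 mm, inclusive.

**ECG events.** Beats are detected on the squared, smoothed derivative
of the low-pass-filtered record (Pan–Tompkins-style). Slow conduction
makes the QRS of this preparation nearly as low-frequency as its T wave,
and the terminal deflection of each paced complex (wavefront collision
with the tissue boundary) arrives later than a refractory lockout; both
are removed by *paced-template subtraction* — the median paced complex,
built from the logged cycles (excluding the first beat, which starts
from rest), is subtracted at each paced event, and ectopy is detected on
the residual against a local (rolling-median) noise floor. Onsets are
the foot of a lightly smoothed detection function, searched forward from
a local floor, which resolves both paced and ectopic onsets to a few ms
and collapses multi-lobed complexes to a single beat. PVCs are
premature (interval < 0.9 × the median of the last five non-PVC
intervals) non-paced beats; VF is ≥ 4 consecutive deflections with cycle
length < 250 ms and coefficient of variation > 0.1 (the irregularity
term excludes regular rapid pacing); sustained means duration ≥ 8 s,
inclusive; spontaneous means no extrastimulus within 2 s and pacing rate
≤ 2 Hz at onset, inclusive at exactly 2 Hz. The T-wave end uses the
tangent method on the low-passed record, with a median template fallback
when a short-coupled PVC truncates the T wave. These ECG-level rules are
this package's operationalization — the reference methods specify the
classifications but not algorithms — and every threshold is
configuration-exposed.

**Phase and trigger origin.** Phase is the angle of the FFT-based
analytic signal of the mean-subtracted trace (no installed package
provides the Hilbert transform, so the five-line FFT construction is
implemented here). Singularities are plaquette winding numbers (exactly
matching a brute-force loop oracle); tracks are nearest-neighbor links
with a 3-px/frame gate, and a track persisting at least one rotation
(lifetime ≥ the local cycle length) marks a rotor. The trigger origin is
the centroid of the earliest-activated 1 % of valid pixels of the
trigger-beat activation map — the percentile replaces the visual
identification used on published phase snapshots — and early cycles are
classified breakthrough (focal: the origin activates before its 5-px
ring) versus rotor, stopping after 4–5 cycles as the optical signals
beyond the first complexes of VF must be interpreted with caution.

**Statistics.** Shapiro–Wilk at α = 0.05 selects t-type versus
rank-based tests; more than two groups use Kruskal–Wallis with
Holm–Šidák-adjusted pairwise rank-sum comparisons (step-down Šidák with
enforced monotonicity); independence of categorical variables uses the
two-sided Fisher exact test (library implementation, validated in the
test suite against a full hypergeometric enumeration oracle — the
contract is oracle agreement, not a particular backend). Narrative
summaries round means to one decimal and percentages to integers, which
is why 74 episodes over 16 preparations reads as "an average of 5".

## What the synthetic validation shows — and does not

The generator's defaults *are* the study conditions: recovery tests
demonstrate that the full simulate → acquire → measure chain returns the
calibrated physiology (core-minus-remote APD80 within a few ms of
−89 ms; trigger-origin gradients within 20 % of 15.9 ms/mm against
1.5 ms/mm at nontrigger sites; coupling means near 297 ms; origins
within ~2 px and always ≤ 3.5 mm from the border). They do not
demonstrate performance on real movies: the generator has no motion
artifact (the experiments used electromechanical uncoupling), no
ratiometric dye behavior, isotropic conduction (no fiber-direction
anisotropy), a single circular lesion, 2-D epicardial propagation only,
and a phenomenological rather than emergent VF. Conclusions about
mechanism belong to the experiments; the package establishes that the
*measurements* are faithful where truth is known.

Problem sizes used throughout (tests and the acceptance study) were
chosen to characterize the estimators well while staying modest: 16
preparations for the map/gradient recovery (matching the number of
optically mapped initiations in the reference study), 5 of them for the
APD shortening, 50 episodes for the coupling study, the default 128×128 grid
for all calibrated results, and half-size grids with half-scale lesions
(same pitch, same calibration) for unit and integration tests.

## Known limitations

* The measured core-minus-remote shortening (≈ −83 ms for a −89 ms
  target) carries a real electrotonic bias: a ~1–2-cm core surrounded by
  long-APD tissue is pulled upward by a few ms at this space constant.
  It is physics, not an estimator error, and it is well inside the ±10-ms
  recovery criterion.
* ECG-measured couplings sit a constant ~12 ms above delivery at the
  default electrode, and couplings below the refractory floor are
  censored upward; both effects are documented rather than corrected.
* The spec of a beat's "onset" on a pseudo-ECG is convention-laden; all
  timing comparisons in the package use one convention consistently.
* Rotor classification depends on singularity tracks surviving the
  SNR mask; in heavily masked regions a rotor can be reported as
  indeterminate.
* Beat-wise VF detection on the pseudo-ECG of scripted fibrillatory
  episodes is imperfect: confined core breakthroughs produce small,
  multi-lobed, overlapping deflections (a fractionated far-field, much
  like real VF electrograms), and a missed deflection splits a detected
  episode. The temporal classification rules themselves (8-s sustained
  boundary, 2-Hz spontaneity, trigger attribution) are exact and tested
  on event tables independently of deflection detection.
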