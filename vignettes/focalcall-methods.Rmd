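---
title: "Methods: caller identification by relative received level and downstream acoustic-behaviour statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: caller identification by relative received level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acoustic tags record every detectable sound, from the animal carrying the
tag and from its neighbours alike. In a social group of baleen whales the
members are close enough that most calls register on several tags, so per-tag
detections alone cannot say who called. When *every* member of the group is
tagged, however, physics provides the discriminant: the caller's own tag is
decimetres-to-metres from the sound source while every other tag is tens of
metres away, so — regardless of the source level of the call — the received
level (RL) should be highest on the caller's tag. `focalcall` implements
this comparison and everything downstream of it.

The method's validity rests on two assumptions that the package makes
explicit and testable: (i) the group is fully tagged and acoustically
isolated from other whales, so every detected call was produced by a tagged
animal; and (ii) the tag-to-own-source distance is much smaller than
inter-animal distances, so transmission loss orders RLs correctly. When
animals come into near contact the RL gap collapses and calls are —
correctly — labelled indeterminate rather than guessed.

## Received-level measurement

Each annotated call span is processed as:

1. **Decimation to 12 kHz.** A windowed-sinc (Kaiser, β = 8) anti-aliasing
   low-pass followed by rational rate conversion handles both 64 and 96 kHz
   source rates exactly (×3/16 and ×1/8). Passband gain error is below
   0.001 dB and alias rejection better than 100 dB, so the resampler
   contributes nothing measurable to level error.
2. **500 Hz high-pass** to suppress flow noise: a 4th-order Butterworth
   applied forward and backward. The zero-phase pass avoids biasing the
   position of the energy window; squaring the magnitude response doubles
   the rolloff, giving ≥ 40 dB rejection an octave below the cutoff while
   leaving tones at 1 kHz within 0.5 dB.
3. **90% energy window.** The window runs from the first sample at which
   cumulative squared-sample energy reaches 5% of the total to the first at
   which it reaches 95%. This bounds the sensitivity of rms levels to how
   generously an analyst drew the selection box.
4. **Calibration.** rms in full-scale units is treated as volts (1.0 full
   scale ≡ 1 V at the ADC) and converted with the nominal hydrophone
   sensitivity, −171 dB re 1 V/µPa by default:
   `RL = 20·log10(rms) − sensitivity`. The tag's true ADC gain is not
   modelled, so absolute levels carry this convention; *relative* levels
   across tags — the quantity the caller-ID decision uses — are unaffected.

A measurement is invalidated (and never used in assignment) when the
detection is flagged as noise-masked, overlaps another detection on the
same tag, clips, or contains no energy. Overlap is assessed per tag only:
a call overlapping a *different* call on a *different* tag is still
measurable on its own tag.

The energy window is computed after conditioning. Computing it before the
high-pass would let low-frequency flow noise drag the window; since the rms
is taken on the conditioned signal either way, the consistent order is to
window what is measured.

## Caller assignment

Detections on different tags are matched into unique calls when their
start times differ by ≤ 0.5 s and their spans overlap by ≥ 30% of the
shorter span. The 0.5 s default covers the ≤ 0.33 s one-way acoustic travel
time across a group spread over 500 m plus annotation jitter. Clusters are
single-linkage connected components, because the same call is typically
boxed with slightly different spans on each tag. A cluster may never
contain two detections from one tag: links are admitted strongest-first
(smallest start-time difference) and any link that would merge two same-tag
detections is cut. Frequency-band agreement is deliberately *not* required
for matching — bands are advisory annotations — but disjoint bands within a
cluster are counted and reported.

Assignment rules, in order:

* single-tag cluster → focal on that tag (a call inaudible elsewhere in a
  fully tagged group must be the tag wearer's);
* all members but one masked by noise → focal on the unmasked tag;
* otherwise the tag with the highest valid RL is focal iff it exceeds the
  second-highest by ≥ `delta_db`; all others non-focal;
* no clear winner, or no two valid RLs to compare → every member
  indeterminate.

`delta_db` defaults to 3 dB. The underlying field decision ("no clear
difference in relative intensity") was an analyst judgement with no printed
threshold; 3 dB is the smallest margin that is conventionally treated as a
real level difference, and at the geometry the method targets (tens of
metres of separation, 1 m tag offset) the expected gap is an order of
magnitude larger, so results are insensitive to the choice. A cluster with
exactly one valid RL and no masking information is labelled indeterminate
rather than awarded to the only measurable tag: a single number provides no
*relative* evidence.

## Bout model

Within-individual inter-call intervals are modelled as a mixture of two
exponential processes — fast (within bouts) and slow (between bouts):

$$f(t) = p\,\lambda_f e^{-\lambda_f t} + (1-p)\,\lambda_s e^{-\lambda_s t}.$$

The fit maximizes the likelihood on the **raw** intervals via EM iterations;
the log-transform enters only through the initialisation, a two-segment
("broken-stick") least-squares fit to the log-frequency histogram of
log-intervals that supplies a starting split into fast and slow subsets.
EM is used because each iteration provably increases the mixture
likelihood and the M-step is closed-form for exponentials; the test suite
cross-checks the optimum against an independent direct `optim()`
maximisation. Convergence is declared at a relative log-likelihood change
below 1e−8. Fits where the two rates differ by less than a factor of 1.5
are rejected as degenerate — a single Poisson process has no bout
structure, and the crossing-point formula below becomes meaningless as the
rates merge. At least 30 intervals are required.

The bout-end criterion is the interval at which the weighted component
densities cross,

$$\mathrm{BEC} = \frac{\ln\!\big(p\lambda_f/((1-p)\lambda_s)\big)}{\lambda_f - \lambda_s},$$

and a bout is a maximal run of ≥ 2 calls whose successive start-to-start
intervals fall below it. Singleton calls are not bouts; "mean calls per
bout" averages over bouts, not calls. The criterion is fitted on intervals
pooled across individuals by default — bout timing is treated as a
species/dataset property, and per-individual interval counts are often too
small to identify the slow process — with per-individual fitting available
by calling `fit_bout_model()` on a single whale's series.

On simulated data (20 datasets of 1000 intervals from
p = 0.75, λf = 0.5 s⁻¹, λs = 0.01 s⁻¹, true BEC 10.23 s) the median
relative error of the recovered criterion is ~3–5% and of both rates below
20%.

## Vocal exchanges

For each call, the exchange interval is the time to the next strictly later
call by a *different* individual. The probability of an answer within a
horizon (100 s by default) is reported two ways, because the density
estimator underlying the published quantity is not uniquely determined:

* `auc_kde` — trapezoidal integral over [0, horizon] of a Gaussian kernel
  density with Silverman's bandwidth, **reflected at zero**: intervals are
  non-negative, and an unreflected kernel estimate leaks mass below zero
  and biases the integral down near the boundary;
* `proportion_empirical` — the fraction of intervals ≤ horizon.

For n ≥ 500 the two agree within 0.05 on uniform, exponential and mixture
interval laws; both are emitted so the choice is transparent.

## Dive context

Depth at call time is linear interpolation of the 5 Hz pressure record at
the call's *start* (nearest-sample lookup differs by at most the
within-sample descent, ≤ 0.2 m at 1 m/s; interpolation is the less biased
choice and the difference is immaterial at these rates). A dive is a
maximal excursion at or below 2 m depth lasting ≥ 10 s: the 2 m figure is
the surface-call threshold the analysis already uses, and the 10 s floor
rejects pressure-sensor blips; neither parameter is sharp, and both are
configurable. Surface calls are those shallower than 2 m at onset.

## The scene simulator

The simulator exists to give the analysis chain a ground truth the field
data cannot provide: who really called, at what level, from where. It
emulates the data-collection situation the method requires — a fully tagged
group of 2–3 whales, isolated from other whales — with:

* **Tracks** at 5 Hz: whales anchored on a segment/polygon with
  nearest-neighbour spacing `spacing_mean`, either static (`fixed`) or
  wandering around the anchors under an Ornstein–Uhlenbeck pull
  (`ou_wander`); depth cycles between a 20% surface phase (0.5 m) and a
  per-cycle maximum drawn between 60 and 100% of `dive_depth_max` (default
  45 m, the middle of typical 30–60 m feeding-ground dives) every
  `dive_cycle_s` (default 300 s).
* **Calls** as a renewal process with two-process-mixture intervals
  (defaults p = 0.75, λf = 0.5 s⁻¹, λs = 0.01 s⁻¹); on hearing a
  conspecific's spontaneous call, each other whale answers with probability
  `response_prob` (default 0.5) after an exponential latency (mean 20 s).
  Responses are triggered by spontaneous calls only, so the insertion
  process cannot cascade; the real mechanism of answering is unknown, and
  this is the simplest device that produces the observed temporal
  association between individuals' calls. Source levels are Normal(155, 6)
  dB re 1 µPa @ 1 m — a simulator choice, as no source-level distribution
  for these social calls is established — and durations Normal(1, 0.3) s.
* **Propagation** by geometric spreading only, `RL = SL − k·log10(r)` with
  k = 20 (spherical) and `r` the 3-D source–receiver distance, floored at
  1 m; the caller's own tag sits at a fixed acoustic offset of 1 m. At the
  sub-kilometre ranges the grouping criterion implies, absorption and
  multipath refinements would not change the RL *ordering*, which is all
  the caller-ID decision consumes. A call registers on a tag only when its
  RL clears the noise floor (default 95 dB) by `detect_snr` (default
  10 dB).
* **Waveforms** (optional): each call is a Hann-windowed 300→800 Hz linear
  FM sweep — a stand-in with energy in the band these social calls occupy,
  not a vocalisation model — summed into Gaussian noise at the configured
  floor, one WAV per tag.

Waveform calls are calibrated *through the measurement chain*: the unit
sweep is conditioned, windowed and rms-measured exactly as an analysed call
would be, and the scale factor is chosen so that this measured level equals
the target RL. Scaling the raw broadband rms instead would make every
measured level fall short of its target by the energy the 500 Hz high-pass
removes from the lower third of the sweep (~1–2 dB depending on duration)
— a calibration artefact, not a property of the method. With chain-based
calibration the round trip closes to < 0.01 dB noise-free, and the 0.5 dB
validation tolerance absorbs windowing interaction with real noise.

Detection times are the emission times; the ≤ 0.33 s propagation delay
across a group is far below the 0.5 s matching tolerance and is not
modelled. All randomness flows from the single `seed`; identical
configurations reproduce byte-identical scenes, selection tables and WAVs.

What the simulator does **not** emulate — and hence what passing tests do
not establish about field data: analyst annotation variability (spans are
exact), call-type diversity and frequency overlap with noise, tag placement
differences that shift the own-tag offset between deployments, surfacing
self-noise bursts, and propagation anomalies. The noise-masking pathway
(the `noise_flag`) is exercised in tests by flagging detections directly
rather than by synthesising masking noise.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run simulations sized so the
statistical claims are meaningful but desk-scale: mixture fits on 1000
intervals (×20 replicates), detection-level scenes of 1200–1800 s,
waveform scenes of 4–10 minutes at 24–96 kHz, and 1000-case brute-force
oracle sweeps for the interval operators. These sizes put simulation
standard errors well inside the asserted tolerances.

## Known limitations

* Absolute dB values depend on the full-scale-equals-1-V convention; use
  relative levels across tags for inference unless the tag's gain chain is
  known.
* The mixture is fixed at two processes; datasets with three timescales
  (e.g. bouts within exchanges within sessions) will fold the extra
  structure into the two fitted rates.
* Indeterminate calls are never tie-broken by prior caller identity or call
  type; whales in physical contact remain unresolvable by this method.
* The pipeline assumes tags are already coarsely time-aligned; it refuses
  clock offsets above 60 s rather than attempting alignment itself.
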