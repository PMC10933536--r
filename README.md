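# focalcall

Caller identification and individual acoustic behaviour from simultaneous
animal-borne sound tags.

When every member of a small social group of whales carries an acoustic
recording tag, a call should register loudest on the tag attached to the
animal that produced it — its tag is closest to the sound source regardless
of the call's source level. `focalcall` implements this relative
received-level (RL) method of caller identification and the individual- and
group-level acoustic statistics it unlocks: call rates and silence, call
bouts, inter-individual vocal exchanges, and the depth of call production.
A multi-tag acoustic scene simulator with full ground truth supports
end-to-end validation of the whole chain.

## What it computes

**Received levels.** Each annotated call is decimated to 12 kHz, high-pass
filtered at 500 Hz (zero-phase 4th-order Butterworth) to suppress flow
noise, restricted to its 90% cumulative-energy window, and its rms level is
converted to dB re 1 µPa through the hydrophone sensitivity (−171 dB re
1 V/µPa by default):

    RL = 20·log10(rms) − sensitivity

Calls that overlap other calls or flagged noise on the same tag, clip, or
are silent are marked invalid and excluded.

**Caller assignment.** Detections of the same physical call are matched
across tags (start times within 0.5 s and spans overlapping by ≥30% of the
shorter, single-linkage), and each unique call is labelled *focal* on the
tag with the highest RL when it exceeds the runner-up by at least a margin
ΔdB (default 3 dB), *non-focal* elsewhere, and *indeterminate* when no tag
stands out. Calls seen on a single tag are focal there; when every tag but
one is masked by noise, the unmasked tag is focal.

**Bouts.** Inter-call intervals (ICIs, start-to-start within an individual)
are modelled as a two-process exponential mixture — a fast within-bout
Poisson process and a slow between-bout process:

    f(t) = p·λf·exp(−λf·t) + (1 − p)·λs·exp(−λs·t)

fitted by maximum likelihood (`fit_bout_model()`, an S3 model object with
`print`/`summary`/`coef`/`logLik`/`predict`/`simulate`/`plot` methods). The
bout-end criterion (BEC) is the interval at which the two weighted
densities cross,

    BEC = log(p·λf / ((1 − p)·λs)) / (λf − λs),

and runs of ≥2 calls with ICIs below it are bouts.

**Vocal exchanges.** For every call, the interval to the next call by a
*different* individual; the probability of a conspecific answer within a
horizon (default 100 s) is reported both as the integral of a
boundary-corrected Gaussian kernel density and as the empirical fraction.

**Call depths.** Depths at call times are interpolated from the 5 Hz
pressure record; dives are excursions ≥2 m for ≥10 s; calls shallower than
2 m are surface calls.

## Worked example

Simulate a half-hour scene with two tagged whales 100 m apart, write it to
disk in the package's exchange formats (Raven-style selection tables, depth
CSVs, YAML manifest), and run the full pipeline:

```r
library(focalcall)

cfg <- sim_config(n_whales = 2, duration = 1800, spacing_mean = 100, seed = 7)
sc  <- simulate_scene(cfg)
dir <- tempfile(); write_scene(sc, dir)

man <- read_manifest(file.path(dir, "manifest.yaml"))
res <- run_pipeline(man, run_config(seed = 7))
res
#> Pipeline result for group sim_seed7 (0.50 h)
#>   147 unique calls: 147 assigned (100%), 0 indeterminate, 135 multi-tag
#>   group call rate 294.0 calls/h; 93% silent; longest silence 244 s
#>   BEC 9.78 s
```

At 100 m spacing the geometric RL gap between the caller's own tag (1 m)
and the other whale's tag is 20·log10(100) = 40 dB, far above the 3 dB
margin, so every call is assigned — and checking against the simulator's
ground truth shows every assignment is correct. The fitted bout model
recovers the generating ICI mixture:

```r
res$bout_model
#> Two-process exponential mixture bout model
#>   n = 145 intervals, log-likelihood = -531.74
#>   p (fast)      = 0.592
#>   lambda_fast   = 0.3584 /s  (mean within-bout ICI 2.79 s)
#>   lambda_slow   = 0.0188 /s  (mean between-bout ICI 53.2 s)
#>   bout-end criterion = 9.78 s
```

(The slow rate is inflated and the weight shifted relative to the
generating values because conspecific responses — enabled by default —
add short cross-stimulated intervals; see the methods vignette.)
Per-whale summaries, the exchange probability and call depths:

```r
res$per_whale[, 1:5]
#>   whale_id n_focal call_rate n_bouts bout_rate
#> 1   whale1      83       166      17        34
#> 2   whale2      64       128      10        20
res$exchange$proportion_empirical
#> [1] 0.9246575
res$call_depths$pooled$mean_depth
#> [1] 11.33282
```

A thin command-line front end with `simulate`, `run` and `fixtures` verbs
is installed at `inst/cli/whaletag.R`.

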