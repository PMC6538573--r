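---
title: "Preprocessing pupil size data with pupilprep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing pupil size data with pupilprep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilprep)
```

## The problem

Video eyetrackers report pupil diameter as a by-product of gaze
tracking, and the resulting time series is far from analysis-ready:
blinks leave missing-data gaps flanked by spurious dips (the eyelid
partly occludes the pupil before the tracker loses it entirely),
tracking glitches produce isolated spikes and short clusters of
deviant samples, and momentary misdetections — for instance a "pupil"
found during closed eyes — leave small islands of samples inside long
gaps. On top of that, sampling is often nonuniform, the two eyes are
recorded at slightly different sizes, and different trackers mark
invalid data differently.

`pupilprep` turns such recordings into smooth, uniformly sampled,
per-segment summaries in four steps: standardization, robust artifact
filtering, valid-sample processing, and segmentation. The design goal
is tracker independence: everything operates on a standardized
timestamp + left/right diameter table, and all rejection rules are
either robust statistics of the data themselves or explicit durations.

## Step 1 — standardization

`load_raw()` maps arbitrary tabular exports onto the internal model via
a `format_spec()` (column names, timestamp unit, invalid-value
sentinels, optional validity columns with per-eye or per-row scope).
Clearly invalid samples — nonpositive diameters, sentinel values,
source-flagged samples — carry no information and are removed at
ingestion rather than being left for the statistical filter. Rows that
were *empty* at the source are kept as missing samples: missingness is
information (it drives gap-edge and sparsity filtering), invalidity is
not. Timestamps are sorted and exact duplicates keep the first
occurrence, so sample-to-sample time differences are strictly positive
everywhere downstream — the dilation-speed statistic divides by them.

## Step 2 — the raw-data filter

Five stages run per eye, each seeing only the survivors of the
previous one.

**Feasible range.** Diameters outside 1.5–9 mm (inclusive; both bounds
configurable) are physiologically impossible for human pupils and are
rejected first so that they cannot contaminate the robust statistics
below.

**Dilation speed.** For samples `d[i]` at times `t[i]`, the dilation
speed is

```
d'[i] = max( |d[i] - d[i-1]| / (t[i] - t[i-1]),
             |d[i+1] - d[i]| / (t[i+1] - t[i]) )
```

with single-sided values at the series ends (the first and last sample
use their only neighbor rather than being dropped — this preserves
data and is worth knowing when comparing against implementations that
discard endpoints). Normalizing by the time difference makes the
statistic meaningful under nonuniform sampling and across gaps. True
dilation and constriction are slow; blink edges and glitches are fast.
Samples are rejected when their speed strictly exceeds

```
threshold = median(d') + n * MAD(d'),   MAD = median(|d' - median(d')|)
```

The MAD is used raw, without the 1.4826 normal-consistency constant —
the multiplier `n` absorbs any scaling. `n` defaults to 16 but has no
universally correct value: it should be tuned per dataset (tracker
noise, sampling rate and pupil-detection algorithm all shift the speed
distribution), which is why the filter report echoes every threshold
actually used and `plot_steps()` color-codes every stage's rejections.

When the MAD is zero (a majority of identical speeds, e.g. hand-built
fixtures or constant signals) the threshold degenerates to the median:
a constant series rejects nothing under the strict comparison, while
any sample moving at all is rejected. `min_threshold_epsilon` provides
a floor for users who want to soften this; its default of 0 keeps the
formula untouched.

**Gap edges.** After speed filtering, samples bordering missing-data
gaps are still suspect — occlusion dips can be slow enough to pass the
speed filter. Samples within 50 ms (inclusive) of either edge of a gap
longer than 75 ms (strict) are rejected. Gaps are measured between
consecutive present samples of that eye after the previous stages; a
missing run before an eye's first sample also counts as a gap, but
only its sample-adjacent edge can reject anything — the recording
boundary itself is never treated as a gap edge. The margin comparisons
carry a 1 ns slack so the inclusive boundary is stable on
floating-point time grids.

**Trend-line deviation (multipass).** Clustered invalid samples
survive speed filtering because their mutual changes are small.
Instead they are caught by their distance from a smooth trend line:
the currently valid samples are linearly interpolated onto a uniform
grid (100 Hz by default — comfortably above the 4 Hz cutoff, and
cheaper than the full output rate inside an iterated filter) and
smoothed with the same zero-phase 4 Hz low-pass used in Step 3. The
absolute deviations of *all samples considered in the first pass* are
fed through the same median + n·MAD threshold. Because an outlying
cluster pulls the first trend line toward itself, the filter runs a
second pass (configurable upward) with the cluster gone; clean
neighbors rejected in pass 1 are then reinstated. Reinstatement is
limited to the filter's own scope — it can never resurrect samples
rejected by the range, speed or gap-edge stages, and each stage runs
exactly once, in order.

**Sparsity.** Valid pupil data are temporally contiguous. The valid
samples are split at gaps longer than 40 ms, and sections spanning
less than 50 ms (last minus first timestamp, so a lone sample spans
0 ms) are rejected wholly.

## Step 3 — processing the valid samples

**Binocular fusion.** The two pupils are highly correlated but differ
by a slowly drifting size offset, so simply averaging whatever is
available would introduce jumps whenever one eye drops out. At
double-coverage points (mutual nearest-neighbor matches within half
the median inter-sample interval) the fused value is exactly
`(L + R) / 2` and the signed offset `R − L` is recorded; at
single-coverage points the offset is linearly interpolated (held
constant beyond the first/last double-coverage point, avoiding runaway
extrapolation) and the available eye is shifted by half of it. If no
double-coverage exists at all the offset is unidentifiable and the
better-covered eye passes through unadjusted, with a warning.

**Upsampling and smoothing.** The nonuniform valid samples are
linearly interpolated onto a uniform grid (1000 Hz default — 1 ms
resolution for segment arithmetic; linear interpolation cannot
overshoot inside gaps, unlike splines). The grid signal is smoothed by
a first-order Butterworth low-pass at 4 Hz applied forward and
backward, giving zero phase shift (pupil event latencies are
preserved) and unit DC gain. The forward–backward pass is realized
with odd-reflection padding at both ends so start-up transients decay
inside the padding; r-signal's stock `filtfilt` starts from zero
state, which would bend the first ~0.5 s of every recording toward
zero.

**Gap masking.** Interpolation across long gaps fabricates data, so
grid points lying strictly between raw valid samples more than 250 ms
apart are set missing after smoothing (masking after smoothing means
filter transients inside masked stretches are discarded with them).
The masked points remain flagged in the output
(`interpolated_over_gap`), so the provenance of every grid point is
reconstructible.

## Step 4 — segmentation

Segments are half-open windows `[t_start, t_end)` on the grid — the
grid point at `t_end` belongs to the next window, so contiguous
segments partition the grid exactly. Per segment: mean, max, min,
standard deviation (n−1 denominator, `NA` below two points), missing
percentage and grid-point count. Segments exceeding the missing-data
limit are *flagged*, never dropped — and the limit itself,
`max_missing_pct`, deliberately has no default: how much missing data
is tolerable depends on the paradigm, so the pipeline refuses to guess
(the shipped config template carries it commented out).
`bin_timecourse()` produces fixed-width bin means (100 ms default) for
multilevel time-course models; the trailing partial bin is kept and
flagged. `pair_baselines()` attaches each response segment's baseline
mean (matched by `trial_id`, or by the nearest preceding baseline when
no trial ids exist) without applying any correction — subtractive
versus divisive baseline correction is an analysis decision, not a
preprocessing one.

## The synthetic generator

There is no packaged real recording, so validation rests on
`generate_recording()`: a seedable two-eye simulator whose every
injected artifact is recorded in a ground-truth ledger. The true trace
is a base diameter (4.5 mm) plus slow sinusoids (0.12 and 0.31 Hz,
0.3 and 0.15 mm — ordinary slow pupil drift), the eyes straddle it by
a slowly drifting offset (0.3 mm mean), and each eye gets independent
Gaussian noise (SD 0.03 mm, a typical research-grade tracker at
moderate rates). Artifacts follow the classes above: blinks (120 ms
gaps with 0.6 mm linear occlusion ramps over the 12 ms of edge
samples — the dip's functional form is not constrained by any
published shape, a ramp is the simplest monotone model), spikes
(0.8 mm), clusters (5 samples at 0.5 mm) and islands (40 ms runs
inside 100 ms flanks). Default artifact amplitudes sit at or above
10× the noise SD, i.e. clearly pathological, and the defaults are the
study conditions the acceptance checks run under: 60 s at 250 Hz,
uniform sampling (timestamp jitter is exercised separately).

What passing these tests shows — and does not. The generator produces
stationary noise, a perfectly smooth underlying trace, and artifacts
drawn from exactly the taxonomy the filter targets. Real data add
gaze-position foreshortening, luminance responses, slow drift of
tracker calibration, and artifact shapes outside the taxonomy; none of
these are modeled, so the measured sensitivity/false-rejection figures
bound behavior under the taxonomy, not in the wild. Foreshortening and
luminance correction are explicitly out of scope for this package, as
is blink-event labeling (the intersample differences are used for
rejection only).

## Numerical choices and degenerate inputs

* Inclusive boundaries everywhere a duration is compared ("within
  50 ms" rejects at exactly 50 ms; range bounds inclusive); gap
  qualification is strict ("larger than 75 ms").
* Median/MAD degeneracies resolve by the formula itself (threshold =
  median when MAD = 0); constant series reject nothing.
* Fewer than 2 valid samples: speed, trend and resampling operations
  raise insufficient-data errors; the pipeline surfaces them with the
  stage name.
* An all-rejected eye yields a warning and an empty valid set, not an
  error — the other eye may still carry the recording.
* Problem sizes in the test suite: fixtures run at 100–1000 Hz over
  1–30 s; the acceptance suite uses twenty 60 s, 250 Hz scenarios.

## Known limitations

* The speed filter runs once; gaps created by its own rejections are
  handled by the gap-edge stage, not by a second speed pass.
* Trend lines inside the deviation filter are built over all gaps
  regardless of length (they only score deviations and are never
  output); the 250 ms interpolation limit applies to output signals
  only.
* The left–right offset model is piecewise linear between
  double-coverage points; pathological alternating dropouts could
  alias it.
* `n = 16` is a starting point, not a recommendation — inspect the
  diagnostic figures and the filter report, and tune per dataset.
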