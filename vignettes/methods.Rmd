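---
title: "Methods: simulating and analyzing semantic-priming adaptation in MTL recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing semantic-priming adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtladapt)
```

## The scientific problem

Neural adaptation — the reduction of bulk-tissue neural activity to
repeated or semantically related stimuli — can arise from several distinct
single-neuron mechanisms:

* **sharpening** — a neuron keeps firing to its optimal stimulus but
  disproportionally attenuates responses to non-optimal stimuli;
* **fatiguing** — a neuron attenuates proportionally across all
  response-eliciting stimuli, preserving its tuning-curve shape;
* **facilitation** — periods of firing shorten (earlier offsets), leaving
  rates intact.

In a semantic priming task, a target image is *primed* when the preceding
image belongs to the same semantic category and is a *control* target
otherwise. Behaviorally, priming shortens reaction times; the question is
which single-neuron mechanism accompanies the macroscopic (iEEG ERP)
adaptation. `mtladapt` implements the complete analysis chain — behavior,
iEEG, cluster statistics, and single-unit tuning analyses — together with
a synthetic-session generator whose ground-truth mechanism is
configurable, so that every stage can be validated by parameter recovery.

## The session design and its generator

A session comprises 10 runs; in each run all 100 images (10 semantic
categories x 10 exemplars; 5 manmade, 5 natural categories) appear exactly
once as target, preceded by one extra presentation that only primes the
first target and is discarded. Across the session every image is primed
in exactly 5 of its 10 presentations.

`generate_trial_sequence()` meets these constraints constructively rather
than by blind rejection: a session plan first fixes in which runs each
stimulus is primed (resampled until every run x category cell keeps at
least one control exemplar); within a run, each category's primed
exemplars are appended to blocks led by a control exemplar, and blocks
are ordered with no two same-category blocks adjacent (a greedy scheduler
with a forced pick whenever one category holds more than half of the
remaining slots). Both stages restart on the rare dead end and fail with
an explicit error after a bounded number of attempts — constraints are
never silently relaxed. `validate_trial_sequence()` re-checks every
invariant independently and is itself exercised against hand-broken
tables.

```{r}
ss <- generate_stimulus_set(10, 10, seed = 1)
tt <- generate_trial_sequence(ss, n_runs = 10, seed = 1)
validate_trial_sequence(tt, ss)$valid
```

### Reaction times

`simulate_behavior()` draws RTs from a shifted lognormal
(`RT = shift + Lognormal(meanlog, sdlog)`), which produces realistic right
skew, with an additive priming effect on the median. The defaults
(`shift = 193` ms, `meanlog = log(500)`, `sdlog = 0.35`, `effect = 109`
ms) are calibrated so that the statistic the analyses report — the median
across sessions of per-session mean RT, which for a skewed law sits about
20 ms above the distribution median after trimming — lands at the study's
conditions (about 713 ms control, 604 ms primed). Error rates default to
0.6% (primed) and 2% (control). A configurable fraction of trials
(default 2%) is replaced by planted outliers drawn near +-3 SD of the
generating law (slow lapses 2000-3000 ms, fast anticipations 20-80 ms)
and flagged in ground truth; plants are deliberately *not* more extreme,
because a single absurd value inflates the pooled session SD to the point
where the 2.5 SD rule can no longer exclude anything.

### Spike trains

`simulate_unit()` draws spikes from an inhomogeneous Poisson process:
baseline rate outside the response window, `baseline x gain(stimulus)`
within `[onset, onset + duration)`. Tuned stimuli (by default exemplars
of a single semantic category) receive non-increasing gains per rank —
the default `c(8, 6, 4, 3, 1)` gives a graded "semantic tuning curve"
rather than an all-or-none response, with four response-eliciting
stimuli strong enough that the binwise detection criterion actually
finds them: the population the rank analyses emulate is the *selected*
multi-responsive subpopulation, so default units must be able to pass
the selection they are meant to feed. Condition modulation on primed trials implements
the mechanism under test exactly as defined above: fatiguing multiplies
all tuned gains by `1 - attenuation`; sharpening spares rank 1 and
attenuates ranks >= 2; facilitation shortens the response duration by the
same factor and leaves rates alone. Spike times are continuous
milliseconds relative to stimulus onset; all windows are half-open
`[start, end)` so sample and spike membership is unambiguous.

### iEEG

`simulate_ieeg()` renders each trial as a condition-specific template
(sum of Gaussian deflections; by default a negative peak at 283 ms and a
positive peak at 520 ms, the primed condition scaled to 0.75 and shifted
-16 ms) plus 1/f ("pink") noise, sampled at 256 Hz over `[-1000, 2000)`
ms. Artifacts are injected as multiplicative amplitude bursts (default:
5% of trials, x10 over 300 ms) with ground-truth flags, so the
median-ratio rejection filters can be scored for recall. What the
generator does *not* emulate: line noise, electrode drift, correlated
noise across trials, epileptiform transients, or any coupling between the
spiking and field-potential channels — passing tests therefore certify
the statistical machinery under the stated model, not robustness to every
pathology of clinical recordings.

## Analyses

### Behavior

Per session, trials with `RT < M - 2.5 SD` or `RT > M + 2.5 SD` (M, SD
from all of the session's RTs, conditions pooled) are excluded; incorrect
trials are excluded from RT averaging by default (configurable — the
convention is standard but not universal). Session-wise condition means
enter a two-tailed Wilcoxon signed-rank test. With
`exclude_response_priming = TRUE`, control trials whose prime belongs to
the other manmade/natural meta-category — trials on which prime and
target require different button presses — are dropped first, isolating
semantic relatedness priming from motor response priming. The unit of
observation is the session; a `participant` argument aggregates sessions
per participant first when participant-level inference is wanted.

### iEEG preprocessing and artifact rejection

Continuous traces are resampled to 256 Hz (polyphase, anti-aliased),
band-passed 0.1-80 Hz with zero-phase (forward-backward) Butterworth
filtering — phase preservation is non-negotiable here because downstream
analyses measure peak *latencies* — segmented to `[-1000, 2000)` ms, and
baseline-corrected by the `[-200, 0)` ms mean. The band is realized as a
2nd-order high-pass cascaded with a 6th-order low-pass: a low filter
order keeps the 0.1 Hz edge numerically stable, while the 6th-order
low-pass, applied twice by `filtfilt`, attenuates a 100 Hz tone by more
than 20 dB. The trace mean is removed before filtering so that a DC
offset cannot ring through the very slow high-pass transient.

Artifact rejection computes, on the same set of segments, (1) each
segment's absolute maximum divided by the median of these maxima and (2)
each segment's median absolute sample divided by the median of these
medians; a segment is excluded when either ratio strictly exceeds 2.5
("exceeds" is read as strict). The two criteria are evaluated
independently and OR-combined without re-computation after removal, so
their order is immaterial.

### Cluster-based permutation statistics

Paired t-tests at every sample between condition traces of the same
sessions; clusters are maximal runs of consecutive samples with
`p < 0.001` and a common t sign (runs are split at sign changes — a
summed t of mixed sign would be uninterpretable). The null is built by
swapping the condition labels of each session independently (equivalently,
flipping the sign of each difference trace), 1000 times by default,
recording per permutation the maximum positive and minimum negative
cluster sums (0 when no cluster forms). The max-statistic convention is
used because it controls familywise error over clusters. An observed
positive cluster is significant when its sum exceeds the 99th percentile
of the positive-tail null (negative: below the 1st percentile); a
Monte-Carlo p-value `(1 + #extreme) / (1 + n_perm)` is reported alongside
because percentile decisions alone do not convey evidence strength. When
the requested permutation count exceeds the `2^n` distinct sign
assignments the test switches to exact enumeration with a warning.

### Single-unit response detection

Firing rates are z-scored per unit against the mean and SD of the
baseline-window (`[-500, 0)` ms) rates of all trials pooled over
conditions; the activation window for z-scores is `[100, 1000)` ms, while
the detection criterion and tuning curves use the response window
`[0, 1000)` ms — the two windows are kept as distinct named constants on
purpose.

A stimulus is response-eliciting when (a) rank-sum tests of its 19
overlapping 100 ms response bins against the unit's baseline
distribution, Simes-corrected over the 19 bins, are significant at
`alpha = 0.001`; (b) the mean response-window rate over its 10
presentations exceeds the mean baseline rate; and (c) at least one spike
occurs in the response window on at least half of the presentations.
Two design decisions matter here. First, criterion (a) is the Simes
*global* test (reject iff any sorted `p_(i) <= i * alpha / m`), not a
raw-minimum rule. Second, the baseline distribution is the spike rate in
the five 100 ms bins tiling `[-500, 0)` ms of every trial, i.e. the same
bin width on both sides of the rank-sum test. Testing 100 ms bin rates
against rates integrated over the whole 500 ms baseline window would
compare two differently-discretized distributions and reject *null* units
at double-digit rates; with matched bin widths the two samples are
exchangeable for a unit at baseline, and the measured false-positive rate
is a fraction of a percent while planted five-fold responses are detected
essentially always. Rank-sum p-values use the tie-corrected normal
approximation (the 10-versus-thousands sample sizes make exact
enumeration pointless); the implementation is verified against
`stats::wilcox.test` on random data.

### Tuning curves and mechanism classification

For units with at least `min_stimuli = 4` response-eliciting stimuli
(2 and 3 supported as variants), stimuli are ranked by pooled
(primed + control) response-window rate, ties broken by stimulus id.
Per-rank condition means (5 trials each) are normalized by `FRmax`, the
control rate of the rank-1 stimulus, so the control curve starts at 1 by
construction. Ranks 1-4 are contrasted across units with a paired t-test
(default; signed-rank reported alongside, as the two conventions coexist
in the literature), and the attenuation `control - primed` is contrasted
between every pair of ranks.

`classify_population_profile()` calls a rank *attenuated* when its test
is significant **and** primed < control — the direction is part of the
definition, because the mechanisms predict attenuation, and a significant
rank-1 difference with primed *above* control is evidence of neither.
Sharpening requires rank 1 not attenuated, rank 2 attenuated, and a
significantly larger attenuation at rank 2 than rank 1; fatiguing
requires rank 1 attenuated with no significant rank-2 vs rank-1
attenuation difference; everything else is indeterminate. The rank-2 vs
rank-1 pair is the decisive attenuation comparison (using all six rank
pairs would inflate the "some pair significant" rate under uniform
attenuation and misclassify fatiguing cohorts).

### Bursts and the pre-stimulus test

For units with baseline rate above 2 Hz, firing onset and offset per
trial come from Poisson-surprise burst detection: the spike run
maximizing `S = -log10 P(>= k spikes in T | baseline rate)` is accepted
when `S >= 2`. The maximization scans all candidate run endpoints —
per-trial spike counts are small, so the exact maximizer is affordable
and subsumes greedy extension. Because the maximum is taken over many
candidate runs, the nominal per-run level understates the acceptance rate
on homogeneous trains; the threshold is exposed in configuration and the
false-acceptance rate is verified to fall steeply with it. For
low-baseline units the fallback is the first spike in `[100, 1000)` ms,
which contributes onset latencies only, not durations.

The spreading-activation probe compares, per unit with at least one
response-eliciting stimulus, mean z-scored firing in `[-500, 0)` ms
before primed versus control presentations of those stimuli, with a
paired t-test across units (raw-rate variant available).

## Pipeline, reproducibility, problem sizes

`run_config()` collects every constant with the study's analysis values
as defaults and validates ranges at load time; `run_all()` executes the
full chain on simulated sessions and emits a JSON report plus CSV
exports. One global seed expands deterministically into per-stage seeds
(a fixed hash of the stage label), so any stage can be rerun in
isolation; reports are byte-identical across reruns of the same seed and
embed the package version, the seeds, and a config hash.

Default simulation sizes are chosen so a full run stays interactive on a
single core: 8 sessions, 4 iEEG regions, a 24-unit cohort, 1000
permutations. Calibration and recovery studies use study-scale inputs
where the quantity demands it (59-session behavioral cohorts; 88- and
123-unit cohorts at attenuation 0.3 with 10 trials per stimulus split
5/5; 20-pair x 768-sample ERP datasets) and replicate counts in the tens
to hundreds. Mechanism-recovery cohorts simulate each unit only on the
trials of its five tuned stimuli — the only trials the rank contrast
consumes — which leaves the contrast's sampling distribution untouched
while keeping cohort replication cheap; response-detection operating
characteristics are measured separately on full 1000-trial sessions.

## Known limitations

* The generator's mechanisms are pure cases; real populations presumably
  mix mechanisms and regions, and the classifier only reports the three
  canonical profiles or "indeterminate".
* Poisson spiking ignores refractoriness and bursting statistics of real
  neurons; the burst detector is correspondingly easier to satisfy on
  synthetic data than on recordings.
* Burst *duration* estimates are rate-dependent: when a mechanism
  attenuates primed firing rates (sharpening, fatiguing), the
  surprise-maximizing spike run shortens even though the generator's
  response window did not, so a primed-vs-control duration difference is
  not by itself evidence of facilitation. The facilitation recovery test
  uses unchanged rates with a genuinely shortened window, where the
  contrast measures what it claims to.
* The iEEG noise model (stationary 1/f plus multiplicative bursts) does
  not emulate non-stationary clinical artifacts, and re-referencing is
  assumed to have happened upstream.
* The RT distribution and its between-session variance are not published
  quantities; the defaults are one reasonable calibration, concentrated
  in `rt_params()` so they can be changed in one place.
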