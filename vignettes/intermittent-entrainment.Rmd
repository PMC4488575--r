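---
title: "Detecting intermittent entrainment in self-paced tapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting intermittent entrainment in self-paced tapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapentrain)
```

This vignette documents the statistical model behind `tapentrain`, the
conventions and numerical choices the implementation commits to, what the
synthetic tapper does and does not emulate, and the package's known
limitations.

## The inference problem

A participant taps two keys alternately, 30 taps per trial, at their own
pace, while an isochronous tone sequence (inter-stimulus interval, ISI,
320–800 ms) plays as a to-be-ignored distractor. The full design collects,
per condition, 6 sessions of 3 test trials (18 trials, 540 taps), plus 30
no-stimulus training trials interleaved through the study. The question is
whether tap timing is attracted to the beat — and the statistical
difficulty is that a tapper whose spontaneous tempo happens to match the
ISI will show concentrated tap phases *without any coupling*, simply by
being regular. The pipeline therefore layers four analyses:

1. a condition-level omnibus test of phase uniformity on the pooled taps;
2. a Monte Carlo re-pairing null that asks how often self-paced tapping
   alone, re-paired with a stimulus sequence it never heard, produces an
   equally extreme omnibus result;
3. a trial-by-trial Rayleigh analysis that localises entrainment episodes;
4. spontaneous-tempo statistics that relate detectability to the percent
   mismatch between motor tempo and ISI.

## Phase mapping

Each tap is matched to the **nearest** stimulus onset; the signed
asynchrony (positive = tap after onset) is divided by the local ISI and
scaled to degrees, onsets at 0°, range (−180°, 180°]. Conventions the
implementation fixes, where the procedure leaves room:

- **Matching rule.** Nearest-onset matching is the only rule under which
  "onsets at 0° with a ±180° range" is coherent; a tap exactly midway
  between onsets is assigned +180° relative to the *preceding* onset, so
  the antipode has one representation (`wrap_degrees(-180)` is `+180`).
- **Envelope.** Taps earlier than the first onset minus half the first
  interval, or later than the last onset plus half the last interval, are
  excluded and counted (`n_dropped`), not extrapolated.
- **Time zero.** Trial-relative time zero is the first stimulus onset for
  test trials. For re-paired training trials (which never heard a
  stimulus) the tap clock zero is aligned to the track zero; no other
  alignment is defensible without extra assumptions, and the choice only
  fixes an arbitrary global rotation of each re-paired trial's phases —
  the uniformity tests are rotation-invariant, so the null is unaffected.
- **RANDOM condition.** With irregular stimulus sequences the
  normalisation is ambiguous. Default: the interval that *contains* the
  tap (`random_normalization = "local"`), which keeps |angle| ≤ 180 and
  treats each inter-onset gap as one cycle; a fixed-reference variant
  (`"fixed"`, with `reference_isi_ms`) is exposed as a switch.
- Degrees are the external unit everywhere; radians appear only inside
  trigonometric code.

## The two uniformity tests

**Hodges–Ajne omnibus test.** The statistic `m` is the minimum, over all
half-circles, of the number of sample points the half-circle contains.
Half-circles are closed on the leading boundary and open on the trailing
one, so antipodal ties are counted exactly once; this makes `m`
well-defined and checkable by brute force (the test suite compares against
a 3600-rotation scan). The implementation scans the 2n candidate
boundaries defined by the data points and their antipodes with binary
searches (O(n log n)).

The p-value uses the exact null tail
`P(M <= m) = (n − 2m) C(n, m) 2^(1−n)` for `n <= 50` and `m < n/3`,
evaluated in log space with `lchoose` (relative error ~1e−15, so no
big-integer arithmetic is needed). Beyond that, the standard large-sample
approximation `p = sqrt(2*pi)/A * exp(-pi^2/(8*A^2))` with
`A = pi*sqrt(n) / (2(n − 2m))` is used — the 540-tap pools force an
approximation. Two numerical guards matter:

- the approximation is a tail formula and turns back down once
  `n − 2m < sqrt(n)`; in that region the sample carries no evidence
  against uniformity and the implementation reports `p = 1`, which also
  keeps `p` monotone non-decreasing in `m`;
- all p-values are clamped into (0, 1] so downstream log-reporting is safe.

The one-term approximation is accurate where decisions are made: at
`n = 540` its values agree with the simulated null CDF to ~0.02 at every
achievable `m`, and at `n = 50` it tracks the exact tail within 15% for
p between ~0.015 and 0.16 (and is conservative — never smaller than the
exact value — deeper in the tail). Its *relative* error in the far tail
is large; only the crossing of a criterion matters there, and the
conservative direction is the safe one.

Because `m` is integer-valued, the Ajne p-value is discrete: at `n = 540`
its null distribution has atoms of up to ~0.06, the attainable rejection
level just below 0.05 is ~0.0415, and the plain Kolmogorov–Smirnov
distance of its p-values from Uniform(0,1) is bounded below by the modal
atom no matter how well calibrated the test is. Calibration checks in the
test suite therefore measure the discrepancy at the achievable p-values
(jump tops) rather than the raw KS supremum.

**Rayleigh test.** `Z = n R²` with the small-sample-corrected p
`exp(sqrt(1 + 4n + 4(n² − (nR)²)) − (1 + 2n))`. It is used per trial
(n = 30), where a unimodal concentration is the expected signature of an
entrainment episode, and for instructed-synchronization summaries.

A caveat the pipeline is explicitly built around: successive tap phases
within a trial are serially correlated (the tapper is a random walk), so
per-trial Rayleigh p-values are anti-conservative for stable tappers near
the stimulus tempo. This is not a defect of the test implementation but a
property of the data-generating process — it is exactly why the re-pairing
null and the stimulus-vs-no-stimulus vector-length comparison
(`vector_length_comparison()`, a paired t on per-dataset mean resultant
lengths) exist.

## The Monte Carlo re-pairing null

Each iteration draws `n_select = 18` of the (default 30) training trials
without replacement, maps each trial's taps against the stimulus track,
pools the 540 phases, and runs the omnibus test; `proportion_extreme` is
the fraction of iterations with `p_sim <= p_obs` — "at least as skewed",
operationalised through the test's own p-value, which is the only
skewness ordering the omnibus test defines. Since re-paired trials are
aligned at trial start, each trial's phase set is fixed and is computed
once; iterations then only resample and pool, which makes the default
10,000 iterations cheap.

Calibration: with fully independent 18-trial sets the proportion is
uniform on (0, 1) up to the discreteness of the omnibus statistic (KS
~0.04 in the test suite's 200-replicate check). Under the design's own
structure — all simulated sets drawn from *one* 30-trial pool — the
proportions are additionally conditioned on the realised pool, which
inflates their spread (KS ~0.12 intrinsically). The acceptance checks
test both facts separately rather than pretending the pooled version is
exactly uniform.

## Spontaneous-tempo statistics

The tempo summary pools inter-tap intervals (ITIs) across the no-stimulus
trials: the median ITI is the spontaneous motor tempo, and variability is
the **mean absolute deviation about the median** — the single deviation
metric consistent with reporting "median and absolute deviation", and the
band used for outlier exclusion (median ± 2 deviations, closed interval;
deviations are computed *without* prior exclusion by default, exclusion
being a robustness check). Between-group comparisons use pooled-variance
Student's t (the variant that reproduces the published comparison of
median ITIs to three decimals; the published deviation comparison differs
in the third decimal because it was evidently computed from unrounded raw
data). Percent tempo mismatch is `100 |ISI − median ITI| / median ITI`,
with ~20% as the empirical boundary below which the distractor effect
appears.

## The synthetic tapper

No tapping data are deposited with the original study, so the simulator is
a first-class module, not a test fixture. Its generative model is the
minimal structure that reproduces the observed marginal statistics:

- **Motor period**: a random walk, `p_k = p_{k−1} + N(0, drift_sd)`, reset
  to the base period at each trial start;
- **Interval noise**: each ITI adds `N(0, noise_sd)` and is floored at
  `min_iti_ms` (100 ms) so onsets stay strictly increasing;
- **Phase coupling** (optional): the next provisional tap is shifted
  toward the nearest onset.

A single white-noise term cannot produce a large mean absolute deviation
with a stable median; the random-walk component is what makes the
chimpanzee-like preset fluctuate continuously through a trial rather than
pause occasionally. Preset calibration (`inst/extdata/tapper_profiles.yaml`,
versioned):

| preset | base period (ms) | noise SD (ms) | drift SD (ms) | pooled MAD target |
|---|---|---|---|---|
| `chimp_like` | U(355, 450) | 130 | 30 | 120–152 ms |
| `human_like` | U(333, 505) | 20 | 2.5 | 13–23 ms |
| `entrainable` | U(380, 420) | 45 | 10 | intermediate |

The acceptance checks verify that ≥90% of simulated participants land in
the target bands (30 trials × 30 taps each, the design's training-pool
size).

**Coupling shape.** The default correction is the sine phase response of
the classic circle map,

    shift = -alpha * (ISI / 2*pi) * sin(2*pi * asynchrony / ISI),

whose slope at zero phase is `alpha` — so `coupling_gain` keeps its
meaning as "fraction of the current asynchrony corrected on the next tap"
— and whose correction is bounded by `alpha * ISI / (2*pi)` per tap. The
bounded correction is what produces an Arnold tongue: locking occurs only
when the per-cycle tempo offset is smaller than the maximal correction,
i.e. when motor and stimulus tempi are close, which is precisely the
tempo-proximity rule the analysis is designed to detect. Two simpler
shapes were considered and rejected: proportional correction applied at
every phase locks *stably at a shifted phase* even at 30% tempo mismatch
(fixed point `a* = (1−alpha)(a* + Delta)` of the wrapped map), abolishing
any mismatch dependence; proportional correction gated by a hard phase
window fails to recapture a tapper that diffuses out of the window at
matched tempo. The windowed-proportional variant remains available
(`coupling_shape = "proportional"`, `coupling_window_deg`) for users who
want the cruder mechanism.

**Planted-episode studies.** `planted_entrainment_study()` plants exactly
`n` entrained trials among 18. Planted trials start at the stationary
locked asynchrony (SD `noise_sd / sqrt(1 − (1−alpha)²)`) — they model
entrainment *episodes* as they appear in data, where capture has already
happened — while background trials start at uniform phase. The
`entrainable` preset is used because detectability at the strict
trial-level criterion requires sub-chimpanzee asynchrony spread, while
false-positive control requires enough within-trial drift that uncoupled
trials dephase; noise 45 / drift 10 ms satisfies both. At matched tempo
the uncoupled background still produces occasional spurious episodes
(~0.08 per trial at the criterion used) — the simulator reproduces, rather
than hides, the confound that motivates the re-pairing null.

What the simulator does **not** emulate: inter-key biomechanics (the
C4/C5 alternation is a label sequence only), reward and training effects,
wrong-key taps, long pauses, within-trial autocorrelation structure beyond
the random walk (no data exist to calibrate it), period correction (the
coupled tapper adjusts phase, not tempo — instructed synchronization at a
distant ISI is emulated by setting the base period to the target ISI), and
any claim about mechanism in real chimpanzees. Passing recovery tests on
simulated data therefore demonstrate that the *pipeline* detects the kind
of signal it assumes, not that real tapping contains it.

## Multiple-comparison criteria

The published analyses report corrected criteria (0.000794, 0.00000159,
0.000278, 0.0056, 0.00389, 0.0028) without the comparison counts behind
them, and the counts cannot be reconstructed unambiguously. They are
shipped verbatim as `study_criteria`, and `bonferroni_plan()` accepts
either an explicit criterion or `alpha / n_comparisons`. Families are
explicit configuration, never inferred.

## Problem sizes and determinism

Every stochastic operation takes a seed; `simulate_study()`,
`repaired_null()` and `run_study()` are bit-reproducible under it, and the
RNG state of the caller is never disturbed (`withr`-style local seeding).
The test suite exercises the statistics at full pooled size (n = 540,
2,000 replicates for calibration), the recovery experiment at 100
replicates, the re-pairing calibration at 200 replicates × 400 inner
iterations, and the simulator bands at 100 participants per profile;
these sizes give Monte Carlo standard errors comfortably below the
thresholds tested while keeping the whole suite under a few minutes.

## Known limitations

- The omnibus test at 540 pooled taps detects *any* phase-density
  nonuniformity, including the weak dwell asymmetry of a tapper drifting
  through an incommensurate rhythm; condition-level significance alone is
  therefore not evidence of episodic locking — the trialwise analysis and
  the re-pairing null carry that burden.
- Per-trial Rayleigh tests on 30 serially correlated phases are
  anti-conservative near tempo match; counts of "significant trials"
  should always be read against the re-paired no-stimulus counts.
- The exact/approximate switch in the Ajne p-value (at n = 50) leaves a
  small discontinuity in p across n for fixed m/n; both branches are
  conservative where they are used.
- MIDI import handles format 0/1 files with metrical division only (no
  SMPTE), which covers keyboard-recording workflows.
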