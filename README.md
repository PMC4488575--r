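# tapentrain

Circular statistics for detecting intermittent entrainment of self-paced
tapping by auditory distractor rhythms.

## The problem

When a person (or a chimpanzee) taps two keys alternately at their own pace
while an isochronous tone sequence plays in the background, the tones are
task-irrelevant — yet when the stimulus tempo is close to the tapper's
spontaneous motor tempo, tap timing can be transiently attracted to the
beat. This *distractor effect* (intermittent entrainment, or relative
coordination) is weak, episodic, and easily confused with the spurious
phase stability of any regular tapper whose tempo happens to match the
stimulus. `tapentrain` implements the full inference chain needed to
separate the two, for researchers in sensorimotor synchronization and
comparative cognition.

## The method

Each tap at time `t` is matched to the nearest stimulus onset and mapped to
a phase angle on a circular scale with onsets at 0°:

    theta = 360 * (t - nearest onset) / ISI,  theta in (-180, 180]

so positive angles mean the tap followed the beat. Four statistical tools
operate on these angles:

- **Hodges–Ajne omnibus test** — condition-level test of phase uniformity
  on all pooled taps (540 per condition in the full design). The statistic
  `m` is the minimal number of points in any half-circle; the exact null
  tail `P(M <= m) = (n - 2m) C(n, m) 2^(1-n)` is used for small samples and
  the standard large-sample approximation beyond that. Sensitive to
  multimodal as well as unimodal departures.
- **Rayleigh test** — trial-by-trial test (`Z = n R²`, `R` = mean resultant
  length) that finds the individual entrainment episodes behind a
  condition-level effect.
- **Monte Carlo re-pairing null** — no-stimulus training trials are
  re-paired with the stimulus sequence they never heard (18 of 30 drawn
  without replacement, 10,000 sets by default); the fraction of re-paired
  sets whose omnibus p-value is at least as extreme as the observed one
  measures how easily self-paced tapping alone produces the observed
  phase concentration.
- **Spontaneous-tempo statistics** — median inter-tap interval (the
  spontaneous motor tempo), its mean absolute deviation, outlier exclusion
  at median ± 2 deviations, pooled-variance and paired t tests, and the
  percent tempo mismatch `100 |ISI - median ITI| / median ITI` that governs
  where entrainment can occur.

Because no raw tapping data are distributed with the original study, the
package includes a first-class simulator: a tapper whose motor period
follows a random walk with white interval noise, optionally phase-coupled
to the stimulus through a sine (circle-map) phase response. Presets
reproduce the published chimpanzee-like and human-like variability bands,
and `planted_entrainment_study()` builds datasets with a known number of
entrained trials for power and recovery analysis.

## Worked example

A simulated human-like participant with spontaneous tempo ~480 ms, weakly
coupled (gain 0.5) to distractor rhythms at 400, 500 and 600 ms:

```r
library(tapentrain)
ds <- simulate_study("human_like", coupling_gain = 0.5, seed = 42,
                     conditions = c("NO_STIM", "ISI400", "ISI500", "ISI600"),
                     base_period_ms = 480)
report <- run_study(ds, study_config(run_monte_carlo = TRUE, n_iter = 2000, seed = 1))
print(report)
```

```
Entrainment study report for 'sim_human_like'
  spontaneous tempo: median ITI 478.3 ms (MAD 17.3 ms)
  condition n_taps   m         p mean_direction_deg resultant_length
1    ISI400    540 192 1.753e-09              51.68           0.2104
2    ISI500    540  39 4.681e-85             -17.09           0.8173
3    ISI600    540 197 2.688e-08             -43.80           0.2044
  significant n_significant_trials mismatch_pct monte_carlo_p
1        TRUE                    0       16.377             0
2        TRUE                   18        4.528             0
3        TRUE                    0       25.434             0
```

At ISI 500 — a 4.5% mismatch with the spontaneous tempo — tapping locks
hard: mean resultant length 0.82, mean direction −17° (taps slightly
anticipate the beat), and all 18 trials individually significant at the
trial-level criterion. At 16% and 25% mismatch the pooled test still picks
up weak relative coordination (the omnibus test is very sensitive with 540
taps), but not a single individual trial reaches the episode criterion.
`monte_carlo_p = 0` means none of the 2,000 re-paired no-stimulus sets
matched the observed phase concentration. `tempo_summary()`,
`trialwise_entrainment()`, `repaired_null()` and the circular tests are
all available individually; `read_trials()` / `write_trials()` and
`read_midi_onsets()` handle CSV/JSON and standard-MIDI-file input.

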