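test_that("simulate_trial: deterministic limit and reproducibility", {
  p0 <- tapper_params(400, 0, 0)
  tr <- simulate_trial(p0, seed = 1)
  expect_length(tr$onsets_ms, 30L)
  expect_equal(diff(tr$onsets_ms), rep(400, 29))

  p <- tapper_params(400, 45, 10)
  expect_identical(simulate_trial(p, seed = 3)$onsets_ms,
                   simulate_trial(p, seed = 3)$onsets_ms)
  expect_false(identical(simulate_trial(p, seed = 3)$onsets_ms,
                         simulate_trial(p, seed = 4)$onsets_ms))
})

test_that("strong coupling pulls phases to the stimulus within a few taps", {
  tk <- generate_stimulus_track("ISI400", 40)
  p <- tapper_params(400, 0, 0, coupling_gain = 0.9)
  set.seed(17)
  for (i in 1:5) {
    tr <- simulate_trial(p, track = tk)
    tail_phases <- phases_for_trial(tr, tk)$angles_deg
    tail_phases <- tail_phases[15:length(tail_phases)]
    expect_true(all(abs(tail_phases) < 5))
  }
  # proportional shape with full window converges likewise
  pp <- tapper_params(400, 0, 0, coupling_gain = 0.9, coupling_shape = "proportional")
  tr <- simulate_trial(pp, track = tk, seed = 18)
  expect_true(all(abs(phases_for_trial(tr, tk)$angles_deg[10:30]) < 1))
})

test_that("uncoupled phases against an incommensurate ISI are uniform", {
  # deterministic tapper at 400 ms vs ISI 400 * golden ratio conjugate:
  # the phase sequence is an irrational rotation, hence equidistributed
  isi <- 400 * (sqrt(5) - 1) / 2
  tk <- stimulus_track("ISI500", (0:120) * isi, nominal_isi_ms = isi)
  p <- tapper_params(400, 0, 0, n_taps_per_trial = 80L)
  angles <- phases_for_trial(simulate_trial(p, track = tk, seed = 19), tk)$angles_deg
  expect_gt(suppressWarnings(ks.test((angles + 180) / 360, "punif")$p.value), 0.01)

  # noisy uncoupled tapping pooled over independent trials is also uniform
  tk2 <- generate_stimulus_track("ISI400", 40)
  pn <- tapper_params(430, 45, 10)
  set.seed(20)
  pool <- unlist(lapply(1:40, function(i)
    phases_for_trial(simulate_trial(pn, track = tk2), tk2)$angles_deg))
  # phases within a trial are serially correlated, which inflates the KS
  # statistic relative to its iid null; the bound only excludes gross
  # non-uniformity
  expect_gt(suppressWarnings(ks.test((pool + 180) / 360, "punif")$p.value), 1e-4)
  expect_lt(circ_summary(pool)$resultant_length, 0.1)
})

test_that("tempo variability is monotone in both noise sources", {
  mad_of <- function(noise, drift, seed) {
    set.seed(seed)
    trials <- lapply(1:12, function(i) simulate_trial(tapper_params(400, noise, drift)))
    tempo_summary(trials)$mean_abs_dev_ms
  }
  m_noise <- vapply(c(5, 40, 130), mad_of, numeric(1), drift = 0, seed = 21)
  expect_true(all(diff(m_noise) > 0))
  m_drift <- vapply(c(0, 15, 45), mad_of, numeric(1), noise = 10, seed = 22)
  expect_true(all(diff(m_drift) > 0))
})

test_that("simulate_study assembles the full design and is seed-stable", {
  ds <- simulate_study("human_like", seed = 23,
                       conditions = c("NO_STIM", "ISI400", "RANDOM"),
                       n_training = 5)
  expect_length(ds$sessions$ISI400, 18L)
  expect_equal(sum(vapply(ds$sessions$ISI400,
                          function(p) length(p$trial$onsets_ms), integer(1))), 540L)
  expect_length(ds$training_pool, 5L)
  expect_true(all(vapply(ds$sessions$RANDOM,
                         function(p) p$track$condition == "RANDOM", logical(1))))

  ds2 <- simulate_study("human_like", seed = 23,
                        conditions = c("NO_STIM", "ISI400", "RANDOM"),
                        n_training = 5)
  expect_identical(ds$sessions$ISI400[[7]]$trial$onsets_ms,
                   ds2$sessions$ISI400[[7]]$trial$onsets_ms)
  expect_identical(ds$sessions$RANDOM[[3]]$track$onsets_ms,
                   ds2$sessions$RANDOM[[3]]$track$onsets_ms)
})

test_that("species presets reproduce the observed variability contrast", {
  chimp <- tempo_summary(simulate_study("chimp_like", seed = 24,
                                        conditions = "NO_STIM")$sessions$NO_STIM
                         |> lapply(`[[`, "trial"))
  human <- tempo_summary(simulate_study("human_like", seed = 25,
                                        conditions = "NO_STIM")$sessions$NO_STIM
                         |> lapply(`[[`, "trial"))
  expect_gt(chimp$mean_abs_dev_ms / human$mean_abs_dev_ms, 5)
  # medians both inside the plausible spontaneous-tempo range
  expect_true(chimp$median_iti_ms > 300 && chimp$median_iti_ms < 520)
  expect_true(human$median_iti_ms > 300 && human$median_iti_ms < 560)
})

test_that("planted_entrainment_study records ground truth and plants signal", {
  ds <- planted_entrainment_study(4, coupling_gain = 0.5, mismatch_pct = 0, seed = 26)
  expect_length(ds$sessions$ISI400, 18L)
  planted <- attr(ds, "planted_trials")
  expect_length(planted, 4L)
  expect_true(all(grepl("planted", planted)))
  expect_length(ds$training_pool, 30L)

  # planted trials concentrate phases; a saturated plant is omnibus-significant
  sat <- planted_entrainment_study(18, coupling_gain = 0.9, seed = 27,
                                   profile = "human_like")
  res <- condition_omnibus(sat, "ISI400",
                           bonferroni_plan("sat", criterion = 0.000794))
  expect_true(res$pooled$significant)
  expect_gt(res$pooled$summary$resultant_length, 0.5)

  expect_error(planted_entrainment_study(19), "invalid planted count")
})
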