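test_that("bonferroni plans: arithmetic and validation", {
  plan <- bonferroni_plan("omnibus", n_comparisons = 20)
  expect_equal(plan$criterion, 0.0025)
  expect_lte(plan$criterion, plan$alpha)
  explicit <- bonferroni_plan("reported", criterion = 0.000794)
  expect_equal(explicit$criterion, 0.000794)
  expect_error(bonferroni_plan("bad", criterion = 0.2), "exceed")
  expect_error(bonferroni_plan("bad", n_comparisons = 0), "n_comparisons")
})

test_that("condition omnibus pools complete trials and flags degenerate locking", {
  # all taps exactly on the beat: maximal concentration
  tk <- generate_stimulus_track("ISI400", 40)
  pairs <- lapply(1:3, function(i)
    list(trial = make_trial(tk$onsets_ms[1:30], sprintf("t%d", i)),
         track = tk, session = 1L))
  ds <- study_dataset("p", sessions = list(ISI400 = pairs))
  res <- condition_omnibus(ds, "ISI400", bonferroni_plan("f", criterion = 0.000794))
  expect_equal(res$n_taps, 90L)
  expect_equal(res$pooled$statistic, 0)
  expect_true(res$pooled$significant)
  expect_equal(res$pooled$summary$resultant_length, 1)

  # incomplete trials are excluded by the min-tap threshold
  short <- list(list(trial = make_trial(tk$onsets_ms[1:5], "s"), track = tk,
                     session = 1L))
  ds2 <- study_dataset("p", sessions = list(ISI400 = c(pairs, short)))
  res2 <- condition_omnibus(ds2, "ISI400", bonferroni_plan("f", criterion = 0.000794))
  expect_equal(res2$n_trials_used, 3L)

  expect_error(condition_omnibus(ds, "NO_STIM", bonferroni_plan("f")), "NO_STIM")
})

test_that("re-pairing null: edge cases, determinism, structure", {
  ds <- planted_entrainment_study(0, seed = 28, n_training = 20)
  track <- ds$sessions$ISI400[[1]]$track
  mc <- repaired_null(ds$training_pool, track, observed_p = 1,
                      n_iter = 50, n_select = 18, seed = 1)
  expect_equal(mc$proportion_extreme, 1)   # every simulated p <= 1

  mc1 <- repaired_null(ds$training_pool, track, observed_p = 0.05,
                       n_iter = 100, n_select = 18, seed = 2)
  mc2 <- repaired_null(ds$training_pool, track, observed_p = 0.05,
                       n_iter = 100, n_select = 18, seed = 2)
  expect_identical(mc1$proportion_extreme, mc2$proportion_extreme)
  expect_true(mc1$proportion_extreme >= 0 && mc1$proportion_extreme <= 1)

  expect_error(repaired_null(ds$training_pool[1:5], track, 0.5, n_select = 18),
               "pool")
  expect_error(repaired_null(ds$training_pool, track, NA), "observed_p")
})

test_that("a strongly coupled condition beats its own re-paired null", {
  ds <- planted_entrainment_study(18, coupling_gain = 0.7, seed = 29)
  omni <- condition_omnibus(ds, "ISI400", bonferroni_plan("f", criterion = 0.000794))
  expect_true(omni$pooled$significant)
  mc <- repaired_null(ds$training_pool, ds$sessions$ISI400[[1]]$track,
                      observed_p = omni$pooled$p_value, n_iter = 200, seed = 3)
  expect_lt(mc$proportion_extreme, 0.05)
})

test_that("trialwise detection counts entrained trials and keeps summaries", {
  tk <- generate_stimulus_track("ISI400", 40)
  locked <- make_trial(tk$onsets_ms[1:30] + 40, "locked")
  set.seed(30)
  drifting <- make_trial(cumsum(c(5, runif(29, 250, 550))), "drifting")
  plan <- bonferroni_plan("trials", criterion = 0.000278)
  res <- trialwise_entrainment(list(locked, drifting), tk, plan)
  expect_equal(nrow(res$per_trial), 2L)
  expect_equal(res$n_significant, 1L)
  expect_true(res$per_trial$significant[res$per_trial$trial_id == "locked"])
  expect_equal(res$per_trial$resultant_length[1], 1)
  expect_equal(res$per_trial$mean_direction_deg[1], 36)  # 40/400 * 360

  # accepts the (trial, track) pair form stored in datasets
  ds <- planted_entrainment_study(2, seed = 31)
  res2 <- trialwise_entrainment(ds$sessions$ISI400, plan = plan)
  expect_equal(nrow(res2$per_trial), 18L)
})

test_that("vector-length comparison is a paired t on per-dataset means", {
  same <- vector_length_comparison(c(0.4, 0.5, 0.3, 0.6), c(0.4, 0.5, 0.3, 0.6))
  expect_equal(same$t, 0)
  expect_equal(same$df, 3)

  res <- vector_length_comparison(list(c(0.5, 0.7), c(0.6, 0.8), c(0.4, 0.6)),
                                  list(c(0.1, 0.3), c(0.2, 0.2), c(0.1, 0.2)))
  expect_equal(res$df, 2)
  expect_gt(res$t, 0)
  expect_error(vector_length_comparison(c(0.1, 0.2), c(0.1)), "unpaired")
})

test_that("run_study produces a coherent deterministic report", {
  expect_silent(empty <- run_study(study_dataset("none")))
  expect_null(empty$table)

  ds <- simulate_study("human_like", coupling_gain = 0.8, seed = 32,
                       conditions = c("NO_STIM", "ISI400", "ISI500"),
                       base_period_ms = 450, n_training = 20)
  cfg <- study_config(run_monte_carlo = TRUE, n_iter = 60, seed = 7)
  rep1 <- run_study(ds, cfg)
  rep2 <- run_study(ds, cfg)
  expect_identical(rep1$table, rep2$table)

  expect_setequal(rep1$table$condition, c("ISI400", "ISI500"))
  expect_equal(rep1$table$n_taps, c(540L, 540L))
  expect_false(is.null(rep1$tempo))
  expect_equal(rep1$conditions$ISI400$mismatch_pct,
               tempo_mismatch(rep1$tempo$median_iti_ms, 400))

  # tight instructed-synchronization-like coupling: high resultant lengths
  expect_true(all(rep1$table$resultant_length > 0.7))
  expect_true(all(rep1$table$significant))
  # mean directions respect the sign convention (taps near the onset here)
  expect_true(all(abs(rep1$table$mean_direction_deg) < 90))

  out <- write_report(rep1, file.path(tempdir(), "rep"))
  j <- jsonlite::read_json(file.path(out, "report.json"))
  expect_equal(j$participant, ds$participant_id)
  expect_length(j$conditions, 2L)
  expect_true(file.exists(file.path(out, "report.csv")))
})

test_that("familywise control holds for uncoupled chimp-like tapping", {
  # pooled omnibus at the reported criterion across several uncoupled studies:
  # none should be flagged (criterion is far below alpha)
  flags <- vapply(1:8, function(i) {
    ds <- simulate_study("chimp_like", coupling_gain = 0, seed = 100 + i,
                         conditions = "ISI400", n_training = 0)
    condition_omnibus(ds, "ISI400",
                      bonferroni_plan("f", criterion = 0.000794))$pooled$significant
  }, logical(1))
  expect_equal(sum(flags), 0L)
})
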