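test_that("domain constructors enforce their invariants", {
  expect_error(tap_trial("x", "test", c(0, 400, 400)), "strictly increasing")
  expect_error(tap_trial("x", "test", c(0, -5)), "non-negative")
  expect_error(tap_trial("x", "test", c(0, 400), key_labels = c("C4", "C4")),
               "alternate")
  tr <- tap_trial("x", "test", c(0, 400, 800), key_labels = c("C4", "C5", "C4"))
  expect_false(tr$complete)                      # < 30 taps is flagged
  expect_true(tap_trial("y", "test", seq(0, by = 400, length.out = 30))$complete)

  expect_error(stimulus_track("NO_STIM", c(0, 400)), "empty")
  expect_error(stimulus_track("ISI400", c(0, 400, 900)), "equal")
  expect_error(stimulus_track("RANDOM", c(0, 350)), "300,400,500,600,700,800")
  expect_silent(stimulus_track("RANDOM", c(0, 300, 1100)))

  expect_error(study_dataset("p", sessions = list(BAD = list())), "named by condition")
})

test_that("CSV write/read round-trips a dataset exactly", {
  ds <- tiny_dataset()
  path <- file.path(tempdir(), "roundtrip.csv")
  write_trials(ds, path, format = "csv")
  back <- read_trials(path, format = "csv")

  expect_equal(back$participant_id, ds$participant_id)
  expect_equal(length(back$training_pool), 3L)
  expect_identical(back$sessions$ISI400[[1]]$trial$onsets_ms,
                   ds$sessions$ISI400[[1]]$trial$onsets_ms)
  expect_identical(back$sessions$ISI400[[1]]$track$onsets_ms,
                   ds$sessions$ISI400[[1]]$track$onsets_ms)
  expect_identical(back$training_pool[[2]]$onsets_ms, ds$training_pool[[2]]$onsets_ms)

  # bit-identical onsets for non-integer values too
  tr <- make_trial(c(0, 400.123456789012, 803.987654321098), "frac")
  ds2 <- study_dataset("p2", sessions = list(ISI400 = list(
    list(trial = tr, track = generate_stimulus_track("ISI400", 4), session = 1L))))
  p2 <- file.path(tempdir(), "frac.csv")
  write_trials(ds2, p2)
  expect_identical(read_trials(p2)$sessions$ISI400[[1]]$trial$onsets_ms, tr$onsets_ms)
})

test_that("JSON write/read round-trips, including a simulated study", {
  ds <- simulate_study("human_like", coupling_gain = 0.3, seed = 5,
                       conditions = c("NO_STIM", "ISI400", "RANDOM"),
                       n_sessions = 2, n_training = 4)
  path <- file.path(tempdir(), "study.json")
  write_trials(ds, path, format = "json")
  back <- read_trials(path, format = "json")
  expect_equal(names(back$sessions), names(ds$sessions))
  for (cond in c("ISI400", "RANDOM")) {
    for (i in seq_along(ds$sessions[[cond]])) {
      expect_identical(back$sessions[[cond]][[i]]$trial$onsets_ms,
                       ds$sessions[[cond]][[i]]$trial$onsets_ms)
      expect_identical(back$sessions[[cond]][[i]]$track$onsets_ms,
                       ds$sessions[[cond]][[i]]$track$onsets_ms)
    }
  }
})

test_that("a complete simulated condition writes 540 test-tap rows", {
  ds <- simulate_study("human_like", seed = 6, conditions = c("ISI500"),
                       n_training = 0)
  path <- file.path(tempdir(), "full.csv")
  write_trials(ds, path)
  rows <- read.csv(path)
  expect_equal(nrow(rows[rows$condition == "ISI500" & rows$role == "test", ]), 540L)
})

test_that("empty dataset writes a header-only file", {
  path <- file.path(tempdir(), "empty.csv")
  write_trials(study_dataset("none"), path)
  expect_equal(nrow(read.csv(path)), 0L)
  expect_equal(length(read_trials(path)$sessions), 0L)
})

test_that("schema and data errors are located", {
  path <- file.path(tempdir(), "bad.csv")
  writeLines(c("participant,condition,onset_ms", "p,ISI400,0"), path)
  expect_error(read_trials(path), "missing columns")

  # duplicated onset within a trial violates strict monotonicity
  ds <- tiny_dataset()
  good <- file.path(tempdir(), "good.csv")
  write_trials(ds, good)
  rows <- read.csv(good, colClasses = c(onset_ms = "character"))
  rows$onset_ms[2] <- rows$onset_ms[1]
  dup <- file.path(tempdir(), "dup.csv")
  write.csv(rows, dup, row.names = FALSE, quote = FALSE, na = "")
  expect_error(read_trials(dup), "ISI400_1")

  # inversions beyond the jitter tolerance are errors, within it re-sorted
  rows <- read.csv(good, colClasses = c(onset_ms = "character"))
  rows$onset_ms[1:2] <- rows$onset_ms[2:1]
  swap <- file.path(tempdir(), "swap.csv")
  write.csv(rows, swap, row.names = FALSE, quote = FALSE, na = "")
  expect_error(read_trials(swap), "non-monotone")
  fixed <- read_trials(swap, jitter_tolerance_ms = 500)
  expect_identical(fixed$sessions$ISI400[[1]]$trial$onsets_ms,
                   ds$sessions$ISI400[[1]]$trial$onsets_ms)
})
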