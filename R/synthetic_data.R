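#' Tapper simulator parameters
#'
#' The simulated tapper produces inter-tap intervals from a motor period that
#' follows a random walk (drift) plus white per-interval noise, optionally
#' phase-coupled to a stimulus track. The two noise sources are the minimal
#' structure that reproduces both a stable spontaneous tempo with small mean
#' absolute deviation (human-like) and continuous fluctuation with a stable
#' median but large deviation (chimp-like).
#'
#' Coupling moves the next provisional tap toward the nearest stimulus onset.
#' With `coupling_shape = "sine"` (default) the shift is
#' `-alpha * (ISI / 2 pi) * sin(2 pi * asynchrony / ISI)`: near an onset this
#' corrects the fraction `alpha` of the current asynchrony, the correction is
#' bounded, and phase locking only occurs when the motor and stimulus tempi
#' are close (the classic circle-map entrainment region), which is exactly
#' the intermittent, tempo-dependent behaviour under study.
#' `coupling_shape = "proportional"` corrects `alpha` times the asynchrony
#' whenever the tap phase lies within `coupling_window_deg` of an onset.
#'
#' @param base_period_ms Motor period (spontaneous tempo), > 0.
#' @param period_noise_sd_ms SD of white per-interval Gaussian noise, >= 0.
#' @param drift_sd_ms SD of the Gaussian random-walk increment of the local
#'   period, >= 0.
#' @param coupling_gain Fraction of the current asynchrony corrected on the
#'   next tap, in \[0, 1).
#' @param coupling_shape `"sine"` or `"proportional"`.
#' @param coupling_window_deg Hard phase window (degrees) for the
#'   proportional shape; 180 = always apply. In (0, 180].
#' @param n_taps_per_trial Taps per trial (default 30, the study design).
#' @param min_iti_ms Smallest physically allowed inter-tap interval.
#' @return A list of class `tapper_params`.
#' @export
tapper_params <- function(base_period_ms, period_noise_sd_ms = 0,
                          drift_sd_ms = 0, coupling_gain = 0,
                          coupling_shape = c("sine", "proportional"),
                          coupling_window_deg = 180, n_taps_per_trial = 30L,
                          min_iti_ms = 100) {
  coupling_shape <- match.arg(coupling_shape)
  stopifnot(base_period_ms > 0, period_noise_sd_ms >= 0, drift_sd_ms >= 0,
            coupling_gain >= 0, coupling_gain < 1,
            coupling_window_deg > 0, coupling_window_deg <= 180,
            n_taps_per_trial >= 1)
  structure(list(base_period_ms = base_period_ms,
                 period_noise_sd_ms = period_noise_sd_ms,
                 drift_sd_ms = drift_sd_ms, coupling_gain = coupling_gain,
                 coupling_shape = coupling_shape,
                 coupling_window_deg = coupling_window_deg,
                 n_taps_per_trial = as.integer(n_taps_per_trial),
                 min_iti_ms = min_iti_ms),
            class = "tapper_params")
}

#' Species-profile presets for the tapper simulator
#'
#' Reads the versioned preset table shipped with the package
#' (`inst/extdata/tapper_profiles.yaml`). `chimp_like` and `human_like` are
#' calibrated so that pooled no-stimulus tapping lands in the observed
#' mean-absolute-deviation bands (about 120-152 ms and 13-23 ms); the
#' `entrainable` preset has intermediate variability, representing tapping
#' during entrainment-prone sessions, and is the default substrate of
#' [planted_entrainment_study()].
#'
#' @param profile `"chimp_like"`, `"human_like"` or `"entrainable"`.
#' @return A list with `base_period_range_ms`, `period_noise_sd_ms`,
#'   `drift_sd_ms`.
#' @export
tapper_profile <- function(profile = c("chimp_like", "human_like", "entrainable")) {
  profile <- match.arg(profile)
  path <- system.file("extdata", "tapper_profiles.yaml", package = "tapentrain")
  yaml::read_yaml(path)[[profile]]
}

# Internal: signed asynchrony of time t to the nearest onset of a track
# (NA outside the track's half-interval envelope).
nearest_asynchrony <- function(t, onsets) {
  n <- length(onsets)
  k <- findInterval(t, onsets)
  if (k == 0L) return(t - onsets[1])
  if (k == n) return(t - onsets[n])
  d1 <- t - onsets[k]; d2 <- t - onsets[k + 1L]
  if (abs(d1) <= abs(d2)) d1 else d2
}

#' Simulate one tapping trial
#'
#' Generates `n_taps_per_trial` tap onsets. The local period follows a random
#' walk with increment SD `drift_sd_ms`; each interval adds white noise with
#' SD `period_noise_sd_ms`; intervals are floored at `min_iti_ms`. With a
#' stimulus track and `coupling_gain > 0`, each provisional tap is shifted
#' toward the nearest onset according to the coupling shape (see
#' [tapper_params()]). The first tap falls at a uniformly random offset
#' within one period (or at `initial_asynchrony_ms` relative to the first
#' onset, to start a trial inside an entrainment episode).
#'
#' @param params A `tapper_params`.
#' @param track Optional `stimulus_track`; `NULL` or `NO_STIM` gives pure
#'   self-paced tapping.
#' @param trial_id,role Passed to [tap_trial()].
#' @param initial_asynchrony_ms Optional first-tap asynchrony (ms) relative
#'   to the first stimulus onset.
#' @param seed Optional seed for a fully reproducible trial; by default the
#'   caller's RNG stream is used.
#' @return A `tap_trial`.
#' @export
simulate_trial <- function(params, track = NULL, trial_id = "sim", role = "test",
                           initial_asynchrony_ms = NULL, seed = NULL) {
  stopifnot(inherits(params, "tapper_params"))
  if (!is.null(seed)) {
    return(withr_seed(seed, simulate_trial(params, track, trial_id, role,
                                           initial_asynchrony_ms)))
  }
  has_track <- !is.null(track) && length(track$onsets_ms) > 0L
  n <- params$n_taps_per_trial
  alpha <- if (has_track) params$coupling_gain else 0
  isi_ref <- if (has_track) {
    if (!is.na(track$nominal_isi_ms)) track$nominal_isi_ms
    else mean(diff(track$onsets_ms))
  } else NA_real_
  onsets <- numeric(n)
  onsets[1] <- if (has_track && !is.null(initial_asynchrony_ms)) {
    max(track$onsets_ms[1] + initial_asynchrony_ms %% isi_ref, 0)
  } else {
    runif(1, 0, params$base_period_ms)
  }
  period <- params$base_period_ms
  for (k in seq_len(n - 1L) + 1L) {
    period <- period + rnorm(1, 0, params$drift_sd_ms)
    interval <- max(period + rnorm(1, 0, params$period_noise_sd_ms), params$min_iti_ms)
    prov <- onsets[k - 1L] + interval
    if (alpha > 0) {
      asyn <- nearest_asynchrony(prov, track$onsets_ms)
      shift <- if (params$coupling_shape == "sine") {
        alpha * isi_ref / (2 * pi) * sin(2 * pi * asyn / isi_ref)
      } else if (abs(wrap_degrees(360 * asyn / isi_ref)) <= params$coupling_window_deg) {
        alpha * asyn
      } else 0
      prov <- prov - shift
    }
    onsets[k] <- max(prov, onsets[k - 1L] + params$min_iti_ms / 2)
  }
  tap_trial(trial_id, role = role, onsets_ms = onsets, n_complete = n)
}

# Internal: a stimulus track long enough to cover a whole simulated trial.
track_for_trial <- function(condition, params, seed = NULL, margin = 1.7) {
  duration <- params$n_taps_per_trial * params$base_period_ms * margin
  isi <- condition_isi(condition)
  n_onsets <- if (!is.na(isi)) ceiling(duration / isi) + 3L
              else ceiling(duration / min(RANDOM_ISI_SET)) + 3L
  generate_stimulus_track(condition, n_onsets, seed = seed)
}

#' Simulate a complete one-participant study
#'
#' Builds a `study_dataset` with the full design: for each condition,
#' `n_sessions` sessions of `n_test_per_session` test trials (6 x 3 = 18 by
#' default, 540 taps when complete), plus `n_training` no-stimulus training
#' trials for the re-pairing null. The participant's base period is drawn
#' once from the profile's range; test trials in stimulus conditions are
#' coupled with `coupling_gain`.
#'
#' @param profile `"chimp_like"`, `"human_like"` or `"entrainable"`.
#' @param coupling_gain Phase-coupling gain applied in stimulus conditions.
#' @param conditions Character vector of condition labels.
#' @param seed Integer seed; the whole dataset is reproducible under it.
#' @param participant_id Dataset label.
#' @param n_sessions,n_test_per_session,n_training Design counts.
#' @param base_period_ms Override the profile's base-period draw.
#' @param coupling_shape Passed to [tapper_params()].
#' @return A `study_dataset`.
#' @export
simulate_study <- function(profile = c("chimp_like", "human_like", "entrainable"),
                           coupling_gain = 0,
                           conditions = c("NO_STIM", "ISI400", "ISI500", "ISI600", "RANDOM"),
                           seed = 1L, participant_id = paste0("sim_", profile),
                           n_sessions = 6L, n_test_per_session = 3L,
                           n_training = 30L, base_period_ms = NULL,
                           coupling_shape = "sine") {
  profile <- match.arg(profile)
  prof <- tapper_profile(profile)
  withr_seed(seed, {
    base <- if (is.null(base_period_ms)) {
      runif(1, prof$base_period_range_ms[1], prof$base_period_range_ms[2])
    } else base_period_ms
    params <- tapper_params(base, prof$period_noise_sd_ms, prof$drift_sd_ms,
                            coupling_gain = coupling_gain,
                            coupling_shape = coupling_shape)
    sessions <- list()
    for (cond in conditions) {
      pairs <- list()
      for (s in seq_len(n_sessions)) {
        for (j in seq_len(n_test_per_session)) {
          track <- if (cond == "NO_STIM") stimulus_track("NO_STIM")
                   else track_for_trial(cond, params,
                                        seed = if (cond == "RANDOM")
                                          sample.int(.Machine$integer.max, 1) else NULL)
          trial <- simulate_trial(params, track = track,
                                  trial_id = sprintf("%s_s%d_t%d", cond, s, j))
          pairs[[length(pairs) + 1L]] <- list(trial = trial, track = track, session = s)
        }
      }
      sessions[[cond]] <- pairs
    }
    training <- lapply(seq_len(n_training), function(i)
      simulate_trial(params, track = NULL,
                     trial_id = sprintf("train_%02d", i), role = "training"))
    ds <- study_dataset(participant_id, sessions = sessions,
                        training_pool = training, species_profile = profile)
    attr(ds, "params") <- params
    ds
  })
}

#' Simulate a condition with a known number of entrained trials
#'
#' Builds a single-condition `study_dataset` in which exactly
#' `n_entrained_trials` of the `n_trials` test trials are phase-coupled to
#' the stimulus (started inside an entrainment episode, i.e. at the
#' stationary locked asynchrony) and the rest are uncoupled. The identities
#' of the planted trials are recorded as ground truth in
#' `attr(dataset, "planted_trials")` for recovery experiments. The motor
#' period is `isi_ms * (1 + mismatch_pct / 100)`.
#'
#' @param n_entrained_trials Number of coupled trials (0 to `n_trials`).
#' @param coupling_gain Phase-coupling gain of the planted trials.
#' @param mismatch_pct Percent tempo mismatch between the motor period and
#'   the stimulus ISI.
#' @param seed Integer seed.
#' @param isi_ms Stimulus ISI (condition label must match one of the
#'   isochronous conditions; default 400).
#' @param n_trials Total test trials (default 18).
#' @param n_training Training trials for the re-pairing null (default 30).
#' @param profile Tapper variability preset (default `"entrainable"`).
#' @return A `study_dataset` with one condition plus a training pool.
#' @export
planted_entrainment_study <- function(n_entrained_trials, coupling_gain = 0.5,
                                      mismatch_pct = 0, seed = 1L, isi_ms = 400,
                                      n_trials = 18L, n_training = 30L,
                                      profile = "entrainable") {
  if (n_entrained_trials < 0 || n_entrained_trials > n_trials) {
    stop("planted_entrainment_study: invalid planted count", call. = FALSE)
  }
  cond <- paste0("ISI", isi_ms)
  cond <- match.arg(cond, STIM_CONDITIONS)
  prof <- tapper_profile(profile)
  base <- isi_ms * (1 + mismatch_pct / 100)
  withr_seed(seed, {
    coupled <- tapper_params(base, prof$period_noise_sd_ms, prof$drift_sd_ms,
                             coupling_gain = coupling_gain)
    uncoupled <- tapper_params(base, prof$period_noise_sd_ms, prof$drift_sd_ms)
    # stationary asynchrony SD of the linearised correction map
    lock_sd <- prof$period_noise_sd_ms / sqrt(1 - (1 - coupling_gain)^2)
    planted <- sort(sample.int(n_trials, n_entrained_trials))
    pairs <- list()
    for (j in seq_len(n_trials)) {
      track <- track_for_trial(cond, coupled)
      is_planted <- j %in% planted
      trial <- simulate_trial(
        if (is_planted) coupled else uncoupled, track = track,
        trial_id = sprintf("%s_%02d%s", cond, j, if (is_planted) "_planted" else ""),
        initial_asynchrony_ms = if (is_planted) rnorm(1, 0, lock_sd) else NULL)
      pairs[[length(pairs) + 1L]] <- list(trial = trial, track = track,
                                          session = (j - 1L) %/% 3L + 1L)
    }
    training <- lapply(seq_len(n_training), function(i)
      simulate_trial(uncoupled, track = NULL,
                     trial_id = sprintf("train_%02d", i), role = "training"))
    ds <- study_dataset(sprintf("planted_%d_of_%d", n_entrained_trials, n_trials),
                        sessions = setNames(list(pairs), cond),
                        training_pool = training)
    attr(ds, "planted_trials") <- vapply(pairs[planted],
                                         function(p) p$trial$trial_id, character(1))
    ds
  })
}
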