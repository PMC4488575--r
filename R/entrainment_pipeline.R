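#' Bonferroni correction plan
#'
#' A named family of comparisons with its corrected criterion
#' `alpha / n_comparisons`, or an explicitly supplied criterion when the
#' comparison count behind a reported criterion is not reconstructible.
#'
#' @param family_label Name of the test family.
#' @param n_comparisons Number of comparisons in the family (>= 1).
#' @param alpha Nominal familywise level (default 0.05).
#' @param criterion Optional explicit per-comparison criterion; overrides
#'   `alpha / n_comparisons`.
#' @return A list of class `bonferroni_plan`.
#' @export
bonferroni_plan <- function(family_label, n_comparisons = 1L, alpha = 0.05,
                            criterion = NULL) {
  stopifnot(n_comparisons >= 1, alpha > 0, alpha <= 1)
  crit <- if (is.null(criterion)) alpha / n_comparisons else criterion
  if (crit > alpha) stop("bonferroni_plan: criterion must not exceed alpha", call. = FALSE)
  structure(list(family_label = family_label,
                 n_comparisons = as.integer(n_comparisons),
                 alpha = alpha, criterion = crit),
            class = "bonferroni_plan")
}

#' Reported correction criteria of the original study
#'
#' The corrected criteria printed with the original analyses, usable directly
#' as `criterion` in [bonferroni_plan()]. The comparison counts behind them
#' are not reconstructible, so they are shipped as constants: condition-level
#' omnibus tests (chimpanzee exp. 1: 0.000794; humans exp. 1: 0.00000159;
#' exp. 2: 0.0056), trial-by-trial Rayleigh tests (exp. 1: 0.000278; exp. 2:
#' 0.00389) and instructed synchronization (exp. 3: 0.0028).
#'
#' @format Named list of six numeric criteria.
#' @export
study_criteria <- list(
  omnibus_exp1_chimp = 0.000794,
  omnibus_exp1_human = 0.00000159,
  trialwise_exp1     = 0.000278,
  omnibus_exp2       = 0.0056,
  trialwise_exp2     = 0.00389,
  rayleigh_exp3      = 0.0028
)

# Internal: pooled phase angles of a condition's complete test trials.
pooled_condition_phases <- function(pairs, min_taps = 30L, ...) {
  angles <- numeric(0)
  n_dropped <- 0L
  n_trials_used <- 0L
  for (pair in pairs) {
    if (length(pair$trial$onsets_ms) < min_taps) next
    ph <- phases_for_trial(pair$trial, pair$track, ...)
    angles <- c(angles, ph$angles_deg)
    n_dropped <- n_dropped + ph$n_dropped
    n_trials_used <- n_trials_used + 1L
  }
  list(angles_deg = angles, n_dropped = n_dropped, n_trials_used = n_trials_used)
}

#' Condition-level omnibus test of phase uniformity
#'
#' Pools the phase angles of all complete test trials of one condition (540
#' taps in the full design) and applies the Hodges-Ajne omnibus test at the
#' plan's corrected criterion, together with the circular summary (mean
#' direction, mean resultant length).
#'
#' @param dataset A `study_dataset`.
#' @param condition Condition label present in the dataset (not `NO_STIM`:
#'   phases only exist against a stimulus track; see [repaired_null()]).
#' @param plan A `bonferroni_plan`.
#' @param min_taps Minimum taps for a trial to enter the pool (default 30).
#' @param ... Passed to [tap_to_phase()] (RANDOM normalisation switches).
#' @return A list with `participant`, `condition`, `pooled` (a `circ_test`),
#'   `n_taps`, `n_trials_used`, `n_dropped`.
#' @export
condition_omnibus <- function(dataset, condition, plan, min_taps = 30L, ...) {
  stopifnot(inherits(dataset, "study_dataset"), inherits(plan, "bonferroni_plan"))
  if (condition == "NO_STIM") {
    stop("condition_omnibus: NO_STIM has no phases; use repaired_null with a reference track",
         call. = FALSE)
  }
  pairs <- dataset$sessions[[condition]]
  if (is.null(pairs)) stop(sprintf("condition_omnibus: no condition '%s'", condition),
                           call. = FALSE)
  pooled <- pooled_condition_phases(pairs, min_taps = min_taps, ...)
  if (length(pooled$angles_deg) < 4L) {
    stop("condition_omnibus: fewer than 4 matched phases", call. = FALSE)
  }
  test <- hodges_ajne_test(pooled$angles_deg, criterion = plan$criterion)
  list(participant = dataset$participant_id, condition = condition,
       pooled = test, n_taps = length(pooled$angles_deg),
       n_trials_used = pooled$n_trials_used, n_dropped = pooled$n_dropped)
}

#' Monte Carlo re-pairing null for a condition-level result
#'
#' Tests whether an observed condition-level omnibus p-value could arise from
#' the participant's self-paced tapping alone. Each iteration draws
#' `n_select` trials without replacement from the no-stimulus training pool,
#' re-pairs each trial with the stimulus track (tap clock zero = track zero),
#' pools the resulting phases and runs the Hodges-Ajne test. The reported
#' proportion is the fraction of iterations whose p-value is at most the
#' observed one (an equally or more skewed phase distribution).
#'
#' @param training_pool List of no-stimulus `tap_trial`s (>= `n_select`).
#' @param track The stimulus track of the condition under test.
#' @param observed_p Observed condition-level p-value.
#' @param n_iter Number of simulated sets (default 10000).
#' @param n_select Trials drawn per set (default 18).
#' @param seed Integer seed (mandatory: the draw must be reproducible).
#' @param min_taps Minimum taps for a training trial to be eligible.
#' @return A list of class `monte_carlo_result` with `observed_p`,
#'   `proportion_extreme`, `n_iterations`, `n_selected_trials`, `seed`.
#' @export
repaired_null <- function(training_pool, track, observed_p, n_iter = 10000L,
                          n_select = 18L, seed = 1L, min_taps = 30L) {
  if (is.null(observed_p) || is.na(observed_p)) {
    stop("repaired_null: observed_p is required", call. = FALSE)
  }
  eligible <- Filter(function(t) length(t$onsets_ms) >= min_taps, training_pool)
  if (length(eligible) < n_select) {
    stop(sprintf("repaired_null: pool has %d eligible trials, need %d",
                 length(eligible), n_select), call. = FALSE)
  }
  # phases are per-trial fixed under trial-start alignment: precompute once
  phase_sets <- lapply(eligible, function(t) phases_for_trial(t, track)$angles_deg)
  sim_p <- withr_seed(seed, {
    vapply(seq_len(n_iter), function(i) {
      angles <- unlist(phase_sets[sample.int(length(phase_sets), n_select)])
      hodges_ajne_test(angles)$p_value
    }, numeric(1))
  })
  structure(list(observed_p = observed_p,
                 proportion_extreme = mean(sim_p <= observed_p),
                 n_iterations = as.integer(n_iter),
                 n_selected_trials = as.integer(n_select), seed = seed),
            class = "monte_carlo_result")
}

#' @export
print.monte_carlo_result <- function(x, ...) {
  cat(sprintf(
    "Re-pairing null: %d sets of %d trials; P(p_sim <= %.3g) = %.4f\n",
    x$n_iterations, x$n_selected_trials, x$observed_p, x$proportion_extreme))
  invisible(x)
}

#' Trial-by-trial entrainment detection
#'
#' Runs a Rayleigh test on each trial's phase angles (a unimodal departure is
#' expected within an entrainment episode) at the plan's corrected criterion
#' and counts significant trials; per-trial mean direction and resultant
#' length are retained for episode-level summaries.
#'
#' @param trials List of `tap_trial`s, or a list of `(trial, track)` pairs as
#'   stored in a `study_dataset` (then `track` may be omitted).
#' @param track A `stimulus_track` shared by all trials (ignored when pairs
#'   are supplied).
#' @param plan A `bonferroni_plan`.
#' @param min_phases Minimum matched phases for a trial to be tested.
#' @param ... Passed to [tap_to_phase()].
#' @return A list with `per_trial` (data.frame: trial_id, n, statistic, p,
#'   resultant_length, mean_direction_deg, significant) and `n_significant`.
#' @export
trialwise_entrainment <- function(trials, track = NULL, plan, min_phases = 2L, ...) {
  stopifnot(inherits(plan, "bonferroni_plan"))
  pairs <- lapply(trials, function(x) {
    if (inherits(x, "tap_trial")) list(trial = x, track = track)
    else x
  })
  rows <- lapply(pairs, function(pair) {
    ph <- phases_for_trial(pair$trial, pair$track, ...)
    if (length(ph$angles_deg) < min_phases) return(NULL)
    rt <- rayleigh_test(ph$angles_deg, criterion = plan$criterion)
    data.frame(trial_id = pair$trial$trial_id, n = rt$summary$n,
               statistic = rt$statistic, p = rt$p_value,
               resultant_length = rt$summary$resultant_length,
               mean_direction_deg = rt$summary$mean_direction_deg,
               significant = rt$significant, stringsAsFactors = FALSE)
  })
  per_trial <- do.call(rbind, rows)
  if (is.null(per_trial)) {
    per_trial <- data.frame(trial_id = character(), n = integer(),
                            statistic = numeric(), p = numeric(),
                            resultant_length = numeric(),
                            mean_direction_deg = numeric(),
                            significant = logical(), stringsAsFactors = FALSE)
  }
  list(per_trial = per_trial, n_significant = sum(per_trial$significant))
}

#' Paired comparison of mean vector lengths, stimulus vs re-paired null
#'
#' Compares, across paired datasets (participant x condition), the average
#' per-trial resultant length when tapping with the auditory rhythm against
#' the average resultant length of no-stimulus trials re-paired to the same
#' track. Inputs are either numeric vectors of per-dataset averages or lists
#' of per-trial resultant-length vectors (then averaged per dataset).
#'
#' @param condition_trials_R Per-dataset average R with stimulus (vector), or
#'   list of per-trial R vectors.
#' @param null_trials_R Matching averages for the re-paired no-stimulus
#'   trials.
#' @return The [paired_t()] result (df = number of pairs - 1).
#' @export
vector_length_comparison <- function(condition_trials_R, null_trials_R) {
  to_means <- function(x) if (is.list(x)) vapply(x, mean, numeric(1)) else x
  a <- to_means(condition_trials_R)
  b <- to_means(null_trials_R)
  if (length(a) != length(b)) {
    stop("vector_length_comparison: unpaired input", call. = FALSE)
  }
  paired_t(a, b)
}

#' Analysis configuration for [run_study()]
#'
#' @param alpha Nominal familywise level.
#' @param omnibus_criterion Corrected criterion for condition-level omnibus
#'   tests (default: the reported chimpanzee exp. 1 criterion).
#' @param trialwise_criterion Corrected criterion for trial-by-trial Rayleigh
#'   tests (default: the reported exp. 1 criterion).
#' @param run_monte_carlo Run the re-pairing null for conditions whose
#'   omnibus test is significant.
#' @param n_iter,n_select Re-pairing null settings.
#' @param seed Seed for all stochastic steps.
#' @param min_taps Minimum taps for a trial to enter pooled analyses.
#' @param random_normalization `"local"` or `"fixed"` phase normalisation for
#'   RANDOM tracks (see [tap_to_phase()]).
#' @param reference_isi_ms Reference ISI when `random_normalization = "fixed"`.
#' @return A list of class `study_config`.
#' @export
study_config <- function(alpha = 0.05,
                         omnibus_criterion = study_criteria$omnibus_exp1_chimp,
                         trialwise_criterion = study_criteria$trialwise_exp1,
                         run_monte_carlo = FALSE, n_iter = 10000L,
                         n_select = 18L, seed = 1L, min_taps = 30L,
                         random_normalization = "local",
                         reference_isi_ms = NULL) {
  structure(list(alpha = alpha, omnibus_criterion = omnibus_criterion,
                 trialwise_criterion = trialwise_criterion,
                 run_monte_carlo = run_monte_carlo, n_iter = as.integer(n_iter),
                 n_select = as.integer(n_select), seed = seed,
                 min_taps = as.integer(min_taps),
                 random_normalization = random_normalization,
                 reference_isi_ms = reference_isi_ms),
            class = "study_config")
}

#' Run the full entrainment analysis on one dataset
#'
#' For each stimulus condition: pooled Hodges-Ajne omnibus test, trial-by-
#' trial Rayleigh analysis, tempo mismatch between the spontaneous tempo (from
#' the no-stimulus condition) and the condition ISI, and optionally the Monte
#' Carlo re-pairing null (for significant omnibus results, against the first
#' trial's track). The no-stimulus condition contributes the tempo summary.
#' Reports are deterministic under the config seed.
#'
#' @param dataset A `study_dataset`.
#' @param config A [study_config()].
#' @return A list of class `study_report` with `participant`, `tempo`
#'   (a `tempo_summary` or `NULL`), `conditions` (per-condition list:
#'   `omnibus`, `trialwise`, `mismatch_pct`, `monte_carlo`), and `table`
#'   (data.frame: condition, n_taps, m, p, mean_direction_deg,
#'   resultant_length, significant, n_significant_trials, mismatch_pct).
#' @export
run_study <- function(dataset, config = study_config()) {
  stopifnot(inherits(dataset, "study_dataset"), inherits(config, "study_config"))
  phase_args <- if (identical(config$random_normalization, "fixed")) {
    list(random_normalization = "fixed", reference_isi_ms = config$reference_isi_ms)
  } else list()

  nostim_trials <- c(lapply(dataset$sessions[["NO_STIM"]], `[[`, "trial"))
  tempo <- if (length(nostim_trials)) {
    tempo_summary(nostim_trials, participant_id = dataset$participant_id)
  } else NULL

  omnibus_plan <- bonferroni_plan("condition omnibus", alpha = config$alpha,
                                  criterion = config$omnibus_criterion)
  trial_plan <- bonferroni_plan("trialwise", alpha = config$alpha,
                                criterion = config$trialwise_criterion)

  conditions <- setdiff(names(dataset$sessions), "NO_STIM")
  reports <- list()
  rows <- list()
  for (cond in conditions) {
    pairs <- dataset$sessions[[cond]]
    omni <- do.call(condition_omnibus,
                    c(list(dataset, cond, omnibus_plan, min_taps = config$min_taps),
                      phase_args))
    tw <- do.call(trialwise_entrainment,
                  c(list(pairs, plan = trial_plan), phase_args))
    mismatch <- if (!is.null(tempo) && !is.na(condition_isi(cond))) {
      tempo_mismatch(tempo$median_iti_ms, condition_isi(cond))
    } else NA_real_
    mc <- NULL
    if (config$run_monte_carlo && omni$pooled$significant &&
        length(dataset$training_pool) >= config$n_select) {
      mc <- repaired_null(dataset$training_pool, pairs[[1]]$track,
                          observed_p = omni$pooled$p_value,
                          n_iter = config$n_iter, n_select = config$n_select,
                          seed = config$seed, min_taps = config$min_taps)
    }
    reports[[cond]] <- list(omnibus = omni, trialwise = tw,
                            mismatch_pct = mismatch, monte_carlo = mc)
    rows[[cond]] <- data.frame(
      condition = cond, n_taps = omni$n_taps, m = omni$pooled$statistic,
      p = omni$pooled$p_value,
      mean_direction_deg = omni$pooled$summary$mean_direction_deg,
      resultant_length = omni$pooled$summary$resultant_length,
      significant = omni$pooled$significant,
      n_significant_trials = tw$n_significant,
      mismatch_pct = mismatch,
      monte_carlo_p = if (is.null(mc)) NA_real_ else mc$proportion_extreme,
      stringsAsFactors = FALSE)
  }
  structure(list(participant = dataset$participant_id, tempo = tempo,
                 conditions = reports,
                 table = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                         else NULL,
                 config = config),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("Entrainment study report for '%s'\n", x$participant))
  if (!is.null(x$tempo)) {
    cat(sprintf("  spontaneous tempo: median ITI %.1f ms (MAD %.1f ms)\n",
                x$tempo$median_iti_ms, x$tempo$mean_abs_dev_ms))
  }
  if (!is.null(x$table)) print(x$table, digits = 4)
  invisible(x)
}

#' Write a study report to JSON and CSV
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if needed); writes
#'   `report.json` and `report.csv`.
#' @return Invisibly, the directory path.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ser_cond <- function(r) list(
    pooled = list(m = r$omnibus$pooled$statistic, p = r$omnibus$pooled$p_value,
                  mean_dir_deg = r$omnibus$pooled$summary$mean_direction_deg,
                  R = r$omnibus$pooled$summary$resultant_length,
                  n = r$omnibus$n_taps),
    trials = lapply(seq_len(nrow(r$trialwise$per_trial)), function(i) {
      row <- r$trialwise$per_trial[i, ]
      list(trial = row$trial_id, p = row$p, R = row$resultant_length,
           mean_dir_deg = row$mean_direction_deg, significant = row$significant)
    }),
    n_significant_trials = r$trialwise$n_significant,
    monte_carlo = if (is.null(r$monte_carlo)) NULL else
      list(proportion = r$monte_carlo$proportion_extreme,
           n_iter = r$monte_carlo$n_iterations, seed = r$monte_carlo$seed),
    mismatch_pct = r$mismatch_pct,
    significant = r$omnibus$pooled$significant)
  doc <- list(participant = report$participant,
              tempo = if (is.null(report$tempo)) NULL else
                list(median_iti_ms = report$tempo$median_iti_ms,
                     mean_abs_dev_ms = report$tempo$mean_abs_dev_ms,
                     n_itis = report$tempo$n_itis),
              conditions = lapply(report$conditions, ser_cond))
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = I(17), null = "null")
  if (!is.null(report$table)) {
    write.csv(report$table, file.path(dir, "report.csv"), row.names = FALSE)
  }
  invisible(dir)
}
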