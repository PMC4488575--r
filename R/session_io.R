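#' @importFrom stats median rnorm runif sd var setNames
#' @importFrom utils read.csv write.csv
NULL

STIM_CONDITIONS <- c("NO_STIM", "ISI320", "ISI340", "ISI360", "ISI380",
                     "ISI400", "ISI500", "ISI600", "RANDOM")
RANDOM_ISI_SET <- c(300, 400, 500, 600, 700, 800)

# Internal: nominal ISI in ms encoded by a condition label, NA for NO_STIM/RANDOM.
condition_isi <- function(condition) {
  if (grepl("^ISI[0-9]+$", condition)) as.numeric(sub("^ISI", "", condition)) else NA_real_
}

#' Construct a tap trial
#'
#' A trial is an ordered sequence of tap-onset times (ms from trial start).
#' Complete trials in the study design contain 30 taps; shorter trials are
#' retained but flagged so analyses can apply a minimum-tap threshold.
#'
#' @param trial_id Character scalar identifying the trial.
#' @param role `"training"` or `"test"`.
#' @param onsets_ms Strictly increasing numeric vector of non-negative onset
#'   times in milliseconds from trial start.
#' @param key_labels Optional character vector (`"C4"`/`"C5"`), one per tap,
#'   strictly alternating (the two keys are tapped alternately).
#' @param n_complete Number of taps that makes the trial complete (default 30).
#' @return A list of class `tap_trial` with fields `trial_id`, `role`,
#'   `onsets_ms`, `key_labels`, `complete`.
#' @export
tap_trial <- function(trial_id, role = c("test", "training"), onsets_ms,
                      key_labels = NULL, n_complete = 30L) {
  role <- match.arg(role)
  onsets_ms <- as.numeric(onsets_ms)
  if (any(!is.finite(onsets_ms)) || any(onsets_ms < 0)) {
    stop(sprintf("tap_trial '%s': onsets must be finite and non-negative", trial_id),
         call. = FALSE)
  }
  if (length(onsets_ms) > 1L && any(diff(onsets_ms) <= 0)) {
    stop(sprintf("tap_trial '%s': onsets must be strictly increasing", trial_id),
         call. = FALSE)
  }
  if (!is.null(key_labels)) {
    if (length(key_labels) != length(onsets_ms)) {
      stop(sprintf("tap_trial '%s': one key label per tap required", trial_id),
           call. = FALSE)
    }
    if (!all(key_labels %in% c("C4", "C5"))) {
      stop(sprintf("tap_trial '%s': key labels must be C4/C5", trial_id), call. = FALSE)
    }
    if (length(key_labels) > 1L && any(key_labels[-1] == key_labels[-length(key_labels)])) {
      stop(sprintf("tap_trial '%s': key labels must strictly alternate", trial_id),
           call. = FALSE)
    }
  }
  structure(list(trial_id = as.character(trial_id), role = role,
                 onsets_ms = onsets_ms, key_labels = key_labels,
                 complete = length(onsets_ms) >= n_complete),
            class = "tap_trial")
}

#' Construct a stimulus track
#'
#' @param condition One of NO_STIM, ISI320, ISI340, ISI360, ISI380, ISI400,
#'   ISI500, ISI600, RANDOM.
#' @param onsets_ms Strictly increasing stimulus-onset times in ms
#'   (empty for `NO_STIM`). For isochronous conditions successive differences
#'   must all equal the nominal ISI; for `RANDOM` every difference must be in
#'   \{300, 400, 500, 600, 700, 800\} ms.
#' @param nominal_isi_ms Nominal ISI in ms; inferred from the condition label
#'   for isochronous conditions, `NA` for `RANDOM`/`NO_STIM`.
#' @param seed Optional seed recorded for reproducibility of `RANDOM` tracks.
#' @return A list of class `stimulus_track`.
#' @export
stimulus_track <- function(condition, onsets_ms = numeric(),
                           nominal_isi_ms = condition_isi(condition),
                           seed = NULL) {
  condition <- match.arg(condition, STIM_CONDITIONS)
  onsets_ms <- as.numeric(onsets_ms)
  if (condition == "NO_STIM" && length(onsets_ms) > 0L) {
    stop("stimulus_track: NO_STIM has an empty onset list", call. = FALSE)
  }
  if (length(onsets_ms) > 1L) {
    d <- diff(onsets_ms)
    if (any(d <= 0)) stop("stimulus_track: onsets must be strictly increasing", call. = FALSE)
    if (!is.na(nominal_isi_ms) && any(abs(d - nominal_isi_ms) > 1e-9)) {
      stop(sprintf("stimulus_track: %s intervals must all equal %g ms",
                   condition, nominal_isi_ms), call. = FALSE)
    }
    if (condition == "RANDOM" &&
        !all(vapply(d, function(x) any(abs(x - RANDOM_ISI_SET) < 1e-9), logical(1)))) {
      stop("stimulus_track: RANDOM intervals must come from {300,400,500,600,700,800} ms",
           call. = FALSE)
    }
  }
  structure(list(condition = condition, onsets_ms = onsets_ms,
                 nominal_isi_ms = if (is.na(nominal_isi_ms)) NA_real_ else nominal_isi_ms,
                 seed = seed),
            class = "stimulus_track")
}

#' Construct a study dataset
#'
#' One participant's data: per-condition collections of (trial, track) pairs
#' plus the pool of no-stimulus training trials used by the Monte Carlo
#' re-pairing null. A complete condition holds 6 sessions x 3 test trials =
#' 18 test trials (540 taps); a complete training pool holds 30 trials.
#'
#' @param participant_id Character scalar.
#' @param sessions Named list (by condition) of lists of
#'   `list(trial = <tap_trial>, track = <stimulus_track>, session = <int>)`.
#' @param training_pool List of no-stimulus `tap_trial`s.
#' @param species_profile Optional `"chimp_like"` / `"human_like"` label.
#' @return A list of class `study_dataset`.
#' @export
study_dataset <- function(participant_id, sessions = list(),
                          training_pool = list(), species_profile = NULL) {
  if (length(sessions)) {
    if (is.null(names(sessions)) || !all(names(sessions) %in% STIM_CONDITIONS)) {
      stop("study_dataset: sessions must be a list named by condition", call. = FALSE)
    }
    for (cond in names(sessions)) {
      for (pair in sessions[[cond]]) {
        if (!inherits(pair$trial, "tap_trial") || !inherits(pair$track, "stimulus_track")) {
          stop("study_dataset: each pair needs a tap_trial and a stimulus_track",
               call. = FALSE)
        }
        if (pair$track$condition != cond) {
          stop(sprintf("study_dataset: track condition '%s' under '%s'",
                       pair$track$condition, cond), call. = FALSE)
        }
      }
    }
  }
  if (length(training_pool) &&
      !all(vapply(training_pool, inherits, logical(1), "tap_trial"))) {
    stop("study_dataset: training_pool must contain tap_trial objects", call. = FALSE)
  }
  structure(list(participant_id = as.character(participant_id),
                 species_profile = species_profile,
                 sessions = sessions, training_pool = training_pool),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  n_test <- sum(vapply(x$sessions, length, integer(1)))
  cat(sprintf("Study dataset '%s': %d condition(s), %d test trials, %d training trials\n",
              x$participant_id, length(x$sessions), n_test, length(x$training_pool)))
  invisible(x)
}

# Internal: flatten a dataset to the long one-row-per-tap data.frame schema.
dataset_to_rows <- function(dataset) {
  rows <- list()
  add <- function(trial, cond, session) {
    n <- length(trial$onsets_ms)
    if (n == 0L) return(NULL)
    data.frame(participant = dataset$participant_id, condition = cond,
               session = session, trial = trial$trial_id, role = trial$role,
               tap_index = seq_len(n), onset_ms = trial$onsets_ms,
               key = if (is.null(trial$key_labels)) NA_character_ else trial$key_labels,
               stringsAsFactors = FALSE)
  }
  for (cond in names(dataset$sessions)) {
    for (pair in dataset$sessions[[cond]]) {
      rows[[length(rows) + 1L]] <- add(pair$trial, cond,
                                       if (is.null(pair$session)) NA_integer_ else pair$session)
    }
  }
  for (tr in dataset$training_pool) {
    rows[[length(rows) + 1L]] <- add(tr, "NO_STIM", NA_integer_)
  }
  if (!length(rows)) {
    return(data.frame(participant = character(), condition = character(),
                      session = integer(), trial = character(), role = character(),
                      tap_index = integer(), onset_ms = numeric(), key = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

track_to_list <- function(track, trial_id) {
  list(trial = trial_id, condition = track$condition,
       nominal_isi_ms = if (is.na(track$nominal_isi_ms)) NULL else track$nominal_isi_ms,
       onsets_ms = track$onsets_ms, seed = track$seed)
}

# Internal: tolerate null / missing / string-NA numerics coming back from JSON.
num_or_na <- function(x) {
  if (is.null(x) || !length(x)) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

#' Write a study dataset to disk
#'
#' The canonical interchange format is a long-form CSV (one row per tap, with
#' columns `participant,condition,session,trial,role,tap_index,onset_ms,key`)
#' plus a JSON sidecar (`<path without extension>_stimuli.json`) holding the
#' stimulus tracks. With `format = "json"` the whole dataset is written as a
#' single JSON document instead. Onset values round-trip bit-identically
#' (full double precision is serialized).
#'
#' @param dataset A `study_dataset`.
#' @param path Output file path.
#' @param format `"csv"` (default) or `"json"`.
#' @return Invisibly, `path`.
#' @seealso [read_trials()]
#' @export
write_trials <- function(dataset, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "study_dataset"))
  tracks <- list()
  for (cond in names(dataset$sessions)) {
    for (pair in dataset$sessions[[cond]]) {
      tracks[[length(tracks) + 1L]] <- track_to_list(pair$track, pair$trial$trial_id)
    }
  }
  if (format == "csv") {
    rows <- dataset_to_rows(dataset)
    # format onsets at full precision so read -> write -> read is the identity
    rows$onset_ms <- vapply(rows$onset_ms, function(x) format(x, digits = 17), character(1))
    write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
    sidecar <- sub("\\.[^./]*$", "", path)
    jsonlite::write_json(
      list(participant = dataset$participant_id,
           species_profile = dataset$species_profile, tracks = tracks),
      paste0(sidecar, "_stimuli.json"), auto_unbox = TRUE, digits = I(17), null = "null")
  } else {
    ser_trial <- function(tr) list(trial_id = tr$trial_id, role = tr$role,
                                   onsets_ms = tr$onsets_ms, key_labels = tr$key_labels)
    doc <- list(
      participant = dataset$participant_id,
      species_profile = dataset$species_profile,
      sessions = lapply(dataset$sessions, function(pairs) lapply(pairs, function(p)
        list(session = p$session, trial = ser_trial(p$trial),
             track = track_to_list(p$track, p$trial$trial_id)))),
      training_pool = lapply(dataset$training_pool, ser_trial))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  }
  invisible(path)
}

# Internal: group long-format rows into tap_trial objects, restoring order and
# validating monotonicity (small violations within jitter_tolerance_ms are
# re-sorted; larger ones are data errors naming the trial).
rows_to_trials <- function(rows, jitter_tolerance_ms) {
  split_keys <- paste(rows$condition, rows$trial, sep = "\r")
  lapply(split(seq_len(nrow(rows)), factor(split_keys, levels = unique(split_keys))),
         function(idx) {
    r <- rows[idx, ][order(rows$tap_index[idx]), ]
    onsets <- r$onset_ms
    if (length(onsets) > 1L && any(diff(onsets) <= 0)) {
      worst <- -min(diff(onsets))
      if (worst <= jitter_tolerance_ms) onsets <- sort(onsets)
      else stop(sprintf("read_trials: non-monotone onsets in trial '%s' (max inversion %g ms)",
                        r$trial[1], worst), call. = FALSE)
    }
    if (length(onsets) > 1L && any(diff(onsets) == 0)) {
      stop(sprintf("read_trials: duplicated onset time in trial '%s'", r$trial[1]),
           call. = FALSE)
    }
    keys <- if (all(is.na(r$key)) || all(r$key == "")) NULL else r$key
    list(condition = r$condition[1],
         session = r$session[1],
         trial = tap_trial(r$trial[1], role = r$role[1], onsets_ms = onsets,
                           key_labels = keys))
  })
}

#' Read a study dataset from disk
#'
#' Reads the long-form CSV (+ JSON stimulus sidecar) or single-JSON formats
#' written by [write_trials()]. Rows are grouped into trials in file order;
#' onsets are re-sorted only if an order violation is within
#' `jitter_tolerance_ms`, otherwise loading fails naming the trial.
#'
#' @param path Input file path.
#' @param format `"csv"` (default) or `"json"`.
#' @param jitter_tolerance_ms Largest onset-order inversion silently repaired
#'   by re-sorting (default 0: any violation is an error).
#' @return A validated `study_dataset`.
#' @export
read_trials <- function(path, format = c("csv", "json"), jitter_tolerance_ms = 0) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("read_trials: no such file '%s'", path), call. = FALSE)
  if (format == "json") {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    de_trial <- function(t) tap_trial(t$trial_id, role = t$role,
                                      onsets_ms = unlist(t$onsets_ms),
                                      key_labels = if (is.null(t$key_labels)) NULL
                                                   else unlist(t$key_labels))
    sessions <- lapply(doc$sessions, function(pairs) lapply(pairs, function(p) {
      tk <- p$track
      list(trial = de_trial(p$trial),
           track = stimulus_track(tk$condition, unlist(tk$onsets_ms),
                                  nominal_isi_ms = num_or_na(tk$nominal_isi_ms),
                                  seed = tk$seed),
           session = p$session)
    }))
    return(study_dataset(doc$participant, sessions = sessions,
                         training_pool = lapply(doc$training_pool, de_trial),
                         species_profile = doc$species_profile))
  }
  rows <- read.csv(path, stringsAsFactors = FALSE,
                   colClasses = c(onset_ms = "numeric"))
  needed <- c("participant", "condition", "session", "trial", "role",
              "tap_index", "onset_ms")
  if (!all(needed %in% names(rows))) {
    stop(sprintf("read_trials: missing columns: %s",
                 paste(setdiff(needed, names(rows)), collapse = ", ")), call. = FALSE)
  }
  if (!"key" %in% names(rows)) rows$key <- NA_character_
  participant <- if (nrow(rows)) rows$participant[1] else "unknown"

  sidecar <- paste0(sub("\\.[^./]*$", "", path), "_stimuli.json")
  tracks <- list()
  species <- NULL
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = FALSE)
    species <- side$species_profile
    for (tk in side$tracks) {
      tracks[[tk$trial]] <- stimulus_track(
        tk$condition, unlist(tk$onsets_ms),
        nominal_isi_ms = num_or_na(tk$nominal_isi_ms),
        seed = tk$seed)
    }
  }

  parsed <- if (nrow(rows)) rows_to_trials(rows, jitter_tolerance_ms) else list()
  sessions <- list()
  training_pool <- list()
  for (item in parsed) {
    cond <- item$condition
    if (cond == "NO_STIM" && item$trial$role == "training") {
      training_pool[[length(training_pool) + 1L]] <- item$trial
      next
    }
    track <- tracks[[item$trial$trial_id]]
    if (is.null(track)) {
      track <- stimulus_track(cond,
                              onsets_ms = numeric(),
                              nominal_isi_ms = condition_isi(cond))
    }
    sessions[[cond]] <- c(sessions[[cond]],
                          list(list(trial = item$trial, track = track,
                                    session = item$session)))
  }
  study_dataset(participant, sessions = sessions, training_pool = training_pool,
                species_profile = species)
}
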