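#' Generate a stimulus track
#'
#' Isochronous conditions produce onsets 0, ISI, 2*ISI, ...; the `RANDOM`
#' condition draws successive intervals i.i.d. uniformly from
#' \{300, 400, 500, 600, 700, 800\} ms (reproducibly under `seed`).
#' `NO_STIM` only admits an empty track.
#'
#' @param condition Condition label (see [stimulus_track()]).
#' @param n_onsets Number of onsets (>= 1 except for `NO_STIM`).
#' @param seed RNG seed, required for `RANDOM`.
#' @return A `stimulus_track`.
#' @examples
#' generate_stimulus_track("ISI400", 5)  # 0 400 800 1200 1600
#' @export
generate_stimulus_track <- function(condition, n_onsets, seed = NULL) {
  condition <- match.arg(condition, STIM_CONDITIONS)
  if (condition == "NO_STIM") {
    if (n_onsets > 0) stop("generate_stimulus_track: NO_STIM has no onsets", call. = FALSE)
    return(stimulus_track("NO_STIM"))
  }
  if (n_onsets < 1) stop("generate_stimulus_track: need n_onsets >= 1", call. = FALSE)
  if (condition == "RANDOM") {
    if (is.null(seed)) stop("generate_stimulus_track: RANDOM requires a seed", call. = FALSE)
    onsets <- withr_seed(seed, {
      cumsum(c(0, sample(RANDOM_ISI_SET, n_onsets - 1L, replace = TRUE)))
    })
    return(stimulus_track("RANDOM", onsets, nominal_isi_ms = NA_real_, seed = seed))
  }
  isi <- condition_isi(condition)
  stimulus_track(condition, (seq_len(n_onsets) - 1L) * isi, nominal_isi_ms = isi)
}

# Internal: evaluate an expression under a local RNG seed without disturbing
# the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Map a tap time to circular phase relative to stimulus onsets
#'
#' Each tap is matched to the nearest stimulus onset; the signed asynchrony
#' (positive = tap after onset) is normalised by the local inter-stimulus
#' interval and expressed in degrees, stimulus onsets at 0 degrees, range
#' (-180, 180]. A tap exactly midway between two onsets is assigned +180
#' degrees relative to the preceding onset. Taps outside the track envelope
#' (before the first onset minus half the first interval, or after the last
#' onset plus half the last interval) are unmatched.
#'
#' For isochronous tracks the local ISI is the nominal ISI. For `RANDOM`
#' tracks it is, by default, the interval that contains the tap
#' (`random_normalization = "local"`); `"fixed"` normalises by `reference_isi_ms`
#' instead.
#'
#' @param tap_time_ms Scalar tap-onset time (ms, same clock as the track).
#' @param track A non-empty `stimulus_track`.
#' @param random_normalization `"local"` or `"fixed"` (RANDOM tracks only).
#' @param reference_isi_ms Reference ISI for `"fixed"` normalisation.
#' @return A list of class `phase_sample` with `tap_time_ms`,
#'   `matched_onset_ms`, `local_isi_ms`, `asynchrony_ms`, `angle_deg`,
#'   `matched` (FALSE for taps outside the envelope, all other fields `NA`).
#' @export
tap_to_phase <- function(tap_time_ms, track,
                         random_normalization = c("local", "fixed"),
                         reference_isi_ms = NULL) {
  random_normalization <- match.arg(random_normalization)
  on <- track$onsets_ms
  if (!length(on)) stop("tap_to_phase: empty stimulus track", call. = FALSE)
  n <- length(on)
  first_gap <- if (n > 1L) on[2] - on[1] else track$nominal_isi_ms
  last_gap <- if (n > 1L) on[n] - on[n - 1L] else track$nominal_isi_ms
  unmatched <- list(tap_time_ms = tap_time_ms, matched_onset_ms = NA_real_,
                    local_isi_ms = NA_real_, asynchrony_ms = NA_real_,
                    angle_deg = NA_real_, matched = FALSE)
  class(unmatched) <- "phase_sample"
  if (is.na(first_gap) ||
      tap_time_ms < on[1] - first_gap / 2 || tap_time_ms > on[n] + last_gap / 2) {
    return(unmatched)
  }
  # nearest onset; exact midpoint ties to the preceding onset (+180 deg)
  k <- findInterval(tap_time_ms, on)        # preceding onset index (0 if before first)
  if (k == 0L) { matched <- 1L } else if (k == n) { matched <- n } else {
    mid <- (on[k] + on[k + 1L]) / 2
    matched <- if (tap_time_ms <= mid) k else k + 1L
  }
  asyn <- tap_time_ms - on[matched]
  # local ISI: the interval containing the tap (nominal for isochronous tracks)
  local_isi <- if (!is.na(track$nominal_isi_ms)) {
    track$nominal_isi_ms
  } else if (random_normalization == "fixed") {
    if (is.null(reference_isi_ms)) {
      stop("tap_to_phase: fixed normalisation needs reference_isi_ms", call. = FALSE)
    }
    reference_isi_ms
  } else if (asyn >= 0) {
    if (matched < n) on[matched + 1L] - on[matched]
    else on[n] - on[n - 1L]                  # past the last onset: trailing interval
  } else {
    if (matched > 1L) on[matched] - on[matched - 1L]
    else on[2] - on[1]                       # before the first onset: leading interval
  }
  angle <- wrap_degrees(360 * asyn / local_isi)
  out <- list(tap_time_ms = tap_time_ms, matched_onset_ms = on[matched],
              local_isi_ms = local_isi, asynchrony_ms = asyn,
              angle_deg = angle, matched = TRUE)
  class(out) <- "phase_sample"
  out
}

#' Convert a phase angle back to a signed asynchrony
#'
#' @param angle_deg Angle in degrees, in (-180, 180].
#' @param isi_ms Inter-stimulus interval in ms (> 0).
#' @return Signed asynchrony in ms (`angle_deg / 360 * isi_ms`); positive
#'   means the tap followed the stimulus onset.
#' @examples
#' angle_to_ms(128.35, 400)   # 142.6 ms after the onset
#' angle_to_ms(-64.26, 500)   # 89.3 ms before the onset
#' @export
angle_to_ms <- function(angle_deg, isi_ms) {
  if (any(isi_ms <= 0)) stop("angle_to_ms: isi_ms must be positive", call. = FALSE)
  if (any(angle_deg <= -180 | angle_deg > 180)) {
    stop("angle_to_ms: angle must lie in (-180, 180]", call. = FALSE)
  }
  angle_deg / 360 * isi_ms
}

#' Phase angles for a whole trial
#'
#' Applies [tap_to_phase()] to every tap of a trial and collects the matched
#' angles in tap order; taps outside the track envelope are dropped and
#' counted.
#'
#' @param trial A `tap_trial`.
#' @param track A non-`NO_STIM` `stimulus_track` on the same clock.
#' @param ... Passed to [tap_to_phase()].
#' @return A list with `angles_deg`, `asynchronies_ms`, `local_isis_ms`
#'   (matched taps, in order) and `n_dropped`.
#' @export
phases_for_trial <- function(trial, track, ...) {
  stopifnot(inherits(trial, "tap_trial"), inherits(track, "stimulus_track"))
  if (track$condition == "NO_STIM" || !length(track$onsets_ms)) {
    stop("phases_for_trial: phases require a stimulus track with onsets", call. = FALSE)
  }
  ps <- lapply(trial$onsets_ms, tap_to_phase, track = track, ...)
  matched <- vapply(ps, `[[`, logical(1), "matched")
  list(angles_deg = vapply(ps[matched], `[[`, numeric(1), "angle_deg"),
       asynchronies_ms = vapply(ps[matched], `[[`, numeric(1), "asynchrony_ms"),
       local_isis_ms = vapply(ps[matched], `[[`, numeric(1), "local_isi_ms"),
       n_dropped = sum(!matched))
}
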