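#' Inter-tap intervals of one trial
#'
#' @param trial A `tap_trial`.
#' @return Numeric vector of successive onset differences (ms), length
#'   `n_taps - 1`; empty (with a warning) for trials with fewer than 2 taps.
#' @export
trial_itis <- function(trial) {
  stopifnot(inherits(trial, "tap_trial"))
  if (length(trial$onsets_ms) < 2L) {
    warning(sprintf("trial '%s' has fewer than 2 taps; no intervals", trial$trial_id))
    return(numeric())
  }
  diff(trial$onsets_ms)
}

#' Spontaneous-tempo summary for a participant
#'
#' Pools the inter-tap intervals of the supplied trials and reports the
#' median ITI (the spontaneous motor tempo) and the mean absolute deviation
#' of the ITIs about that median (the tempo variability measure). The result
#' is invariant to trial order.
#'
#' @param trials List of `tap_trial`s (typically the no-stimulus condition).
#' @param participant_id Identifier copied into the summary.
#' @param min_taps Trials with fewer taps are skipped (default 2, i.e. every
#'   trial contributing at least one interval is used).
#' @return A list of class `tempo_summary` with `participant_id`,
#'   `median_iti_ms`, `mean_abs_dev_ms`, `n_itis`, `n_outliers_excluded`
#'   (0 here; see [exclude_outliers()]).
#' @export
tempo_summary <- function(trials, participant_id = "participant", min_taps = 2L) {
  if (inherits(trials, "tap_trial")) trials <- list(trials)
  keep <- vapply(trials, function(t) length(t$onsets_ms) >= min_taps, logical(1))
  itis <- unlist(lapply(trials[keep], function(t) diff(t$onsets_ms)))
  if (!length(itis)) stop("tempo_summary: no inter-tap intervals in pool", call. = FALSE)
  med <- median(itis)
  structure(list(participant_id = participant_id,
                 median_iti_ms = med,
                 mean_abs_dev_ms = mean(abs(itis - med)),
                 n_itis = length(itis),
                 n_outliers_excluded = 0L),
            class = "tempo_summary")
}

#' @export
print.tempo_summary <- function(x, ...) {
  cat(sprintf("Tempo summary '%s': median ITI %.1f ms, mean abs deviation %.1f ms (n = %d)\n",
              x$participant_id, x$median_iti_ms, x$mean_abs_dev_ms, x$n_itis))
  invisible(x)
}

#' Exclude outlying inter-tap intervals
#'
#' Retains the intervals inside the closed band
#' `median +/- 2 * mean_abs_dev` of the supplied summary (intervals deviating
#' from the median by more than two absolute deviations are treated as
#' outliers). The median itself is always retained.
#'
#' @param itis Numeric vector of inter-tap intervals (ms).
#' @param summary A `tempo_summary` computed from the same pool.
#' @return Filtered numeric vector.
#' @export
exclude_outliers <- function(itis, summary) {
  stopifnot(inherits(summary, "tempo_summary"))
  band <- 2 * summary$mean_abs_dev_ms
  itis[abs(itis - summary$median_iti_ms) <= band]
}

# Internal: two-sided p for a t statistic, guarding non-finite t.
t_two_sided_p <- function(t, df) {
  if (!is.finite(t)) return(0)
  2 * stats::pt(-abs(t), df)
}

#' Pooled-variance two-sample t test
#'
#' Student's t test for independent samples with the pooled variance estimate
#' (df = n_a + n_b - 2), the variant that reproduces the between-species
#' tempo comparisons. Degenerate pools (zero pooled variance) yield t = 0 /
#' p = 1 for equal means and a flagged signed infinite t otherwise.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`, `degenerate` (TRUE when the pooled
#'   variance is zero).
#' @examples
#' two_sample_t(c(449.5, 386.5, 355.5), c(358.5, 481.5, 505, 419.5, 487, 333))
#' @export
two_sample_t <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("two_sample_t: each group needs >= 2 values", call. = FALSE)
  df <- na + nb - 2L
  sp2 <- ((na - 1) * var(group_a) + (nb - 1) * var(group_b)) / df
  if (sp2 <= 0) {
    delta <- mean(group_a) - mean(group_b)
    t <- if (delta == 0) 0 else sign(delta) * Inf
    return(list(t = t, df = df, p = if (delta == 0) 1 else 0, degenerate = TRUE))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, degenerate = FALSE)
}

#' Paired t test
#'
#' One-sample t test on the within-pair differences (df = n - 1). A constant
#' non-zero difference (zero spread) yields a flagged signed infinite t.
#'
#' @param x,y Numeric vectors of equal length >= 2, paired by position.
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("paired_t: length mismatch", call. = FALSE)
  if (length(x) < 2L) stop("paired_t: need >= 2 pairs", call. = FALSE)
  d <- x - y
  df <- length(d) - 1L
  if (sd(d) == 0) {
    m <- mean(d)
    t <- if (m == 0) 0 else sign(m) * Inf
    return(list(t = t, df = df, p = if (m == 0) 1 else 0, degenerate = TRUE))
  }
  fit <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, degenerate = FALSE)
}

#' Tempo mismatch between spontaneous tempo and a stimulus ISI
#'
#' @param median_iti_ms Spontaneous motor tempo (median ITI, ms, > 0).
#' @param isi_ms Stimulus inter-onset interval (ms, > 0).
#' @return Percent mismatch `100 * |isi - median| / median`.
#' @examples
#' tempo_mismatch(449.5, 400)  # ~11%: close tempi, entrainment plausible
#' tempo_mismatch(355.5, 600)  # ~68.8%: too distant
#' @export
tempo_mismatch <- function(median_iti_ms, isi_ms) {
  if (any(median_iti_ms <= 0) || any(isi_ms <= 0)) {
    stop("tempo_mismatch: tempi must be positive", call. = FALSE)
  }
  100 * abs(isi_ms - median_iti_ms) / median_iti_ms
}
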