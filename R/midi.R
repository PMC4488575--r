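# Minimal standard-MIDI-file (format 0/1) reader for the tap-import path.
# Only what the import needs is implemented: note-on extraction on one channel
# with tempo-map tick->ms conversion. Metrical division only (SMPTE timecode
# division is rejected).

# Internal: read a big-endian unsigned integer from raw bytes.
be_uint <- function(bytes) {
  Reduce(function(acc, b) acc * 256 + as.integer(b), bytes, accumulate = FALSE, init = 0)
}

# Internal: variable-length quantity at position i; returns value and next position.
read_vlq <- function(raw, i) {
  val <- 0
  repeat {
    b <- as.integer(raw[i]); i <- i + 1L
    val <- val * 128 + (b %% 128L)
    if (b < 128L) break
  }
  list(value = val, pos = i)
}

# Internal: parse one MTrk chunk into a data.frame of events with absolute
# ticks. Keeps note-ons (velocity > 0) and tempo meta events.
parse_track <- function(raw, from, to) {
  i <- from
  tick <- 0
  status <- NA_integer_
  ons <- list()
  tempos <- list()
  while (i <= to) {
    v <- read_vlq(raw, i); i <- v$pos
    tick <- tick + v$value
    b <- as.integer(raw[i])
    if (b >= 128L) { status <- b; i <- i + 1L } # else running status
    if (is.na(status)) stop("read_midi_onsets: data byte with no running status", call. = FALSE)
    if (status == 255L) {               # meta event
      type <- as.integer(raw[i]); i <- i + 1L
      v <- read_vlq(raw, i); i <- v$pos
      if (type == 81L && v$value == 3L) {
        tempos[[length(tempos) + 1L]] <- c(tick, be_uint(raw[i:(i + 2L)]))
      }
      i <- i + v$value
    } else if (status %in% c(240L, 247L)) {  # sysex
      v <- read_vlq(raw, i); i <- v$pos
      i <- i + v$value
    } else {
      hi <- status %/% 16L
      n_data <- if (hi %in% c(12L, 13L)) 1L else 2L  # program change / channel pressure
      if (hi == 9L && as.integer(raw[i + 1L]) > 0L) { # note-on, velocity > 0
        ons[[length(ons) + 1L]] <- c(tick, status %% 16L, as.integer(raw[i]))
      }
      i <- i + n_data
    }
  }
  list(
    ons = if (length(ons)) do.call(rbind, ons) else matrix(numeric(), 0, 3),
    tempos = if (length(tempos)) do.call(rbind, tempos) else matrix(numeric(), 0, 2)
  )
}

# Internal: convert absolute ticks to ms under a tempo map
# (rows: tick, microseconds per quarter note; default 500000 before any entry).
ticks_to_ms <- function(ticks, tempo_map, division) {
  if (nrow(tempo_map)) tempo_map <- tempo_map[order(tempo_map[, 1]), , drop = FALSE]
  segs <- rbind(c(0, 500000), tempo_map)
  # drop a default segment immediately overridden at tick 0
  if (nrow(segs) > 1 && segs[2, 1] == 0) segs <- segs[-1, , drop = FALSE]
  seg_start_ms <- numeric(nrow(segs))
  for (k in seq_len(nrow(segs))[-1]) {
    seg_start_ms[k] <- seg_start_ms[k - 1] +
      (segs[k, 1] - segs[k - 1, 1]) * segs[k - 1, 2] / division / 1000
  }
  idx <- findInterval(ticks, segs[, 1])
  seg_start_ms[idx] + (ticks - segs[idx, 1]) * segs[idx, 2] / division / 1000
}

#' Read tap onsets from a standard MIDI file
#'
#' Extracts note-on events (velocity > 0) on one MIDI channel and converts
#' their tick times to milliseconds using the file's tempo map (all tempo
#' meta events across tracks; 120 bpm where none is given). Returns one
#' [tap_trial()] per track containing note-ons, or, when `gap_split_ms` is
#' set, splits a track's onsets into separate trials at gaps exceeding the
#' threshold. Each trial's onsets are re-zeroed to its first tap.
#'
#' @param path Path to a format 0 or 1 standard MIDI file.
#' @param channel MIDI channel to keep, 1-16 (default 1).
#' @param gap_split_ms Optional gap threshold (ms) for splitting a track into
#'   trials; `NULL` (default) keeps one trial per track.
#' @param role Role assigned to the resulting trials (default `"test"`).
#' @return List of `tap_trial` objects (possibly empty).
#' @export
read_midi_onsets <- function(path, channel = 1L, gap_split_ms = NULL, role = "test") {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 14L || rawToChar(raw[1:4]) != "MThd") {
    stop("read_midi_onsets: not a standard MIDI file (missing MThd)", call. = FALSE)
  }
  division <- be_uint(raw[13:14])
  if (division >= 32768L) {
    stop("read_midi_onsets: SMPTE time division not supported", call. = FALSE)
  }
  n_tracks <- be_uint(raw[11:12])
  i <- 15L
  tracks <- list()
  while (length(tracks) < n_tracks) {
    if (i + 7L > length(raw) || rawToChar(raw[i:(i + 3L)]) != "MTrk") {
      stop("read_midi_onsets: malformed MIDI file (missing MTrk chunk)", call. = FALSE)
    }
    len <- be_uint(raw[(i + 4L):(i + 7L)])
    tracks[[length(tracks) + 1L]] <- parse_track(raw, i + 8L, i + 7L + len)
    i <- i + 8L + len
  }
  tempo_map <- do.call(rbind, c(list(matrix(numeric(), 0, 2)),
                                lapply(tracks, `[[`, "tempos")))
  trials <- list()
  for (t_idx in seq_along(tracks)) {
    ons <- tracks[[t_idx]]$ons
    ons <- ons[ons[, 2] == channel - 1L, , drop = FALSE]
    if (!nrow(ons)) next
    ms <- sort(ticks_to_ms(ons[, 1], tempo_map, division))
    pieces <- if (is.null(gap_split_ms)) list(ms) else
      split(ms, cumsum(c(0, diff(ms) > gap_split_ms)))
    for (p_idx in seq_along(pieces)) {
      onsets <- pieces[[p_idx]] - pieces[[p_idx]][1]
      trials[[length(trials) + 1L]] <-
        tap_trial(sprintf("midi_t%d_%d", t_idx, p_idx), role = role,
                  onsets_ms = onsets)
    }
  }
  trials
}
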