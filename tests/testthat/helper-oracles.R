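# Independent oracles and fixture builders used across the suite.

# Brute-force Hodges-Ajne statistic: minimal count over 3600 rotated
# half-circles [theta, theta + 180). Independent of the scan implementation.
brute_ajne_m <- function(angles_deg) {
  a <- angles_deg %% 360
  m <- length(a)
  for (theta in seq(0, 359.9, by = 0.1)) {
    m <- min(m, sum(((a - theta) %% 360) < 180))
  }
  m
}

# Mean resultant length by direct vector summation.
brute_resultant <- function(angles_deg) {
  r <- angles_deg * pi / 180
  sqrt(sum(cos(r))^2 + sum(sin(r))^2) / length(r)
}

# --- standard-MIDI-file fixture builder (binary written at test time) ------

midi_vlq <- function(x) {
  bytes <- x %% 128L
  x <- x %/% 128L
  while (x > 0L) {
    bytes <- c(x %% 128L + 128L, bytes)
    x <- x %/% 128L
  }
  as.raw(bytes)
}

midi_be <- function(x, width) {
  as.raw(rev((x %/% 256^(seq_len(width) - 1)) %% 256))
}

# events: list of lists with fields delta (ticks) and bytes (raw event bytes)
midi_track_chunk <- function(events) {
  body <- do.call(c, c(lapply(events, function(e) c(midi_vlq(e$delta), as.raw(e$bytes))),
                       list(c(midi_vlq(0L), as.raw(c(0xFF, 0x2F, 0x00))))))
  c(charToRaw("MTrk"), midi_be(length(body), 4L), body)
}

# Builds a format-1 MIDI file. tracks: list of event lists (see above).
write_midi_fixture <- function(path, tracks, division = 480L) {
  header <- c(charToRaw("MThd"), midi_be(6L, 4L), midi_be(1L, 2L),
              midi_be(length(tracks), 2L), midi_be(division, 2L))
  writeBin(c(header, do.call(c, lapply(tracks, midi_track_chunk))), path)
  path
}

note_on <- function(delta, note = 60L, channel = 1L, velocity = 100L) {
  list(delta = delta, bytes = c(0x90 + channel - 1L, note, velocity))
}
note_off <- function(delta, note = 60L, channel = 1L) {
  list(delta = delta, bytes = c(0x80 + channel - 1L, note, 0L))
}
tempo_event <- function(delta, usec_per_quarter) {
  list(delta = delta,
       bytes = c(0xFF, 0x51, 0x03,
                 as.integer(midi_be(usec_per_quarter, 3L))))
}

# --- small dataset builders -------------------------------------------------

make_trial <- function(onsets, id = "t1", role = "test") {
  tap_trial(id, role = role, onsets_ms = onsets)
}

# A tiny two-condition dataset with hand-built trials.
tiny_dataset <- function() {
  tr1 <- make_trial(c(0, 400, 800, 1200), "ISI400_1")
  tr2 <- make_trial(c(100, 480, 910, 1290), "ISI400_2")
  tk <- generate_stimulus_track("ISI400", 6)
  train <- lapply(1:3, function(i) make_trial(c(0, 350, 720, 1100) + i,
                                              sprintf("train_%d", i), "training"))
  study_dataset("p1",
                sessions = list(ISI400 = list(
                  list(trial = tr1, track = tk, session = 1L),
                  list(trial = tr2, track = tk, session = 1L))),
                training_pool = train)
}
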