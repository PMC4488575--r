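Package: tapentrain
Title: Circular Statistics for Intermittent Entrainment in Self-Paced Tapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of whether isochronous auditory distractor rhythms
    intermittently entrain self-paced alternate tapping. Maps tap onsets to
    circular phase relative to stimulus onsets, tests phase uniformity with
    the Hodges-Ajne omnibus test and the Rayleigh test, builds a Monte Carlo
    re-pairing null from no-stimulus training trials, detects trial-by-trial
    entrainment episodes, and summarises spontaneous motor tempo (median
    inter-tap interval and its mean absolute deviation). Includes a stochastic
    tapper simulator (random-walk motor period with optional sine phase
    coupling to the stimulus) that generates study-structured datasets for
    calibration and power analysis, plus CSV/JSON and standard-MIDI-file
    import of tap-onset data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
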