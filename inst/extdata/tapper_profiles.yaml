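# Tapper simulator presets (version 1).
#
# chimp_like / human_like are calibrated so that pooled no-stimulus tapping
# (30 trials x 30 taps) lands in the observed mean-absolute-deviation bands:
# roughly 120-152 ms for chimpanzee-like tapping (large continuous
# fluctuation: the period random walk dominates) and 13-23 ms for human-like
# tapping. Base periods are drawn uniformly from the observed median-ITI
# ranges. The entrainable preset sits between the two and is the substrate
# for planted-entrainment recovery experiments: entrained episodes must have
# sub-chimp asynchrony spread to be detectable at all, while still enough
# within-trial drift that uncoupled trials dephase.
version: 1
chimp_like:
  base_period_range_ms: [355, 450]
  period_noise_sd_ms: 130
  drift_sd_ms: 30
human_like:
  base_period_range_ms: [333, 505]
  period_noise_sd_ms: 20
  drift_sd_ms: 2.5
entrainable:
  base_period_range_ms: [380, 420]
  period_noise_sd_ms: 45
  drift_sd_ms: 10
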