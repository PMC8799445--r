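# conjugate, then sample after a 2-minute soak, imaged 30 min after sample.
# Per-batch durations are placeholder estimates for a generic 8-channel
# instrument; calibrate them for a real deck before trusting the timings.
imaging_tolerance: 60
prep_duration: 15
n_channels: 8
steps:
  - action: dispense_reagent
    reagent: conjugate
    volume: 10
    destination: conjugate_well
    duration: 30
    liquid_class: HighVis
  - action: dispense_sample
    reagent: sample
    volume: 50
    destination: sample_port
    min_delay: 120
    duration: 30
  - action: image
    target_time: 1800        # 1800 s = 30 min; use 2100 for a 35-min read
    duration: 10
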