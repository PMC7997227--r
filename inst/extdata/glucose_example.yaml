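# Built-in glucose screening example: standardized log-transformed 2-h
# post-load glucose, 179 diabetic vs 2488 non-diabetic subjects.
# All quantities are in units of the non-diseased sample's SD.
scenario:
  non_diseased:
    mean: 0.0
    sd: 1.0
    size: 2488
  diseased:
    mean: 2.99
    sd: 0.75
    size: 179
  measurement:
    u_m: 0.046
    n_u: 80
  threshold: 2.26
  confidence: 0.95
sweep:
  axis: threshold
  from: 1.1
  to: 2.5
  points: 101
  measures: [DOR]
  output: absolute
output:
  table_format: csv
  plot_format: png
seed: 1
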