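# Example run configuration: quarter-scale intact cord, drug-induced rhythm.
# Seeds are mandatory; build controls network sampling, run controls
# initial conditions.
model:
  variant: drug
  topology: intact
  alpha: 0.17
  scale: 0.25
sim:
  dt: 0.1
  settle_s: 10
  record_s: 30
seeds:
  build: 42
  run: 7
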