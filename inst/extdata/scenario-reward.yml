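# example scenario configuration: linear-reward allocation on the unit domain
prior:
  kind: skewed
  rate: 2.5
reward:
  kind: linear
  intercept: 0
  slope: 1
objective: reward
optimizer:
  n_knots: 12
  restarts: 1
  capacity_squared: 200000
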