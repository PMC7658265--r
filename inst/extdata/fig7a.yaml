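analysis: gate
topology:
  kind: cyclic
  'N': 3
params:
  nu: 1.84
  sigma_M: 100.0
  sigma_inh: 35.0
  M: 10.0
  'n': 4
  L: 5.0e+06
  phi: 1.0
  k_s: 0.06
  q: 1.0
  k_ADP: 0.1
schedule: []
options:
  knockout:
  - 0
  - 1
  - 1
seed: 1
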