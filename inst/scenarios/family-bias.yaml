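name: family-bias
seed: 104
dag:
  depth: 3
  branching: 2
  slimFraction: 0.5
  namespace: biological_process
length:
  meanLog: 5.19
  sdLog: 0.2
ss:
  self: 0.8
background: 0
classes:
- "n": 150
  signal:
    residues: [K, R]
    fold: 2.0
  families:
    copies: 5
    mutRate: 0.25
- "n": 150
  signal:
    residues: [I, L, V]
    fold: 2.0
  families:
    copies: 5
    mutRate: 0.25
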