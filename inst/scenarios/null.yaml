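name: "null"
seed: 103
dag:
  depth: 3
  branching: 2
  slimFraction: 0.5
  namespace: biological_process
length:
  meanLog: 5.704
  sdLog: 0.25
ss:
  self: 0.8
background: 250
classes:
- "n": 250
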