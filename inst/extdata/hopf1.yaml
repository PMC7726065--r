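alpha: 1.0
d: 0.0
tau0: 0.75
gamma: 3.3482
kernel:
- eta: 12.5
  mu: 2.0
- eta: -10.0
  mu: 1.0
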