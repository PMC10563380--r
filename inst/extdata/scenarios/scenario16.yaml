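name: scenario16
rawA:
- 0.08
- 0.16
- 0.24
- 0.32
- 0.4
rawB:
- 0.08
- 0.16
- 0.24
phiT_metric: 0.35
tox:
- - 0.5
  - 0.56
  - 0.65
  - 0.68
  - 0.72
- - 0.55
  - 0.62
  - 0.7
  - 0.72
  - 0.8
- - 0.6
  - 0.67
  - 0.75
  - 0.79
  - 0.85
eff:
- - 0.52
  - 0.62
  - 0.7
  - 0.76
  - 0.79
- - 0.55
  - 0.66
  - 0.74
  - 0.79
  - 0.82
- - 0.58
  - 0.7
  - 0.78
  - 0.82
  - 0.85
eff_threshold: 0.45
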