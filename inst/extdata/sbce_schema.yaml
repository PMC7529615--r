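# Canonical 9-feature coding of one SBCE reading.
# Level code 1 is always the normal/absent condition.
features:
- column: f1
  name: area affected
  levels: [normal, proximal & beyond]
- column: f2
  name: distribution pattern
  levels: [normal, patchy, continuous]
- column: f3
  name: mosaic pattern
  levels: [absent, present]
- column: f4
  name: fissuring
  levels: [absent, present]
- column: f5
  name: scalloping
  levels: [absent, present]
- column: f6
  name: villous atrophy
  levels: [absent, present]
- column: f7
  name: nodularity
  levels: [absent, present]
- column: f8
  name: ulcers
  levels: [absent, present]
- column: f9
  name: percent length of abnormal mucosa
  levels: [under 50%, over 50%]
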