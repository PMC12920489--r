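weights:
  histopathology: 0.3
  tumor_burden: 0.25
  molecular: 0.25
  immune: 0.2
low_max: 0.8
intermediate_max: 1.4
override_margin_mm: 2.0
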