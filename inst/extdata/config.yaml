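criteria_set: emirates_default
report:
  precision: 1.0
  format: csv
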