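above_50:
- genetic_curative
- highly_effective_chronic
below_50:
- high_quality_symptomatic
- low_quality_symptomatic
expected_order:
- genetic_curative
- highly_effective_chronic
- high_quality_symptomatic
- low_quality_symptomatic
min_spread: 40.0
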