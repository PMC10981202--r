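"participant","cost_effectiveness","magnitude_of_health_gain","therapeutic_alternative","disease_severity","budget_impact","disease_rarity","clinical_evidence","household_burden","indication_uniqueness","patient_age"
"p01",25,40,30,40,40,0,25,40,25,25
"p02",25,40,30,40,40,0,25,40,25,25
"p03",25,40,30,40,40,0,25,40,25,25
"p04",25,40,30,40,40,0,25,40,25,25
"p05",25,40,30,40,40,0,25,40,25,25
"p06",25,40,30,40,40,0,25,40,25,25
"p07",25,40,30,40,40,0,25,40,25,25
"p08",25,40,30,40,40,0,25,40,25,25
"p09",25,40,30,40,40,0,25,40,25,25
"p10",25,40,30,40,40,0,25,40,25,25
"p11",25,40,30,40,40,0,25,40,25,25
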