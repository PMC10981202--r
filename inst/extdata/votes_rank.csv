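"participant","cost_effectiveness","magnitude_of_health_gain","therapeutic_alternative","disease_severity","budget_impact","disease_rarity","clinical_evidence","household_burden","indication_uniqueness","patient_age"
"p01",1,2,3,4,5,6,6,7,8,9
"p02",1,2,3,4,5,6,6,7,8,9
"p03",1,2,3,4,5,6,6,7,8,9
"p04",1,2,3,4,5,6,6,7,8,9
"p05",1,2,3,4,5,6,6,7,8,9
"p06",1,2,3,4,5,6,6,7,8,9
"p07",1,2,3,4,5,6,6,7,8,9
"p08",1,2,3,4,5,6,6,7,8,9
"p09",1,2,3,4,5,6,6,7,8,9
"p10",1,2,3,4,5,6,6,7,8,9
"p11",1,2,3,4,5,6,6,7,8,9
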