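"criterion","genetic_curative","highly_effective_chronic","high_quality_symptomatic","low_quality_symptomatic"
"cost_effectiveness","Between 5-10x GDP per capita","Between 2-3x GDP per capita","Between 3-5x GDP per capita","Between 5-10x GDP per capita"
"magnitude_of_health_gain","Curative therapy (no need for further therapy)","Long-term remission on therapy (therapy until progression)","Symptom relief or short-term benefit","Symptom relief or short-term benefit"
"therapeutic_alternative","No effective treatments are available","Less effective treatments are available","Less effective treatments are available","Similarly effective treatments are available"
"disease_severity","Chronic life threatening","Chronic with severe invalidity","Chronic with severe invalidity","Other chronic diseases"
"budget_impact","Below 0.01% of annual drug budget","Between 0.05-0.10% of annual drug budget","Between 0.1-0.3% of annual drug budget","Above 0.3% of annual drug budget"
"disease_rarity","Ultrarare disease","Rare disease","Rare disease","Rare disease"
"clinical_evidence","Single arm phase 2 study","Supportive RCT with at least 1 year follow-up","Supportive RCT and real-world evidence","Supportive RCT with <1 year follow-up"
"household_burden","Burden on patients or caregivers > direct medical cost","Significant burden on patients or caregivers","Significant burden on patients or caregivers","No evidence on household burden"
"indication_uniqueness","One unique orphan indication","One unique orphan indication","Two orphan indications","Non-orphan indications"
"patient_age","Pediatrics (0-16 years)","Young adults (17-30 years)","Middle aged adults (31-65 years)","Old age adults (above 65 years)"
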