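name: emirates_orphan_mcda
criteria:
- id: cost_effectiveness
  name: Cost-effectiveness (Cost/QALY)
  category: economics-related
  rank: 1
  weight_increase: 25.0
  levels:
  - label: Below 1x GDP per capita
    score: 100.0
  - label: Between 1-2x GDP per capita
    score: 80.0
  - label: Between 2-3x GDP per capita
    score: 60.0
  - label: Between 3-5x GDP per capita
    score: 40.0
  - label: Between 5-10x GDP per capita
    score: 20.0
  - label: Above 10x GDP per capita
    score: 0.0
- id: magnitude_of_health_gain
  name: Magnitude of health gain
  category: treatment-related
  rank: 2
  weight_increase: 40.0
  levels:
  - label: Curative therapy (no need for further therapy)
    score: 100.0
  - label: Long-term remission on therapy (therapy until progression)
    score: 75.0
  - label: Duration of benefits is 1-5 years
    score: 50.0
  - label: Symptom relief or short-term benefit
    score: 0.0
- id: therapeutic_alternative
  name: Therapeutic alternative (unmet need)
  category: disease-related
  rank: 3
  weight_increase: 30.0
  levels:
  - label: No effective treatments are available
    score: 100.0
  - label: Less effective treatments are available
    score: 50.0
  - label: Similarly effective treatments are available
    score: 0.0
- id: disease_severity
  name: Disease severity (expected QALYs without therapy)
  category: disease-related
  rank: 4
  weight_increase: 40.0
  levels:
  - label: Chronic life threatening
    score: 100.0
  - label: Acute life threatening
    score: 80.0
  - label: Chronic with severe invalidity
    score: 60.0
  - label: Acute with severe invalidity
    score: 40.0
  - label: Other chronic diseases
    score: 20.0
  - label: Other acute diseases
    score: 0.0
- id: budget_impact
  name: Budget impact
  category: economics-related
  rank: 5
  weight_increase: 40.0
  levels:
  - label: Below 0.01% of annual drug budget
    score: 100.0
  - label: Between 0.01-0.05% of annual drug budget
    score: 75.0
  - label: Between 0.05-0.10% of annual drug budget
    score: 50.0
  - label: Between 0.1-0.3% of annual drug budget
    score: 25.0
  - label: Above 0.3% of annual drug budget
    score: 0.0
- id: disease_rarity
  name: Disease rarity
  category: disease-related
  rank: 6
  weight_increase: 0.0
  levels:
  - label: Ultrarare disease
    score: 100.0
  - label: Rare disease
    score: 50.0
  - label: Rare subgroup of a common disease
    score: 0.0
- id: clinical_evidence
  name: Credibility and robustness of clinical evidence
  category: treatment-related
  rank: 6
  weight_increase: 25.0
  levels:
  - label: Supportive RCT and real-world evidence
    score: 100.0
  - label: Supportive RCT with at least 1 year follow-up
    score: 75.0
  - label: Supportive RCT with <1 year follow-up
    score: 50.0
  - label: Single arm phase 2 study
    score: 0.0
- id: household_burden
  name: Burden on households (patients & caregivers)
  category: disease-related
  rank: 7
  weight_increase: 40.0
  levels:
  - label: Burden on patients or caregivers > direct medical cost
    score: 100.0
  - label: Significant burden on patients or caregivers
    score: 75.0
  - label: No evidence on household burden
    score: 0.0
- id: indication_uniqueness
  name: Indication uniqueness
  category: treatment-related
  rank: 8
  weight_increase: 25.0
  levels:
  - label: One unique orphan indication
    score: 100.0
  - label: Two orphan indications
    score: 50.0
  - label: More than two orphan indications
    score: 25.0
  - label: Non-orphan indications
    score: 0.0
- id: patient_age
  name: Average age of patients in clinical trials or real-world
  category: treatment-related
  rank: 9
  weight_increase: 25.0
  levels:
  - label: Pediatrics (0-16 years)
    score: 100.0
  - label: Young adults (17-30 years)
    score: 60.0
  - label: Middle aged adults (31-65 years)
    score: 30.0
  - label: Old age adults (above 65 years)
    score: 0.0
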