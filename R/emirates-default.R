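#' The Emirates ten-criterion orphan-drug MCDA set
#'
#' Builds the value framework agreed by the eleven-expert UAE consensus panel:
#' ten criteria spanning disease-related, economics-related and
#' treatment-related categories, each with a categorical scoring function
#' (fractions from 100% down to 0%), the importance ranking (disease rarity
#' and clinical evidence tied at rank 6), and the SMART & Swing weight
#' increases from which the normalized weights are derived. Cost-effectiveness
#' carries the largest share (25.1%) and patient age the smallest (2.6%); the
#' three orphan-specific criteria (rarity, indication uniqueness, therapeutic
#' alternative) jointly hold 23.1% of the weight.
#'
#' Rarity classes follow the NICE convention: rare = fewer than 5 per 10,000
#' population, ultrarare = about 1 per 50,000. The thresholds are
#' documentation only — the assessor selects the class, the tool does not
#' derive it from prevalence data.
#'
#' @return A [criteria_set()] with derived normalized weights cached.
#' @examples
#' cs <- emirates_default()
#' round(criteria_weights(cs, percent = TRUE), 1)
#' @export
emirates_default <- function() {
  criteria <- list(
    criterion(
      "cost_effectiveness", "Cost-effectiveness (Cost/QALY)", "economics-related",
      c("Below 1x GDP per capita" = 1,
        "Between 1-2x GDP per capita" = 0.8,
        "Between 2-3x GDP per capita" = 0.6,
        "Between 3-5x GDP per capita" = 0.4,
        "Between 5-10x GDP per capita" = 0.2,
        "Above 10x GDP per capita" = 0)
    ),
    criterion(
      "magnitude_of_health_gain", "Magnitude of health gain", "treatment-related",
      c("Curative therapy (no need for further therapy)" = 1,
        "Long-term remission on therapy (therapy until progression)" = 0.75,
        "Duration of benefits is 1-5 years" = 0.5,
        "Symptom relief or short-term benefit" = 0)
    ),
    criterion(
      "therapeutic_alternative", "Therapeutic alternative (unmet need)", "disease-related",
      c("No effective treatments are available" = 1,
        "Less effective treatments are available" = 0.5,
        "Similarly effective treatments are available" = 0)
    ),
    criterion(
      "disease_severity", "Disease severity (expected QALYs without therapy)",
      "disease-related",
      c("Chronic life threatening" = 1,
        "Acute life threatening" = 0.8,
        "Chronic with severe invalidity" = 0.6,
        "Acute with severe invalidity" = 0.4,
        "Other chronic diseases" = 0.2,
        "Other acute diseases" = 0)
    ),
    criterion(
      "budget_impact", "Budget impact", "economics-related",
      c("Below 0.01% of annual drug budget" = 1,
        "Between 0.01-0.05% of annual drug budget" = 0.75,
        "Between 0.05-0.10% of annual drug budget" = 0.5,
        "Between 0.1-0.3% of annual drug budget" = 0.25,
        "Above 0.3% of annual drug budget" = 0)
    ),
    criterion(
      "disease_rarity", "Disease rarity", "disease-related",
      c("Ultrarare disease" = 1,
        "Rare disease" = 0.5,
        "Rare subgroup of a common disease" = 0)
    ),
    criterion(
      "clinical_evidence", "Credibility and robustness of clinical evidence",
      "treatment-related",
      c("Supportive RCT and real-world evidence" = 1,
        "Supportive RCT with at least 1 year follow-up" = 0.75,
        "Supportive RCT with <1 year follow-up" = 0.5,
        "Single arm phase 2 study" = 0)
    ),
    criterion(
      "household_burden", "Burden on households (patients & caregivers)",
      "disease-related",
      c("Burden on patients or caregivers > direct medical cost" = 1,
        "Significant burden on patients or caregivers" = 0.75,
        "No evidence on household burden" = 0)
    ),
    criterion(
      "indication_uniqueness", "Indication uniqueness", "treatment-related",
      c("One unique orphan indication" = 1,
        "Two orphan indications" = 0.5,
        "More than two orphan indications" = 0.25,
        "Non-orphan indications" = 0)
    ),
    criterion(
      "patient_age", "Average age of patients in clinical trials or real-world",
      "treatment-related",
      c("Pediatrics (0-16 years)" = 1,
        "Young adults (17-30 years)" = 0.6,
        "Middle aged adults (31-65 years)" = 0.3,
        "Old age adults (above 65 years)" = 0)
    )
  )

  ranking <- list(
    "cost_effectiveness",
    "magnitude_of_health_gain",
    "therapeutic_alternative",
    "disease_severity",
    "budget_impact",
    c("disease_rarity", "clinical_evidence"),
    "household_burden",
    "indication_uniqueness",
    "patient_age"
  )

  # percent increase over the next-ranked criterion; 0 marks the within-tie
  # entry at rank 6; the lowest-ranked entry (patient_age) is carried unused
  increases <- c(
    cost_effectiveness       = 25,
    magnitude_of_health_gain = 40,
    therapeutic_alternative  = 30,
    disease_severity         = 40,
    budget_impact            = 40,
    disease_rarity           = 0,
    clinical_evidence        = 25,
    household_burden         = 40,
    indication_uniqueness    = 25,
    patient_age              = 25
  )

  criteria_set(criteria, ranking, increases, name = "emirates_orphan_mcda")
}
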