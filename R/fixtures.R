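#' Generate synthetic consensus-session vote panels
#'
#' Emulates a structured consensus-building session of the kind that produced
#' the embedded criteria set: each participant submits a full ranking of the
#' criteria, a weight-increase percentage per criterion, and a desired
#' criteria count. The consensus values are taken from the criteria set
#' itself (its ranking, increase column, and criteria count); `dispersion`
#' controls how far individual participants stray from consensus.
#'
#' With `dispersion = 0` every participant votes the consensus exactly —
#' including tied ranks, which participants may express directly — so the
#' aggregation pipeline recovers the set's own ranking and weights. With
#' `dispersion > 0`, rank votes are strict permutations obtained by
#' perturbing the consensus positions with Gaussian noise and re-ranking, and
#' increase votes are consensus values plus truncated Gaussian noise.
#'
#' @param cs A `criteria_set` providing the consensus ranking and increases.
#' @param n_participants Number of panel members (the original session had 11).
#' @param dispersion Non-negative noise scale; 0 gives identical participants.
#' @param seed Optional integer seed; a fixed seed gives identical panels.
#' @return List with `rank_votes` and `increase_votes` (tibbles: `participant`
#'   column plus one column per criterion) and `count_votes` (integer vector).
#' @export
synthetic_votes <- function(cs, n_participants = 11, dispersion = 0,
                            seed = NULL) {
  stopifnot(n_participants >= 1, dispersion >= 0)
  if (!is.null(seed)) set.seed(seed)
  ids <- criterion_ids(cs)
  consensus_pos <- rank_positions(cs$ranking)[ids]
  consensus_inc <- cs$increases[ids]
  n_crit <- length(ids)

  rank_rows <- matrix(NA_real_, n_participants, n_crit,
                      dimnames = list(NULL, ids))
  inc_rows <- matrix(NA_real_, n_participants, n_crit,
                     dimnames = list(NULL, ids))
  counts <- integer(n_participants)
  for (p in seq_len(n_participants)) {
    if (dispersion == 0) {
      rank_rows[p, ] <- consensus_pos
      inc_rows[p, ] <- consensus_inc
      counts[p] <- n_crit
    } else {
      noisy <- consensus_pos + stats::rnorm(n_crit, sd = dispersion)
      rank_rows[p, ] <- rank(noisy, ties.method = "first")
      inc_rows[p, ] <- pmax(0, consensus_inc + stats::rnorm(n_crit, sd = 10 * dispersion))
      counts[p] <- max(1L, min(n_crit, n_crit +
                                 as.integer(round(stats::rnorm(1, sd = dispersion)))))
    }
  }
  participant <- sprintf("p%02d", seq_len(n_participants))
  list(
    rank_votes = tibble::as_tibble(cbind(data.frame(participant = participant),
                                         as.data.frame(rank_rows))),
    increase_votes = tibble::as_tibble(cbind(data.frame(participant = participant),
                                             as.data.frame(inc_rows))),
    count_votes = counts
  )
}

#' Four archetype drug profiles for the default criteria set
#'
#' Reconstructed validation cases mirroring the four therapy archetypes used
#' to exercise the original tool: a genetic curative therapy for an ultrarare
#' disease, a highly effective chronic therapy for a rare disease, a
#' high-quality symptomatic chronic therapy, and a lower-quality symptomatic
#' chronic therapy. The original per-criterion selections were never
#' published; these profiles are synthetic reconstructions chosen so that the
#' two disease-modifying therapies score above 50 points, the two symptomatic
#' ones below 50, and the rank order runs curative > highly-effective >
#' high-quality-symptomatic > low-quality-symptomatic. Their exact totals are
#' a property of this reconstruction, not of the original test cases.
#'
#' @return Named list of four complete [drug_profile()]s over
#'   [emirates_default()].
#' @export
archetype_profiles <- function() {
  cs <- emirates_default()
  profiles <- list(
    drug_profile("genetic_curative", c(
      cost_effectiveness       = "Between 5-10x GDP per capita",
      magnitude_of_health_gain = "Curative therapy (no need for further therapy)",
      therapeutic_alternative  = "No effective treatments are available",
      disease_severity         = "Chronic life threatening",
      budget_impact            = "Below 0.01% of annual drug budget",
      disease_rarity           = "Ultrarare disease",
      clinical_evidence        = "Single arm phase 2 study",
      household_burden         = "Burden on patients or caregivers > direct medical cost",
      indication_uniqueness    = "One unique orphan indication",
      patient_age              = "Pediatrics (0-16 years)"
    ), cs),
    drug_profile("highly_effective_chronic", c(
      cost_effectiveness       = "Between 2-3x GDP per capita",
      magnitude_of_health_gain = "Long-term remission on therapy (therapy until progression)",
      therapeutic_alternative  = "Less effective treatments are available",
      disease_severity         = "Chronic with severe invalidity",
      budget_impact            = "Between 0.05-0.10% of annual drug budget",
      disease_rarity           = "Rare disease",
      clinical_evidence        = "Supportive RCT with at least 1 year follow-up",
      household_burden         = "Significant burden on patients or caregivers",
      indication_uniqueness    = "One unique orphan indication",
      patient_age              = "Young adults (17-30 years)"
    ), cs),
    drug_profile("high_quality_symptomatic", c(
      cost_effectiveness       = "Between 3-5x GDP per capita",
      magnitude_of_health_gain = "Symptom relief or short-term benefit",
      therapeutic_alternative  = "Less effective treatments are available",
      disease_severity         = "Chronic with severe invalidity",
      budget_impact            = "Between 0.1-0.3% of annual drug budget",
      disease_rarity           = "Rare disease",
      clinical_evidence        = "Supportive RCT and real-world evidence",
      household_burden         = "Significant burden on patients or caregivers",
      indication_uniqueness    = "Two orphan indications",
      patient_age              = "Middle aged adults (31-65 years)"
    ), cs),
    drug_profile("low_quality_symptomatic", c(
      cost_effectiveness       = "Between 5-10x GDP per capita",
      magnitude_of_health_gain = "Symptom relief or short-term benefit",
      therapeutic_alternative  = "Similarly effective treatments are available",
      disease_severity         = "Other chronic diseases",
      budget_impact            = "Above 0.3% of annual drug budget",
      disease_rarity           = "Rare disease",
      clinical_evidence        = "Supportive RCT with <1 year follow-up",
      household_burden         = "No evidence on household burden",
      indication_uniqueness    = "Non-orphan indications",
      patient_age              = "Old age adults (above 65 years)"
    ), cs)
  )
  stats::setNames(profiles, vapply(profiles, `[[`, character(1), "drug_name"))
}
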