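# Independent brute-force oracle for the swing-weight chain: each criterion's
# unnormalized weight is computed directly as base times the product of
# (1 + step/100) over every rank group strictly below its own (a tied group's
# step is the maximum of its members' increase entries). This is a direct
# closed-form product, independent of the iterative chain in swing_weights().
oracle_swing <- function(ranking, increases, base = 1) {
  n_groups <- length(ranking)
  steps <- vapply(ranking, function(g) max(increases[g]), numeric(1))
  out <- numeric(0)
  for (g in seq_len(n_groups)) {
    factors <- if (g < n_groups) 1 + steps[seq(g, n_groups - 1L)] / 100 else numeric(0)
    w <- base * prod(factors)
    out <- c(out, stats::setNames(rep(w, length(ranking[[g]])), ranking[[g]]))
  }
  out
}

# random small elicitation instance: <= max_criteria criteria, random tie
# structure and non-negative increases
random_instance <- function(max_criteria = 8) {
  n <- sample(2:max_criteria, 1)
  ids <- paste0("c", seq_len(n))
  groups <- list()
  i <- 1L
  while (i <= n) {
    size <- min(sample(1:2, 1), n - i + 1L)
    groups[[length(groups) + 1L]] <- ids[i:(i + size - 1L)]
    i <- i + size
  }
  increases <- stats::setNames(sample(c(0, 5, 10, 25, 30, 40, 100), n,
                                      replace = TRUE), ids)
  # mark within-tie entries with 0 for all but one member of each tied group
  for (g in groups) {
    if (length(g) > 1L) increases[g[-1]] <- 0
  }
  list(ranking = groups, increases = increases)
}

# small three-criterion set used by unit tests
toy_criteria_set <- function() {
  criteria_set(
    criteria = list(
      criterion("efficacy", "Efficacy", "treatment-related",
                c("High" = 1, "Moderate" = 0.5, "None" = 0)),
      criterion("safety", "Safety", "treatment-related",
                c("Favourable" = 1, "Acceptable" = 0.6, "Poor" = 0)),
      criterion("cost", "Cost", "economics-related",
                c("Low" = 1, "Medium" = 0.5, "High" = 0))
    ),
    ranking = list("efficacy", "safety", "cost"),
    increases = c(efficacy = 50, safety = 20, cost = 0),
    name = "toy"
  )
}

emirates_printed_weights <- c(
  cost_effectiveness = 25.1, magnitude_of_health_gain = 20.1,
  therapeutic_alternative = 14.3, disease_severity = 11.0,
  budget_impact = 7.9, disease_rarity = 5.6, clinical_evidence = 5.6,
  household_burden = 4.5, indication_uniqueness = 3.2, patient_age = 2.6
)
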