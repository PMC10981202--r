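test_that("vote averaging is the plain arithmetic mean", {
  expect_equal(average_votes(c(25, 25, 25)), 25)
  expect_equal(average_votes(c(20, 30)), 25)
  expect_equal(average_votes(c(0, 0, 75)), 25)
  expect_error(average_votes(numeric(0)), "no votes")
})

test_that("rank aggregation orders by mean rank and groups exact ties", {
  # a single participant's ranking is returned verbatim
  one <- data.frame(A = 2, B = 1, C = 3)
  expect_equal(aggregate_ranking(one), list("B", "A", "C"))

  # mean ranks {A: 1, B: 2.5, C: 2.5} give a tied group, re-indexed from 1
  two <- data.frame(A = c(1, 1), B = c(2, 3), C = c(3, 2))
  expect_equal(aggregate_ranking(two), list("A", c("B", "C")))

  # near-ties beyond the tolerance stay separate
  close <- data.frame(A = c(1, 1, 1), B = c(2, 2, 3), C = c(3, 3, 2))
  expect_equal(aggregate_ranking(close), list("A", "B", "C"))

  # invalid panels are rejected with the participant named
  miss <- data.frame(participant = c("p1", "p2"), A = c(1, NA), B = c(2, 2))
  expect_error(aggregate_ranking(miss), "participant 'p2' has missing ranks")
})

test_that("criteria-count selection is plurality with ties going to the larger count", {
  expect_equal(select_criteria_count(c(10, 10, 10, 10, 10, 10, 8, 8, 12, 9, 11)), 10)
  expect_equal(select_criteria_count(c(8, 8, 10)), 8)
  expect_equal(select_criteria_count(c(8, 10)), 10)
  expect_error(select_criteria_count(integer(0)), "no votes")
})

test_that("truncation drops whole bottom rank groups and refuses to split ties", {
  # twelve candidates; the two lowest-ranked are excluded when keeping ten
  twelve <- as.list(c(
    "cost_effectiveness", "magnitude_of_health_gain", "therapeutic_alternative",
    "disease_severity", "budget_impact", "disease_rarity", "clinical_evidence",
    "household_burden", "indication_uniqueness", "patient_age",
    "advancement_of_technology", "manufacturing_complexity"
  ))
  kept <- truncate_to_count(twelve, 10)
  ids <- unlist(kept)
  expect_length(ids, 10)
  expect_false("advancement_of_technology" %in% ids)
  expect_false("manufacturing_complexity" %in% ids)

  expect_identical(truncate_to_count(twelve, 12), twelve)
  expect_error(truncate_to_count(list("A", c("B", "C")), 2),
               "ambiguous truncation at tied rank")
  expect_error(truncate_to_count(list("A"), 5), "more criteria than are ranked")
})

test_that("the swing chain reproduces the elicited multiplicative weights", {
  cs <- emirates_default()
  raw <- swing_weights(criteria_ranking(cs), cs$increases)
  # frozen chain from lowest to highest rank, base 1
  chain <- c(1, 1.25, 1.75, 2.1875, 2.1875, 3.0625, 4.2875, 5.57375,
             7.80325, 9.7540625)
  lowest_first <- rev(unlist(criteria_ranking(cs)))
  expect_equal(unname(raw[lowest_first]), chain, tolerance = 1e-12)

  # degenerate cases
  eq <- swing_weights(list("A", "B", "C"), c(A = 0, B = 0, C = 0), base = 2)
  expect_equal(unname(eq), c(2, 2, 2))
  two <- swing_weights(list("top", "bottom"), c(top = 100, bottom = 0))
  expect_equal(two, c(top = 2, bottom = 1))
  expect_error(swing_weights(list("A", "B"), c(A = -5, B = 0)), "negative")
  expect_error(swing_weights(list("A", "B"), c(A = 10)), "missing")
})

test_that("normalization rescales to unit sum and rejects degenerate input", {
  expect_equal(normalize_weights(c(A = 2, B = 2)), c(A = 0.5, B = 0.5))
  expect_equal(normalize_weights(c(A = 1, B = 0.5, C = 0.5)),
               c(A = 0.5, B = 0.25, C = 0.25))
  expect_error(normalize_weights(c(A = 0, B = 0)), "degenerate weights")
  expect_error(normalize_weights(c(A = -1, B = 2)), "negative")
})

test_that("normalized swing weights are invariant to the base", {
  set.seed(42)
  cs <- emirates_default()
  ref <- normalize_weights(swing_weights(criteria_ranking(cs), cs$increases, base = 1))
  for (b in stats::runif(20, min = 1e-6, max = 1e6)) {
    w <- normalize_weights(swing_weights(criteria_ranking(cs), cs$increases, base = b))
    expect_equal(w, ref, tolerance = 1e-12)
  }
})

test_that("raising one group's increase never hurts criteria at or above it", {
  set.seed(7)
  for (rep in 1:25) {
    inst <- random_instance()
    before <- normalize_weights(swing_weights(inst$ranking, inst$increases))
    # perturb one non-lowest group's step upward
    g <- sample(seq_len(max(1, length(inst$ranking) - 1L)), 1)
    bumped <- inst$increases
    lead <- inst$ranking[[g]][which.max(bumped[inst$ranking[[g]]])]
    bumped[lead] <- bumped[lead] + 20
    after <- normalize_weights(swing_weights(inst$ranking, bumped))
    above <- unlist(inst$ranking[seq_len(g)])
    below <- unlist(inst$ranking[-seq_len(g)])
    expect_true(all(after[above] >= before[above] - 1e-12))
    if (length(below)) expect_true(all(after[below] <= before[below] + 1e-12))
  }
})

test_that("the iterative chain agrees with the brute-force product oracle", {
  set.seed(11)
  for (rep in 1:50) {
    inst <- random_instance(max_criteria = 8)
    base <- stats::runif(1, 0.1, 10)
    got <- swing_weights(inst$ranking, inst$increases, base = base)
    want <- oracle_swing(inst$ranking, inst$increases, base = base)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})

test_that("elicit_weights chains rank aggregation, averaging and normalization", {
  rv <- data.frame(A = c(1, 1), B = c(2, 2), C = c(3, 3))
  iv <- data.frame(A = c(40, 60), B = c(100, 100), C = c(0, 0))
  fit <- elicit_weights(rv, iv)
  expect_equal(fit$ranking, list("A", "B", "C"))
  expect_equal(unname(fit$increases), c(50, 100, 0))
  expect_equal(unname(fit$raw), c(3, 2, 1))
  expect_equal(unname(fit$weights), c(3, 2, 1) / 6)
})
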