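test_that("level_score returns the printed fraction for an outcome", {
  cs <- emirates_default()
  expect_equal(level_score(cs, "therapeutic_alternative",
                           "No effective treatments are available"), 1)
  expect_equal(level_score(cs, "budget_impact",
                           "Between 0.1-0.3% of annual drug budget"), 0.25)
  expect_equal(level_score(cs, "magnitude_of_health_gain",
                           "Symptom relief or short-term benefit"), 0)
  expect_error(level_score(cs, "budget_impact", "nope"), "valid labels")
  expect_error(level_score(cs, "nope", "x"), "unknown criterion")
})

test_that("the additive model attains the score bounds at the extreme profiles", {
  cs <- emirates_default()
  expect_equal(score_drug(uniform_profile(cs, "best"), cs)$total, 100)
  expect_equal(score_drug(uniform_profile(cs, "worst"), cs)$total, 0)
})

test_that("a single non-worst selection contributes weight x fraction x 100", {
  cs <- emirates_default()
  prof <- uniform_profile(cs, "worst", drug_name = "ce_only")
  prof$selections[["cost_effectiveness"]] <- "Between 1-2x GDP per capita"
  sb <- score_drug(prof, cs)
  expect_equal(round(sb$total, 1), 20.1)  # 0.8 x 25.103 points
  expect_equal(sb$total,
               100 * 0.8 * criteria_weights(cs)[["cost_effectiveness"]])
})

test_that("breakdown rows follow rank order and reconcile with the total", {
  cs <- emirates_default()
  sb <- score_drug(archetype_profiles()$genetic_curative, cs)
  expect_equal(sb$breakdown$criterion_id, unlist(criteria_ranking(cs)))
  expect_lt(abs(sb$total - sum(sb$breakdown$contribution)), 1e-9)
  expect_true(sb$total >= 0 && sb$total <= 100)
  # a criterion held at its best level contributes its full weight in points
  best_rows <- sb$breakdown[sb$breakdown$fraction == 1, ]
  expect_equal(best_rows$contribution, 100 * best_rows$weight)
})

test_that("improving one selection strictly increases the total", {
  set.seed(3)
  cs <- emirates_default()
  for (rep in 1:10) {
    sel <- vapply(cs$criteria, function(cr) sample(cr$levels$label, 1), character(1))
    prof <- drug_profile("random", sel, cs)
    base_total <- score_drug(prof, cs)$total
    id <- sample(criterion_ids(cs), 1)
    lv <- get_criterion(cs, id)$levels
    current <- match(prof$selections[[id]], lv$label)
    if (current == 1L) next  # already at the best level
    better <- prof
    better$selections[[id]] <- lv$label[current - 1L]
    expect_gt(score_drug(better, cs)$total, base_total)
  }
})

test_that("comparisons are invariant to input order and reject duplicates", {
  cs <- emirates_default()
  profs <- archetype_profiles()
  cmp <- compare_drugs(profs, cs)
  expect_equal(unname(vapply(cmp, `[[`, character(1), "drug_name")),
               c("genetic_curative", "highly_effective_chronic",
                 "high_quality_symptomatic", "low_quality_symptomatic"))
  expect_equal(unname(vapply(cmp, `[[`, numeric(1), "rank")), 1:4)

  cmp_perm <- compare_drugs(profs[c(3, 1, 4, 2)], cs)
  expect_equal(comparison_totals(cmp_perm), comparison_totals(cmp))

  single <- compare_drugs(list(profs[[1]]), cs)
  expect_equal(single[[1]]$rank, 1)

  expect_error(compare_drugs(list(profs[[1]], profs[[1]]), cs),
               "duplicate drug names")
})

test_that("tied totals share a rank", {
  cs <- toy_criteria_set()
  a <- drug_profile("a", c(efficacy = "High", safety = "Poor", cost = "High"), cs)
  b <- drug_profile("b", c(efficacy = "High", safety = "Poor", cost = "High"), cs)
  best <- drug_profile("top", c(efficacy = "High", safety = "Favourable",
                                cost = "Low"), cs)
  cmp <- compare_drugs(list(a, b, best), cs)
  expect_equal(vapply(cmp, `[[`, numeric(1), "rank"), c(1, 2, 2))
})

test_that("the budget-share classifier is total over non-negative shares", {
  expect_equal(classify_budget_share(0.005), "Below 0.01% of annual drug budget")
  expect_equal(classify_budget_share(0.05), "Between 0.05-0.10% of annual drug budget")
  expect_equal(classify_budget_share(0.31), "Above 0.3% of annual drug budget")
  expect_error(classify_budget_share(-0.1), ">= 0")

  cs <- emirates_default()
  set.seed(5)
  shares <- c(0, 0.01, 0.05, 0.10, 0.30, stats::rexp(500, rate = 5))
  labels <- classify_budget_share(shares)
  expect_false(anyNA(labels))
  # every label is a scoreable budget-impact level
  for (l in unique(labels)) {
    expect_silent(level_score(cs, "budget_impact", l))
  }
  # boundaries belong to the interval that starts there
  expect_equal(classify_budget_share(0.01), "Between 0.01-0.05% of annual drug budget")
  expect_equal(classify_budget_share(0.30), "Above 0.3% of annual drug budget")
})

test_that("the ICER classifier is total over positive ratios", {
  expect_equal(classify_icer_multiple(0.5, 1), "Below 1x GDP per capita")
  expect_equal(classify_icer_multiple(2, 1), "Between 2-3x GDP per capita")
  expect_equal(classify_icer_multiple(12, 1), "Above 10x GDP per capita")
  expect_error(classify_icer_multiple(-1, 1), "> 0")
  expect_error(classify_icer_multiple(1, 0), "> 0")

  cs <- emirates_default()
  set.seed(6)
  ratios <- c(1, 2, 3, 5, 10, stats::rexp(500, rate = 0.3) + 1e-9)
  labels <- classify_icer_multiple(ratios, 1)
  expect_false(anyNA(labels))
  for (l in unique(labels)) {
    expect_silent(level_score(cs, "cost_effectiveness", l))
  }
  expect_equal(classify_icer_multiple(1, 1), "Between 1-2x GDP per capita")
})
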