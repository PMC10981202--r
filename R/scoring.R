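#' Fractional score of an outcome level
#'
#' Looks up a criterion's scoring function: the fraction (1 down to 0)
#' attached to one categorical outcome level.
#'
#' @param cs A `criteria_set`.
#' @param criterion_id Criterion identifier.
#' @param level_label Outcome level label, matched exactly.
#' @return The fraction in \[0, 1\].
#' @examples
#' level_score(emirates_default(), "therapeutic_alternative",
#'             "No effective treatments are available")  # 1
#' @export
level_score <- function(cs, criterion_id, level_label) {
  cr <- get_criterion(cs, criterion_id)
  i <- match(level_label, cr$levels$label)
  if (is.na(i)) {
    stop(sprintf("unknown level '%s' for criterion '%s'; valid labels: %s",
                 level_label, criterion_id,
                 paste(sprintf("'%s'", cr$levels$label), collapse = ", ")),
         call. = FALSE)
  }
  cr$levels$fraction[i]
}

#' Score a drug profile on the 0-100 scale
#'
#' The additive value model: total = 100 * sum over criteria of
#' (normalized weight x selected level fraction). Per-criterion contributions
#' are kept at full precision and summed without intermediate rounding; the
#' one-decimal presentation is a reporting concern.
#'
#' @param profile A [drug_profile()], complete for `cs`.
#' @param cs A `criteria_set` with derived weights.
#' @return A `score_breakdown`: list with `drug_name`, `breakdown` (a tibble
#'   with one row per criterion in rank order: id, selected level, fraction,
#'   weight, contribution in points) and `total` in \[0, 100\].
#' @examples
#' cs <- emirates_default()
#' score_drug(uniform_profile(cs, "best"), cs)$total  # 100
#' @export
score_drug <- function(profile, cs) {
  if (is.null(cs$weights)) stop("criteria set has no derived weights", call. = FALSE)
  check_profile(profile, cs)
  ids <- names(rank_positions(cs$ranking))  # rank order
  fraction <- vapply(ids, function(id) level_score(cs, id, profile$selections[[id]]),
                     numeric(1))
  weight <- cs$weights[ids]
  breakdown <- tibble::tibble(
    criterion_id = ids,
    level = unname(profile$selections[ids]),
    fraction = unname(fraction),
    weight = unname(weight),
    contribution = unname(100 * weight * fraction)
  )
  structure(
    list(drug_name = profile$drug_name, breakdown = breakdown,
         total = sum(breakdown$contribution)),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, digits = 1, ...) {
  cat(sprintf("<score_breakdown> %s: %.*f points\n", x$drug_name, digits, x$total))
  b <- x$breakdown
  for (i in seq_len(nrow(b))) {
    cat(sprintf("  %-28s %5.1f%% x %4.0f%% = %5.*f  (%s)\n",
                b$criterion_id[i], 100 * b$weight[i], 100 * b$fraction[i],
                digits, b$contribution[i], b$level[i]))
  }
  invisible(x)
}

#' Compare several drug profiles under one criteria set
#'
#' Scores each profile independently (input order never affects totals) and
#' orders the breakdowns by descending total; equal totals share a rank.
#' Any number of drugs is accepted.
#'
#' @param profiles List of [drug_profile()]s with unique drug names.
#' @param cs A `criteria_set`.
#' @return A `drug_comparison`: list of `score_breakdown`s sorted by total
#'   descending, each carrying a `rank` element.
#' @export
compare_drugs <- function(profiles, cs) {
  if (inherits(profiles, "drug_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L)
  nms <- vapply(profiles, function(p) p$drug_name, character(1))
  if (anyDuplicated(nms)) {
    stop("duplicate drug names: ", paste(unique(nms[duplicated(nms)]), collapse = ", "),
         call. = FALSE)
  }
  scored <- lapply(profiles, score_drug, cs = cs)
  totals <- vapply(scored, `[[`, numeric(1), "total")
  ord <- order(-totals)  # stable: equal totals keep input order
  scored <- scored[ord]
  totals <- totals[ord]
  ranks <- match(totals, unique(totals))  # equal totals share one rank
  for (i in seq_along(scored)) scored[[i]]$rank <- ranks[i]
  structure(scored, class = "drug_comparison")
}

#' @export
print.drug_comparison <- function(x, digits = 1, ...) {
  cat(sprintf("<drug_comparison> %d drugs\n", length(x)))
  for (b in x) {
    cat(sprintf("  %d. %-24s %.*f\n", b$rank, b$drug_name, digits, b$total))
  }
  invisible(x)
}

#' Totals of a drug comparison
#' @param comparison A `drug_comparison`.
#' @return Named numeric vector of totals, best first.
#' @export
comparison_totals <- function(comparison) {
  stats::setNames(vapply(comparison, `[[`, numeric(1), "total"),
                  vapply(comparison, `[[`, character(1), "drug_name"))
}

budget_share_labels <- c(
  "Below 0.01% of annual drug budget",
  "Between 0.01-0.05% of annual drug budget",
  "Between 0.05-0.10% of annual drug budget",
  "Between 0.1-0.3% of annual drug budget",
  "Above 0.3% of annual drug budget"
)

icer_labels <- c(
  "Below 1x GDP per capita",
  "Between 1-2x GDP per capita",
  "Between 2-3x GDP per capita",
  "Between 3-5x GDP per capita",
  "Between 5-10x GDP per capita",
  "Above 10x GDP per capita"
)

#' Classify a budget share into the budget-impact level
#'
#' Maps a numeric share of the annual drug budget (in percent) to the
#' categorical budget-impact level. The printed category bounds overlap at
#' the boundaries, so half-open intervals are used, each boundary belonging
#' to the range that starts there: \[0, 0.01), \[0.01, 0.05), \[0.05, 0.10),
#' \[0.10, 0.30), \[0.30, Inf). Every non-negative share maps to exactly one
#' level.
#'
#' @param share_percent Budget share in percent of the annual drug budget
#'   (vectorized, all values >= 0).
#' @return Character vector of level labels.
#' @examples
#' classify_budget_share(0.05)  # boundary belongs to the upper range
#' @export
classify_budget_share <- function(share_percent) {
  stopifnot(is.numeric(share_percent))
  if (any(share_percent < 0)) stop("budget share must be >= 0", call. = FALSE)
  budget_share_labels[findInterval(share_percent, c(0.01, 0.05, 0.10, 0.30)) + 1L]
}

#' Classify an ICER as a multiple of GDP per capita
#'
#' Computes icer / gdp_per_capita and maps the ratio to the categorical
#' cost-effectiveness level via half-open intervals \[0, 1), \[1, 2),
#' \[2, 3), \[3, 5), \[5, 10), \[10, Inf) — each boundary belongs to the
#' range that starts there.
#'
#' @param icer Incremental cost-effectiveness ratio, cost per QALY
#'   (vectorized, > 0).
#' @param gdp_per_capita GDP per capita in the same currency (> 0).
#' @return Character vector of level labels.
#' @examples
#' classify_icer_multiple(100000, 50000)  # ratio 2 -> "Between 2-3x GDP per capita"
#' @export
classify_icer_multiple <- function(icer, gdp_per_capita) {
  stopifnot(is.numeric(icer), is.numeric(gdp_per_capita))
  if (any(icer <= 0) || any(gdp_per_capita <= 0)) {
    stop("icer and gdp_per_capita must be > 0", call. = FALSE)
  }
  ratio <- icer / gdp_per_capita
  icer_labels[findInterval(ratio, c(1, 2, 3, 5, 10)) + 1L]
}
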