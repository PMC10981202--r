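#' State the expert expectations for a concordance check
#'
#' The validation procedure compares observed drug scores against three
#' predefined expectations: the side of the 50-point threshold each drug
#' should fall on, the expected rank order, and a minimum spread between the
#' highest and lowest comparator (40 points by default).
#'
#' @param above_50 Character vector of drug names expected to score more than
#'   50 points.
#' @param below_50 Character vector of drug names expected to score less than
#'   50 points.
#' @param expected_order Expected rank order, best first: a character vector,
#'   or a list whose elements are character vectors when a tie is explicitly
#'   expected (undeclared observed ties fail the rank check).
#' @param min_spread Minimum required difference between the highest and
#'   lowest total, in points.
#' @return A `concordance_expectation`.
#' @export
concordance_expectation <- function(above_50 = character(0),
                                    below_50 = character(0),
                                    expected_order,
                                    min_spread = 40) {
  if (!is.list(expected_order)) expected_order <- as.list(expected_order)
  stopifnot(all(vapply(expected_order, is.character, logical(1))),
            is.numeric(min_spread), min_spread >= 0)
  drugs <- unlist(expected_order, use.names = FALSE)
  if (anyDuplicated(drugs)) stop("expected order repeats a drug", call. = FALSE)
  both <- intersect(above_50, below_50)
  if (length(both)) {
    stop("drug expected both above and below 50: ", paste(both, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(above_50 = above_50, below_50 = below_50,
         expected_order = expected_order, min_spread = min_spread),
    class = "concordance_expectation"
  )
}

#' Check scored drugs against predefined expectations
#'
#' Runs the three-part concordance analysis on a set of scored drugs. All
#' comparisons use totals rounded to one decimal (the reporting precision):
#' the threshold check compares each rounded total to 50 (an exact 50.0 is
#' indeterminate and fails either expectation), the rank check compares the
#' observed descending-score order — recomputed from the totals, so the input
#' order of `results` is irrelevant — to the expected order, and the spread
#' check requires max - min of the rounded totals to reach the minimum
#' spread.
#'
#' @param results A `drug_comparison` from [compare_drugs()], a list of
#'   `score_breakdown`s, or a named numeric vector of totals (drug name ->
#'   points) when only externally reported scores are available.
#' @param expectation A [concordance_expectation()] covering exactly the
#'   scored drugs.
#' @return A `concordance_report`: list with `threshold_check` (tibble:
#'   drug, total, expected side, pass), `rank_check` (observed order,
#'   expected order, pass), `spread_check` (observed, threshold, pass) and
#'   `overall` — `TRUE` iff all three checks pass.
#' @examples
#' # the printed validation totals: threshold and rank pass, spread 39.7 < 40
#' @export
check_concordance <- function(results, expectation) {
  stopifnot(inherits(expectation, "concordance_expectation"))
  if (inherits(results, "score_breakdown")) results <- list(results)
  if (is.numeric(results)) {
    if (is.null(names(results))) stop("totals must be named by drug", call. = FALSE)
    totals <- results
    drugs <- names(results)
  } else {
    totals <- vapply(results, `[[`, numeric(1), "total")
    drugs <- vapply(results, `[[`, character(1), "drug_name")
  }
  totals <- round(stats::setNames(unname(totals), drugs), 1)

  expected_drugs <- unlist(expectation$expected_order, use.names = FALSE)
  missing <- setdiff(expected_drugs, drugs)
  if (length(missing)) {
    stop("drug in expectation absent from results: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unexpected <- setdiff(drugs, expected_drugs)
  if (length(unexpected)) {
    stop("scored drug not covered by expectation: ",
         paste(unexpected, collapse = ", "), call. = FALSE)
  }

  side <- function(drug) {
    if (drug %in% expectation$above_50) "above" else
      if (drug %in% expectation$below_50) "below" else "none"
  }
  expected_side <- vapply(drugs, side, character(1))
  observed_side <- ifelse(totals > 50, "above",
                          ifelse(totals < 50, "below", "indeterminate"))
  thr_pass <- expected_side == "none" | (observed_side == expected_side)
  threshold_check <- tibble::tibble(
    drug = drugs, total = unname(totals),
    expected = unname(expected_side), observed = unname(observed_side),
    pass = unname(thr_pass)
  )

  # observed order: groups of drugs tied at one rounded total, best first
  obs_sorted <- sort(totals, decreasing = TRUE)
  observed_order <- lapply(unique(unname(obs_sorted)), function(t) {
    sort(names(obs_sorted)[obs_sorted == t])
  })
  expected_order <- lapply(expectation$expected_order, sort)
  rank_pass <- identical(observed_order, expected_order)
  rank_check <- list(observed = observed_order,
                     expected = expected_order, pass = rank_pass)

  spread <- max(totals) - min(totals)
  spread_check <- list(observed = spread, threshold = expectation$min_spread,
                       pass = spread >= expectation$min_spread)

  structure(
    list(threshold_check = threshold_check, rank_check = rank_check,
         spread_check = spread_check,
         overall = all(thr_pass) && rank_pass && spread_check$pass),
    class = "concordance_report"
  )
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  tc <- x$threshold_check
  cat(sprintf("  threshold (50 points): %s\n",
              if (all(tc$pass)) "PASS" else "FAIL"))
  for (i in seq_len(nrow(tc))) {
    cat(sprintf("    %-24s %5.1f  expected %-5s observed %-13s %s\n",
                tc$drug[i], tc$total[i], tc$expected[i], tc$observed[i],
                if (tc$pass[i]) "pass" else "fail"))
  }
  fmt_order <- function(o) paste(vapply(o, paste, character(1), collapse = " = "),
                                 collapse = " > ")
  cat(sprintf("  rank order: %s\n", if (x$rank_check$pass) "PASS" else "FAIL"))
  cat(sprintf("    observed: %s\n", fmt_order(x$rank_check$observed)))
  cat(sprintf("    expected: %s\n", fmt_order(x$rank_check$expected)))
  cat(sprintf("  spread: %s (observed %.1f, threshold %.1f)\n",
              if (x$spread_check$pass) "PASS" else "FAIL",
              x$spread_check$observed, x$spread_check$threshold))
  cat(sprintf("  overall: %s\n", if (x$overall) "CONCORDANT" else "DISCORDANT"))
  invisible(x)
}
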