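#' Define an evaluation criterion
#'
#' A criterion is a named evaluation axis with an ordered set of categorical
#' outcome levels, each mapped to a fractional score in \[0, 1\] (the
#' criterion's scoring function). Levels are stored in descending order of
#' fraction; the best level of a well-formed criterion scores 1 and the worst
#' scores 0, so a drug profile built from best (worst) levels attains the top
#' (bottom) of the 0-100 scale.
#'
#' @param id Short stable identifier (snake_case slug) used as the key in
#'   rankings, weight maps and drug profiles.
#' @param name Display name shown in reports.
#' @param category One of `"disease-related"`, `"economics-related"`,
#'   `"treatment-related"`.
#' @param levels A data frame with columns `label` (character, unique) and
#'   `fraction` (numeric in \[0, 1\]), or a named numeric vector of fractions
#'   keyed by label. Re-ordered to descending fraction.
#' @return An object of class `mcda_criterion`.
#' @examples
#' rarity <- criterion(
#'   "disease_rarity", "Disease rarity", "disease-related",
#'   c("Ultrarare disease" = 1, "Rare disease" = 0.5,
#'     "Rare subgroup of a common disease" = 0)
#' )
#' rarity
#' @export
criterion <- function(id, name, category, levels) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (is.numeric(levels) && !is.null(names(levels))) {
    levels <- data.frame(label = names(levels), fraction = unname(levels),
                         stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(levels), all(c("label", "fraction") %in% names(levels)))
  levels <- tibble::as_tibble(levels[c("label", "fraction")])
  levels <- levels[order(-levels$fraction), , drop = FALSE]
  structure(
    list(id = id, name = name, category = category, levels = levels),
    class = "mcda_criterion"
  )
}

#' @export
print.mcda_criterion <- function(x, ...) {
  cat(sprintf("<criterion> %s (%s)\n", x$id, x$category))
  cat(sprintf("  %s\n", x$name))
  for (i in seq_len(nrow(x$levels))) {
    cat(sprintf("  %5.1f%%  %s\n", 100 * x$levels$fraction[i], x$levels$label[i]))
  }
  invisible(x)
}

#' Assemble a criteria set
#'
#' Bundles criteria with their importance ranking (ties allowed), the per-step
#' swing weight increases elicited from the consensus panel, and the derived
#' normalized weights. Weights are computed once at construction via
#' [swing_weights()] and [normalize_weights()] and cached in the object.
#'
#' @param criteria A list of [criterion()] objects.
#' @param ranking A list of character vectors: rank groups from most to least
#'   important. Criteria in one group share a rank (e.g. the Emirates set ties
#'   disease rarity with clinical evidence at rank 6).
#' @param increases Named numeric vector: for each criterion id, the stated
#'   percentage weight increase over the next-ranked criterion. Within a tied
#'   group, 0 marks a within-tie entry; the group's step over the group below
#'   is the maximum entry among its members. The lowest-ranked group's entries
#'   are carried but never enter the chain.
#' @param name Optional label for the set.
#' @param check If `TRUE` (default), invariant violations abort construction.
#'   `check = FALSE` builds the object regardless so that
#'   [validate_criteria_set()] can report the violations.
#' @return An object of class `criteria_set` with elements `criteria` (named
#'   list), `ranking`, `increases`, `weights` (normalized, summing to 1) and
#'   `name`.
#' @seealso [emirates_default()] for the embedded ten-criterion Emirates set.
#' @export
criteria_set <- function(criteria, ranking, increases, name = "criteria_set",
                         check = TRUE) {
  stopifnot(is.list(criteria), is.list(ranking), is.numeric(increases))
  names(criteria) <- vapply(criteria, function(cr) cr$id, character(1))
  cs <- structure(
    list(name = name, criteria = criteria, ranking = ranking,
         increases = increases, weights = NULL),
    class = "criteria_set"
  )
  problems <- validate_criteria_set(cs)
  if (check && length(problems)) {
    stop("invalid criteria set:\n", paste("-", problems, collapse = "\n"),
         call. = FALSE)
  }
  if (!length(problems)) {
    cs$weights <- normalize_weights(swing_weights(ranking, increases))
    # weights follow rank order; re-key to criteria list order for stability
    cs$weights <- cs$weights[names(criteria)]
  }
  cs
}

#' Validate a criteria set against its structural invariants
#'
#' Checks level fractions are in \[0, 1\] and unique per criterion, labels are
#' unique, each criterion has at least two levels, and the ranking and
#' increase map cover exactly the criteria list. Violations are returned, not
#' raised, so configuration errors can be reported in bulk.
#'
#' @param cs A `criteria_set` (typically built with `check = FALSE`).
#' @return Character vector of human-readable violation messages; empty when
#'   the set is valid.
#' @examples
#' validate_criteria_set(emirates_default())  # character(0)
#' @export
validate_criteria_set <- function(cs) {
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))

  ids <- names(cs$criteria)
  if (anyDuplicated(ids)) note("duplicate criterion ids: %s",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (cr in cs$criteria) {
    lv <- cr$levels
    if (nrow(lv) < 2L) note("criterion '%s': fewer than 2 levels", cr$id)
    bad <- lv$fraction < 0 | lv$fraction > 1
    if (any(bad)) {
      for (i in which(bad)) {
        note("criterion '%s': level '%s' has fraction %s outside [0, 1]",
             cr$id, lv$label[i], format(lv$fraction[i]))
      }
    }
    if (anyDuplicated(lv$label)) note("criterion '%s': duplicate level labels", cr$id)
    if (anyDuplicated(lv$fraction)) {
      note("criterion '%s': duplicate level fractions", cr$id)
    }
    if (is.unsorted(rev(lv$fraction))) {
      note("criterion '%s': level fractions not in descending order", cr$id)
    }
  }

  ranked <- unlist(cs$ranking, use.names = FALSE)
  if (any(lengths(cs$ranking) == 0L)) note("ranking contains an empty rank group")
  if (anyDuplicated(ranked)) {
    note("ranking lists criterion more than once: %s",
         paste(unique(ranked[duplicated(ranked)]), collapse = ", "))
  }
  missing_rank <- setdiff(ids, ranked)
  if (length(missing_rank)) {
    note("ranking does not cover criterion: %s", paste(missing_rank, collapse = ", "))
  }
  extra_rank <- setdiff(ranked, ids)
  if (length(extra_rank)) {
    note("ranking refers to unknown criterion: %s", paste(extra_rank, collapse = ", "))
  }

  missing_inc <- setdiff(ids, names(cs$increases))
  if (length(missing_inc)) {
    note("weight increase missing for criterion: %s",
         paste(missing_inc, collapse = ", "))
  }
  if (any(cs$increases < 0, na.rm = TRUE)) {
    neg <- names(cs$increases)[cs$increases < 0]
    note("negative weight increase for criterion: %s", paste(neg, collapse = ", "))
  }

  if (!is.null(cs$weights)) {
    if (length(setdiff(ids, names(cs$weights))) ||
        length(setdiff(names(cs$weights), ids))) {
      note("weight vector does not cover exactly the criteria list")
    } else if (abs(sum(cs$weights) - 1) > 1e-12 || any(cs$weights < 0)) {
      note("weights must be non-negative and sum to 1")
    }
  }
  problems
}

#' @export
print.criteria_set <- function(x, ...) {
  cat(sprintf("<criteria_set> %s: %d criteria\n", x$name, length(x$criteria)))
  rk <- rank_positions(x$ranking)
  ord <- names(sort(rk))
  for (id in ord) {
    w <- if (is.null(x$weights)) NA_real_ else x$weights[[id]]
    cat(sprintf("  %2d  %-28s %s\n", rk[[id]], id,
                if (is.na(w)) "" else sprintf("%5.1f%%", 100 * w)))
  }
  invisible(x)
}

#' Criterion identifiers of a criteria set
#' @param cs A `criteria_set`.
#' @return Character vector of criterion ids in definition order.
#' @export
criterion_ids <- function(cs) names(cs$criteria)

#' Normalized criterion weights
#' @param cs A `criteria_set`.
#' @param percent Return weights as percentages instead of fractions.
#' @return Named numeric vector; fractions sum to 1.
#' @export
criteria_weights <- function(cs, percent = FALSE) {
  if (is.null(cs$weights)) stop("criteria set has no derived weights", call. = FALSE)
  if (percent) 100 * cs$weights else cs$weights
}

#' Importance ranking of a criteria set
#' @param cs A `criteria_set`.
#' @return List of character vectors (rank groups, best first).
#' @export
criteria_ranking <- function(cs) cs$ranking

#' Look up one criterion by id
#' @param cs A `criteria_set`.
#' @param id Criterion identifier.
#' @return The `mcda_criterion` object.
#' @export
get_criterion <- function(cs, id) {
  cr <- cs$criteria[[id]]
  if (is.null(cr)) {
    stop(sprintf("unknown criterion '%s'; available: %s", id,
                 paste(names(cs$criteria), collapse = ", ")), call. = FALSE)
  }
  cr
}

# rank position of every criterion id, from a list of rank groups
rank_positions <- function(ranking) {
  pos <- rep.int(seq_along(ranking), lengths(ranking))
  stats::setNames(pos, unlist(ranking, use.names = FALSE))
}

#' Describe a candidate drug as one outcome selection per criterion
#'
#' @param drug_name Free-text drug name (unique within a comparison).
#' @param selections Named character vector mapping criterion id to the chosen
#'   outcome level label.
#' @param cs Optional `criteria_set`; when supplied, the profile is checked
#'   for completeness (every criterion selected exactly once) and label
#'   validity immediately.
#' @return An object of class `drug_profile`.
#' @export
drug_profile <- function(drug_name, selections, cs = NULL) {
  stopifnot(is.character(drug_name), length(drug_name) == 1L,
            is.character(selections), !is.null(names(selections)))
  prof <- structure(list(drug_name = drug_name, selections = selections),
                    class = "drug_profile")
  if (!is.null(cs)) check_profile(prof, cs)
  prof
}

#' @export
print.drug_profile <- function(x, ...) {
  cat(sprintf("<drug_profile> %s\n", x$drug_name))
  for (id in names(x$selections)) {
    cat(sprintf("  %-28s %s\n", id, x$selections[[id]]))
  }
  invisible(x)
}

# abort unless the profile selects exactly one known level per criterion
check_profile <- function(profile, cs) {
  for (id in names(cs$criteria)) {
    if (!id %in% names(profile$selections)) {
      stop(sprintf("profile '%s': no selection for criterion '%s'",
                   profile$drug_name, id), call. = FALSE)
    }
  }
  extra <- setdiff(names(profile$selections), names(cs$criteria))
  if (length(extra)) {
    stop(sprintf("profile '%s': selection for unknown criterion '%s'",
                 profile$drug_name, extra[1]), call. = FALSE)
  }
  dup <- names(profile$selections)[duplicated(names(profile$selections))]
  if (length(dup)) {
    stop(sprintf("profile '%s': multiple selections for criterion '%s'",
                 profile$drug_name, dup[1]), call. = FALSE)
  }
  for (id in names(profile$selections)) {
    level_score(cs, id, profile$selections[[id]])  # errors on unknown label
  }
  invisible(TRUE)
}

#' Build the all-best or all-worst profile for a criteria set
#'
#' Convenience constructor for the two extreme profiles: selecting every
#' criterion's highest-fraction level yields the 100-point profile, every
#' lowest-fraction level the 0-point profile.
#'
#' @param cs A `criteria_set`.
#' @param which `"best"` or `"worst"`.
#' @param drug_name Name for the resulting profile.
#' @return A `drug_profile`.
#' @export
uniform_profile <- function(cs, which = c("best", "worst"), drug_name = which) {
  which <- match.arg(which)
  drug_name <- drug_name[1]
  pick <- function(cr) {
    lv <- cr$levels
    if (which == "best") lv$label[which.max(lv$fraction)] else lv$label[which.min(lv$fraction)]
  }
  sel <- vapply(cs$criteria, pick, character(1))
  drug_profile(drug_name, sel, cs)
}
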