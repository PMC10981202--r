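#' Average consensus-session votes
#'
#' The consensus procedure aggregates every vote — ranks, weight increases,
#' criteria counts — by the plain arithmetic mean across participants, with no
#' trimming or participant weighting.
#'
#' @param votes Numeric vector, one entry per participant.
#' @return The arithmetic mean.
#' @examples
#' average_votes(c(20, 30))  # 25
#' @export
average_votes <- function(votes) {
  if (length(votes) == 0L) stop("no votes", call. = FALSE)
  stopifnot(is.numeric(votes), !anyNA(votes))
  mean(votes)
}

# coerce a votes table (optional `participant` column, one numeric column per
# criterion) to a numeric matrix with participant rownames
votes_matrix <- function(votes) {
  votes <- as.data.frame(votes)
  if ("participant" %in% names(votes)) {
    rn <- as.character(votes$participant)
    votes$participant <- NULL
  } else {
    rn <- as.character(seq_len(nrow(votes)))
  }
  m <- as.matrix(votes)
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

#' Aggregate participant rankings into a consensus ranking
#'
#' Each participant assigns a rank position to every criterion (1 = most
#' important; a participant may tie two criteria at one position). Criteria
#' are ordered by ascending mean rank; criteria whose mean ranks coincide
#' (within `tol`) share one rank group, and ranks are re-indexed contiguously
#' from 1.
#'
#' @param rank_votes A data frame or matrix with one row per participant and
#'   one numeric column per criterion (an optional `participant` column names
#'   the rows).
#' @param tol Absolute tolerance for declaring mean ranks tied. Votes are
#'   small integers, so only exact ties are intended.
#' @return A ranking: list of character vectors, best first.
#' @examples
#' rv <- data.frame(A = c(1, 1), B = c(2, 3), C = c(3, 2))
#' aggregate_ranking(rv)  # list("A", c("B", "C"))
#' @export
aggregate_ranking <- function(rank_votes, tol = 1e-9) {
  m <- votes_matrix(rank_votes)
  if (ncol(m) == 0L || nrow(m) == 0L) stop("no votes", call. = FALSE)
  for (i in seq_len(nrow(m))) {
    if (anyNA(m[i, ])) {
      stop(sprintf("participant '%s' has missing ranks", rownames(m)[i]),
           call. = FALSE)
    }
    if (any(m[i, ] < 1)) {
      stop(sprintf("participant '%s' has ranks below 1", rownames(m)[i]),
           call. = FALSE)
    }
  }
  mean_rank <- colMeans(m)
  ord <- order(mean_rank)  # stable: tied criteria keep input column order
  sorted <- mean_rank[ord]
  groups <- list()
  current <- names(sorted)[1]
  anchor <- sorted[[1]]
  for (i in seq_along(sorted)[-1]) {
    if (abs(sorted[[i]] - anchor) <= tol) {
      current <- c(current, names(sorted)[i])
    } else {
      groups[[length(groups) + 1L]] <- current
      current <- names(sorted)[i]
      anchor <- sorted[[i]]
    }
  }
  groups[[length(groups) + 1L]] <- current
  groups
}

#' Select the number of criteria to keep from count votes
#'
#' Plurality rule over participants' desired criteria counts; a tie between
#' counts is broken toward the larger count (keeping more criteria).
#'
#' @param count_votes Integer vector of per-participant desired counts.
#' @return The winning count.
#' @examples
#' select_criteria_count(c(8, 8, 10))  # 8
#' select_criteria_count(c(8, 10))     # 10 (tie -> larger)
#' @export
select_criteria_count <- function(count_votes) {
  if (length(count_votes) == 0L) stop("no votes", call. = FALSE)
  stopifnot(is.numeric(count_votes), all(count_votes >= 1))
  tab <- table(count_votes)
  winners <- as.numeric(names(tab)[tab == max(tab)])
  max(winners)
}

#' Truncate a ranking to the top-n criteria
#'
#' Drops whole rank groups from the bottom of the ranking until exactly `n`
#' criteria remain, mirroring the panel's exclusion of the lowest-ranked
#' candidate criteria after the count vote.
#'
#' @param ranking List of rank groups (character vectors), best first.
#' @param n Number of criteria to keep.
#' @return The truncated ranking.
#' @export
truncate_to_count <- function(ranking, n) {
  stopifnot(length(n) == 1L, n >= 1)
  sizes <- cumsum(lengths(ranking))
  if (n > sizes[length(sizes)]) {
    stop("cannot keep more criteria than are ranked", call. = FALSE)
  }
  keep <- which(sizes == n)
  if (length(keep) == 0L) {
    stop("ambiguous truncation at tied rank", call. = FALSE)
  }
  ranking[seq_len(keep[1])]
}

#' Swing weights from a ranking and per-step increases
#'
#' Implements the SMART & Swing multiplicative chain: every criterion in the
#' lowest rank group receives the base weight; moving up group by group, each
#' higher group's weight is the weight of the group below multiplied by
#' `1 + increase/100`, where the increase is the stated importance gain of the
#' higher group's criteria over the next-ranked criterion. Criteria tied in
#' one group receive identical weight (a tied group's step is the maximum of
#' its members' entries; 0 entries mark within-tie positions). The lowest
#' group's own increase entry is ignored, and the base cancels under
#' normalization.
#'
#' @param ranking List of rank groups (character vectors), best first.
#' @param increases Named numeric vector of percentage increases, covering
#'   every ranked criterion; all values must be non-negative.
#' @param base Positive base weight assigned to the lowest rank group.
#' @return Named numeric vector of unnormalized weights.
#' @examples
#' swing_weights(list("top", "bottom"), c(top = 100, bottom = 0))
#' # top = 2, bottom = 1
#' @seealso [normalize_weights()]
#' @export
swing_weights <- function(ranking, increases, base = 1) {
  stopifnot(is.list(ranking), length(ranking) >= 1L, base > 0)
  ids <- unlist(ranking, use.names = FALSE)
  missing <- setdiff(ids, names(increases))
  if (length(missing)) {
    stop("weight increase missing for criterion: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(increases[ids] < 0)) {
    stop("negative weight increase", call. = FALSE)
  }
  n_groups <- length(ranking)
  group_weight <- numeric(n_groups)
  group_weight[n_groups] <- base
  for (g in rev(seq_len(n_groups - 1L))) {
    step <- max(increases[ranking[[g]]])
    group_weight[g] <- group_weight[g + 1L] * (1 + step / 100)
  }
  w <- rep.int(group_weight, lengths(ranking))
  stats::setNames(w, ids)
}

#' Normalize raw weights to a weight vector summing to 1
#'
#' @param raw Named numeric vector of non-negative unnormalized weights.
#' @return Named numeric vector summing to 1 (within 1e-12); report as
#'   percent by multiplying by 100.
#' @examples
#' normalize_weights(c(A = 1, B = 0.5, C = 0.5))  # 0.5, 0.25, 0.25
#' @export
normalize_weights <- function(raw) {
  stopifnot(is.numeric(raw), !is.null(names(raw)))
  if (any(raw < 0)) stop("negative weight", call. = FALSE)
  total <- sum(raw)
  if (total <= 0) stop("degenerate weights", call. = FALSE)
  raw / total
}

#' Derive a normalized weight vector from raw vote tables
#'
#' Convenience pipeline for a full elicitation round: mean ranks give the
#' consensus ranking, mean increase votes give the per-criterion steps, and
#' the swing chain plus normalization gives the weights.
#'
#' @param rank_votes Participant-by-criterion rank table (see
#'   [aggregate_ranking()]).
#' @param increase_votes Participant-by-criterion table of percentage
#'   increases over the next-ranked criterion.
#' @return List with `ranking` (list of groups), `increases` (mean votes),
#'   `raw` (unnormalized chain) and `weights` (normalized).
#' @export
elicit_weights <- function(rank_votes, increase_votes) {
  ranking <- aggregate_ranking(rank_votes)
  inc_m <- votes_matrix(increase_votes)
  increases <- colMeans(inc_m)
  raw <- swing_weights(ranking, increases)
  list(ranking = ranking, increases = increases, raw = raw,
       weights = normalize_weights(raw))
}
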