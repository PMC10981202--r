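# Config and tabular I/O. YAML is the canonical config dialect; JSON is
# accepted as an alternate encoding of the same schema. Schema violations are
# reported with JSON-pointer-style locations.

schema_fail <- function(location, msg) {
  stop(sprintf("config schema error at %s: %s", location, msg), call. = FALSE)
}

read_structured <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
}

write_structured <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path, precision = 15)
  }
  invisible(path)
}

need_field <- function(x, field, location) {
  if (is.null(x[[field]])) schema_fail(location, sprintf("missing '%s'", field))
  x[[field]]
}

#' Write a criteria set to a config file
#'
#' Serializes the criteria, level scoring functions (as percentages, matching
#' the printed tables), per-criterion rank numbers (ties share a number) and
#' weight-increase percentages. The derived normalized weights are not
#' stored; they are recomputed on read.
#'
#' @param cs A `criteria_set`.
#' @param path Output file; a `.json` extension selects JSON, anything else
#'   YAML.
#' @return `path`, invisibly.
#' @seealso [read_criteria_set()]
#' @export
write_criteria_set <- function(cs, path) {
  rk <- rank_positions(cs$ranking)
  crit_list <- lapply(cs$criteria, function(cr) {
    list(
      id = cr$id, name = cr$name, category = cr$category,
      rank = unname(rk[[cr$id]]),
      weight_increase = unname(cs$increases[[cr$id]]),
      levels = lapply(seq_len(nrow(cr$levels)), function(i) {
        list(label = cr$levels$label[i], score = 100 * cr$levels$fraction[i])
      })
    )
  })
  write_structured(list(name = cs$name, criteria = unname(crit_list)), path)
}

#' Read a criteria set from a config file
#'
#' Parses and schema-validates a criteria-set config written by
#' [write_criteria_set()] (or by hand), rebuilding the ranking from the
#' per-criterion rank numbers and re-deriving the normalized weights.
#'
#' @param path YAML or JSON config file.
#' @return A `criteria_set`.
#' @export
read_criteria_set <- function(path) {
  cfg <- read_structured(path)
  parse_criteria_config(cfg, location = "/")
}

parse_criteria_config <- function(cfg, location = "/") {
  loc <- function(...) paste0(location, paste0(..., collapse = ""))
  crit_cfg <- need_field(cfg, "criteria", loc("criteria"))
  if (!length(crit_cfg)) schema_fail(loc("criteria"), "empty criteria list")
  criteria <- vector("list", length(crit_cfg))
  ranks <- numeric(length(crit_cfg))
  increases <- numeric(length(crit_cfg))
  ids <- character(length(crit_cfg))
  for (i in seq_along(crit_cfg)) {
    here <- loc("criteria/", i - 1L)
    c_i <- crit_cfg[[i]]
    ids[i] <- need_field(c_i, "id", here)
    lv_cfg <- need_field(c_i, "levels", paste0(here, "/levels"))
    labels <- character(length(lv_cfg))
    fractions <- numeric(length(lv_cfg))
    for (j in seq_along(lv_cfg)) {
      lvl_loc <- paste0(here, "/levels/", j - 1L)
      labels[j] <- need_field(lv_cfg[[j]], "label", lvl_loc)
      score <- need_field(lv_cfg[[j]], "score", lvl_loc)
      if (!is.numeric(score)) schema_fail(paste0(lvl_loc, "/score"), "not a number")
      fractions[j] <- score / 100
    }
    criteria[[i]] <- criterion(
      id = ids[i],
      name = need_field(c_i, "name", here),
      category = need_field(c_i, "category", here),
      levels = stats::setNames(fractions, labels)
    )
    rank <- need_field(c_i, "rank", here)
    if (!is.numeric(rank) || rank < 1 || rank != round(rank)) {
      schema_fail(paste0(here, "/rank"), "rank must be a positive integer")
    }
    ranks[i] <- rank
    inc <- need_field(c_i, "weight_increase", here)
    if (!is.numeric(inc) || inc < 0) {
      schema_fail(paste0(here, "/weight_increase"), "must be a number >= 0")
    }
    increases[i] <- inc
  }
  uranks <- sort(unique(ranks))
  if (!identical(as.numeric(uranks), as.numeric(seq_along(uranks)))) {
    schema_fail(loc("criteria"), "ranks must be contiguous integers starting at 1")
  }
  ranking <- lapply(uranks, function(r) ids[ranks == r])
  criteria_set(criteria, ranking, stats::setNames(increases, ids),
               name = if (is.null(cfg$name)) "criteria_set" else cfg$name)
}

#' Read drug profiles from a structured config file
#'
#' @param path YAML or JSON file with a top-level `profiles` list; each entry
#'   has `drug_name` and a `selections` map of criterion id to level label.
#' @param cs Optional `criteria_set` used to validate completeness and level
#'   labels on load.
#' @return A named list of [drug_profile()]s.
#' @export
read_profiles <- function(path, cs = NULL) {
  cfg <- read_structured(path)
  prof_cfg <- need_field(cfg, "profiles", "/profiles")
  profiles <- lapply(seq_along(prof_cfg), function(i) {
    here <- paste0("/profiles/", i - 1L)
    p <- prof_cfg[[i]]
    sel <- need_field(p, "selections", here)
    drug_profile(need_field(p, "drug_name", here),
                 unlist(sel), cs = cs)
  })
  stats::setNames(profiles, vapply(profiles, `[[`, character(1), "drug_name"))
}

#' Read drug profiles from a CSV in the spreadsheet layout
#'
#' The table mirrors the original spreadsheet: criteria as rows, drugs as
#' columns, cells holding the selected outcome level labels. The first column
#' must be named `criterion`.
#'
#' @param path CSV file.
#' @param cs Optional `criteria_set` for validation on load.
#' @return A named list of [drug_profile()]s, one per drug column.
#' @export
read_profiles_csv <- function(path, cs = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "criterion") {
    stop("profile CSV must have 'criterion' as its first column", call. = FALSE)
  }
  drugs <- names(tab)[-1]
  if (!length(drugs)) stop("profile CSV has no drug columns", call. = FALSE)
  profiles <- lapply(drugs, function(d) {
    drug_profile(d, stats::setNames(tab[[d]], tab$criterion), cs = cs)
  })
  stats::setNames(profiles, drugs)
}

#' Write drug profiles to the spreadsheet-layout CSV
#' @param profiles List of [drug_profile()]s (identical criterion coverage).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  ids <- names(profiles[[1]]$selections)
  tab <- data.frame(criterion = ids, check.names = FALSE)
  for (p in profiles) tab[[p$drug_name]] <- unname(p$selections[ids])
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

read_votes_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    stringsAsFactors = FALSE))
}

#' Read elicitation vote tables from CSV
#'
#' Rank and increase votes: one row per participant, one column per criterion
#' (optional leading `participant` column). Count votes: a `count` column.
#'
#' @param path CSV file.
#' @return A tibble ([read_rank_votes()], [read_increase_votes()]) or an
#'   integer vector ([read_count_votes()]).
#' @export
read_rank_votes <- function(path) read_votes_table(path)

#' @rdname read_rank_votes
#' @export
read_increase_votes <- function(path) read_votes_table(path)

#' @rdname read_rank_votes
#' @export
read_count_votes <- function(path) {
  tab <- read_votes_table(path)
  if (!"count" %in% names(tab)) {
    stop("count-votes CSV must have a 'count' column", call. = FALSE)
  }
  as.integer(tab$count)
}

#' Read concordance expectations from a config file
#'
#' @param path YAML or JSON file with fields `above_50`, `below_50`,
#'   `expected_order` (list elements may themselves be lists to declare an
#'   expected tie) and optional `min_spread` (default 40).
#' @return A [concordance_expectation()].
#' @export
read_expectations <- function(path) {
  cfg <- read_structured(path)
  order_cfg <- need_field(cfg, "expected_order", "/expected_order")
  expected_order <- lapply(order_cfg, function(el) unlist(el))
  concordance_expectation(
    above_50 = as.character(unlist(cfg$above_50)),
    below_50 = as.character(unlist(cfg$below_50)),
    expected_order = expected_order,
    min_spread = if (is.null(cfg$min_spread)) 40 else cfg$min_spread
  )
}

#' Load a tool configuration
#'
#' A tool config either names the embedded default criteria set
#' (`criteria_set: emirates_default`) or defines one inline under
#' `criteria_set:` using the same schema as [read_criteria_set()]. An
#' optional `report` block sets the output precision (decimal places,
#' default 1) and default format.
#'
#' @param path YAML or JSON config file.
#' @return A `tool_config`: list with `criteria_set`, `precision`, `format`
#'   and `config_hash` (md5 of the file, for the audit log).
#' @export
load_config <- function(path) {
  cfg <- read_structured(path)
  cs_cfg <- need_field(cfg, "criteria_set", "/criteria_set")
  cs <- if (identical(cs_cfg, "emirates_default")) {
    emirates_default()
  } else if (is.list(cs_cfg)) {
    parse_criteria_config(cs_cfg, location = "/criteria_set/")
  } else {
    schema_fail("/criteria_set", "must be 'emirates_default' or an inline definition")
  }
  report <- if (is.null(cfg$report)) list() else cfg$report
  precision <- if (is.null(report$precision)) 1L else as.integer(report$precision)
  if (is.na(precision) || precision < 0) {
    schema_fail("/report/precision", "must be a non-negative integer")
  }
  fmt <- if (is.null(report$format)) "csv" else report$format
  if (!fmt %in% c("csv", "json", "markdown")) {
    schema_fail("/report/format", "must be one of csv, json, markdown")
  }
  structure(
    list(criteria_set = cs, precision = precision, format = fmt,
         config_hash = unname(tools::md5sum(path))),
    class = "tool_config"
  )
}

# audit log: every run records the config identity and precision in effect
log_run <- function(config_hash, cs, precision) {
  message(sprintf("[orphanmcda] config md5: %s",
                  if (is.null(config_hash) || is.na(config_hash)) "(in-memory)" else config_hash))
  message(sprintf("[orphanmcda] criteria set: %s (%d criteria)",
                  cs$name, length(cs$criteria)))
  message(sprintf("[orphanmcda] report precision: %d decimal place(s)", precision))
  invisible(NULL)
}
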