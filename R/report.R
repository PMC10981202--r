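# Report writers. Output is deterministic: identical inputs produce
# byte-identical files (fixed number formatting, "\n" line endings,
# RFC-4180 quoting for CSV).

fmt_num <- function(x, digits) sprintf(paste0("%.", digits, "f"), x)

comparison_table <- function(comparison, digits) {
  rows <- lapply(comparison, function(b) {
    bd <- b$breakdown
    data.frame(
      drug = b$drug_name,
      rank = b$rank,
      criterion_id = bd$criterion_id,
      level = bd$level,
      fraction = fmt_num(bd$fraction, 4),
      weight = fmt_num(bd$weight, 6),
      contribution = fmt_num(bd$contribution, digits),
      total = fmt_num(b$total, digits),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  })
  do.call(rbind, rows)
}

concordance_table <- function(report, digits) {
  tc <- report$threshold_check
  fmt_order <- function(o) paste(vapply(o, paste, character(1), collapse = " = "),
                                 collapse = " > ")
  rows <- data.frame(
    check = c(rep("threshold", nrow(tc)), "rank_order", "spread", "overall"),
    item = c(tc$drug, "order", "max - min", "all checks"),
    value = c(paste0(fmt_num(tc$total, digits), " (expected ", tc$expected, ")"),
              paste0("observed ", fmt_order(report$rank_check$observed),
                     "; expected ", fmt_order(report$rank_check$expected)),
              paste0(fmt_num(report$spread_check$observed, digits), " vs threshold ",
                     fmt_num(report$spread_check$threshold, digits)),
              ""),
    pass = c(tc$pass, report$rank_check$pass, report$spread_check$pass,
             report$overall),
    stringsAsFactors = FALSE
  )
  rows
}

markdown_table <- function(df) {
  cells <- vapply(df, as.character, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L, dimnames = list(NULL, names(df)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

#' Write a comparison or concordance report to disk
#'
#' Serializes the results of [compare_drugs()] or [check_concordance()] as
#' CSV (one row per criterion per drug for comparisons), JSON, or a Markdown
#' table. Numbers are written at the configured precision; identical inputs
#' produce byte-identical files.
#'
#' @param results A `drug_comparison` or a `concordance_report`.
#' @param path Output file.
#' @param format One of `"csv"`, `"json"`, `"markdown"`.
#' @param precision Decimal places for point totals and contributions.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("csv", "json", "markdown"),
                         precision = 1L) {
  format <- match.arg(format)
  if (inherits(results, "drug_comparison")) {
    tab <- comparison_table(results, precision)
    payload <- lapply(results, function(b) {
      list(drug_name = b$drug_name, rank = b$rank,
           total = as.numeric(fmt_num(b$total, precision)),
           breakdown = lapply(seq_len(nrow(b$breakdown)), function(i) {
             bd <- b$breakdown[i, ]
             list(criterion_id = bd$criterion_id, level = bd$level,
                  fraction = bd$fraction, weight = bd$weight,
                  contribution = as.numeric(fmt_num(bd$contribution, precision)))
           }))
    })
  } else if (inherits(results, "concordance_report")) {
    tab <- concordance_table(results, precision)
    payload <- list(
      threshold_check = lapply(seq_len(nrow(results$threshold_check)), function(i) {
        as.list(results$threshold_check[i, ])
      }),
      rank_check = results$rank_check,
      spread_check = results$spread_check,
      overall = results$overall
    )
  } else {
    stop("results must be a drug_comparison or concordance_report", call. = FALSE)
  }

  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, eol = "\n")
  } else if (format == "json") {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(markdown_table(tab), path, sep = "\n")
  }
  invisible(path)
}
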