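#' Round half-up
#'
#' Base [round()] uses round-half-to-even; the summary tables here use
#' conventional half-up rounding (0.005 -> 0.01), which is what reproduces
#' percentage tables printed in infodemiology reports.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up to `digits` places.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  y <- abs(x) * scale
  # guard against values like 1.005 * 100 = 100.49999... (binary round-off)
  sign(x) * floor(y + 0.5 + abs(y) * 1e-12) / scale
}

#' Percentage share of a count over a total
#'
#' Computes `100 * count / total` rounded half-up to two decimals, the
#' convention used for every percentage in the summary tables (e.g.
#' 11,688/32,794 -> 35.64).
#'
#' @param count non-negative integer(s), `count <= total`.
#' @param total positive integer total (scalar or same length as `count`).
#' @return numeric percentage(s) with two decimals.
#' @examples
#' share_percentage(11688, 32794)
#' share_percentage(7975, 13295)
#' @export
share_percentage <- function(count, total) {
  if (any(total <= 0)) {
    stop("`total` must be positive", call. = FALSE)
  }
  if (any(count < 0) || any(count > total)) {
    stop("`count` must satisfy 0 <= count <= total", call. = FALSE)
  }
  round_half_up(100 * count / total, 2)
}

# Write a list of records as JSON lines with stable formatting (one compact
# JSON object per line), so identical inputs give byte-identical files.
write_jsonl <- function(records, path) {
  lines <- vapply(
    records,
    function(rec) {
      as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", digits = NA))
    },
    character(1)
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

read_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
}

# Deterministic CSV writer (fixed eol, no BOM) used for pipeline outputs.
write_table_csv <- function(df, path) {
  readr::write_csv(df, path, eol = "\n", progress = FALSE)
  invisible(path)
}
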