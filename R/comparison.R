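#' Parse a controlled-vocabulary comparison label
#'
#' Experimental comparisons are written as a three-part phrase `A_vs_B`
#' (`A vs B` is also accepted), where `A` and `B` are the two experimental
#' conditions. A token consisting of a capital `D` followed by digits inside
#' either condition denotes the day of sample collection relative to the
#' start of treatment (e.g. `BleomD14_vs_Ctrl` is bleomycin day 14 versus
#' control).
#'
#' @param raw A single non-empty comparison string.
#' @return A `comparison_label` list with fields `condition_a`,
#'   `condition_b`, `day` (integer or `NA`), and `raw` (the input,
#'   byte-identical).
#' @examples
#' parse_comparison_label("IPF_vs_Ctrl")
#' parse_comparison_label("BleomD14_vs_Ctrl")$day
#' @export
parse_comparison_label <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) abort("Comparison label must be non-empty.")
  parts <- strsplit(raw, "_vs_", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) parts <- strsplit(raw, " vs ", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !all(nzchar(parts))) {
    abort(sprintf("Malformed comparison label %s: expected exactly one 'A_vs_B' separator.",
                  encodeString(raw, quote = '"')))
  }
  day_tok <- stringr::str_extract(parts, "D[0-9]+$")
  day <- suppressWarnings(as.integer(sub("^D", "", day_tok)))
  day <- day[!is.na(day)]
  structure(
    list(condition_a = parts[[1L]], condition_b = parts[[2L]],
         day = if (length(day)) day[[1L]] else NA_integer_, raw = raw),
    class = "comparison_label"
  )
}

#' @export
print.comparison_label <- function(x, ...) {
  cat(sprintf("<comparison> %s vs %s%s\n", x$condition_a, x$condition_b,
              if (!is.na(x$day)) sprintf(" (day %d)", x$day) else ""))
  invisible(x)
}
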