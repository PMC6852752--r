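#' Audit region codes
#'
#' The nine purchase-audit regions: the eight largest provinces plus Prince
#' Edward Island and Newfoundland reported as a single region (`"PEI/NL"`).
#'
#' @return Character vector of region codes.
#' @export
#' @examples
#' cdh_regions()
cdh_regions <- function() {
  c("BC", "AB", "SK", "MB", "ON", "QC", "NB", "NS", "PEI/NL")
}

#' Study window
#'
#' An inclusive range of calendar months, `"YYYY-MM"`. The default covers the
#' two-year observation period July 2016 through June 2018.
#'
#' @param start,end First and last month of the window, `"YYYY-MM"` strings.
#' @return A `study_window` object (list with `start` and `end`).
#' @export
#' @examples
#' study_window()
#' study_window("2017-01", "2017-12")
study_window <- function(start = "2016-07", end = "2018-06") {
  s <- month_index(start)
  e <- month_index(end)
  if (s > e) {
    abort(sprintf("study window start (%s) is after end (%s)", start, end))
  }
  structure(list(start = start, end = end), class = "study_window")
}

#' @export
print.study_window <- function(x, ...) {
  cat(sprintf("<study_window> %s to %s (%d months)\n",
              x$start, x$end, month_index(x$end) - month_index(x$start) + 1L))
  invisible(x)
}

# months since year 0, so windows can be compared and differenced
month_index <- function(month) {
  ok <- grepl("^\\d{4}-(0[1-9]|1[0-2])$", month)
  if (!all(ok)) {
    abort(sprintf("malformed month value(s): %s (expected \"YYYY-MM\")",
                  paste(unique(month[!ok]), collapse = ", ")))
  }
  year <- as.integer(substr(month, 1, 4))
  mon <- as.integer(substr(month, 6, 7))
  year * 12L + (mon - 1L)
}

month_label <- function(index) {
  sprintf("%04d-%02d", index %/% 12L, index %% 12L + 1L)
}

in_window <- function(month, window) {
  idx <- month_index(month)
  idx >= month_index(window$start) & idx <= month_index(window$end)
}

window_months <- function(window) {
  month_label(seq(month_index(window$start), month_index(window$end)))
}

#' Assign months to window-anchored quarters
#'
#' Quarters are consecutive 3-month blocks counted from the window start
#' (under the default window, quarter 1 is July--September 2016), not
#' calendar quarters of the year. Labels use the calendar quarter of the
#' block's first month, e.g. `"2016Q3"`.
#'
#' @param month Character vector of `"YYYY-MM"` months.
#' @param window A [study_window()].
#' @return A tibble with columns `month`, `quarter` (1-based ordinal within
#'   the window) and `quarter_label`.
#' @export
#' @examples
#' quarter_of(c("2016-07", "2016-09", "2016-10"), study_window())
quarter_of <- function(month, window = study_window()) {
  idx <- month_index(month)
  start <- month_index(window$start)
  if (any(idx < start | idx > month_index(window$end))) {
    abort("month outside the study window has no quarter")
  }
  q <- (idx - start) %/% 3L + 1L
  first <- start + (q - 1L) * 3L
  tibble(
    month = month,
    quarter = as.integer(q),
    quarter_label = sprintf("%dQ%d", first %/% 12L, (first %% 12L) %/% 3L + 1L)
  )
}

# round half away from zero (the convention recovering the printed tables;
# base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# integer apportionment of `total` across `weights` by largest remainder,
# so that the parts always sum exactly to `total`
apportion <- function(total, weights) {
  stopifnot(length(weights) >= 1, all(weights >= 0), sum(weights) > 0)
  total <- as.numeric(total)
  stopifnot(total >= 0, total == floor(total))
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  short <- as.integer(round(total - sum(base)))
  if (short > 0) {
    frac <- quota - base
    top <- order(frac, decreasing = TRUE)[seq_len(short)]
    base[top] <- base[top] + 1
  }
  base
}
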