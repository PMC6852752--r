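#' @keywords internal
purchase_columns <- function() {
  c("region", "sector", "month", "molecule", "brand", "role",
    "form", "strength", "dollars", "units")
}

purchase_sectors <- function() c("drugstore", "hospital")
purchase_roles <- function() c("originator", "biosimilar")

#' Validate purchase records
#'
#' Checks a purchase table against the audit schema: required columns, known
#' region codes, sector and role enumerations, well-formed months inside the
#' study window, non-negative dollars and units, dollars that are a whole
#' number of cents, and the rule that zero units imply zero dollars (a cell
#' with dollars but no units would make its unit price undefined).
#'
#' @param records A data frame of purchase records (one row per
#'   region x sector x month x product cell).
#' @param window A [study_window()]; months must fall inside it.
#' @param regions Allowed region codes (default [cdh_regions()]).
#' @return The records as a tibble, invisibly unchanged, for piping.
#' @export
validate_purchases <- function(records, window = study_window(),
                               regions = cdh_regions()) {
  records <- as_tibble(records)
  missing <- setdiff(purchase_columns(), names(records))
  if (length(missing) > 0) {
    abort(sprintf("purchase table is missing required column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  fail_rows <- function(bad, what) {
    if (any(bad)) {
      abort(sprintf("invalid purchase record(s): %s in row(s) %s",
                    what, paste(utils::head(which(bad), 5), collapse = ", ")))
    }
  }
  fail_rows(!records$region %in% regions, "unknown region")
  fail_rows(!records$sector %in% purchase_sectors(), "unknown sector")
  fail_rows(!records$role %in% purchase_roles(), "unknown role")
  month_index(records$month)  # aborts on malformed months
  fail_rows(!in_window(records$month, window), "month outside study window")
  fail_rows(is.na(records$dollars) | records$dollars < 0, "negative or missing dollars")
  fail_rows(is.na(records$units) | records$units < 0, "negative or missing units")
  fail_rows(records$units != floor(records$units), "non-integer units")
  cents <- records$dollars * 100
  fail_rows(abs(cents - round(cents)) > 1e-6, "dollars not a whole number of cents")
  fail_rows(records$units == 0 & records$dollars > 0,
            "dollars recorded against zero units")
  invisible(records)
}

#' Read purchase records from CSV
#'
#' Reads a comma-delimited, UTF-8, headered purchase table with columns
#' `region, sector, month, molecule, brand, role, form, strength, dollars,
#' units`, validates it, and drops records outside the study window with an
#' informative message.
#'
#' @param path Path to the CSV file.
#' @inheritParams validate_purchases
#' @return A tibble of validated in-window purchase records.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_purchases(generate_purchases(synth_config(seed = 1)), f)
#' head(read_purchases(f))
read_purchases <- function(path, window = study_window(),
                           regions = cdh_regions()) {
  if (!file.exists(path)) {
    abort(sprintf("purchase file not found: %s", path))
  }
  parsers <- c(lapply(purchase_columns()[1:8], function(.) readr::col_character()),
               list(readr::col_double(), readr::col_double()))
  names(parsers) <- purchase_columns()
  present <- intersect(purchase_columns(),
                       names(readr::read_csv(path, n_max = 0,
                                             show_col_types = FALSE)))
  records <- readr::read_csv(path,
                             col_types = do.call(readr::cols, parsers[present]))
  missing <- setdiff(purchase_columns(), names(records))
  if (length(missing) > 0) {
    abort(sprintf("purchase file %s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  month_index(records$month)
  out <- in_window(records$month, window)
  if (any(!out)) {
    inform(sprintf("dropped %d record(s) outside study window %s to %s",
                   sum(!out), window$start, window$end))
    records <- records[out, , drop = FALSE]
  }
  validate_purchases(records, window = window, regions = regions)
  records[purchase_columns()]
}

#' Write purchase records to CSV
#'
#' Writes the documented schema with dollars formatted to exactly two
#' decimals, so that a write/read round trip reproduces dollars (to the
#' cent) and units exactly.
#'
#' @param records A purchase table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_purchases <- function(records, path) {
  records <- as_tibble(records)[purchase_columns()]
  records$dollars <- sprintf("%.2f", records$dollars)
  records$units <- format(records$units, scientific = FALSE, trim = TRUE)
  readr::write_csv(records, path)
  invisible(path)
}

#' Packaged national aggregates for the three biosimilar markets
#'
#' National, sector- and month-collapsed purchase totals (Canadian dollars
#' and units, July 2016 to June 2018) for the three originator/biosimilar
#' pairs: Lantus/Basaglar (insulin glargine), Neupogen/Grastofil
#' (filgrastim) and Remicade/Inflectra (infliximab). These six published
#' aggregates are the desk-scale inputs from which the national savings
#' analysis is fully reproducible.
#'
#' @return A tibble with columns `molecule`, `brand`, `role`, `form`,
#'   `strength`, `dollars`, `units` (one row per product).
#' @export
#' @examples
#' load_table1_fixture()
load_table1_fixture <- function() {
  path <- system.file("extdata", "cdh_table1_national.csv",
                      package = "biosimsavings", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    molecule = readr::col_character(),
    brand = readr::col_character(),
    role = readr::col_character(),
    form = readr::col_character(),
    strength = readr::col_character(),
    dollars = readr::col_double(),
    units = readr::col_double()
  ))
}

#' Packaged province-level realized and unrealized savings
#'
#' Published region-stratified realized and unrealized savings (Canadian
#' dollars) for the three biosimilars combined, including the published
#' `TOTAL` row. Note the published province cells do not sum exactly to the
#' published total (the gap is about $1.3M on the full-conversion
#' potential); both are shipped as printed and [scenario_table()] surfaces
#' the discrepancy.
#'
#' @return A tibble with columns `region`, `realized`, `unrealized`.
#' @export
#' @examples
#' load_table2_fixture()
load_table2_fixture <- function() {
  path <- system.file("extdata", "cdh_table2_region_savings.csv",
                      package = "biosimsavings", mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    region = readr::col_character(),
    realized = readr::col_double(),
    unrealized = readr::col_double()
  ))
}
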