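#' Biosimilar uptake report
#'
#' Biosimilar share of purchases per molecule. With monthly records the
#' share is quarterly ([uptake_series()]); for already-collapsed inputs
#' without a time dimension (such as [load_table1_fixture()]) a single
#' full-window share per molecule is reported.
#'
#' @param records A purchase table.
#' @param map Optional comparator map.
#' @param basis `"units"` or `"dollars"`.
#' @param window A [study_window()].
#' @param out Optional CSV path to write the report to.
#' @return A tibble with one row per molecule (and quarter, when monthly
#'   data are available): `molecule`, `basis`, `biosimilar`, `total`,
#'   `share`.
#' @export
#' @examples
#' make_uptake_report(load_table1_fixture())
make_uptake_report <- function(records, map = NULL,
                               basis = c("units", "dollars"),
                               window = study_window(), out = NULL) {
  basis <- match.arg(basis)
  if ("month" %in% names(records)) {
    report <- uptake_series(records, map = map, basis = basis, window = window)
  } else {
    collapsed <- collapse_purchases(records, map = map, scope = "national",
                                    period = "full_window", window = window)
    value <- if (basis == "units") collapsed$units else collapsed$dollars
    collapsed$value <- value
    report <- collapsed |>
      group_by(.data$molecule) |>
      summarise(
        basis = basis,
        biosimilar = sum(.data$value[.data$role == "biosimilar"]),
        total = sum(.data$value), .groups = "drop") |>
      mutate(share = ifelse(.data$total > 0, .data$biosimilar / .data$total, 0))
  }
  if (!is.null(out)) readr::write_csv(as_tibble(report), out)
  report
}

#' Run the full savings pipeline
#'
#' Executes read/generate, comparator matching, collapsing, national
#' (pooled) and — when regional data are available — region-stratified
#' savings, market-share scenarios, eligibility sensitivity, and the
#' uptake report, optionally writing the result tables as CSV plus a
#' machine-readable JSON summary. Every figure in the summary is
#' re-derivable from the emitted tables.
#'
#' @param input Path to a purchase CSV (exclusive with `fixture` and
#'   `records`).
#' @param fixture `"table1"` to analyse the packaged national aggregates.
#' @param records A purchase table supplied directly.
#' @param window A [study_window()].
#' @param pairing Brand pairing; default [default_pairing()].
#' @param delta_convention Price-delta convention, see [discount()].
#' @param totals_convention `"pooled"` (national prices), `"stratified"`
#'   (per-region prices) or `"both"`.
#' @param fractions Market-share scenario fractions in `(0, 1]`.
#' @param eligibility Eligible-fraction sensitivity values in `[0, 1]`.
#' @param basis Uptake basis, `"units"` or `"dollars"`.
#' @param out_dir Optional output directory (created if needed) for
#'   `national_savings.csv`, `scenario_table.csv`, `uptake.csv` and
#'   `summary.json`.
#' @return A list with elements `national`, `stratified` (or `NULL`),
#'   `scenarios`, `sensitivity`, `uptake`, `excluded`, invisibly when
#'   `out_dir` is given.
#' @export
#' @examples
#' res <- run_pipeline(fixture = "table1")
#' glance(res$national)
run_pipeline <- function(input = NULL, fixture = NULL, records = NULL,
                         window = study_window(),
                         pairing = default_pairing(),
                         delta_convention = c("cent_rounded", "exact"),
                         totals_convention = c("both", "pooled", "stratified"),
                         fractions = c(0.25, 0.5, 0.75, 1),
                         eligibility = c(0.8, 1),
                         basis = c("units", "dollars"),
                         out_dir = NULL) {
  delta_convention <- match.arg(delta_convention)
  totals_convention <- match.arg(totals_convention)
  basis <- match.arg(basis)
  supplied <- c(!is.null(input), !is.null(fixture), !is.null(records))
  if (sum(supplied) != 1) {
    abort("supply exactly one of `input`, `fixture`, `records`")
  }
  if (!is.null(input)) {
    records <- read_purchases(input, window = window)
  } else if (!is.null(fixture)) {
    if (!identical(fixture, "table1")) {
      abort(sprintf("unknown fixture: %s", fixture))
    }
    records <- load_table1_fixture()
  }
  records <- as_tibble(records)
  map <- build_comparator_map(records, pairing = pairing)

  national_tab <- collapse_purchases(records, map = map, scope = "national",
                                     period = "full_window", window = window)
  excluded <- attr(national_tab, "excluded")
  national <- NULL
  if (totals_convention %in% c("both", "pooled")) {
    national <- savings_national(national_tab, pairing = pairing,
                                 convention = delta_convention)
  }
  stratified <- NULL
  if (totals_convention %in% c("both", "stratified") &&
      "region" %in% names(records)) {
    regional_tab <- collapse_purchases(records, map = map, scope = "region",
                                       period = "full_window", window = window)
    stratified <- savings_stratified(regional_tab, pairing = pairing,
                                     convention = delta_convention)
  }

  scenario_src <- if (!is.null(stratified)) {
    stratified
  } else {
    g <- glance(national)
    tibble(region = "national", realized = g$realized,
           unrealized = g$unrealized)
  }
  scenarios <- scenario_table(scenario_src, fractions = fractions)

  base <- if (!is.null(national)) national else stratified
  sensitivity <- tibble(
    eligible_fraction = eligibility,
    unrealized = sensitivity_eligibility(glance(base)$unrealized, eligibility))

  uptake <- make_uptake_report(records, map = map, basis = basis,
                               window = window)

  result <- list(national = national, stratified = stratified,
                 scenarios = scenarios, sensitivity = sensitivity,
                 uptake = uptake, excluded = excluded)
  if (is.null(out_dir)) {
    return(result)
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(national)) {
    readr::write_csv(tidy(national), file.path(out_dir, "national_savings.csv"))
  }
  if (!is.null(stratified)) {
    readr::write_csv(tidy(stratified),
                     file.path(out_dir, "stratified_savings.csv"))
  }
  readr::write_csv(
    tidyr::pivot_wider(scenarios, names_from = "region",
                       values_from = "savings"),
    file.path(out_dir, "scenario_table.csv"))
  readr::write_csv(as_tibble(uptake), file.path(out_dir, "uptake.csv"))

  summary <- list(
    window = list(start = window$start, end = window$end),
    delta_convention = delta_convention,
    pooled = if (!is.null(national)) as.list(glance(national)),
    stratified = if (!is.null(stratified)) as.list(glance(stratified)),
    scenarios = lapply(split(scenarios, scenarios$fraction), function(d) {
      as.list(stats::setNames(d$savings, d$region))
    }),
    sensitivity = stats::setNames(as.list(sensitivity$unrealized),
                                  sprintf("%g", sensitivity$eligible_fraction)),
    excluded_dollars = sum(excluded$dollars)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}
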