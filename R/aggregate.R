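#' Collapse purchase records to analysis strata
#'
#' Sums dollars and units over sectors, over months within the chosen
#' period, and over matched `(form, strength)` keys. Originator keys the
#' comparator map marks as excluded (no biosimilar counterpart on the
#' market) are dropped before summing — no substitution savings can accrue
#' to them — and their dollars and units are reported via the `excluded`
#' attribute and an informative message.
#'
#' Records that are already collapsed (no `region`/`sector`/`month`
#' columns, e.g. [load_table1_fixture()]) are accepted whenever the
#' requested stratification does not need the missing columns.
#'
#' @param records A purchase table.
#' @param map A comparator map from [build_comparator_map()], or `NULL` to
#'   keep all keys.
#' @param scope `"national"` (pool regions) or `"region"`.
#' @param period `"full_window"` (pool months) or `"quarter"`
#'   (window-anchored 3-month blocks, see [quarter_of()]).
#' @param window A [study_window()] (needed for quarter assignment).
#' @param by_sector Keep the drugstore/hospital split instead of pooling
#'   sectors (exploratory; published prices pool sectors).
#' @return A tibble with the stratum columns (`region`, `quarter` +
#'   `quarter_label`, `sector` as requested) plus `molecule`, `brand`,
#'   `role`, `dollars`, `units`; attribute `excluded` holds the dropped
#'   originator-only aggregates.
#' @export
#' @examples
#' collapse_purchases(load_table1_fixture())
collapse_purchases <- function(records, map = NULL,
                               scope = c("national", "region"),
                               period = c("full_window", "quarter"),
                               window = study_window(),
                               by_sector = FALSE) {
  scope <- match.arg(scope)
  period <- match.arg(period)
  records <- as_tibble(records)

  excluded <- tibble(molecule = character(), dollars = numeric(),
                     units = numeric())
  if (!is.null(map)) {
    key <- function(d) paste(d$molecule, d$form, d$strength, sep = "\r")
    matched <- filter(map, .data$status == "matched")
    drop_mask <- records$role == "originator" & !(key(records) %in% key(matched))
    if (any(drop_mask)) {
      dropped <- records[drop_mask, , drop = FALSE]
      excluded <- dropped |>
        group_by(.data$molecule) |>
        summarise(dollars = sum(.data$dollars), units = sum(.data$units),
                  .groups = "drop")
      inform(sprintf(
        "excluded %d originator record(s) with no biosimilar-matched (form, strength) key ($%s)",
        nrow(dropped), format(sum(dropped$dollars), big.mark = ",")))
      records <- records[!drop_mask, , drop = FALSE]
    }
  }

  groups <- c("molecule", "brand", "role")
  if (scope == "region") {
    if (!"region" %in% names(records)) {
      abort("records carry no `region` column; region scope is unavailable")
    }
    groups <- c("region", groups)
  }
  if (period == "quarter") {
    if (!"month" %in% names(records)) {
      abort("records carry no `month` column; quarterly periods are unavailable")
    }
    q <- quarter_of(records$month, window)
    records$quarter <- q$quarter
    records$quarter_label <- q$quarter_label
    groups <- c("quarter", "quarter_label", groups)
  }
  if (by_sector) {
    if (!"sector" %in% names(records)) {
      abort("records carry no `sector` column; sector stratification is unavailable")
    }
    groups <- c(groups, "sector")
  }

  out <- records |>
    group_by(across(dplyr::all_of(groups))) |>
    summarise(dollars = sum(.data$dollars), units = sum(.data$units),
              .groups = "drop") |>
    arrange(across(dplyr::all_of(groups)))
  attr(out, "excluded") <- excluded
  out
}

#' Unit price
#'
#' Total purchase dollars divided by total units within a stratum. The
#' quotient is exact; rounding to cents is a presentation convention
#' applied downstream (see [discount()]).
#'
#' @param dollars,units Numeric vectors; `units` must be positive.
#' @return CAD per unit.
#' @export
#' @examples
#' unit_price(141135286, 7328068)
unit_price <- function(dollars, units) {
  if (any(units <= 0)) {
    abort("unit price is undefined for strata with zero (or negative) units")
  }
  dollars / units
}

#' Quarterly biosimilar uptake series
#'
#' For each molecule and window-anchored quarter, the biosimilar share of
#' purchases, `biosimilar / (biosimilar + originator)`, on a units or
#' dollars basis, pooled over regions, sectors and matched keys. Quarters
#' where neither product sold are omitted with a message.
#'
#' @param records A purchase table with a `month` column.
#' @param map Optional comparator map; matched keys only are counted.
#' @param basis `"units"` or `"dollars"`.
#' @param window A [study_window()].
#' @return A tibble (class `biosim_uptake`) with columns `molecule`,
#'   `quarter`, `quarter_label`, `basis`, `biosimilar`, `total`, `share`.
#' @export
#' @examples
#' uptake_series(generate_purchases(synth_config(seed = 1)))
uptake_series <- function(records, map = NULL, basis = c("units", "dollars"),
                          window = study_window()) {
  basis <- match.arg(basis)
  collapsed <- collapse_purchases(records, map = map, scope = "national",
                                  period = "quarter", window = window)
  value <- if (basis == "units") collapsed$units else collapsed$dollars
  collapsed$value <- value
  out <- collapsed |>
    group_by(.data$molecule, .data$quarter, .data$quarter_label) |>
    summarise(
      biosimilar = sum(.data$value[.data$role == "biosimilar"]),
      total = sum(.data$value),
      .groups = "drop") |>
    mutate(basis = basis, .after = "quarter_label")
  empty <- out$total <= 0
  if (any(empty)) {
    inform(sprintf("omitted %d quarter(s) with no purchases on the %s basis",
                   sum(empty), basis))
    out <- out[!empty, , drop = FALSE]
  }
  out <- mutate(out, share = .data$biosimilar / .data$total)
  class(out) <- c("biosim_uptake", class(out))
  out
}
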