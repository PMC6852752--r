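#' Price discount of a biosimilar against its originator
#'
#' The per-unit price difference (originator minus biosimilar) and the
#' relative discount. Under the `"cent_rounded"` convention — the default,
#' and the one whose products recover the published savings figures — both
#' prices are rounded to the cent before differencing; `"exact"` keeps full
#' precision. A biosimilar priced above its originator yields a negative
#' delta, which is preserved, never clamped.
#'
#' @param originator_price,biosimilar_price Unit prices (CAD/unit, > 0);
#'   vectorized.
#' @param convention `"cent_rounded"` or `"exact"`.
#' @return A tibble with `originator_price`, `biosimilar_price` (as used,
#'   i.e. rounded under `"cent_rounded"`), `delta` (CAD/unit) and `percent`
#'   (fraction of the originator price).
#' @export
#' @examples
#' discount(141135286 / 7328068, 9402061 / 619155)
discount <- function(originator_price, biosimilar_price,
                     convention = c("cent_rounded", "exact")) {
  convention <- match.arg(convention)
  if (any(originator_price <= 0, na.rm = TRUE) ||
      any(biosimilar_price <= 0, na.rm = TRUE)) {
    abort("unit prices must be positive")
  }
  if (convention == "cent_rounded") {
    originator_price <- round_half_up(originator_price, 2)
    biosimilar_price <- round_half_up(biosimilar_price, 2)
    delta <- round_half_up(originator_price - biosimilar_price, 2)
  } else {
    delta <- originator_price - biosimilar_price
  }
  tibble(originator_price = originator_price,
         biosimilar_price = biosimilar_price,
         delta = delta,
         percent = delta / originator_price)
}

# sum dollars/units per molecule and role over a collapsed table restricted
# to one pairing's brands; returns one row per molecule with both roles wide
pair_totals <- function(collapsed, pairing, extra = character()) {
  labelled <- collapsed |>
    inner_join(pairing, by = "molecule") |>
    filter((.data$role == "originator" & .data$brand == .data$originator_brand) |
             (.data$role == "biosimilar" & .data$brand == .data$biosimilar_brand))
  labelled |>
    group_by(across(dplyr::all_of(c(extra, "molecule", "originator_brand",
                                    "biosimilar_brand", "role")))) |>
    summarise(dollars = sum(.data$dollars), units = sum(.data$units),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("dollars", "units"),
                       values_fill = 0)
}

new_biosim_savings <- function(detail, scope, convention, fallback = NULL) {
  structure(list(detail = detail, scope = scope, convention = convention,
                 fallback = fallback),
            class = "biosim_savings")
}

savings_rows <- function(wide, convention) {
  rows <- wide |>
    mutate(
      originator_price = ifelse(.data$units_originator > 0,
                                .data$dollars_originator / .data$units_originator,
                                NA_real_),
      biosimilar_price = ifelse(.data$units_biosimilar > 0,
                                .data$dollars_biosimilar / .data$units_biosimilar,
                                NA_real_))
  d <- discount(rows$originator_price, rows$biosimilar_price,
                convention = convention)  # NA prices pass through
  rows$originator_price <- d$originator_price
  rows$biosimilar_price <- d$biosimilar_price
  rows$delta <- d$delta
  rows$percent_discount <- d$percent
  rows
}

finish_savings <- function(rows) {
  rows |>
    mutate(
      realized = ifelse(is.na(.data$delta) | .data$units_biosimilar == 0, 0,
                        round_half_up(.data$delta * .data$units_biosimilar)),
      unrealized = ifelse(.data$units_originator == 0, 0,
                          ifelse(is.na(.data$delta), NA_real_,
                                 round_half_up(.data$delta * .data$units_originator))),
      potential = .data$realized + .data$unrealized,
      percent_realized = ifelse(.data$potential > 0,
                                .data$realized / .data$potential, NA_real_)) |>
    rename(originator_units = "units_originator",
           biosimilar_units = "units_biosimilar",
           originator_dollars = "dollars_originator",
           biosimilar_dollars = "dollars_biosimilar")
}

warn_negative_deltas <- function(detail) {
  neg <- !is.na(detail$delta) & detail$delta < 0
  if (any(neg)) {
    warn(sprintf(
      "biosimilar priced above originator (negative savings preserved): %s",
      paste(unique(detail$molecule[neg]), collapse = ", ")))
  }
}

#' National (pooled) savings summary
#'
#' The pooled-convention savings method: unit prices are computed from
#' dollars and units pooled over all regions and sectors, the per-unit
#' price delta is taken (cent-rounded by default), and realized savings are
#' `delta x biosimilar units`, unrealized (potential) savings
#' `delta x originator units`, each rounded to whole dollars. A molecule
#' whose biosimilar sold no units in the window has no comparator price and
#' is flagged.
#'
#' @param national A collapsed national table from
#'   [collapse_purchases()] (columns `molecule`, `brand`, `role`,
#'   `dollars`, `units`).
#' @param pairing Brand pairing; default [default_pairing()].
#' @param convention Price-delta convention, see [discount()].
#' @param delta_override Optional tibble (`molecule`, `delta`) replacing the
#'   pooled per-unit delta, e.g. the unweighted cross-province mean from
#'   [province_mean_delta()].
#' @return A `biosim_savings` object; see [tidy.biosim_savings()] and
#'   [glance.biosim_savings()].
#' @export
#' @examples
#' load_table1_fixture() |> collapse_purchases() |> savings_national()
savings_national <- function(national, pairing = default_pairing(),
                             convention = c("cent_rounded", "exact"),
                             delta_override = NULL) {
  convention <- match.arg(convention)
  wide <- pair_totals(national, pairing)
  no_price <- wide$units_biosimilar == 0
  if (any(no_price)) {
    warn(sprintf("no comparator price (zero biosimilar units) for: %s",
                 paste(wide$molecule[no_price], collapse = ", ")))
  }
  rows <- savings_rows(wide, convention)
  if (!is.null(delta_override)) {
    rows <- rows |>
      left_join(rename(delta_override, override = "delta"), by = "molecule") |>
      mutate(delta = ifelse(is.na(.data$override), .data$delta,
                            .data$override)) |>
      select(-"override")
  }
  detail <- finish_savings(rows) |> arrange(.data$molecule)
  warn_negative_deltas(detail)
  new_biosim_savings(detail, scope = "national", convention = convention)
}

#' Unweighted cross-province mean price delta
#'
#' The simple (volume-unweighted) mean over regions of the per-region
#' originator-minus-biosimilar unit-price delta — an alternative national
#' summary delta to the pooled-price delta used by [savings_national()].
#' Regions where either product sold no units contribute no delta.
#'
#' @param regional A collapsed region-scope table from
#'   [collapse_purchases()].
#' @param pairing Brand pairing; default [default_pairing()].
#' @param convention Price-delta convention, see [discount()].
#' @return A tibble (`molecule`, `delta`) suitable for
#'   `savings_national(delta_override = )`.
#' @export
province_mean_delta <- function(regional, pairing = default_pairing(),
                                convention = c("cent_rounded", "exact")) {
  convention <- match.arg(convention)
  savings_rows(pair_totals(regional, pairing, extra = "region"),
               convention) |>
    filter(!is.na(.data$delta)) |>
    group_by(.data$molecule) |>
    summarise(delta = round_half_up(mean(.data$delta), 2), .groups = "drop")
}

#' Region-stratified savings summary
#'
#' The stratified-convention savings method: the originator/biosimilar
#' price delta is computed within each region before multiplying by that
#' region's biosimilar (realized) and originator (unrealized) units;
#' regional summaries are then summed. Regions where the biosimilar sold
#' no units have no local comparator price; by default the national pooled
#' delta for the molecule is substituted (`fallback = "national_delta"`),
#' and with `fallback = "skip_region"` such region-molecule cells are
#' dropped. Fallback use is reported.
#'
#' @param regional A collapsed region-scope table from
#'   [collapse_purchases()] (columns `region`, `molecule`, `brand`, `role`,
#'   `dollars`, `units`).
#' @param pairing Brand pairing; default [default_pairing()].
#' @param fallback Price source for regions without biosimilar sales.
#' @param convention Price-delta convention, see [discount()].
#' @return A `biosim_savings` object with per-region detail.
#' @export
savings_stratified <- function(regional, pairing = default_pairing(),
                               fallback = c("national_delta", "skip_region"),
                               convention = c("cent_rounded", "exact")) {
  fallback <- match.arg(fallback)
  convention <- match.arg(convention)
  wide <- pair_totals(regional, pairing, extra = "region")
  rows <- savings_rows(wide, convention)

  needs_fallback <- is.na(rows$delta)
  fallback_used <- tibble(region = rows$region[needs_fallback],
                          molecule = rows$molecule[needs_fallback])
  if (any(needs_fallback)) {
    if (fallback == "national_delta") {
      national <- regional |>
        group_by(.data$molecule, .data$brand, .data$role) |>
        summarise(dollars = sum(.data$dollars), units = sum(.data$units),
                  .groups = "drop")
      nat <- savings_rows(pair_totals(national, pairing), convention) |>
        select("molecule", national_delta = "delta")
      rows <- left_join(rows, nat, by = "molecule") |>
        mutate(delta = ifelse(is.na(.data$delta), .data$national_delta,
                              .data$delta)) |>
        select(-"national_delta")
      warn(sprintf(
        "substituted the national pooled delta in %d region-molecule cell(s) without biosimilar sales",
        nrow(fallback_used)))
    } else {
      rows <- rows[!needs_fallback, , drop = FALSE]
      warn(sprintf("skipped %d region-molecule cell(s) without biosimilar sales",
                   nrow(fallback_used)))
    }
  }
  detail <- finish_savings(rows) |> arrange(.data$region, .data$molecule)
  warn_negative_deltas(detail)
  new_biosim_savings(detail, scope = "region", convention = convention,
                     fallback = fallback_used)
}

#' Market-share scenario table
#'
#' Applies hypothetical biosimilar market shares to the full-conversion
#' potential (realized + unrealized savings) of each region: the cell for
#' fraction `f` and region `r` is `f` times region `r`'s potential, rounded
#' to whole dollars. A `TOTAL` row is appended as the sum of the region
#' cells; if the input already carries a `TOTAL` row (as the packaged
#' published table does) that row is scaled as given, with a warning when
#' it disagrees with the sum of the region rows.
#'
#' @param x A `biosim_savings` object with region scope, or a data frame
#'   with columns `region`, `realized`, `unrealized`.
#' @param fractions Market-share fractions in `(0, 1]`.
#' @return A tibble (class `biosim_scenario`) with columns `fraction`,
#'   `region`, `savings`.
#' @export
#' @examples
#' scenario_table(load_table2_fixture())
scenario_table <- function(x, fractions = c(0.25, 0.5, 0.75, 1)) {
  if (any(fractions <= 0 | fractions > 1)) {
    abort("market-share fractions must lie in (0, 1]")
  }
  if (inherits(x, "biosim_savings")) {
    if (!identical(x$scope, "region")) {
      abort("scenario tables need region-stratified savings")
    }
    x <- x$detail |>
      group_by(.data$region) |>
      summarise(realized = sum(.data$realized),
                unrealized = sum(.data$unrealized), .groups = "drop")
  }
  x <- as_tibble(x)
  stopifnot(all(c("region", "realized", "unrealized") %in% names(x)))
  x$potential <- x$realized + x$unrealized

  given_total <- x$region == "TOTAL"
  regions <- x[!given_total, , drop = FALSE]
  if (any(given_total)) {
    total_potential <- x$potential[given_total][1]
    if (abs(total_potential - sum(regions$potential)) > 0.5) {
      warn(sprintf(
        "TOTAL row potential ($%s) differs from the sum of region rows ($%s); scaling the TOTAL as given",
        format(total_potential, big.mark = ","),
        format(sum(regions$potential), big.mark = ",")))
    }
  }

  cells <- tidyr::expand_grid(fraction = fractions, region = regions$region) |>
    left_join(select(regions, "region", "potential"), by = "region") |>
    mutate(savings = round_half_up(.data$fraction * .data$potential)) |>
    select(-"potential")
  totals <- if (any(given_total)) {
    tibble(fraction = fractions, region = "TOTAL",
           savings = round_half_up(fractions * x$potential[given_total][1]))
  } else {
    cells |>
      group_by(.data$fraction) |>
      summarise(region = "TOTAL", savings = sum(.data$savings),
                .groups = "drop")
  }
  out <- bind_rows(cells, totals) |> arrange(.data$fraction)
  class(out) <- c("biosim_scenario", class(out))
  out
}

#' Eligibility sensitivity analysis
#'
#' Scales potential (unrealized) savings by the fraction of originator
#' units assumed clinically eligible for conversion to the biosimilar
#' (e.g. 0.8 if one in five patients is assumed unable to switch).
#'
#' @param unrealized Unrealized savings total (CAD).
#' @param eligible_fraction Fraction(s) in `[0, 1]`; vectorized.
#' @return `eligible_fraction * unrealized`, exact (no rounding).
#' @export
#' @examples
#' sensitivity_eligibility(1048663876, 0.8)
sensitivity_eligibility <- function(unrealized, eligible_fraction) {
  if (any(eligible_fraction < 0 | eligible_fraction > 1)) {
    abort("eligible fraction must lie in [0, 1]")
  }
  eligible_fraction * unrealized
}
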