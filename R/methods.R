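#' @export
print.biosim_savings <- function(x, ...) {
  cat(sprintf("<biosim_savings> scope: %s, delta convention: %s\n",
              x$scope, x$convention))
  print(as_tibble(x$detail), ...)
  g <- glance(x)
  cat(sprintf("TOTAL: realized $%s, unrealized $%s, potential $%s (%.1f%% realized)\n",
              format(g$realized, big.mark = ","),
              format(g$unrealized, big.mark = ","),
              format(g$potential, big.mark = ","),
              100 * g$percent_realized))
  invisible(x)
}

#' Tidy a savings summary
#'
#' One row per molecule (national scope) or per region-molecule cell
#' (region scope), with prices, the per-unit delta, relative discount,
#' realized and unrealized savings, full-conversion potential, and the
#' percent of potential realized.
#'
#' @param x A `biosim_savings` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.biosim_savings <- function(x, ...) {
  as_tibble(x$detail)
}

#' One-row totals for a savings summary
#'
#' @param x A `biosim_savings` object.
#' @param ... Unused.
#' @return A one-row tibble with `scope`, `convention`, `realized`,
#'   `unrealized`, `potential`, `percent_realized`, and `n_strata`.
#' @export
glance.biosim_savings <- function(x, ...) {
  d <- x$detail
  realized <- sum(d$realized, na.rm = TRUE)
  unrealized <- sum(d$unrealized, na.rm = TRUE)
  tibble(scope = x$scope, convention = x$convention,
         realized = realized, unrealized = unrealized,
         potential = realized + unrealized,
         percent_realized = realized / (realized + unrealized),
         n_strata = nrow(d))
}

#' Plot realized against unrealized savings
#'
#' Stacked bars of realized and unrealized (forgone) savings per molecule,
#' or per region for region-stratified summaries.
#'
#' @param object A `biosim_savings` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biosim_savings <- function(object, ...) {
  d <- object$detail
  by <- if (object$scope == "region") "region" else "molecule"
  long <- d |>
    select(dplyr::all_of(by), "realized", "unrealized") |>
    group_by(across(dplyr::all_of(by))) |>
    summarise(across(c("realized", "unrealized"), ~ sum(.x, na.rm = TRUE)),
              .groups = "drop") |>
    tidyr::pivot_longer(c("realized", "unrealized"),
                        names_to = "component", values_to = "savings")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[by]], y = .data$savings / 1e6,
                                     fill = .data$component)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Savings (CAD, millions)",
                  fill = NULL,
                  title = "Realized and unrealized biosimilar savings") +
    ggplot2::theme_minimal()
}

#' Plot a biosimilar uptake series
#'
#' Quarterly biosimilar share of purchases, one line per molecule.
#'
#' @param object A `biosim_uptake` tibble from [uptake_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.biosim_uptake <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$quarter, y = .data$share,
                                       colour = .data$molecule)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::scale_x_continuous(breaks = unique(object$quarter),
                                labels = unique(object$quarter_label)) +
    ggplot2::labs(x = NULL,
                  y = sprintf("Biosimilar share of %s", object$basis[1]),
                  colour = NULL,
                  title = "Quarterly biosimilar uptake") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
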