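#' Default region volume weights
#'
#' Approximate population-proportional purchase-volume weights for the nine
#' audit regions; they sum to 1.
#'
#' @return Named numeric vector over [cdh_regions()].
#' @export
default_region_weights <- function() {
  c(BC = 0.135, AB = 0.115, SK = 0.032, MB = 0.037, ON = 0.385,
    QC = 0.230, NB = 0.022, NS = 0.027, `PEI/NL` = 0.017)
}

default_molecules <- function() {
  list(
    `insulin glargine` = list(
      originator_brand = "Lantus", biosimilar_brand = "Basaglar",
      form = "cartridge", strength = "100 U/mL",
      base_price = 19.26, discount = 0.211, monthly_units = 331134,
      uptake_start = 0.018, uptake_end = 0.148, uptake_shape = "linear",
      region_multipliers = NULL),
    filgrastim = list(
      originator_brand = "Neupogen", biosimilar_brand = "Grastofil",
      form = "syringe", strength = "300 mcg",
      base_price = 197.53, discount = 0.178, monthly_units = 58990,
      uptake_start = 0.015, uptake_end = 0.436, uptake_shape = "linear",
      region_multipliers = NULL),
    infliximab = list(
      originator_brand = "Remicade", biosimilar_brand = "Inflectra",
      form = "vial", strength = "100 mg",
      base_price = 1001.07, discount = 0.448, monthly_units = 94075,
      uptake_start = 0.003, uptake_end = 0.034, uptake_shape = "linear",
      region_multipliers = NULL)
  )
}

#' Configuration for the synthetic purchase-audit generator
#'
#' Describes a market the generator will emulate: region volume weights, a
#' study window, per-molecule economics (originator base unit price in CAD,
#' biosimilar discount fraction, total units purchased per month, an uptake
#' trajectory for the biosimilar unit share, optional per-region price
#' multipliers), multiplicative lognormal price noise (as a coefficient of
#' variation), negative-binomial dispersion on unit counts, the fraction of
#' units flowing through the drugstore (vs hospital) sector, and a seed.
#'
#' Defaults mirror the national market under study: nine regions with
#' population-like weights, July 2016 to June 2018, and the three molecule
#' pairs at their pooled national prices, discounts, monthly volumes and
#' start/end uptake shares.
#'
#' @param regions Named numeric vector of region volume weights summing
#'   to 1.
#' @param window A [study_window()].
#' @param molecules Named list (by molecule) of lists with fields
#'   `originator_brand`, `biosimilar_brand`, `form`, `strength`,
#'   `base_price` (CAD/unit, > 0), `discount` (fraction in `[0, 1)`),
#'   `monthly_units` (positive integer), `uptake_start`, `uptake_end`
#'   (shares in `[0, 1]`), `uptake_shape` (`"linear"` or `"logistic"`), and
#'   optional `region_multipliers` (positive, named by region; default
#'   all 1).
#' @param price_cv Coefficient of variation of multiplicative lognormal
#'   price noise; 0 means deterministic prices.
#' @param unit_dispersion Negative-binomial dispersion of unit counts
#'   around their expectation; 0 means deterministic counts (largest-
#'   remainder rounding, conserving configured totals exactly).
#' @param sector_split Fraction of units purchased through the drugstore
#'   sector, in `[0, 1]`.
#' @param seed Integer seed; identical configurations and seeds generate
#'   identical data.
#' @return A validated `synth_config` object.
#' @export
#' @examples
#' cfg <- synth_config(seed = 42)
#' head(generate_purchases(cfg))
synth_config <- function(regions = default_region_weights(),
                         window = study_window(),
                         molecules = default_molecules(),
                         price_cv = 0.05,
                         unit_dispersion = 0.1,
                         sector_split = 0.7,
                         seed = 20160701) {
  bad <- function(field, why) {
    abort(sprintf("invalid synth_config field `%s`: %s", field, why))
  }
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    bad("regions", "must be a named weight vector")
  }
  if (any(regions < 0) || abs(sum(regions) - 1) > 1e-9) {
    bad("regions", "weights must be non-negative and sum to 1")
  }
  if (!inherits(window, "study_window")) bad("window", "must be a study_window")
  if (length(molecules) == 0 || is.null(names(molecules))) {
    bad("molecules", "must be a non-empty named list")
  }
  for (mol in names(molecules)) {
    m <- molecules[[mol]]
    chk <- function(cond, field, why) {
      if (!cond) bad(paste0("molecules$`", mol, "`$", field), why)
    }
    chk(is.numeric(m$base_price) && m$base_price > 0, "base_price", "must be > 0")
    chk(is.numeric(m$discount) && m$discount >= 0 && m$discount < 1,
        "discount", "must lie in [0, 1)")
    chk(is.numeric(m$monthly_units) && m$monthly_units >= 1 &&
          m$monthly_units == floor(m$monthly_units),
        "monthly_units", "must be a positive integer")
    for (f in c("uptake_start", "uptake_end")) {
      chk(is.numeric(m[[f]]) && m[[f]] >= 0 && m[[f]] <= 1, f,
          "must lie in [0, 1]")
    }
    chk(m$uptake_shape %in% c("linear", "logistic"), "uptake_shape",
        "must be \"linear\" or \"logistic\"")
    if (!is.null(m$region_multipliers)) {
      chk(all(names(regions) %in% names(m$region_multipliers)) &&
            all(m$region_multipliers > 0),
          "region_multipliers", "must be positive and cover every region")
    }
    for (f in c("originator_brand", "biosimilar_brand", "form", "strength")) {
      chk(is.character(m[[f]]) && nzchar(m[[f]]), f, "must be a non-empty string")
    }
  }
  if (!is.numeric(price_cv) || price_cv < 0) bad("price_cv", "must be >= 0")
  if (!is.numeric(unit_dispersion) || unit_dispersion < 0) {
    bad("unit_dispersion", "must be >= 0")
  }
  if (!is.numeric(sector_split) || sector_split < 0 || sector_split > 1) {
    bad("sector_split", "must lie in [0, 1]")
  }
  if (!is.numeric(seed) || seed != floor(seed)) bad("seed", "must be an integer")
  structure(list(regions = regions, window = window, molecules = molecules,
                 price_cv = price_cv, unit_dispersion = unit_dispersion,
                 sector_split = sector_split, seed = as.integer(seed)),
            class = "synth_config")
}

# uptake share per month index (0-based) over T months
uptake_share <- function(s0, s1, shape, T) {
  if (T == 1) return(s0)
  if (shape == "linear") {
    s0 + (s1 - s0) * (seq_len(T) - 1) / (T - 1)
  } else {
    x <- seq(-6, 6, length.out = T)
    g <- 1 / (1 + exp(-x))
    s0 + (s1 - s0) * (g - g[1]) / (g[T] - g[1])
  }
}

# deterministic 31-bit substream seed from labels, so per-cell draws do not
# shift when unrelated regions or molecules are added
substream_seed <- function(seed, ...) {
  s <- paste(c(seed, ...), collapse = "\r")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Generate synthetic purchase-audit records
#'
#' Emits one record per (region, sector, month, product). Biosimilar unit
#' share in month t follows the configured uptake curve; expected biosimilar
#' unit price is the originator base price times the region multiplier times
#' (1 - discount); unit counts are split across products, regions and
#' sectors by largest-remainder apportionment (exactly conserving the
#' configured monthly totals) and, when `unit_dispersion > 0`, resampled
#' from a negative binomial around that expectation. Dollars are the
#' realized cent-rounded unit price times units. Each (region, month,
#' product) cell draws from its own deterministic substream of `seed`.
#'
#' @param config A [synth_config()].
#' @return A validated tibble of purchase records.
#' @export
generate_purchases <- function(config) {
  if (!inherits(config, "synth_config")) {
    abort("`config` must be a synth_config object")
  }
  months <- window_months(config$window)
  n_months <- length(months)
  regions <- names(config$regions)
  n_regions <- length(regions)
  size <- if (config$unit_dispersion > 0) 1 / config$unit_dispersion else Inf
  sdlog <- sqrt(log(1 + config$price_cv^2))

  blocks <- vector("list", length(config$molecules) * n_months * 2L)
  b <- 0L
  for (mol in names(config$molecules)) {
    m <- config$molecules[[mol]]
    mult <- if (is.null(m$region_multipliers)) rep(1, n_regions) else
      as.numeric(m$region_multipliers[regions])
    shares <- uptake_share(m$uptake_start, m$uptake_end, m$uptake_shape, n_months)
    for (t in seq_len(n_months)) {
      split_units <- apportion(m$monthly_units, c(shares[t], 1 - shares[t]))
      for (p in 1:2) {
        role <- c("biosimilar", "originator")[p]
        brand <- if (role == "biosimilar") m$biosimilar_brand else m$originator_brand
        price0 <- m$base_price * (if (role == "biosimilar") 1 - m$discount else 1)
        runits <- apportion(split_units[p], config$regions)
        price <- numeric(n_regions)
        sunits <- matrix(0, nrow = n_regions, ncol = 2)
        for (r in seq_len(n_regions)) {
          # one substream per (region, month, product) cell
          set.seed(substream_seed(config$seed, mol, brand, regions[r], months[t]))
          pr <- price0 * mult[r]
          if (config$price_cv > 0) {
            pr <- pr * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
          }
          price[r] <- round_half_up(pr, 2)
          mu <- apportion(runits[r], c(config$sector_split,
                                       1 - config$sector_split))
          if (is.finite(size)) {
            mu[1] <- if (mu[1] == 0) 0 else stats::rnbinom(1, size = size, mu = mu[1])
            mu[2] <- if (mu[2] == 0) 0 else stats::rnbinom(1, size = size, mu = mu[2])
          }
          sunits[r, ] <- mu
        }
        u <- as.vector(t(sunits))
        b <- b + 1L
        blocks[[b]] <- tibble(
          region = rep(regions, each = 2L),
          sector = rep(purchase_sectors(), n_regions),
          month = months[t],
          molecule = mol, brand = brand, role = role,
          form = m$form, strength = m$strength,
          dollars = round_half_up(rep(price, each = 2L) * u, 2),
          units = u
        )
      }
    }
  }
  records <- bind_rows(blocks)
  validate_purchases(records, window = config$window,
                     regions = names(config$regions))
  records
}

#' Deterministic data calibrated to the packaged national aggregates
#'
#' Produces full purchase records (regions x sectors x months) whose
#' national product totals restore the packaged aggregates of
#' [load_table1_fixture()] exactly. Units, then dollars (in cents), are
#' spread by largest-remainder apportionment over a fixed region x month x
#' sector weight grid, so the full aggregation code path is exercised while
#' re-aggregation reproduces every published dollar and unit figure.
#'
#' @param scenario Scenario label; only `"table1_national"` is defined.
#' @return A validated tibble of purchase records.
#' @export
#' @examples
#' rec <- generate_paperlike()
#' sum(rec$dollars)  # restores the published grand total
generate_paperlike <- function(scenario = "table1_national") {
  if (!identical(scenario, "table1_national")) {
    abort(sprintf("unknown scenario: %s", scenario))
  }
  fixture <- load_table1_fixture()
  months <- window_months(study_window())
  weights <- default_region_weights()
  grid <- expand.grid(region = names(weights), month = months,
                      sector = purchase_sectors(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  w <- weights[grid$region] * ifelse(grid$sector == "drugstore", 0.7, 0.3)

  out <- purrr::pmap(fixture, function(molecule, brand, role, form, strength,
                                       dollars, units) {
    u <- apportion(units, w)
    cents <- apportion(dollars * 100, u)
    tibble(region = grid$region, sector = grid$sector, month = grid$month,
           molecule = molecule, brand = brand, role = role,
           form = form, strength = strength,
           dollars = cents / 100, units = u)
  })
  records <- bind_rows(out) |> filter(.data$units > 0 | .data$dollars > 0)
  validate_purchases(records)
  records
}
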