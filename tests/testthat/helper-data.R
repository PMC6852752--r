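# small in-code fixtures shared across tests

# a single purchase record with sensible defaults; override any field
rec <- function(region = "ON", sector = "drugstore", month = "2016-07",
                molecule = "filgrastim", brand = "Neupogen",
                role = "originator", form = "syringe", strength = "300 mcg",
                dollars = 100, units = 10) {
  tibble::tibble(region = region, sector = sector, month = month,
                 molecule = molecule, brand = brand, role = role,
                 form = form, strength = strength,
                 dollars = dollars, units = units)
}

# both products of one molecule in one cell, at given unit prices
pair_recs <- function(region = "ON", month = "2016-07",
                      orig_price = 10, bio_price = 8,
                      orig_units = 100, bio_units = 50,
                      molecule = "filgrastim",
                      orig_brand = "Neupogen", bio_brand = "Grastofil",
                      sector = "drugstore") {
  dplyr::bind_rows(
    rec(region = region, month = month, sector = sector,
        molecule = molecule, brand = orig_brand, role = "originator",
        dollars = orig_price * orig_units, units = orig_units),
    rec(region = region, month = month, sector = sector,
        molecule = molecule, brand = bio_brand, role = "biosimilar",
        dollars = bio_price * bio_units, units = bio_units))
}

# single-molecule generator configuration on a whole-cent price grid
one_mol_config <- function(seed = 1, price_cv = 0, unit_dispersion = 0,
                           base_price = 200, discount = 0.2,
                           monthly_units = 10000,
                           uptake_start = 0.1, uptake_end = 0.5,
                           uptake_shape = "linear",
                           region_multipliers = NULL, ...) {
  synth_config(
    price_cv = price_cv, unit_dispersion = unit_dispersion, seed = seed,
    molecules = list(filgrastim = list(
      originator_brand = "Neupogen", biosimilar_brand = "Grastofil",
      form = "syringe", strength = "300 mcg",
      base_price = base_price, discount = discount,
      monthly_units = monthly_units,
      uptake_start = uptake_start, uptake_end = uptake_end,
      uptake_shape = uptake_shape,
      region_multipliers = region_multipliers)),
    ...)
}

# split every record with >= 2 units into two records at the same implied
# unit price (prices must be whole cents, so the split is exact)
split_same_price <- function(records) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (r$units < 2) return(r)
    price_cents <- round(r$dollars * 100) / r$units
    stopifnot(price_cents == round(price_cents))
    w <- r$units %/% 2
    a <- r; a$units <- w; a$dollars <- price_cents * w / 100
    b <- r; b$units <- r$units - w; b$dollars <- r$dollars - a$dollars
    dplyr::bind_rows(a, b)
  })
  dplyr::bind_rows(out)
}

expect_savings_close <- function(actual, expected, tol) {
  expect_true(all(abs(actual - expected) <= tol),
              label = sprintf("savings %s within $%s of %s",
                              paste(actual, collapse = ","), tol,
                              paste(expected, collapse = ",")))
}
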