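test_that("collapsing sums additively over sectors and months", {
  records <- dplyr::bind_rows(
    rec(sector = "drugstore", dollars = 10, units = 1),
    rec(sector = "hospital", dollars = 20, units = 2))
  out <- collapse_purchases(records)
  expect_equal(nrow(out), 1)
  expect_equal(out$dollars, 30)
  expect_equal(out$units, 3)
})

test_that("the packaged aggregates collapse to their own totals", {
  out <- collapse_purchases(load_table1_fixture())
  lantus <- out[out$brand == "Lantus", ]
  expect_equal(lantus$dollars, 141135286)
  expect_equal(lantus$units, 7328068)
})

test_that("quarters are window-anchored three-month blocks", {
  q <- quarter_of(c("2016-07", "2016-09", "2016-10", "2018-06"))
  expect_equal(q$quarter, c(1L, 1L, 2L, 8L))
  expect_equal(q$quarter_label, c("2016Q3", "2016Q3", "2016Q4", "2018Q2"))
  # total and disjoint: every in-window month maps to exactly one quarter
  months <- sort(unique(generate_purchases(synth_config(seed = 2))$month))
  qq <- quarter_of(months)
  expect_equal(nrow(qq), 24)
  expect_equal(as.integer(table(qq$quarter)), rep(3L, 8))
  expect_error(quarter_of("2016-06"), "outside the study window")
})

test_that("unit price is the exact dollars/units quotient", {
  expect_equal(round(unit_price(141135286, 7328068), 2), 19.26)
  expect_equal(round(unit_price(9402061, 619155), 2), 15.19)
  expect_equal(unit_price(42.42, 1), 42.42)
  expect_error(unit_price(10, 0), "undefined")
})

test_that("national pooled price equals the units-weighted mean of region prices", {
  records <- generate_purchases(synth_config(
    seed = 9, price_cv = 0.1, unit_dispersion = 0.2))
  regional <- collapse_purchases(records, scope = "region")
  national <- collapse_purchases(records, scope = "national")
  pooled <- regional |>
    dplyr::mutate(price = dollars / units) |>
    dplyr::group_by(molecule, brand, role) |>
    dplyr::summarise(price = sum(price * units) / sum(units),
                     .groups = "drop")
  joined <- dplyr::inner_join(national, pooled,
                              by = c("molecule", "brand", "role"))
  expect_equal(joined$dollars / joined$units, joined$price)
})

test_that("uptake share is 0.5 when biosimilar and originator volumes match", {
  records <- dplyr::bind_rows(lapply(sprintf("2016-%02d", 7:12), function(m) {
    pair_recs(month = m, orig_units = 40, bio_units = 40,
              orig_price = 10, bio_price = 10)
  }))
  up <- uptake_series(records, basis = "units")
  expect_equal(up$share, rep(0.5, 2))
})

test_that("quarters with no purchases are omitted with a message", {
  records <- pair_recs(month = "2016-07", orig_units = 10, bio_units = 0,
                       bio_price = 1)
  records$dollars[records$role == "biosimilar"] <- 0
  # originator only in Q1; nothing at all in later quarters -> only Q1 reported
  up <- uptake_series(records, basis = "units")
  expect_equal(up$quarter, 1L)
  expect_equal(up$share, 0)
})

test_that("region scope requires regional columns", {
  expect_error(collapse_purchases(load_table1_fixture(), scope = "region"),
               "region")
  expect_error(collapse_purchases(load_table1_fixture(), period = "quarter"),
               "month")
})
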