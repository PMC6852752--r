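test_that("published per-unit discounts emerge from cent-rounded prices", {
  d <- discount(c(141135286 / 7328068, 204152590 / 1033508,
                  2192819808 / 2190467),
                c(9402061 / 619155, 62061576 / 382254, 37202503 / 67330))
  expect_equal(d$delta, c(4.07, 35.17, 448.53))
  expect_equal(round(100 * d$percent, 1), c(21.1, 17.8, 44.8))
})

test_that("equal prices give zero discount; bad prices are domain errors", {
  d <- discount(19.26, 19.26, convention = "exact")
  expect_equal(d$delta, 0)
  expect_equal(d$percent, 0)
  expect_error(discount(0, 1), "positive")
  expect_error(discount(10, -1), "positive")
})

test_that("national savings on the packaged aggregates match published cells", {
  s <- load_table1_fixture() |>
    collapse_purchases() |>
    savings_national()
  d <- tidy(s)
  get <- function(mol, col) d[[col]][d$molecule == mol]
  # filgrastim row is exact; the others differ only in the published
  # last-dollar rounding
  expect_equal(get("filgrastim", "realized"), 13443873)
  expect_equal(get("filgrastim", "unrealized"), 36348476)
  expect_savings_close(get("insulin glargine", "realized"), 2519961, 2)
  expect_savings_close(get("insulin glargine", "unrealized"), 29825236, 2)
  expect_savings_close(get("infliximab", "realized"), 30199524, 2)
  expect_savings_close(get("infliximab", "unrealized"), 982490164, 2)
  g <- glance(s)
  expect_savings_close(g$realized, 46163358, 5)
  expect_savings_close(g$unrealized, 1048663876, 5)
})

test_that("zero originator units yield zero unrealized savings", {
  records <- pair_recs(orig_units = 0, bio_units = 50)
  records$dollars[records$role == "originator"] <- 0
  s <- suppressWarnings(savings_national(collapse_purchases(records)))
  expect_equal(tidy(s)$unrealized, 0)
})

test_that("a molecule whose biosimilar never sold is flagged, not priced", {
  records <- pair_recs(bio_units = 0, bio_price = 1)
  records$dollars[records$role == "biosimilar"] <- 0
  expect_warning(s <- savings_national(collapse_purchases(records)),
                 "no comparator price")
  expect_equal(tidy(s)$realized, 0)
  expect_true(is.na(tidy(s)$unrealized))
})

test_that("negative deltas are preserved with a warning, never clamped", {
  records <- pair_recs(orig_price = 8, bio_price = 10)
  expect_warning(s <- savings_national(collapse_purchases(records)),
                 "priced above")
  expect_equal(tidy(s)$delta, -2)
  expect_equal(tidy(s)$realized, -2 * 50)
  expect_equal(tidy(s)$unrealized, -2 * 100)
})

test_that("stratified savings on a single region equal the national method", {
  records <- generate_purchases(one_mol_config(
    seed = 4, price_cv = 0.05, regions = c(ON = 1)))
  national <- savings_national(collapse_purchases(records))
  stratified <- savings_stratified(collapse_purchases(records,
                                                      scope = "region"))
  for (col in c("delta", "realized", "unrealized", "potential")) {
    expect_equal(tidy(stratified)[[col]], tidy(national)[[col]])
  }
})

test_that("region deltas multiply region volumes; pooling differs as the oracle says", {
  records <- dplyr::bind_rows(
    pair_recs(region = "ON", orig_price = 10, bio_price = 8,
              orig_units = 100, bio_units = 50),
    pair_recs(region = "QC", orig_price = 20, bio_price = 16,
              orig_units = 100, bio_units = 50))
  stratified <- savings_stratified(collapse_purchases(records,
                                                      scope = "region"))
  expect_equal(glance(stratified)$unrealized, 2 * 100 + 4 * 100)
  pooled <- savings_national(collapse_purchases(records))
  want <- oracle_savings(records, level = "national")
  expect_equal(glance(pooled)$unrealized, sum(want$unrealized))
  expect_equal(glance(pooled)$realized, sum(want$realized))
})

test_that("regions without biosimilar sales fall back to the national delta", {
  records <- dplyr::bind_rows(
    pair_recs(region = "ON", orig_price = 10, bio_price = 8,
              orig_units = 100, bio_units = 50),
    rec(region = "SK", role = "originator", dollars = 12 * 80, units = 80))
  regional <- collapse_purchases(records, scope = "region")
  expect_warning(s <- savings_stratified(regional), "national pooled delta")
  d <- tidy(s)
  # national pooled prices: originator (10*100 + 12*80)/180 = 10.89 (cents),
  # biosimilar 8.00, so the fallback delta is 2.89
  expect_equal(d$delta[d$region == "SK"], 2.89)
  expect_equal(d$unrealized[d$region == "SK"], round(2.89 * 80))
  expect_equal(nrow(s$fallback), 1)

  expect_warning(skip <- savings_stratified(regional,
                                            fallback = "skip_region"),
                 "skipped")
  expect_false("SK" %in% tidy(skip)$region)
})

test_that("the cross-province mean delta is the unweighted mean of region deltas", {
  records <- dplyr::bind_rows(
    pair_recs(region = "ON", orig_price = 10, bio_price = 8,
              orig_units = 300, bio_units = 100),
    pair_recs(region = "QC", orig_price = 20, bio_price = 16,
              orig_units = 100, bio_units = 100))
  regional <- collapse_purchases(records, scope = "region")
  pm <- province_mean_delta(regional)
  expect_equal(pm$delta, (2 + 4) / 2)
  national <- collapse_purchases(records)
  s <- savings_national(national, delta_override = pm)
  expect_equal(tidy(s)$unrealized, 3 * 400)
  # pooled delta differs: originator (10*300+20*100)/400 = 12.50, biosimilar
  # (8*100+16*100)/200 = 12.00
  expect_equal(tidy(savings_national(national))$delta, 0.5)
})
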