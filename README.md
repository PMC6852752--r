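# biosimsavings

Biosimilar drugs sell at a discount to the originator biologics they copy,
but their uptake is often slow, so health systems forgo large savings.
`biosimsavings` turns drugstore/hospital purchase-audit records — dollars
and units per region, sector, month and product — into the standard
budget-impact quantities used to measure that gap:

- **unit prices** within a stratum, `price = dollars / units`;
- the per-unit **price delta** `Δ = p_originator − p_biosimilar` and
  relative discount `Δ / p_originator`;
- **realized savings** `Δ × units_biosimilar` (what biosimilar purchases
  actually saved) and **unrealized savings** `Δ × units_originator` (what
  full substitution would additionally have saved), under two
  stratification conventions — prices pooled nationally, or computed per
  province before summing;
- **relative market-share scenarios** `f × (realized + unrealized)` for
  `f` = 25–100%, and an **eligibility sensitivity** scaling potential
  savings by the fraction of originator units assumed clinically
  convertible;
- quarterly **biosimilar uptake shares** on a units or dollars basis.

It ships the published national aggregates for the three Canadian
originator/biosimilar pairs of 2016–2018 — Remicade/Inflectra
(infliximab), Lantus/Basaglar (insulin glargine) and Neupogen/Grastofil
(filgrastim) — as a packaged fixture, plus a synthetic purchase-audit
generator (configurable uptake curves, discounts, regional weights,
lognormal price noise, negative-binomial count noise) so the whole
pipeline is testable without proprietary audit data.

Intended users: pharmacoeconomists, drug-plan analysts and
health-services researchers working with purchase or claims audit tables.

## Worked example

```r
library(biosimsavings)

res <- run_pipeline(fixture = "table1")
tidy(res$national)[, c("molecule", "delta", "realized", "unrealized")]
#> # A tibble: 3 × 4
#>   molecule          delta realized unrealized
#>   <chr>             <dbl>    <dbl>      <dbl>
#> 1 filgrastim        35.2  13443873   36348476
#> 2 infliximab       449.   30199525  982490164
#> 3 insulin glargine   4.07  2519961   29825237

glance(res$national)
#> # A tibble: 1 × 7
#>   scope    convention   realized unrealized  potential percent_realized n_strata
#>   <chr>    <chr>           <dbl>      <dbl>      <dbl>            <dbl>    <int>
#> 1 national cent_rounded 46163359 1048663877 1094827236           0.0422        3

res$sensitivity
#> # A tibble: 2 × 2
#>   eligible_fraction  unrealized
#>               <dbl>       <dbl>
#> 1               0.8  838931102.
#> 2               1   1048663877
```

Reading: over the two-year window the three biosimilars saved about
$46.2M (4.2% of the $1.09B full-conversion potential); had every
originator unit been switched, a further ~$1.049B would have been saved,
or ~$838.9M if only 80% of units were clinically eligible. The per-unit
deltas correspond to discounts of 21.1% (insulin glargine), 17.8%
(filgrastim) and 44.8% (infliximab).

Synthetic data work the same way:

```r
records <- generate_purchases(synth_config(seed = 42))
map <- build_comparator_map(records)
savings_stratified(collapse_purchases(records, map, scope = "region")) |>
  glance()
autoplot(uptake_series(records, map, basis = "dollars"))
```

A thin CLI wraps the same functions
(`Rscript inst/cli/biosim.R <generate|analyze|reproduce-table1> ...`).

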