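---
title: "Estimating biosimilar cost savings from purchase-audit data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating biosimilar cost savings from purchase-audit data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biosimsavings)
```

## The problem and the model

When a biosimilar enters a market it typically sells below the originator
biologic it references. Purchase audits — projected estimates of the
dollars spent and units bought by drugstores and hospitals, per region and
month — let us quantify both what the biosimilar's uptake actually saved
and what full substitution would have saved. The model is deliberately
simple accounting, not a behavioural or forecasting model:

1. **Unit price.** Within a stratum (a product within a region or the
   whole country, over a period), `price = total dollars / total units`.
   Audit "units" are only comparable between an originator and its
   biosimilar within a matched dosage form and strength, so originator
   keys with no biosimilar counterpart on the market are excluded from
   price and savings calculations (they can contribute no substitution
   savings); their dollars are reported, never silently discarded.
2. **Price delta.** `Δ = p_originator − p_biosimilar` per unit, with the
   relative discount `Δ / p_originator`. A negative Δ (biosimilar dearer)
   is propagated with a warning, never clamped.
3. **Savings.** `realized = Δ × units_biosimilar` — savings already
   obtained through biosimilar purchases — and
   `unrealized = Δ × units_originator` — what converting the remaining
   originator volume would additionally have saved. Their sum is the
   full-conversion potential; `realized / potential` is the percent of
   potential realized.
4. **Scenarios and sensitivity.** A relative market-share scenario scales
   the potential linearly: the cell for fraction `f` and region `r` is
   `f × potential_r`. The eligibility sensitivity scales unrealized
   savings by the fraction of originator units assumed clinically
   convertible (default cases 0.8 and 1).
5. **Uptake.** The biosimilar share of purchases,
   `biosimilar / (biosimilar + originator)`, per quarter, on a units or
   dollars basis.

Assumptions inherited from this design: originator and biosimilar are
therapeutically interchangeable for the eligible fraction; audit prices
(which exclude confidential rebates and purchase agreements) proxy real
prices; purchases proxy utilisation; no discounting over time is applied
(the window is a fixed two-year cross-section); no seasonality, inflation
or currency adjustment.

## Aggregation conventions

Two conventions appear in published summaries, and both are implemented
and always reportable:

- **Pooled** (`savings_national()`): prices are computed from dollars and
  units pooled over all regions and sectors, giving one national Δ per
  molecule. The national pooled price is identically the units-weighted
  mean of region prices.
- **Stratified** (`savings_stratified()`): Δ is computed within each
  region, multiplied by that region's volumes, then summed. The two
  conventions differ whenever regional prices and uptake are correlated,
  and their totals differ in practice by a small amount that the package
  surfaces rather than hides.

Two further choices are genuinely open and resolved as follows:

- *Sectors* (drugstore vs hospital) are pooled **before** unit-price
  calculation — the convention that reproduces the published national
  prices — with `by_sector = TRUE` available for exploration.
- A national summary Δ could also be the **unweighted cross-province
  mean** of region deltas rather than the pooled-price delta. The pooled
  delta is the default because it reproduces the published national cells
  from the printed inputs; `province_mean_delta()` provides the
  alternative via `savings_national(delta_override = )`.
- In region-stratified savings, a region where the biosimilar sold no
  units has no local comparator price. The default fallback substitutes
  the national pooled Δ (`fallback = "national_delta"`), since potential
  savings exist wherever the originator sold; `"skip_region"` drops such
  cells instead. Fallback use is always reported.

## Numerical conventions

- Dollars are validated to be a whole number of cents and units whole
  counts; the CSV writer emits two-decimal dollars so a write/read round
  trip is exact.
- Prices are carried at full precision internally. The default
  `"cent_rounded"` delta convention rounds each price to the cent before
  differencing, because published savings cells are recoverable only from
  cent-rounded deltas; `"exact"` is available and is what parameter-
  recovery tests use.
- Final savings figures round half-away-from-zero to whole dollars
  (`round()`'s half-to-even would not reproduce published cells).
  Published tables mix truncation and rounding in the last dollar, so
  reproduction tests allow ±$2 per cell and ±$5 on totals.
- Scenario tables append a `TOTAL` row equal to the sum of the region
  rows. If the input itself carries a `TOTAL` row — the packaged
  region-savings table does, and its printed province cells do *not* sum
  to its printed total (the gap is ≈ $1.3M on the full-conversion
  potential) — that row is scaled as given and the discrepancy is
  reported with a warning. Published headline shares are also internally
  ambiguous at one decimal (a "4.2%" can be read as the biosimilar dollar
  share or the realized share of potential); the package reports the two
  quantities separately (`make_uptake_report()` on a dollars basis, and
  `percent_realized` in `glance()`) and leaves interpretation to the
  analyst.
- Quarters are window-anchored consecutive 3-month blocks (quarter 1 =
  July–September 2016 under the default window), labelled by the calendar
  quarter of their first month.

## The synthetic generator

`synth_config()` / `generate_purchases()` emulate the structure the
analysis assumes: 9 regions with volume weights, 24 months, per-molecule
originator base price, discount fraction `d`, monthly unit totals, and a
monotone uptake trajectory (linear or logistic between a start and end
share). Defaults are the national market under study: base prices and
discounts set to the pooled published values (e.g. $1001.07 and 44.8% for
infliximab), monthly volumes equal to the published two-year totals
divided by 24, uptake start/end shares taken from the published first- and
last-quarter dollar shares, a 70/30 drugstore/hospital split, and
population-like region weights.

Noise model (the audit's own sampling error is proprietary, so the
generator must state one): multiplicative lognormal price noise with a
given coefficient of variation (default 0.05), and negative-binomial unit
counts around the expected split (dispersion default 0.1); both are
non-negative by construction. At zero noise, expected counts are
apportioned by largest remainder, so configured monthly totals are
conserved *exactly* and the configured discount is recovered *exactly*
from the pooled data whenever the base and discounted prices are whole
cents — the price grid the recovery tests use. Each
(region, month, product) cell draws from its own hash-derived substream
of the seed, so adding a region or molecule does not perturb the draws of
existing cells, and identical configurations and seeds are byte-identical.

`generate_paperlike("table1_national")` instead distributes the packaged
published aggregates deterministically over the full region × month ×
sector grid (units first, then dollars in cents, both by largest
remainder), so aggregation code paths are exercised on data whose national
totals restore the published figures exactly.

What passing tests on synthetic data do **not** show about real audits:
real price dispersion is not lognormal i.i.d. (tenders and listing
agreements move prices in steps), uptake is not smooth (formulary
decisions cause jumps), region volumes are not a fixed multinomial split,
and audited "units" can change definition across presentations. The
generator is a test harness for the accounting pipeline, not a market
simulator.

## Problem sizes and test design

The packaged national analysis is desk-scale (six aggregate rows).
Synthetic property checks use one-molecule markets of 10,000 units/month
across 9 regions and 24 months (864 records per dataset): exact discount
recovery at zero noise; recovery within ±0.02 in at least 95% of 200
seeded replicates at 5% price noise; conservation and scenario/eligibility
linearity; invariance of every downstream quantity under splitting records
at constant unit price; and agreement of both savings conventions with an
independent per-record enumeration oracle to within $1 per molecule.

## Limitations

Savings here are purchase-side upper bounds: confidential rebates shrink
real deltas; audit intake overstates dispensed volume; eligibility is a
single scalar, not a patient-level model; and no behavioural response
(price changes under competition, prescriber switching dynamics) is
modelled. Region-stratified results inherit whatever projection the audit
used to allocate purchases to regions.
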