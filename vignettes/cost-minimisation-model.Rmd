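---
title: "A staged cost-minimisation model of MRgFUS versus unilateral DBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A staged cost-minimisation model of MRgFUS versus unilateral DBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorcma)
```

## The decision problem

Medication-refractory essential tremor can be treated by MR-guided
focussed ultrasound (MRgFUS) thalamotomy or by unilateral deep brain
stimulation (DBS). Clinical evidence indicates equivalent tremor relief
over 12 months, so the economic comparison is a cost-minimisation
analysis: only direct healthcare costs matter, from the Japanese payer's
perspective, over a 12-month horizon. With a horizon that short,
discounting is immaterial and is not applied.

## Model structure and assumptions

Each procedure is costed in three stages — pre-procedure, procedure,
post-procedure — as sums of tariff line items
(`unit_cost` × `quantity`). Two probability-weighted downstream events
capture follow-on surgery within the horizon:

* **Re-treatment after MRgFUS.** 8.9% of MRgFUS patients experience
  tremor recurrence and 40% of those undergo a radiofrequency
  thalamotomy (RFT), giving an event weight of 0.0356 per index
  procedure.
* **Extraction after DBS.** Electrode extraction (breakage or infection)
  occurs in 1% of unilateral DBS procedures per year.

An event contributes `probability × total cost of the referenced
procedure`. The referenced procedures carry no events of their own (the
event tree has depth 1), and the expected event cost is allocated
entirely to the post-procedure stage: both re-treatment and extraction
happen after the index procedure, and published stage subtotals are
consistent with this allocation (only the totals constrain it). Event
probabilities enter as plain 12-month probabilities — no half-cycle
correction, matching the horizon's coarse granularity.

Hospitalisation is priced by a *day-indexed fee schedule* rather than a
flat per-diem: the published totals imply a non-constant marginal day
cost for the DBS post-procedure stay (≈17,077 JPY/day up to day 8,
20,410 JPY/day thereafter under FFS), so the schedule is
piecewise-constant over contiguous day ranges. All arithmetic is exact
double-precision JPY with no intermediate rounding; a single rendering
function (`round_jpy`, half away from zero) rounds to the nearest yen
only when tables are printed.

## Tariff scenarios

Small Japanese hospitals bill itemised **FFS** tariffs (the base case);
large hospitals use the DRG-style **DPC** per-diems. In the DPC scenario
an item is priced under its DPC row where the catalog declares one and
keeps its base price otherwise, which confines the substitution to
pre-procedure, post-procedure and day-of-procedure hospitalisation
prices; procedure fees, devices and drugs stay on FFS/drug-tariff
prices, and the extraction procedure remains FFS-priced (its derived
cost is identical under both published scenarios).

The **labour scenarios** add JHIFS (Gaihoren) hourly labour costs on top
of the medical totals, at 2016 or 2018 rates. Because a comparison of the
JHIFS tariff with the FFS fee schedule shows roughly 40% overestimation,
day-of-procedure labour is multiplied by a correction factor of 0.7;
pre-procedure labour is left uncorrected (a conservative choice, as it
applies only to MRgFUS). Labour for the probability-weighted RFT
re-treatment is included in the MRgFUS labour aggregate; extraction and
device-management labour for DBS is deliberately excluded (one-sided and
negligible). DBS labour is evaluated at a fixed 4-hour duration; only the
MRgFUS duration is varied in sensitivity analysis.

## Calibration: the linear-consistency oracle

The item-level input tables behind the published analysis (including the
JHIFS role-level rates) were never published; only stage subtotals,
labour aggregates and one-way sensitivity rows are available. The
calibrated input set (`calibrated_fixture()`) is therefore
*stage-granular* — one aggregate line item per procedure stage — and the
hidden constants are recovered at run time from the published aggregates:

* The model is affine in each event probability, so the RFT total is the
  slope of the line through the 0%-re-treatment total and the base-case
  total; likewise the extraction total from the 0% and 1% extraction
  rows, and the corrected hourly labour slope from the 2-hour and 4-hour
  labour-scenario totals.
* Published cells are integer-rounded, so a two-point slope is only
  known up to a band. `linear_consistency_oracle()` propagates each
  anchor's printing precision (±0.5 JPY for rounded cells; the 0%-event
  rows are taken as exact, since the fractional event term vanishes
  there) into a slope half-width, and snaps to the unique roundest value
  in the band — the largest power of ten with exactly one multiple
  inside it — reflecting that Japanese tariff amounts are round numbers.
  If no power of ten is unique the raw fit is kept. This yields an RFT
  total of 835,300 and an extraction total of 519,400 JPY under FFS
  (both snapped), an RFT total of ≈733,314.6 under DPC (raw fit), and a
  corrected labour slope of 206,997 JPY/hour.
* The MRgFUS 2018 labour aggregate splits into a duration-independent
  component of 102,989 JPY (pre-procedure preparation plus weighted RFT
  labour — not separable from published data) and the hourly slope. The
  2016 aggregates and the DBS 2018 aggregate cannot be decomposed at all
  and are stored as single duration-independent entries with the
  correction already embedded.

Every fixture value carries a `printed` or `derived` provenance tag, and
every derived constant reproduces at least one published cell that was
not used in its derivation (for example, the FFS RFT constant — fitted on
the 0% row and the base case — predicts the 10%-re-treatment total
exactly). These held-out reproductions are asserted in the test suite, so
the calibration genuinely tests the model rather than its own
bookkeeping.

Three published cells are internally inconsistent with their own row
totals (the DPC 2018-labour difference, the MRgFUS 2018-labour duration
column header cell, and the 2-day-hospitalisation difference). The
implementation follows the arithmetic implied by the totals in each case
and documents the discrepancy; the affected difference cells are treated
as unreliable.

## Deterministic sensitivity analysis

`run_one_way()` varies exactly one parameter — the re-treatment
proportion (0–10%), the extraction rate (0–2%), the DBS post-procedure
stay (2–10 days) or the MRgFUS duration (2–6 h, labour scenarios only) —
and rebuilds the scenario for every row rather than mutating shared
state, so rows are independent and order-insensitive. The difference is
affine in the two probabilities and in duration, but *not* assumed affine
in hospital days (the fee tiers make it piecewise-linear).
`tornado_summary()` ranks parameters by the span of the cost difference.

## Probabilistic sensitivity analysis

`run_psa()` samples every cost and quantity parameter from a
moment-matched gamma distribution (`shape = (mean/sd)²`,
`scale = sd²/mean`) and every percentage from a moment-matched beta
distribution, with SD equal to 20% of the base-case mean where no
empirical SD exists. Quantities are sampled as continuous gamma values
(the distribution's support is continuous and nothing forces integers);
the number of primary procedures itself is fixed at one per simulated
patient, while the associated hospitalisation and procedure-fee costs are
sampled. Parameters in a *linkage group* share the iteration's quantile
draw — used for tariff premiums, whose quantity equals the parent
activity's frequency, and for the pre-procedure bundle, which is declared
identical resource use in both arms.

Sampling is driven by one root seed from which an independent
sub-stream is derived per parameter (hash of the parameter id), so
results are bit-reproducible and adding a parameter does not perturb the
draws of the others. Draws are made by quantile transform of the
stream's uniforms, which also makes linked draws perfectly correlated.

Because moment matching preserves means and the model is affine in each
sampled parameter (with independent cost × probability products), the
PSA is unbiased for the deterministic base case; the suite asserts the
sample mean lies within three standard errors. The two arms are compared
with a two-tailed t-test at the 1% level after an F-test
variance-homogeneity check; with per-parameter SDs of 20%, the DBS arm's
absolute spread genuinely exceeds the MRgFUS arm's, so the
homogeneity check typically fails and the implementation falls back to
the Welch test with a logged warning (the pooled test gives the same
conclusion, and both are reported in the acceptance analysis).

The *fraction of iterations in which MRgFUS is cheaper* is reported but
depends strongly on decomposition granularity: a stage-granular catalog
concentrates all variance in a few large parameters, giving a wider
spread (and a lower fraction, ≈0.74) than an item-granular catalog
would. Since the original item decomposition is unpublished, this
quantity is only qualitatively reproducible (it stays within 0.6–0.95
across granularities); the mean totals and their difference are the
stable outputs. `generate_synthetic_catalog()` can build arbitrary
item-level decompositions for granularity experiments.

## Numerical and design choices

* **Reference analysis sizes:** 1,000 PSA iterations; moment-recovery
  property checks use 10⁶ draws; oracle-equivalence property checks use
  100 random synthetic catalogs against an independent brute-force item
  loop (agreement to 10⁻⁶ JPY).
* **Rounding:** half away from zero, applied once at rendering; JSON
  output carries unrounded values and round-trips exactly.
* **Degenerate inputs:** zero-quantity items price to zero; a zero
  event probability short-circuits; gamma/beta moment matching rejects
  non-positive means and infeasible SDs (`sd² ≥ mean(1−mean)`) with the
  feasible bound in the message; zero-variance PSA arms cannot be
  tested and say so.
* **Ties and ordering:** DSA rows are evaluated base-first in the order
  given; catalog lookups prefer the scenario's tariff order
  (DPC → FFS → drug tariff in DPC mode).

## What the synthetic generator does and does not emulate

`generate_synthetic_catalog()` reproduces the *structure* the model
assumes — stage-tagged items, premiums linked to parents, depth-1
events, tiered stay schedules — with randomised prices and quantities,
plus independently computed truth totals. It does not emulate real
tariff magnitudes, correlations between items, or the clinical
plausibility of event rates; passing the property suite therefore
demonstrates arithmetical correctness of the costing engine, not
real-world validity of any particular catalog.

## Limitations

The calibrated inputs are aggregates: the package cannot recover the true
item-level tariffs, the FFS per-diem tier structure outside the published
anchor points (the schedule extends the day-3–8 rate to days 1–2), or the
2016 labour decomposition. Adverse-event treatment costs, battery
replacement beyond the horizon, repeat follow-up visits and bilateral DBS
are outside the model's scope, as in the original analysis — all of which
bias against MRgFUS, so the estimated savings are conservative. Tariff
levels are reimbursement prices, not hospital resource costs.
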