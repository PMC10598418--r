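---
title: "Bycatch rates, deterrent trials and depth-restriction scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bycatch rates, deterrent trials and depth-restriction scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trossa)
```

## The problem

Bottom-set gillnet fisheries targeting lumpfish kill diving seabirds —
eiders, guillemots, ducks — and marine mammals as bycatch. In Iceland the
unit of fishing effort is the *trossa*, a tier of individual gillnets tied
together, set on the seabed and normally hauled within three days. This
package implements three linked analyses at trossa resolution:

1. effort-standardised catch (CPUE) and bycatch (BPUE) rates;
2. a depth-matched paired bootstrap estimating whether an above-water
   visual deterrent (a looming-eyes buoy, LEB, moored along the trossa)
   changes those rates;
3. a fleet-wide extrapolation of annual seabird bycatch from national
   landings statistics, and a simulator of depth-based fishing restrictions
   with effort redistribution.

## Effort model

A trossa's fishing effort is its area times its soak time. Area is
`net_length × n_nets × net_height` (m²); soak time is counted in **whole
days with a minimum of one** — the trossa-day is the field's effort unit,
and a set hauled the same day still fished. Soaks beyond the 3-day
regulatory maximum occur legitimately (bad weather) and are flagged by
`validate_dataset()` rather than rejected.

Counts standardise to the **reference trossa-day** at 2000 m², the fleet
mean area (observed range roughly 993–2838 m²):

$$\mathrm{rate} = \frac{C}{A \times T} \times 2000 .$$

Rates are zero exactly when counts are; rescaling all areas and the
reference area together leaves every rate unchanged.

Depth-binned tables (`depth_binned_rates()`) use half-open bins
`[lo, hi)` of 10 m with an open bin above 50 m; a depth exactly on an edge
belongs to the deeper bin. Bin rates are *pooled* — total count over total
standardised effort — not means of per-trossa rates, so that
`rate × effort` reproduces the observed bin total; this is also the
construction under which published per-bin bycatch divides back out of
published rate tables. A bin with no effort has an *undefined* (`NA`) rate,
never zero. Whether raw or standardised trossa-days form the denominator is
switchable (`ref_area = NULL` for raw); standardised is the default.

## The paired bootstrap

Each deterrent trossa shares its fishing trip with 4–16 controls. Per
iteration the estimator draws `n_pairs` deterrent trossas with replacement;
for each it draws a target depth from `Normal(deterrent depth, depth_sd)`
(default 5 m) and selects the same-trip control set closest to that
target. Matching on depth matters because bycatch rates fall steeply with
set depth: an unmatched comparison would confound the device with where it
happened to be deployed.

Numerical choices in matching:

* ties in depth distance are broken uniformly at random over all tied
  candidates — any deterministic rule would bias towards data order;
* target depths are not truncated at zero: only relative distance matters,
  and a negative target simply selects the shallowest candidate;
* controls are drawn independently per pair, so one control may serve
  several pairs within an iteration (no exclusion is imposed);
* as `depth_sd → 0` the matched control converges to the depth-nearest
  control, which the test suite verifies.

**Per-iteration statistic.** Each iteration summarises its sampled pairs by
the deterrent-group rate, the control-group rate and their paired
difference; the reported estimate and 95% interval are the median and
2.5%/97.5% quantiles of these summaries over `n_iter` (default 10,000)
iterations, and an effect is significant when the interval of the
difference excludes zero. The default summary is the **mean over pairs**.
This was a genuinely open design choice and the deciding argument is
zero-inflation: in realistic data more than 80% of trossas catch no bird,
so a median over ~61 resampled pairs is identically zero for every bycatch
group — it cannot describe group-level rates of the observed magnitude
(~0.2 birds per trossa-day) and has essentially no power against even a
strong deterrent effect. The mean-over-pairs summary reproduces rates on
the observed scale, retains the characteristic asymmetry in which the
median of the difference need not equal the difference of the two medians,
and reduces to the classical bootstrap-of-the-mean for the paired
difference. The alternatives remain available
(`bootstrap_config(statistic = "pairwise_median")` or `"group_median"`)
without being asserted as what any particular study used.

**Seeding.** `effect_table()` derives one independent seed per species
group from the root seed and the group *label* (a deterministic string
hash), so adding, removing or reordering groups never perturbs another
group's estimate. Within a group, all randomness (resampling, targets,
tie-breaks) is pre-drawn in a fixed order, making estimates bit-identical
under a fixed seed and invariant to the row order of the input (records are
sorted into a canonical order before sampling).

## From landings to fleet-wide bycatch

National statistics report annual lumpfish landings in tons. With a mean
gravid female of 3 kg, `L` tons are `L × 1000 / 3` fish. Splitting the
landings across depth bins by the published proportion `p_b` and dividing
by the bin's catch rate `r_b` gives the implied fleet effort

$$E_b = \frac{L \, p_b \times 1000}{3 \, r_b}$$

in standardised trossa-days; bycatch extrapolates as
`Σ_b E_b × bird_rate_b`.

Two-decimal published bycatch rates are too coarse for the sparse deep
bins (a rate of 0.01 rounded from 0.0122 is a 20% error). When per-bin
annual bycatch totals are published alongside, `unrounded_bird_rates()`
recovers the full-precision rate as `bycatch_b / E_b`; the packaged
`reference_unrounded_rates()` does this for the 2022 Icelandic trial
inputs, and the test suite shows that projections from printed 2-d.p.
rates agree with the per-bin-total route to about 1% overall but up to
~20% in the sparsest bin.

## Restriction scenarios

`simulate_restriction()` closes every bin whose upper edge is at or below
the restriction depth and reallocates the closed effort to the open bins.
The phrase "in equal proportion to the available greater depths" admits two
readings, and they differ materially:

* **equal absolute shares** (default): banned effort ÷ number of open bins
  added to each open bin;
* **proportional**: banned effort distributed proportionally to each open
  bin's existing effort.

Only the equal-shares scheme reproduces the published scenario projections
(e.g. ~4876 birds under a >10 m restriction versus ~5050 under the
proportional reading); both are implemented
(`scenario_constants(redistribution = )`). Total effort is conserved to
1e-9 relative under either scheme, a restriction of 0 m reproduces the
baseline exactly, catch is invariant to the restriction when all bins share
one catch rate, and the deepest restriction reduces to the closed form
`total effort × top-bin rate` — all verified as invariant tests.

Marine-mammal projections are deliberately emitted **only relative to
baseline**: mammal bycatch in a single bay and year is not representative
enough to extrapolate absolute fleet-wide numbers, but the *direction* of
change under displacement (into the mammal-rich 30–50 m depths for moderate
restrictions) is informative.

`scenario_table()` repeats the simulation for each year of a landings
series and reports means and min–max ranges. Because effort is linear in
tonnage at fixed depth proportions, means depend only on mean tonnage. The
packaged `reference_landings()` series carries the published minimum
(4516 t, 2018), maximum (7601 t, 2021) and mean (5386.8 t); the six
unpublished years are filled with a constant preserving the mean and are
marked `synthetic = TRUE`. Mean projections are therefore exact; range
endpoints driven by the reconstructed years are indicative only. Whether
the depth proportions themselves varied by year is unknown; they are held
constant (per-year proportions can be supplied by editing the rate table
per year and calling `simulate_restriction()` directly).

## The synthetic fleet generator

`generate_fleet()` emulates the study conditions the estimators assume:
7 boats, 84 trips of 5–16 trossas, 61 deterrent trossas (at most one per
trip), soaks of 1–3 whole days, areas on 993.2–2837.7 m² with mean
2000 m², and set depths built from a trip-level centre
(truncated `Normal(25, 10)` m on 5–60 m) plus per-trossa jitter
(`SD = 8` m, clamped). The within-trip spread is a modelling choice, not an
observed quantity: it is set wide enough that depth-matched control
selection is exercised meaningfully, while the marginal depth distribution
keeps ~80% of effort between 10 and 40 m, as observed. Counts are

* birds and mammals: Poisson in `rate(depth) × standardised trossa-days`,
  with the deterrent multiplier applied to bird rates only (the device is
  above water; no effect on fish or mammals is injected by default), and
  species drawn as independent Poissons in the configured mix — equivalent
  to a multinomial split of the group total; an optional gamma mixing
  (`bird_dispersion`) produces clumped bycatch;
* lumpfish: negative-binomial with dispersion `fish_dispersion`
  (default size 2), since fish catch is strongly overdispersed.

Rate–depth functions default to the published depth-binned step functions.
`expected_totals()` gives the generator's analytic means (the depth
marginal is integrated numerically on a fine grid), and the suite checks
Monte-Carlo agreement within 3 standard errors over 500 replicates.

What the generator does **not** emulate: spatial autocorrelation, seasonal
trends in rates, bird-density fields, weather-driven soak patterns, or
correlation between depth and trossa size. Passing calibration and power
tests on this generator therefore demonstrates the estimators' statistical
properties under the assumed data-generating process, not the realism of
that process.

## Test sizing

Statistical tests are sized so their tolerances sit at roughly three
standard errors of the quantity under test, which makes them meaningful and
stable: step-function recovery of fish rates is checked at ~5% per bin and
bird rates at ~150,000 simulated trossas (5% per bin to 40 m, 15% in the
sparse 40–50 m bin, exact zero above 50 m); bootstrap calibration uses 200
replicate fleets of ~225 trossas with 400 iterations each (interval covers
zero in ≥90% under no effect) and power uses 100 replicates with an 80%
bycatch reduction at elevated baseline rates (negative, significant effect
in ≥80%).

## Known limitations

* The depth axis is the only closure dimension; no spatial geometry, travel
  cost or fleet-displacement economics are modelled.
* Absolute mammal extrapolations are intentionally unsupported.
* Scenario projections assume catch rates at depth are maintained when
  effort concentrates there, and that total fleet effort is conserved —
  strong assumptions flagged whenever results are interpreted.
* The effect estimator is design-based; no regression adjustment beyond
  depth matching is offered.
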