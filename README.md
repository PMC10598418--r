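# trossa

Analysis tools for seabird and marine-mammal bycatch in demersal gillnet
fisheries, built around the *trossa* — the tier of gillnets that is the unit
of fishing effort in the Icelandic lumpfish (*Cyclopterus lumpus*) fishery.
The package is aimed at fisheries scientists and conservation analysts who
need to (i) standardise catch and bycatch to comparable effort units,
(ii) estimate the effect of an above-water deterrent device (the
"looming-eyes buoy", LEB) from a paired field trial, and (iii) project
fleet-wide seabird bycatch under depth-based fishing restrictions.

## Methods at a glance

**Effort standardisation.** A trossa of area `A = net length × number of
nets × net height` (m²) soaking for `T` whole days and catching `C` animals
has catch/bycatch per unit effort

```
CPUE = C / (A × T) × 2000
```

expressed per *standardised trossa-day* (reference area 2000 m², the fleet
mean). Depth-binned rate tables pool counts over effort per 10 m depth bin
(`rate = ΣC / Σ(A·T/2000)`), so rate × effort always recovers the observed
total.

**Deterrent effect (depth-matched paired bootstrap).** Per iteration,
deterrent trossas are resampled with replacement; each is paired with a
control from the *same fishing trip*, selected as the control whose set
depth is closest to a target drawn from `Normal(deterrent depth, 5 m)` —
depth being the dominant driver of bycatch, this compares like with like.
Each iteration's deterrent rate, control rate and paired difference are
summarised (mean over pairs, by default) and the medians and 2.5%/97.5%
quantiles over 10,000 iterations give the estimates and confidence
intervals; an effect is significant when the interval of the difference
excludes zero.

**Depth-restriction scenarios.** Annual landings `L` (tons) convert to fish
at 3 kg per female; each depth bin's share `p_b` of the landings, divided by
its catch rate `r_b`, yields the fleet-wide effort
`E_b = L·p_b·1000 / (3·r_b)` in standardised trossa-days. Bycatch
extrapolates as `Σ E_b × bird_rate_b`. A restriction closes all bins above a
depth threshold and redistributes their effort in equal absolute shares to
the open bins (total effort conserved), projecting the annual fish catch and
seabird bycatch under displacement.

A synthetic fleet generator (`generate_fleet()`) with known ground truth —
Poisson bycatch in depth-dependent rates × effort, overdispersed fish catch,
an optional multiplicative deterrent effect — backs calibration, power and
recovery tests of all estimators.

## Worked example

```r
library(trossa)

fleet <- generate_fleet(fleet_config(seed = 42))   # study-shaped synthetic fleet
fleet$dataset
#> # Fleet dataset: 845 trossas, 84 trips, 61 with deterrent

effect_table(fleet$dataset, c("all_birds", "lumpfish"),
             bootstrap_config(n_iter = 10000, seed = 42))
#>       group median_leb ci_leb_lo ci_leb_hi median_control ... median_diff ci_diff_lo ci_diff_hi significant
#> 1 all_birds      0.119    0.0391     0.231          0.101 ...      0.0173    -0.0702      0.118       FALSE
#> 2  lumpfish     32.731   26.5637    39.686         35.738 ...     -3.0688   -12.5556      6.590       FALSE
```

Rates are per standardised trossa-day: the synthetic fleet (generated with
no deterrent effect) shows ~0.12 birds and ~33 lumpfish per trossa-day on
deterrent-equipped trossas, statistically indistinguishable from their
depth-matched controls — the confidence interval of the difference spans
zero in both rows.

```r
rates <- reference_unrounded_rates()          # published depth-binned inputs
scenario_table(reference_landings()[, c("year", "tons")], rates)
#>   restriction_depth catch_tons_mean birds_mean delta_catch delta_birds delta_mammals
#> 1                10            5252     4874.7     -0.0251     -0.2583        0.1249
#> 2                20            5157     2144.4     -0.0426     -0.6737        0.2112
#> 3                30            5252     1036.7     -0.0250     -0.8423        0.3099
#> 4                40            5362      309.6     -0.0045     -0.9529       -0.0296
#> 5                50            5996        0.0      0.1130     -1.0000       -1.0000
```

Reading the last row: restricting the fishery to waters deeper than 50 m
would leave the projected annual catch at ~6000 tons (+11% against the
~5387-ton baseline, because the deepest waters have the best catch rates)
while eliminating the ~6572 projected annual seabird deaths. Mammal bycatch
is reported only relative to baseline (`delta_mammals`); moderate
restrictions displace effort *into* the mammal-rich 30–50 m depths.

An end-to-end run (validation report, effect table, empirical rate table,
scenario table, manifest) is one call:

```r
paths <- make_demo("demo", seed = 1)
run_all(read_pipeline_config(paths$config))
```

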