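# Published depth-specific rates and landings from the 2022 Icelandic
# lumpfish deterrent trial (Húnaflói Bay), used as default inputs to the
# fleet-wide extrapolation and restriction scenarios.

#' Depth-specific rates observed in the 2022 Icelandic lumpfish trial
#'
#' Per 10 m depth bin (final bin open above 50 m): pooled catch and bycatch
#' rates per standardised trossa-day, the proportion of national annual
#' lumpfish landings taken at that depth, and the 2014-2021 mean-year
#' extrapolations (annual fish catch in tons and annual seabird bycatch in
#' individuals). Rates are as published, rounded to two decimals; use
#' [reference_unrounded_rates()] for scenario projections, where two-decimal
#' rounding is too coarse in sparse bins.
#'
#' @return A [rate_table()] with extra columns `annual_catch_tons` and
#'   `annual_bird_bycatch`.
#' @export
reference_rate_table <- function() {
  rate_table(
    depth_lo = c(0, 10, 20, 30, 40, 50),
    depth_hi = c(10, 20, 30, 40, 50, Inf),
    fish_rate = c(43.03, 36.13, 32.84, 33.51, 31.41, 39.76),
    bird_rate = c(0.38, 0.19, 0.09, 0.05, 0.01, 0.00),
    mammal_rate = c(0.00, 0.01, 0.01, 0.02, 0.02, 0.00),
    landings_proportion = c(0.13, 0.34, 0.18, 0.13, 0.10, 0.12),
    annual_catch_tons = c(700.3, 1831.5, 969.6, 700.3, 538.7, 646.4),
    annual_bird_bycatch = c(2067, 3204, 902, 329, 70, 0))
}

#' Mean-year landings implied by the reference rate table
#'
#' Sum of the per-bin 2014-2021 mean annual catch (5386.8 tons).
#'
#' @return Tons per year.
#' @export
reference_mean_tons <- function() {
  sum(reference_rate_table()$annual_catch_tons)
}

#' Reference rate table with unrounded seabird bycatch rates
#'
#' Derives the fleet-wide mean-year effort per bin from the per-bin tonnage
#' and catch rates, then replaces the two-decimal published bird rates by
#' per-bin annual bycatch divided by that effort
#' (see [unrounded_bird_rates()]).
#'
#' @param fish_weight_kg Mean fish weight (kg), default 3.
#' @return A [rate_table()].
#' @export
reference_unrounded_rates <- function(fish_weight_kg = 3) {
  r <- reference_rate_table()
  eff <- effort_from_landings(reference_mean_tons(), r, fish_weight_kg)
  unrounded_bird_rates(r, r$annual_bird_bycatch, eff)
}

#' Annual Icelandic lumpfish landings, 2014-2021 (partly synthetic)
#'
#' National landings are published for 2014-2021, ranging between 4516 tons
#' (2018) and 7601 tons (2021), with a multi-year mean of 5386.8 tons. Only
#' the minimum, maximum and mean are available here; the remaining six years
#' are filled with a constant chosen so the 8-year mean equals 5386.8 tons.
#' This synthetic reconstruction reproduces every mean-based projection
#' exactly (projections are linear in tonnage) but not year-specific values.
#'
#' @return Tibble with columns `year`, `tons` and `synthetic` (TRUE for the
#'   reconstructed years).
#' @export
reference_landings <- function() {
  years <- 2014:2021
  known <- c("2018" = 4516, "2021" = 7601)
  fill <- (reference_mean_tons() * length(years) - sum(known)) /
    (length(years) - length(known))
  tons <- ifelse(as.character(years) %in% names(known),
                 known[as.character(years)], fill)
  tibble::tibble(year = years, tons = unname(tons),
                 synthetic = !as.character(years) %in% names(known))
}

#' Reported bycatch totals by species from the 2022 trial
#'
#' Species totals split by control (875 trossas) and deterrent-equipped
#' (61 trossas) sets: 250 seabirds and 29 marine mammals in all. Used as the
#' default species mix of the synthetic fleet generator.
#'
#' @return Tibble with columns `species`, `taxon` (`"bird"`/`"mammal"`),
#'   `control`, `experimental`, `total`.
#' @export
reference_species_totals <- function() {
  tibble::tribble(
    ~species, ~taxon, ~control, ~experimental,
    "black_guillemot", "bird", 26L, 3L,
    "common_guillemot", "bird", 43L, 5L,
    "atlantic_puffin", "bird", 0L, 1L,
    "european_shag", "bird", 2L, 0L,
    "great_cormorant", "bird", 7L, 0L,
    "common_eider", "bird", 124L, 27L,
    "long_tailed_duck", "bird", 10L, 0L,
    "red_throated_diver", "bird", 1L, 0L,
    "northern_fulmar", "bird", 1L, 0L,
    "harbour_seal", "mammal", 7L, 3L,
    "grey_seal", "mammal", 2L, 1L,
    "harp_seal", "mammal", 3L, 0L,
    "white_beaked_dolphin", "mammal", 1L, 0L,
    "bottlenose_dolphin", "mammal", 2L, 0L,
    "harbour_porpoise", "mammal", 9L, 1L) |>
    dplyr::mutate(total = .data$control + .data$experimental)
}
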