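# Landings-to-effort extrapolation and depth-restriction closure simulation.
#
# National landings statistics report tons of lumpfish landed per year.
# Dividing each depth bin's share of the landings (converted to fish at a
# mean female weight of 3 kg) by that bin's empirical catch rate yields the
# fleet-wide fishing effort per bin in standardised trossa-days; multiplying
# effort by the depth-specific seabird bycatch rate extrapolates the annual
# fleet-wide bycatch.  A depth restriction closes the shallow bins and
# redistributes their effort to the remaining open bins, mimicking the
# displacement effect of a spatial closure while conserving total effort.

#' Convert landed tonnage to a number of fish
#'
#' The fishery targets gravid females, assumed to weigh 3 kg on average.
#'
#' @param tons Landings in metric tons.
#' @param fish_weight_kg Mean weight of one fish (kg), default 3.
#' @return Number of fish, vectorised.
#' @export
landings_to_fish <- function(tons, fish_weight_kg = 3) {
  if (any(fish_weight_kg <= 0)) abort("fish_weight_kg must be > 0")
  if (any(tons < 0)) abort("tons must be >= 0")
  tons * 1000 / fish_weight_kg
}

#' Fleet-wide fishing effort per depth bin implied by annual landings
#'
#' Splits one year's landings across depth bins by the rate table's
#' `landings_proportion`, converts each bin's tonnage to fish, and divides by
#' the bin's catch rate: `effort = tons * proportion * 1000 / w / fish_rate`
#' standardised trossa-days.
#'
#' @param annual_tons Annual landings (metric tons).
#' @param rates A [rate_table()] with `landings_proportion` summing to 1 and
#'   `fish_rate > 0` wherever the proportion is positive.
#' @param fish_weight_kg Mean fish weight (kg), default 3.
#' @return An `effort_profile` tibble: `depth_lo`, `depth_hi`, `effort`.
#' @export
effort_from_landings <- function(annual_tons, rates, fish_weight_kg = 3) {
  p <- rates$landings_proportion
  if (any(is.na(p))) abort("rate table has no landings_proportion")
  if (abs(sum(p) - 1) > 1e-9) abort("landings_proportion must sum to 1")
  bad <- p > 0 & (is.na(rates$fish_rate) | rates$fish_rate <= 0)
  if (any(bad)) {
    abort("effort undefined: positive landings proportion with zero fish rate")
  }
  effort <- ifelse(p > 0,
                   landings_to_fish(annual_tons * p, fish_weight_kg) / rates$fish_rate,
                   0)
  structure(tibble::tibble(depth_lo = rates$depth_lo, depth_hi = rates$depth_hi,
                           effort = effort),
            class = c("effort_profile", class(tibble::tibble())))
}

#' Recover unrounded bycatch rates from per-bin bycatch totals
#'
#' Published depth-specific bycatch rates are typically printed at two
#' decimals, which is too coarse for scenario projections in sparse bins.
#' When the per-bin annual bycatch and the derived effort are known, the
#' unrounded rate is their ratio; this replaces `bird_rate` bin-wise.
#'
#' @param rates A [rate_table()].
#' @param per_bin_bycatch Annual seabird bycatch per bin (individuals).
#' @param effort An `effort_profile` aligned with `rates`.
#' @return The rate table with `bird_rate` replaced by
#'   `per_bin_bycatch / effort` (0 where the bycatch is 0).
#' @export
unrounded_bird_rates <- function(rates, per_bin_bycatch, effort) {
  if (length(per_bin_bycatch) != nrow(rates) || nrow(effort) != nrow(rates)) {
    abort("per_bin_bycatch and effort must align with the rate table bins")
  }
  if (any(per_bin_bycatch > 0 & effort$effort <= 0)) {
    abort("positive bycatch in a bin with no effort")
  }
  rates$bird_rate <- ifelse(per_bin_bycatch > 0,
                            per_bin_bycatch / effort$effort, 0)
  rates
}

#' Extrapolate annual fleet-wide seabird bycatch
#'
#' @param effort An `effort_profile` (standardised trossa-days per bin).
#' @param rates A [rate_table()] aligned with `effort`.
#' @return List with `per_bin` (tibble of per-bin bycatch) and `total`.
#' @export
extrapolate_bycatch <- function(effort, rates) {
  if (nrow(effort) != nrow(rates)) abort("effort and rates must align bin-wise")
  per_bin <- effort$effort * ifelse(is.na(rates$bird_rate), 0, rates$bird_rate)
  list(per_bin = tibble::tibble(depth_lo = effort$depth_lo,
                                depth_hi = effort$depth_hi,
                                bycatch = per_bin),
       total = sum(per_bin))
}

#' Scenario constants
#'
#' @param fish_weight_kg Mean fish weight (kg) used to convert projected fish
#'   counts back to tons, default 3.
#' @param redistribution How effort from closed bins is reallocated to the
#'   open bins: `"equal"` (default) adds the banned effort in equal absolute
#'   shares to each open bin; `"proportional"` scales it by each open bin's
#'   existing effort.
#' @return A `scenario_constants` list.
#' @export
scenario_constants <- function(fish_weight_kg = 3,
                               redistribution = c("equal", "proportional")) {
  if (fish_weight_kg <= 0) abort("fish_weight_kg must be > 0")
  structure(list(fish_weight_kg = fish_weight_kg,
                 redistribution = match.arg(redistribution)),
            class = "scenario_constants")
}

#' Simulate a depth-based fishing restriction
#'
#' Closes every bin strictly shallower than `restriction_depth` (i.e. with
#' upper edge at or below it), redistributes the closed bins' effort to the
#' remaining open bins (total effort is conserved), and projects the annual
#' fish catch (tons), seabird bycatch (individuals) and the marine-mammal
#' bycatch relative to the unrestricted baseline. Mammal bycatch is reported
#' only relative to baseline, never as an absolute total.
#'
#' @param effort Unrestricted `effort_profile`.
#' @param rates A [rate_table()] aligned with `effort`.
#' @param restriction_depth Restriction depth in metres; must coincide with a
#'   bin edge. 0 reproduces the baseline exactly.
#' @param constants A [scenario_constants()].
#' @return A `scenario_result`: one-row tibble with `restriction_depth`,
#'   `catch_tons`, `birds`, `mammal_relative` and the fractional changes
#'   `delta_catch`, `delta_birds`, `delta_mammals` relative to baseline.
#' @export
simulate_restriction <- function(effort, rates, restriction_depth,
                                 constants = scenario_constants()) {
  if (nrow(effort) != nrow(rates)) abort("effort and rates must align bin-wise")
  edges <- c(rates$depth_lo, rates$depth_hi[is.finite(rates$depth_hi)])
  if (!restriction_depth %in% edges) {
    abort(sprintf("restriction_depth %s does not coincide with a bin edge",
                  format(restriction_depth)))
  }
  closed <- rates$depth_hi <= restriction_depth
  if (all(closed)) abort("restriction closes every depth bin")
  e <- effort$effort
  banned <- sum(e[closed])
  e_new <- e
  e_new[closed] <- 0
  open <- !closed
  if (constants$redistribution == "equal") {
    e_new[open] <- e[open] + banned / sum(open)
  } else {
    if (banned > 0 && sum(e[open]) == 0) {
      abort("cannot redistribute proportionally: open bins have zero effort")
    }
    if (sum(e[open]) > 0) {
      e_new[open] <- e[open] * (1 + banned / sum(e[open]))
    }
  }
  fr <- ifelse(is.na(rates$fish_rate), 0, rates$fish_rate)
  br <- ifelse(is.na(rates$bird_rate), 0, rates$bird_rate)
  mr <- ifelse(is.na(rates$mammal_rate), 0, rates$mammal_rate)
  catch_tons <- sum(e_new * fr) * constants$fish_weight_kg / 1000
  birds <- sum(e_new * br)
  mam_idx <- sum(e_new * mr)
  base_catch <- sum(e * fr) * constants$fish_weight_kg / 1000
  base_birds <- sum(e * br)
  base_mam <- sum(e * mr)
  rel <- function(x, b) if (b > 0) x / b - 1 else if (x == 0) 0 else NA_real_
  out <- tibble::tibble(
    restriction_depth = restriction_depth,
    catch_tons = catch_tons,
    birds = birds,
    mammal_relative = if (base_mam > 0) mam_idx / base_mam else NA_real_,
    delta_catch = rel(catch_tons, base_catch),
    delta_birds = rel(birds, base_birds),
    delta_mammals = rel(mam_idx, base_mam))
  class(out) <- c("scenario_result", class(out))
  out
}

#' Restriction scenarios averaged over a series of landings years
#'
#' For each year's tonnage, derives the fleet-wide effort profile (holding
#' the depth proportions of the rate table constant across years), simulates
#' every requested restriction depth, and summarises each depth by the mean
#' and min-max range over years. Projections are linear in annual tonnage
#' when depth proportions are held constant.
#'
#' @param landings Tibble with columns `year` and `tons` (or a numeric vector
#'   of annual tonnages).
#' @param rates A [rate_table()] with landings proportions.
#' @param depths Restriction depths (m), each a bin edge; 0 is allowed and
#'   reproduces the baseline.
#' @param constants A [scenario_constants()].
#' @return Tibble with one row per restriction depth: `restriction_depth`,
#'   `catch_tons_mean/min/max`, `birds_mean/min/max`, `delta_catch`,
#'   `delta_birds`, `delta_mammals` (deltas computed on the means).
#' @export
scenario_table <- function(landings, rates, depths = c(10, 20, 30, 40, 50),
                           constants = scenario_constants()) {
  tons <- if (is.data.frame(landings)) landings$tons else as.numeric(landings)
  if (!length(tons)) abort("landings series is empty")
  if (any(tons <= 0)) abort("annual tonnage must be > 0")
  per_year <- lapply(tons, function(tt) {
    eff <- effort_from_landings(tt, rates, constants$fish_weight_kg)
    dplyr::bind_rows(lapply(depths, function(dd)
      simulate_restriction(eff, rates, dd, constants)))
  })
  all_years <- dplyr::bind_rows(per_year)
  out <- dplyr::summarise(
    dplyr::group_by(all_years, .data$restriction_depth),
    catch_tons_mean = mean(.data$catch_tons),
    catch_tons_min = min(.data$catch_tons),
    catch_tons_max = max(.data$catch_tons),
    birds_mean = mean(.data$birds),
    birds_min = min(.data$birds),
    birds_max = max(.data$birds),
    delta_catch = mean(.data$delta_catch),
    delta_birds = mean(.data$delta_birds),
    delta_mammals = mean(.data$delta_mammals),
    .groups = "drop")
  out[order(match(out$restriction_depth, depths)), ]
}
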