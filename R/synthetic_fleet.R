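# Synthetic fleet generator.
#
# Emulates the statistical structure the estimators assume: a fleet of small
# boats making independent trips, each trip setting several trossas at
# depths clustered around a trip-level centre, with bycatch counts Poisson
# in depth-dependent rates times standardised effort, overdispersed target
# catch, and an optional multiplicative deterrent effect on bird rates.
# Ground truth (the realised configuration and per-record expected counts)
# is returned alongside the data so that recovery, calibration and power
# properties of the estimators can be tested against known truth.

#' Turn a rate table column into a step function of depth
#'
#' @param rates A [rate_table()].
#' @param column Rate column name (`"bird_rate"`, `"fish_rate"`, ...).
#' @return Function depth (m) -> rate per standardised trossa-day.
#' @export
rate_step_function <- function(rates, column = "bird_rate") {
  lo <- rates$depth_lo
  v <- ifelse(is.na(rates[[column]]), 0, rates[[column]])
  function(depth) v[pmax(findInterval(depth, lo), 1L)]
}

#' Configuration of the synthetic fleet generator
#'
#' Defaults emulate the 2022 Icelandic trial: 7 boats, 84 trips of 5-16
#' trossas, 61 deterrent-equipped trossas (at most one per trip), set depths
#' concentrated so that most effort falls between 10 and 40 m, soaks of 1-3
#' whole days, trossa areas spanning 993.2-2837.7 m2 with mean 2000 m2, and
#' depth-dependent rates following the published depth-binned step functions.
#'
#' @param n_boats Number of boats.
#' @param n_trips Number of independent fishing trips.
#' @param trossas_per_trip Integer range (length 2) of trossas per trip.
#' @param leb_trossas_total Deterrent trossas in the fleet (at most one per
#'   trip).
#' @param depth_mean,depth_sd Mean and SD (m) of the normal distribution of
#'   trip-level depth centres, truncated to `depth_range`.
#' @param depth_range Allowed set depths (m); per-trossa depths are clamped
#'   to this range.
#' @param within_trip_depth_sd SD (m) of per-trossa depth around the trip
#'   centre, so that depth-matched control selection is exercised.
#' @param soak_days_range Integer range of whole soak days.
#' @param area_range Trossa area range (m2).
#' @param area_mean Mean trossa area (m2); areas are drawn from a scaled Beta
#'   on `area_range` with this mean.
#' @param true_bird_rate,true_fish_rate,true_mammal_rate Functions
#'   depth -> rate per standardised trossa-day (defaults: published
#'   depth-binned step functions).
#' @param leb_multiplier Multiplicative factor applied to bird rates on
#'   deterrent trossas (1 = no effect; the deterrent never affects fish or
#'   mammal rates in the generator).
#' @param fish_dispersion Negative-binomial size of lumpfish counts
#'   (`Inf` = Poisson).
#' @param bird_dispersion Gamma-mixing shape for bird counts (`Inf` = pure
#'   Poisson; finite values make bycatch clumped).
#' @param species_mix,mammal_mix Named proportions splitting bird and mammal
#'   counts into species (defaults: the 2022 trial totals).
#' @param ref_area Reference trossa area (m2).
#' @param start_date,season_days Start and length (days) of the fishing
#'   season over which trips are spread.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return A `fleet_config` list.
#' @export
fleet_config <- function(n_boats = 7, n_trips = 84,
                         trossas_per_trip = c(5L, 16L),
                         leb_trossas_total = 61,
                         depth_mean = 25, depth_sd = 10,
                         depth_range = c(5, 60), within_trip_depth_sd = 8,
                         soak_days_range = c(1L, 3L),
                         area_range = c(993.2, 2837.7), area_mean = 2000,
                         true_bird_rate = rate_step_function(reference_rate_table(), "bird_rate"),
                         true_fish_rate = rate_step_function(reference_rate_table(), "fish_rate"),
                         true_mammal_rate = rate_step_function(reference_rate_table(), "mammal_rate"),
                         leb_multiplier = 1,
                         fish_dispersion = 2, bird_dispersion = Inf,
                         species_mix = NULL, mammal_mix = NULL,
                         ref_area = 2000,
                         start_date = as.Date("2022-03-21"), season_days = 58,
                         seed = NULL) {
  if (leb_trossas_total > n_trips) {
    abort("leb_trossas_total exceeds n_trips (at most one deterrent trossa per trip)")
  }
  if (leb_multiplier < 0) abort("leb_multiplier must be >= 0")
  if (area_mean <= area_range[1] || area_mean >= area_range[2]) {
    abort("area_mean must lie strictly inside area_range")
  }
  totals <- reference_species_totals()
  if (is.null(species_mix)) {
    b <- totals[totals$taxon == "bird", ]
    species_mix <- setNames(b$total / sum(b$total), b$species)
  }
  if (is.null(mammal_mix)) {
    m <- totals[totals$taxon == "mammal", ]
    mammal_mix <- setNames(m$total / sum(m$total), m$species)
  }
  if (abs(sum(species_mix) - 1) > 1e-9 || abs(sum(mammal_mix) - 1) > 1e-9) {
    abort("species mixes must sum to 1")
  }
  structure(list(
    n_boats = n_boats, n_trips = n_trips,
    trossas_per_trip = as.integer(trossas_per_trip),
    leb_trossas_total = as.integer(leb_trossas_total),
    depth_mean = depth_mean, depth_sd = depth_sd, depth_range = depth_range,
    within_trip_depth_sd = within_trip_depth_sd,
    soak_days_range = as.integer(soak_days_range),
    area_range = area_range, area_mean = area_mean,
    true_bird_rate = true_bird_rate, true_fish_rate = true_fish_rate,
    true_mammal_rate = true_mammal_rate,
    leb_multiplier = leb_multiplier,
    fish_dispersion = fish_dispersion, bird_dispersion = bird_dispersion,
    species_mix = species_mix, mammal_mix = mammal_mix,
    ref_area = ref_area, start_date = start_date, season_days = season_days,
    seed = seed), class = "fleet_config")
}

# Beta parameters on [0,1] matching the configured mean area, second shape
# fixed at 2 (mild concentration around the mean).
area_beta_shapes <- function(cfg) {
  mu <- (cfg$area_mean - cfg$area_range[1]) / diff(cfg$area_range)
  b <- 2
  c(a = b * mu / (1 - mu), b = b)
}

rtruncnorm_ <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' Generate a synthetic fleet dataset with known ground truth
#'
#' Bird and mammal counts are Poisson in `rate(depth) * standardised
#' trossa-days` (times `leb_multiplier` for birds on deterrent trossas),
#' split into species by the configured mix (species counts are drawn as
#' independent Poissons, equivalent to a multinomial split of the total);
#' lumpfish counts are negative-binomial with the configured dispersion.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg A [fleet_config()].
#' @return List with `dataset` (a [fleet_dataset()]) and `truth` (the
#'   configuration plus per-record expected counts).
#' @export
generate_fleet <- function(cfg = fleet_config()) {
  gen <- function() {
    n_trips <- cfg$n_trips
    trip_ids <- sprintf("T%03d", seq_len(n_trips))
    boat_ids <- sprintf("B%02d", ((seq_len(n_trips) - 1L) %% cfg$n_boats) + 1L)
    n_tro <- sample(seq(cfg$trossas_per_trip[1], cfg$trossas_per_trip[2]),
                    n_trips, replace = TRUE)
    leb_trips <- sample.int(n_trips, cfg$leb_trossas_total)
    centre <- rtruncnorm_(n_trips, cfg$depth_mean, cfg$depth_sd,
                          cfg$depth_range[1], cfg$depth_range[2])
    trip_day <- sample.int(cfg$season_days, n_trips, replace = TRUE) - 1L

    trip <- rep(seq_len(n_trips), n_tro)
    n <- length(trip)
    depth <- pmin(pmax(centre[trip] + rnorm(n, 0, cfg$within_trip_depth_sd),
                       cfg$depth_range[1]), cfg$depth_range[2])
    sh <- area_beta_shapes(cfg)
    area <- cfg$area_range[1] + diff(cfg$area_range) * rbeta(n, sh["a"], sh["b"])
    n_nets <- sample(10:25, n, replace = TRUE)
    net_height <- 2
    net_length <- area / (n_nets * net_height)
    soak <- sample(seq(cfg$soak_days_range[1], cfg$soak_days_range[2]),
                   n, replace = TRUE)
    has_leb <- rep(FALSE, n)
    first_of_trip <- match(seq_len(n_trips), trip)
    for (tr in leb_trips) {
      has_leb[first_of_trip[tr] + sample.int(n_tro[tr], 1L) - 1L] <- TRUE
    }
    std_days <- area / cfg$ref_area * soak

    mult <- ifelse(has_leb, cfg$leb_multiplier, 1)
    mu_birds <- cfg$true_bird_rate(depth) * std_days * mult
    mu_mams <- cfg$true_mammal_rate(depth) * std_days
    mu_fish <- cfg$true_fish_rate(depth) * std_days

    mix_g <- if (is.finite(cfg$bird_dispersion)) {
      rgamma(n, shape = cfg$bird_dispersion, rate = cfg$bird_dispersion)
    } else rep(1, n)
    x <- tibble::tibble(
      trip_id = trip_ids[trip], boat_id = boat_ids[trip],
      date_set = cfg$start_date + trip_day[trip],
      date_hauled = cfg$start_date + trip_day[trip] + soak,
      mean_depth = depth, net_length = net_length, n_nets = n_nets,
      net_height = net_height, has_leb = has_leb,
      lumpfish_count = if (is.finite(cfg$fish_dispersion)) {
        rnbinom(n, mu = mu_fish, size = cfg$fish_dispersion)
      } else rpois(n, mu_fish))
    for (sp in names(cfg$species_mix)) {
      x[[sp]] <- rpois(n, mu_birds * mix_g * cfg$species_mix[[sp]])
    }
    for (sp in names(cfg$mammal_mix)) {
      x[[sp]] <- rpois(n, mu_mams * cfg$mammal_mix[[sp]])
    }
    list(x = x, mu_birds = mu_birds, mu_mams = mu_mams, mu_fish = mu_fish)
  }
  g <- if (is.null(cfg$seed)) gen() else withr::with_seed(cfg$seed, gen())
  dataset <- fleet_dataset(g$x,
                           bird_species = names(cfg$species_mix),
                           mammal_species = names(cfg$mammal_mix))
  truth <- list(config = cfg,
                expected = tibble::tibble(record = seq_len(nrow(g$x)),
                                          expected_birds = g$mu_birds,
                                          expected_mammals = g$mu_mams,
                                          expected_fish = g$mu_fish))
  list(dataset = dataset, truth = truth)
}

# Marginal density of set depth (trip centre + within-trip jitter, both
# clamped), evaluated by quadrature on a grid; used for analytic means.
depth_rate_expectation <- function(cfg, rate_fun, n_grid = 400) {
  lo <- cfg$depth_range[1]; hi <- cfg$depth_range[2]
  cg <- seq(lo, hi, length.out = n_grid)
  wc <- dnorm(cg, cfg$depth_mean, cfg$depth_sd)
  wc <- wc / sum(wc)  # truncated-normal weights on the grid
  eg <- seq(-6, 6, length.out = 241) * cfg$within_trip_depth_sd
  we <- dnorm(eg, 0, cfg$within_trip_depth_sd)
  we <- we / sum(we)
  depth <- pmin(pmax(outer(cg, eg, `+`), lo), hi)
  sum(outer(wc, we) * matrix(rate_fun(as.numeric(depth)), nrow = n_grid))
}

#' Analytic expected totals of the synthetic fleet generator
#'
#' Closed-form means of the generator: expected records times expected
#' standardised trossa-days times the depth-averaged rate (the depth marginal
#' is integrated numerically on a grid), with the deterrent multiplier
#' applied to the configured number of deterrent trossas.
#'
#' @param cfg A [fleet_config()].
#' @return List with `birds`, `mammals`, `fish` expected fleet totals.
#' @export
expected_totals <- function(cfg = fleet_config()) {
  n_rec <- cfg$n_trips * mean(seq(cfg$trossas_per_trip[1], cfg$trossas_per_trip[2]))
  e_soak <- mean(seq(cfg$soak_days_range[1], cfg$soak_days_range[2]))
  e_std <- cfg$area_mean / cfg$ref_area * e_soak
  e_bird <- depth_rate_expectation(cfg, cfg$true_bird_rate)
  e_mam <- depth_rate_expectation(cfg, cfg$true_mammal_rate)
  e_fish <- depth_rate_expectation(cfg, cfg$true_fish_rate)
  n_leb <- cfg$leb_trossas_total
  # deterrent trossas replace controls one-for-one in expectation
  bird_units <- (n_rec - n_leb) + n_leb * cfg$leb_multiplier
  list(birds = bird_units * e_std * e_bird,
       mammals = n_rec * e_std * e_mam,
       fish = n_rec * e_std * e_fish)
}

#' Write or read a fleet generator configuration as YAML
#'
#' Rate functions are stored as depth-binned step functions (edges and
#' values); arbitrary R functions are not serialised.
#'
#' @param cfg A [fleet_config()] whose rate functions are step functions of
#'   a [rate_table()] (the default), or `path` for the reader.
#' @param path Output/input path.
#' @return `write_fleet_config()` returns `path` invisibly;
#'   `read_fleet_config()` returns a `fleet_config`.
#' @export
write_fleet_config <- function(cfg, path) {
  scalar_fields <- setdiff(names(cfg),
                           c("true_bird_rate", "true_fish_rate", "true_mammal_rate"))
  out <- lapply(cfg[scalar_fields], function(v) {
    if (inherits(v, "Date")) format(v, "%Y-%m-%d") else unclass(v)
  })
  out$species_mix <- as.list(cfg$species_mix)
  out$mammal_mix <- as.list(cfg$mammal_mix)
  grid <- seq(0.5, 100, by = 1)
  edges <- seq(0, 100, by = 10)
  for (fld in c("true_bird_rate", "true_fish_rate", "true_mammal_rate")) {
    out[[fld]] <- list(edges = edges,
                       values = cfg[[fld]](edges + 0.5)[seq_along(edges)])
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_fleet_config
#' @export
read_fleet_config <- function(path) {
  raw <- yaml::read_yaml(path)
  mk_fun <- function(fld) {
    e <- as.numeric(raw[[fld]]$edges); v <- as.numeric(raw[[fld]]$values)
    function(depth) v[pmax(findInterval(depth, e), 1L)]
  }
  args <- raw
  args$true_bird_rate <- mk_fun("true_bird_rate")
  args$true_fish_rate <- mk_fun("true_fish_rate")
  args$true_mammal_rate <- mk_fun("true_mammal_rate")
  args$start_date <- as.Date(raw$start_date)
  args$species_mix <- unlist(raw$species_mix)
  args$mammal_mix <- unlist(raw$mammal_mix)
  for (fld in c("trossas_per_trip", "soak_days_range", "depth_range", "area_range")) {
    args[[fld]] <- as.numeric(unlist(raw[[fld]]))
  }
  if (!is.null(args$fish_dispersion) && args$fish_dispersion == ".inf") {
    args$fish_dispersion <- Inf
  }
  do.call(fleet_config, args)
}
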