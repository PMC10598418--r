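test_that("the default configuration emulates the study's shape", {
  fleet <- generate_fleet(fleet_config(seed = 1))
  d <- fleet$dataset
  expect_equal(length(unique(d$trip_id)), 84L)
  expect_equal(sum(d$has_leb), 61L)
  expect_equal(length(unique(d$boat_id)), 7L)
  per_trip <- table(d$trip_id)
  expect_true(all(per_trip >= 5 & per_trip <= 16))
  expect_true(all(tapply(d$has_leb, d$trip_id, sum) <= 1))
  expect_true(all(d$mean_depth >= 5 & d$mean_depth <= 60))
  area <- trossa_area(d$net_length, d$n_nets, d$net_height)
  expect_true(all(area >= 993.2 & area <= 2837.7))
  expect_true(all(soak_days(d) %in% 1:3))
  # depth concentration: most effort between 10 and 40 m
  expect_gt(mean(d$mean_depth >= 10 & d$mean_depth < 40), 0.7)
})

test_that("generation is reproducible and zero rates give zero counts", {
  cfg <- fleet_config(n_trips = 10, leb_trossas_total = 4, seed = 77)
  d1 <- generate_fleet(cfg)$dataset
  d2 <- generate_fleet(cfg)$dataset
  expect_identical(tibble::as_tibble(d1), tibble::as_tibble(d2))

  zero <- function(depth) rep(0, length(depth))
  dz <- generate_fleet(fleet_config(n_trips = 10, leb_trossas_total = 4,
                                    true_bird_rate = zero,
                                    true_fish_rate = zero,
                                    true_mammal_rate = zero,
                                    seed = 3))$dataset
  expect_equal(sum(group_counts(dz, default_bird_species())), 0)
  expect_equal(sum(dz$lumpfish_count), 0)
})

test_that("infeasible configurations are rejected", {
  expect_error(fleet_config(n_trips = 10, leb_trossas_total = 11), "exceeds")
  expect_error(fleet_config(leb_multiplier = -1), "leb_multiplier")
})

test_that("expected totals: arithmetic cases and calibration to the study", {
  # single trossa, fixed rate 0.2/day, 3 days, area equal to the reference
  cfg1 <- fleet_config(n_trips = 1, n_boats = 1, trossas_per_trip = c(1L, 1L),
                       leb_trossas_total = 0, soak_days_range = c(3L, 3L),
                       area_range = c(1999, 2001), area_mean = 2000,
                       true_bird_rate = function(depth) rep(0.2, length(depth)),
                       true_fish_rate = function(depth) rep(0, length(depth)),
                       true_mammal_rate = function(depth) rep(0, length(depth)))
  et1 <- expected_totals(cfg1)
  expect_equal(et1$birds, 0.6, tolerance = 1e-6)
  expect_equal(et1$fish, 0)
  expect_equal(et1$mammals, 0)

  # the study-shaped default is calibrated to the observed scale
  et <- expected_totals(fleet_config())
  expect_lt(abs(et$birds - 250) / 250, 0.25)
})

test_that("Monte-Carlo means agree with the analytic expectations within 3 SE", {
  cfg <- fleet_config(n_trips = 12, leb_trossas_total = 5, seed = NULL)
  et <- expected_totals(cfg)
  n_rep <- 500
  sims <- withr::with_seed(2024, {
    vapply(seq_len(n_rep), function(i) {
      d <- generate_fleet(cfg)$dataset
      c(birds = sum(group_counts(d, default_bird_species())),
        mammals = sum(group_counts(d, default_mammal_species())),
        fish = sum(d$lumpfish_count))
    }, numeric(3))
  })
  for (taxon in c("birds", "mammals", "fish")) {
    m <- mean(sims[taxon, ])
    se <- stats::sd(sims[taxon, ]) / sqrt(n_rep)
    expect_lt(abs(m - et[[taxon]]), 3 * se + 1e-9)
  }
})

test_that("the deterrent multiplier is recovered from effort-adjusted totals", {
  cfg <- fleet_config(n_trips = 60, leb_trossas_total = 60,
                      true_bird_rate = function(depth) rep(0.8, length(depth)),
                      leb_multiplier = 0.2, seed = NULL)
  ratios <- withr::with_seed(515, {
    vapply(1:40, function(i) {
      d <- generate_fleet(cfg)$dataset
      eff <- effort_days(d)
      leb_rate <- sum(group_counts(d, default_bird_species())[d$has_leb]) /
        sum(eff[d$has_leb])
      ctl_rate <- sum(group_counts(d, default_bird_species())[!d$has_leb]) /
        sum(eff[!d$has_leb])
      leb_rate / ctl_rate
    }, numeric(1))
  })
  expect_equal(mean(ratios), 0.2, tolerance = 0.15)
})

test_that("fleet configurations round-trip through YAML", {
  cfg <- fleet_config(n_trips = 9, leb_trossas_total = 2, leb_multiplier = 0.5,
                      seed = 6)
  path <- withr::local_tempfile(fileext = ".yml")
  write_fleet_config(cfg, path)
  cfg2 <- read_fleet_config(path)
  expect_equal(cfg2$n_trips, 9)
  expect_equal(cfg2$leb_multiplier, 0.5)
  expect_equal(cfg2$species_mix, cfg$species_mix, tolerance = 1e-9)
  depths <- c(3, 12, 27, 44, 70)
  expect_equal(cfg2$true_bird_rate(depths), cfg$true_bird_rate(depths))
  # same seed carried through: identical datasets
  expect_identical(tibble::as_tibble(generate_fleet(cfg2)$dataset),
                   tibble::as_tibble(generate_fleet(cfg)$dataset))
})
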