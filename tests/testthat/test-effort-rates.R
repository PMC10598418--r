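test_that("trossa area is net length x nets x height and rejects bad geometry", {
  expect_equal(trossa_area(50, 20, 2), 2000)
  expect_equal(trossa_area(615, 1, 1), 615)
  expect_error(trossa_area(50, 0, 2), "geometry")
  expect_error(trossa_area(-1, 5, 2), "geometry")
})

test_that("standardised rate scales counts to the reference trossa-day", {
  expect_equal(standardized_rate(0, 1500, 2), 0)
  expect_equal(standardized_rate(6, 2000, 3), 2)
  expect_equal(standardized_rate(1, 1000, 2), 1)
  expect_error(standardized_rate(1, 2000, 0), "soak_days")
  # rate is zero iff count is zero
  expect_true(all(standardized_rate(1:5, 1234, 2) > 0))
})

test_that("depth bins are half-open with an open top bin", {
  d <- tiny_fleet(c(35), birds = 2L)  # 2 birds, 1 standardised trossa-day
  r <- depth_binned_rates(d)
  expect_equal(r$bird_rate[r$depth_lo == 30], 2)
  expect_true(all(is.na(r$bird_rate[r$depth_lo != 30])))
  expect_equal(r$n_trossas[r$depth_lo == 30], 1L)

  # a depth exactly at an edge belongs to the upper bin
  r2 <- depth_binned_rates(tiny_fleet(20, birds = 1L))
  expect_equal(r2$bird_rate[r2$depth_lo == 20], 1)
  expect_true(is.na(r2$bird_rate[r2$depth_lo == 10]))

  # all records deeper than 50 m: only the open top bin defined
  r3 <- depth_binned_rates(tiny_fleet(c(55, 70), birds = c(1L, 0L)))
  expect_equal(sum(!is.na(r3$bird_rate)), 1L)
  expect_equal(r3$depth_hi[!is.na(r3$bird_rate)], Inf)
})

test_that("bin rate times bin effort recovers total counts for each taxon", {
  fleet <- generate_fleet(fleet_config(n_trips = 30, leb_trossas_total = 10,
                                       seed = 21))
  d <- fleet$dataset
  r <- depth_binned_rates(d)
  ok <- !is.na(r$fish_rate)
  expect_equal(sum(r$fish_rate[ok] * r$effort[ok]), sum(d$lumpfish_count))
  expect_equal(sum(r$bird_rate[ok] * r$effort[ok]),
               sum(group_counts(d, default_bird_species())))
  expect_equal(sum(r$mammal_rate[ok] * r$effort[ok]),
               sum(group_counts(d, default_mammal_species())))
})

test_that("rates are invariant to rescaling area and reference area together", {
  fleet <- generate_fleet(fleet_config(n_trips = 12, leb_trossas_total = 5,
                                       seed = 8))
  d <- fleet$dataset
  r1 <- depth_binned_rates(d, ref_area = 2000)
  d2 <- d
  d2$net_length <- d$net_length * 3
  r2 <- depth_binned_rates(d2, ref_area = 6000)
  expect_equal(r2$fish_rate, r1$fish_rate, tolerance = 1e-12)
  expect_equal(r2$bird_rate, r1$bird_rate, tolerance = 1e-12)
})

test_that("a constant true bird rate is recovered in every bin at study scale", {
  # sized so both tolerances are >= 3 SE of the Poisson totals involved
  cfg <- fleet_config(n_trips = 400, leb_trossas_total = 0,
                      true_bird_rate = function(depth) rep(0.2, length(depth)),
                      seed = 31)
  d <- generate_fleet(cfg)$dataset   # ~4200 trossas
  r <- depth_binned_rates(d)
  ok <- !is.na(r$bird_rate) & r$effort > 100
  expect_true(all(abs(r$bird_rate[ok] - 0.2) / 0.2 < 0.35))  # Poisson error
  pooled <- sum(r$bird_rate[ok] * r$effort[ok]) / sum(r$effort[ok])
  expect_lt(abs(pooled - 0.2) / 0.2, 0.1)
})

test_that("estimated rates converge to the generator's step functions", {
  # one large fleet (~150k trossas) so that the tolerance is >= 3 SE in
  # every tested bin, including the sparse deep ones
  d2 <- generate_fleet(fleet_config(n_trips = 14000, leb_trossas_total = 0,
                                    seed = 42))$dataset
  r2 <- depth_binned_rates(d2)
  truth_f <- reference_rate_table()$fish_rate
  expect_true(all(abs(r2$fish_rate - truth_f) / truth_f < 0.05))

  # bird rates are sparse: 5% for the bins up to 40 m, 15% for 40-50 m
  truth_b <- reference_rate_table()$bird_rate
  expect_true(all(abs(r2$bird_rate[1:4] - truth_b[1:4]) / truth_b[1:4] < 0.05))
  expect_lt(abs(r2$bird_rate[5] - truth_b[5]) / truth_b[5], 0.15)
  expect_equal(r2$bird_rate[6], 0)
})

test_that("rate tables round-trip through CSV", {
  r <- reference_rate_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_table(r, path)
  r2 <- read_rate_table(path)
  expect_equal(tibble::as_tibble(r2)[names(r)], tibble::as_tibble(r),
               tolerance = 1e-12)
  expect_error(rate_table(0, 10, -1, 0, 0), "fish_rate")
  expect_error(rate_table(c(0, 10), c(10, Inf), c(1, 1), c(0, 0), c(0, 0),
                          landings_proportion = c(0.6, 0.6)), "sum to 1")
})
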