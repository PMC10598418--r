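# Small fleets built in code for unit tests.

# n_per_trip trossas per trip, given depths; one LEB per trip (the first
# trossa) when leb = TRUE.
tiny_fleet <- function(depths, trips = rep("T001", length(depths)),
                       leb = rep(FALSE, length(depths)),
                       birds = rep(0L, length(depths)),
                       lumpfish = rep(0L, length(depths)),
                       soak = rep(1L, length(depths)),
                       area = rep(2000, length(depths))) {
  n <- length(depths)
  fleet_dataset(tibble::tibble(
    trip_id = trips, boat_id = "B01",
    date_set = as.Date("2022-04-01"),
    date_hauled = as.Date("2022-04-01") + soak,
    mean_depth = depths,
    net_length = area / 40, n_nets = 20L, net_height = 2,
    has_leb = leb, lumpfish_count = as.integer(lumpfish),
    common_eider = as.integer(birds)))
}

# Paired-design fleet where every trossa is identical: degenerate oracle.
identical_fleet <- function(n_trips = 6, n_ctrl = 4, count = 2L) {
  rows <- do.call(rbind, lapply(seq_len(n_trips), function(i) {
    tibble::tibble(trip = sprintf("T%02d", i),
                   leb = c(TRUE, rep(FALSE, n_ctrl)))
  }))
  tiny_fleet(depths = rep(20, nrow(rows)), trips = rows$trip, leb = rows$leb,
             birds = rep(count, nrow(rows)), lumpfish = rep(10L, nrow(rows)))
}
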