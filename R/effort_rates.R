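# Effort-standardised catch/bycatch rates and depth-binned rate tables.
#
# Effort is the trossa-day: one trossa of reference area 2000 m2 soaking for
# one day.  A trossa's area is net length x number of nets x net height; a
# raw count over (area x soak days) is scaled to the reference area so that
# rates from trossas of different sizes are comparable.

#' Trossa area from its net geometry
#'
#' @param net_length Length of one net (m).
#' @param n_nets Number of nets tied into the tier.
#' @param net_height Net height (m).
#' @return Area in m2 (`net_length * n_nets * net_height`), vectorised.
#' @export
#' @examples
#' trossa_area(50, 20, 2)   # 2000 m2, the reference trossa
trossa_area <- function(net_length, n_nets, net_height) {
  if (any(!is.finite(net_length) | net_length <= 0) ||
      any(is.na(n_nets) | n_nets < 1) ||
      any(!is.finite(net_height) | net_height <= 0)) {
    abort("trossa geometry must be positive (net_length > 0, n_nets >= 1, net_height > 0)")
  }
  net_length * n_nets * net_height
}

#' Catch or bycatch rate per reference trossa-day
#'
#' Standardises a raw count to animals per trossa-day at the reference trossa
#' area (2000 m2): `count / (area * soak_days) * ref_area`.
#'
#' @param count Animals (or fish) caught.
#' @param area Trossa area (m2).
#' @param soak_days Whole soak days (>= 1).
#' @param ref_area Reference trossa area (m2), default 2000.
#' @return Rate per reference trossa-day, vectorised.
#' @export
standardized_rate <- function(count, area, soak_days, ref_area = 2000) {
  if (any(!is.finite(area) | area <= 0)) abort("area must be > 0")
  if (any(is.na(soak_days) | soak_days < 1)) abort("soak_days must be >= 1")
  if (any(is.na(count) | count < 0)) abort("count must be >= 0")
  count / (area * soak_days) * ref_area
}

#' Standardised trossa-days fished by each record
#'
#' @param d A `fleet_dataset`.
#' @param ref_area Reference trossa area (m2); `NULL` uses raw trossa-days
#'   (soak days only, ignoring area).
#' @return Numeric vector of (standardised) trossa-days.
#' @export
effort_days <- function(d, ref_area = 2000) {
  sd_ <- soak_days(d)
  if (is.null(ref_area)) return(as.numeric(sd_))
  trossa_area(d$net_length, d$n_nets, d$net_height) / ref_area * sd_
}

rate_table_columns <- function() {
  c("depth_lo", "depth_hi", "fish_rate", "bird_rate", "mammal_rate",
    "landings_proportion")
}

#' Construct a depth-binned rate table
#'
#' A rate table holds, per 10 m (by default) depth bin, the pooled catch and
#' bycatch rates per standardised trossa-day, and optionally the proportion
#' of national annual landings taken in that bin (the link to fleet-wide
#' extrapolation). Bins are half-open `[lo, hi)`; the final bin is open above
#' (`depth_hi = Inf`).
#'
#' @param depth_lo,depth_hi Bin edges (m), ascending; last `depth_hi` may be `Inf`.
#' @param fish_rate,bird_rate,mammal_rate Rates per standardised trossa-day
#'   (`NA` marks a bin with no effort, whose rate is undefined).
#' @param landings_proportion Fraction of national landings per bin; must sum
#'   to 1 when supplied.
#' @param ... Further per-bin columns (e.g. effort, observed bycatch).
#' @return A `rate_table` tibble.
#' @export
rate_table <- function(depth_lo, depth_hi, fish_rate, bird_rate, mammal_rate,
                       landings_proportion = NA_real_, ...) {
  x <- tibble::tibble(
    depth_lo = as.numeric(depth_lo), depth_hi = as.numeric(depth_hi),
    fish_rate = as.numeric(fish_rate), bird_rate = as.numeric(bird_rate),
    mammal_rate = as.numeric(mammal_rate),
    landings_proportion = as.numeric(landings_proportion), ...)
  if (any(x$depth_hi <= x$depth_lo)) abort("bin edges must be ascending")
  if (is.unsorted(x$depth_lo)) abort("bins must be ordered by depth")
  for (col in c("fish_rate", "bird_rate", "mammal_rate")) {
    if (any(x[[col]] < 0, na.rm = TRUE)) abort(paste0(col, " must be >= 0"))
  }
  p <- x$landings_proportion
  if (!all(is.na(p))) {
    if (any(is.na(p) | p < 0)) abort("landings_proportion must be >= 0 in every bin")
    if (abs(sum(p) - 1) > 1e-9) abort("landings_proportion must sum to 1")
  }
  class(x) <- c("rate_table", class(x))
  x
}

#' Pooled catch and bycatch rates per depth bin
#'
#' Bins every record by its mean set depth into `[0, bin_width)`,
#' `[bin_width, 2*bin_width)`, ..., with a final open bin above `top_open_at`,
#' and computes per bin the effort-weighted pooled rate: total count divided
#' by total (standardised) trossa-days. Pooled rates -- not means of
#' per-trossa rates -- are used so that rate times effort recovers the
#' observed total in each bin. Bins containing no effort get `NA` rates
#' (undefined, not zero) and `n_trossas = 0`.
#'
#' @param d A `fleet_dataset`; every record needs `mean_depth > 0`.
#' @param bin_width Bin width in metres (default 10).
#' @param top_open_at Lower edge of the open top bin (default 50 m).
#' @param ref_area Reference trossa area for standardisation (m2); `NULL`
#'   uses raw trossa-days.
#' @return A [rate_table()] with extra columns `n_trossas`, `effort`
#'   (standardised trossa-days), `fish_count`, `bird_count`, `mammal_count`.
#' @export
depth_binned_rates <- function(d, bin_width = 10, top_open_at = 50,
                               ref_area = 2000) {
  if (any(!is.finite(d$mean_depth) | d$mean_depth <= 0)) {
    abort("every record needs mean_depth > 0")
  }
  lo <- seq(0, top_open_at, by = bin_width)
  hi <- c(lo[-1], Inf)
  eff <- effort_days(d, ref_area)
  bin <- findInterval(d$mean_depth, lo)  # [lo, hi) half-open, last bin open
  birds <- group_counts(d, bird_cols(d))
  mams <- if (length(mammal_cols(d))) group_counts(d, mammal_cols(d)) else
    numeric(nrow(d))
  sum_by <- function(v) {
    out <- numeric(length(lo))
    s <- tapply(v, factor(bin, levels = seq_along(lo)), sum)
    out[as.integer(names(s))] <- ifelse(is.na(s), 0, s)
    out
  }
  effort <- sum_by(eff)
  n <- sum_by(rep(1, nrow(d)))
  fish <- sum_by(as.numeric(d$lumpfish_count))
  bird <- sum_by(birds)
  mam <- sum_by(mams)
  empty <- effort == 0
  rate <- function(cnt) ifelse(empty, NA_real_, cnt / effort)
  rate_table(lo, hi,
             fish_rate = rate(fish), bird_rate = rate(bird),
             mammal_rate = rate(mam),
             landings_proportion = NA_real_,
             n_trossas = as.integer(n), effort = effort,
             fish_count = fish, bird_count = bird, mammal_count = mam)
}

#' Read or write a rate table as CSV
#'
#' Columns: `depth_lo, depth_hi, fish_rate, bird_rate, mammal_rate,
#' landings_proportion` plus any extras. `Inf` is used for the open top bin.
#'
#' @param path CSV path.
#' @return `read_rate_table()` returns a [rate_table()];
#'   `write_rate_table()` returns `path` invisibly.
#' @export
read_rate_table <- function(path) {
  x <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  missing_col <- setdiff(rate_table_columns(), names(x))
  if (length(missing_col)) {
    abort(paste0("rate table missing column(s): ", paste(missing_col, collapse = ", ")))
  }
  extra <- x[setdiff(names(x), rate_table_columns())]
  do.call(rate_table, c(as.list(x[rate_table_columns()]), as.list(extra)))
}

#' @rdname read_rate_table
#' @param x A `rate_table`.
#' @export
write_rate_table <- function(x, path) {
  readr::write_csv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
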