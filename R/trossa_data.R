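# Trossa-level fishing records: domain types, validation and CSV I/O.
#
# A "trossa" is a tier of gillnets tied together, set on the seabed and
# hauled after a soak of (normally) at most three days.  One row of a fleet
# dataset describes one trossa set and hauled once: its effort geometry
# (net length x number of nets x net height), the depth it was set at,
# whether it carried an above-water deterrent device (a looming-eyes buoy,
# LEB), and the catch and bycatch it produced.

#' Bird and mammal species recorded in the 2022 Icelandic lumpfish trial
#'
#' Canonical snake_case species labels used as count columns in a fleet
#' dataset. These are the nine seabird and six marine mammal species reported
#' bycaught during the 2022 Húnaflói Bay deterrent trial; datasets may carry
#' any other species columns as long as they are declared when reading.
#'
#' @return Character vector of column names.
#' @export
default_bird_species <- function() {
  c("black_guillemot", "common_guillemot", "atlantic_puffin",
    "european_shag", "great_cormorant", "common_eider",
    "long_tailed_duck", "red_throated_diver", "northern_fulmar")
}

#' @rdname default_bird_species
#' @export
default_mammal_species <- function() {
  c("harbour_seal", "grey_seal", "harp_seal",
    "white_beaked_dolphin", "bottlenose_dolphin", "harbour_porpoise")
}

#' Default species groupings for effect estimation
#'
#' Named list mapping group labels to species count columns. `"lumpfish"` is
#' special-cased throughout the package and refers to the target-catch column
#' rather than a bycatch species.
#'
#' @return Named list of character vectors.
#' @export
default_species_groups <- function() {
  list(
    all_birds        = default_bird_species(),
    guillemots       = c("common_guillemot", "black_guillemot"),
    common_eider     = "common_eider",
    long_tailed_duck = "long_tailed_duck",
    all_mammals      = default_mammal_species(),
    lumpfish         = "lumpfish"
  )
}

core_columns <- function() {
  c("trip_id", "boat_id", "date_set", "date_hauled", "mean_depth",
    "net_length", "n_nets", "net_height", "has_leb", "lumpfish_count")
}

optional_columns <- function() {
  c("latitude", "longitude", "observer_onboard")
}

#' Default column dialect for trossa tables
#'
#' A dialect maps the package's canonical field names to the column headers
#' of a delimited file, so that deposits with different plain-English headers
#' can be read without editing the file. The default is the identity mapping
#' on the canonical names.
#'
#' @param ... Named overrides, e.g. `mean_depth = "depth_m"`.
#' @return Named character vector (canonical name -> file header).
#' @export
#' @examples
#' default_dialect(mean_depth = "depth", trip_id = "trip")
default_dialect <- function(...) {
  nm <- c(core_columns(), optional_columns())
  dialect <- setNames(nm, nm)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), nm)
    if (length(bad)) {
      abort(paste0("unknown dialect field(s): ", paste(bad, collapse = ", ")))
    }
    dialect[names(over)] <- over
  }
  dialect
}

#' Construct a fleet dataset of trossa records
#'
#' Wraps a data frame of trossa-level records (one row per trossa set and
#' hauled once) into a `fleet_dataset`, attaching the lists of bird and
#' mammal species count columns and the named species groups used by the
#' effect estimator. Types are checked and dates coerced; substantive
#' invariants (positive geometry, non-negative integer counts, haul date not
#' before set date) are checked by [validate_dataset()], which reports rather
#' than rejects.
#'
#' @param x Data frame with the core columns `trip_id`, `boat_id`,
#'   `date_set`, `date_hauled`, `mean_depth`, `net_length`, `n_nets`,
#'   `net_height`, `has_leb`, `lumpfish_count`, plus one count column per
#'   species.
#' @param bird_species,mammal_species Character vectors naming the species
#'   count columns present in `x`. Missing columns are created as zero counts.
#' @param species_groups Named list of species groupings
#'   (see [default_species_groups()]).
#' @return A `fleet_dataset` (a tibble with species metadata attributes).
#' @export
fleet_dataset <- function(x,
                          bird_species = intersect(default_bird_species(), names(x)),
                          mammal_species = intersect(default_mammal_species(), names(x)),
                          species_groups = default_species_groups()) {
  x <- tibble::as_tibble(x)
  missing_core <- setdiff(core_columns(), names(x))
  if (length(missing_core)) {
    abort(paste0("missing required column(s): ",
                 paste(missing_core, collapse = ", ")))
  }
  for (col in c("date_set", "date_hauled")) {
    x[[col]] <- as.Date(x[[col]])
  }
  x$has_leb <- as.logical(x$has_leb)
  for (sp in c(bird_species, mammal_species)) {
    if (!sp %in% names(x)) x[[sp]] <- 0L
  }
  new_fleet_dataset(x, bird_species, mammal_species, species_groups)
}

new_fleet_dataset <- function(x, bird_species, mammal_species, species_groups) {
  structure(
    x,
    bird_species = bird_species,
    mammal_species = mammal_species,
    species_groups = species_groups,
    class = c("fleet_dataset", class(tibble::tibble()))
  )
}

#' @export
print.fleet_dataset <- function(x, ...) {
  cat(sprintf("# Fleet dataset: %d trossas, %d trips, %d with deterrent\n",
              nrow(x), length(unique(x$trip_id)), sum(x$has_leb, na.rm = TRUE)))
  NextMethod()
}

# Species metadata survives most single-table verbs poorly; always recover it
# through these accessors, which fall back to the default species lists.
bird_cols <- function(d) {
  attr(d, "bird_species") %||% intersect(default_bird_species(), names(d))
}
mammal_cols <- function(d) {
  attr(d, "mammal_species") %||% intersect(default_mammal_species(), names(d))
}
group_defs <- function(d) {
  attr(d, "species_groups") %||% default_species_groups()
}

#' Whole-day soak time of each trossa
#'
#' Soak time is the number of days a trossa remains in the water between
#' setting and hauling. The unit of effort is the trossa-day, so fractional
#' soaks are rounded to the nearest whole day with a minimum of one day
#' (a trossa set and hauled on the same date still fished).
#'
#' @param d A `fleet_dataset` or data frame with `date_set`/`date_hauled`.
#' @return Integer vector of soak days (>= 1).
#' @export
soak_days <- function(d) {
  pmax(1L, as.integer(round(as.numeric(d$date_hauled - d$date_set))))
}

#' Resolve a species group to per-record counts
#'
#' @param d A `fleet_dataset`.
#' @param group Either `"lumpfish"`, the name of a group defined in the
#'   dataset's species groups, or a character vector of species count columns.
#' @return Integer vector of per-record counts.
#' @export
group_counts <- function(d, group) {
  if (length(group) == 1L && group %in% names(group_defs(d))) {
    group <- group_defs(d)[[group]]
  }
  if (identical(group, "lumpfish")) {
    return(as.numeric(d$lumpfish_count))
  }
  missing_sp <- setdiff(group, names(d))
  if (length(missing_sp)) {
    abort(paste0("species group resolves to column(s) absent from the dataset: ",
                 paste(missing_sp, collapse = ", ")))
  }
  if (!length(group)) abort("species group resolves to no species")
  rowSums(as.data.frame(d)[, group, drop = FALSE])
}

#' Read a trossa-level fishing table from CSV
#'
#' Reads a delimited table (comma-separated, UTF-8, header row) with one row
#' per trossa. Column headers are resolved through a `dialect`
#' (see [default_dialect()]); dates must be ISO-8601 and booleans `0/1` or
#' `true/false`. Columns that are neither core fields nor declared species
#' are kept on the dataset (and preserved on write) but ignored by every
#' computation, with a warning naming them.
#'
#' @param path Path to the CSV file.
#' @param dialect Named character vector mapping canonical field names to the
#'   file's headers.
#' @param bird_species,mammal_species Species count columns expected in the
#'   file (by their file names; no dialect is applied to species columns).
#' @param species_groups Named list of species groupings.
#' @return A [fleet_dataset()].
#' @export
read_trossa_table <- function(path,
                              dialect = default_dialect(),
                              bird_species = default_bird_species(),
                              mammal_species = default_mammal_species(),
                              species_groups = default_species_groups()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- dialect[core_columns()]
  missing_hdr <- required[!required %in% names(raw)]
  if (length(missing_hdr)) {
    abort(paste0("missing required column(s): ",
                 paste(sprintf("'%s' (field %s)", missing_hdr, names(missing_hdr)),
                       collapse = ", ")))
  }
  present <- dialect[dialect %in% names(raw)]
  x <- raw
  names(x)[match(present, names(x))] <- names(present)

  bird_species <- intersect(bird_species, names(x))
  mammal_species <- intersect(mammal_species, names(x))
  known <- c(core_columns(), optional_columns(), bird_species, mammal_species)
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    warn(paste0("ignoring column(s) not in the dialect or species lists: ",
                paste(extra, collapse = ", ")))
  }

  parse_num <- function(col, integer = FALSE) {
    v <- x[[col]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      abort(sprintf("column '%s': unparseable number at row(s) %s",
                    col, paste(bad, collapse = ", ")))
    }
    if (integer) as.integer(round(out)) else out
  }
  parse_date <- function(col) {
    v <- x[[col]]
    out <- as.Date(v, format = "%Y-%m-%d")
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad)) {
      abort(sprintf("column '%s': unparseable date at row(s) %s",
                    col, paste(bad, collapse = ", ")))
    }
    out
  }
  parse_lgl <- function(col) {
    v <- tolower(x[[col]])
    out <- ifelse(v %in% c("1", "true", "t", "yes"), TRUE,
                  ifelse(v %in% c("0", "false", "f", "no"), FALSE, NA))
    bad <- which(!is.na(x[[col]]) & is.na(out))
    if (length(bad)) {
      abort(sprintf("column '%s': unparseable boolean at row(s) %s",
                    col, paste(bad, collapse = ", ")))
    }
    out
  }

  x$date_set <- parse_date("date_set")
  x$date_hauled <- parse_date("date_hauled")
  for (col in c("mean_depth", "net_length", "net_height")) x[[col]] <- parse_num(col)
  x$n_nets <- parse_num("n_nets", integer = TRUE)
  x$has_leb <- parse_lgl("has_leb")
  x$lumpfish_count <- parse_num("lumpfish_count", integer = TRUE)
  for (sp in c(bird_species, mammal_species)) x[[sp]] <- parse_num(sp, integer = TRUE)
  for (col in intersect(c("latitude", "longitude"), names(x))) x[[col]] <- parse_num(col)
  if ("observer_onboard" %in% names(x)) x$observer_onboard <- parse_lgl("observer_onboard")

  fleet_dataset(x, bird_species, mammal_species, species_groups)
}

#' Write a fleet dataset to CSV
#'
#' Inverse of [read_trossa_table()]: `read_trossa_table(write_trossa_table(d))`
#' reproduces the dataset exactly (counts, flags, dates). Dates are written
#' ISO-8601 and booleans as `true`/`false`; unknown columns carried by the
#' dataset are preserved.
#'
#' @param d A `fleet_dataset`.
#' @param path Output path.
#' @param dialect Column dialect used to rename canonical fields on output.
#' @return `path`, invisibly.
#' @export
write_trossa_table <- function(d, path, dialect = default_dialect()) {
  x <- tibble::as_tibble(d)
  present <- dialect[names(dialect) %in% names(x)]
  names(x)[match(names(present), names(x))] <- present
  for (col in names(x)) {
    if (inherits(x[[col]], "Date")) x[[col]] <- format(x[[col]], "%Y-%m-%d")
    if (is.logical(x[[col]])) x[[col]] <- ifelse(x[[col]], "true", "false")
  }
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}

#' Validate a fleet dataset against its record invariants
#'
#' Checks every record for: haul date not before set date; positive depth and
#' net geometry (`n_nets >= 1`); non-negative integer catch and bycatch
#' counts. Violations are data, not exceptions: the report lists each one
#' with its record index and rule. Records soaking longer than the 3-day
#' regulatory maximum are flagged separately (the regulation allows
#' exceedance in bad weather) and are not treated as violations.
#'
#' @param d A `fleet_dataset`.
#' @return A `validation_report`: list with `n_records`, `n_trips`, `n_leb`,
#'   a `violations` tibble (`record`, `rule`, `message`) and a `flags` tibble.
#' @export
validate_dataset <- function(d) {
  viol <- list()
  add <- function(idx, rule, msg) {
    if (length(idx)) {
      viol[[length(viol) + 1L]] <<- tibble::tibble(
        record = as.integer(idx), rule = rule,
        message = sprintf(msg, idx))
    }
  }
  add(which(is.na(d$date_set) | is.na(d$date_hauled) | d$date_hauled < d$date_set),
      "haul_after_set", "record %d: date_hauled earlier than date_set (or missing)")
  add(which(!is.finite(d$mean_depth) | d$mean_depth <= 0),
      "positive_depth", "record %d: mean_depth must be > 0")
  add(which(!is.finite(d$net_length) | d$net_length <= 0),
      "positive_net_length", "record %d: net_length must be > 0")
  add(which(is.na(d$n_nets) | d$n_nets < 1),
      "min_one_net", "record %d: n_nets must be >= 1")
  add(which(!is.finite(d$net_height) | d$net_height <= 0),
      "positive_net_height", "record %d: net_height must be > 0")
  count_cols <- c("lumpfish_count", bird_cols(d), mammal_cols(d))
  for (col in count_cols) {
    v <- d[[col]]
    bad <- which(is.na(v) | v < 0 | v != round(v))
    add(bad, paste0("count_", col),
        paste0("record %d: ", col, " must be a non-negative integer"))
  }
  flags <- tibble::tibble(record = integer(), rule = character(), message = character())
  ok_dates <- !is.na(d$date_set) & !is.na(d$date_hauled) & d$date_hauled >= d$date_set
  long <- which(ok_dates & soak_days(d) > 3)
  if (length(long)) {
    flags <- tibble::tibble(
      record = long, rule = "soak_over_3_days",
      message = sprintf("record %d: soak exceeds the 3-day regulatory maximum", long))
  }
  violations <- if (length(viol)) dplyr::bind_rows(viol) else
    tibble::tibble(record = integer(), rule = character(), message = character())
  structure(
    list(n_records = nrow(d),
         n_trips = length(unique(d$trip_id)),
         n_leb = sum(d$has_leb, na.rm = TRUE),
         violations = dplyr::arrange(violations, .data$record),
         flags = flags),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation: %d records, %d trips, %d deterrent trossas\n",
              x$n_records, x$n_trips, x$n_leb))
  if (nrow(x$violations) == 0) {
    cat("No invariant violations.\n")
  } else {
    cat(sprintf("%d violation(s):\n", nrow(x$violations)))
    print(x$violations, n = 20)
  }
  if (nrow(x$flags)) cat(sprintf("%d record(s) flagged (soak > 3 days).\n", nrow(x$flags)))
  invisible(x)
}

#' Read species groups from a YAML file
#'
#' The file maps group labels to lists of species column names, e.g.
#' `guillemots: [common_guillemot, black_guillemot]`.
#'
#' @param path Path to a YAML file.
#' @return Named list of character vectors.
#' @export
read_species_groups <- function(path) {
  g <- yaml::read_yaml(path)
  lapply(g, as.character)
}
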