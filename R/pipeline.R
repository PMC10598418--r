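# End-to-end pipeline: validate -> effect table -> depth rates -> scenarios.

#' Pipeline configuration
#'
#' @param data Path to a trossa-level CSV (see [read_trossa_table()]).
#' @param rates Path to a depth rate table CSV with landings proportions
#'   (see [read_rate_table()]); `NULL` derives rates from the data alone
#'   (scenario stage is then skipped unless landings proportions are known).
#' @param landings Path to a landings CSV with columns `year,tons`; `NULL`
#'   skips the scenario stage.
#' @param out_dir Output directory (created if missing).
#' @param groups Species groups for the effect table.
#' @param n_iter Bootstrap iterations.
#' @param depth_sd Depth-matching standard deviation (m).
#' @param scenario_depths Restriction depths (m).
#' @param seed Root seed governing the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(data, rates = NULL, landings = NULL,
                            out_dir = "trossa-run",
                            groups = names(default_species_groups()),
                            n_iter = 10000, depth_sd = 5,
                            scenario_depths = c(10, 20, 30, 40, 50),
                            seed = 1L) {
  structure(list(data = data, rates = rates, landings = landings,
                 out_dir = out_dir, groups = groups, n_iter = n_iter,
                 depth_sd = depth_sd, scenario_depths = scenario_depths,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of
#'   [pipeline_config()]; relative paths are resolved against the file's
#'   directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) {
    if (is.null(p) || file.exists(p) || grepl("^/", p)) p else file.path(base, p)
  }
  cfg <- do.call(pipeline_config, raw)
  for (fld in c("data", "rates", "landings")) cfg[[fld]] <- resolve(cfg[[fld]])
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
          class = "trossa_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Stages: read and validate the trossa data; estimate the deterrent effect
#' per species group (paired depth-matched bootstrap); compute the
#' depth-binned rate table; if a rate table with landings proportions and a
#' landings series are supplied, simulate the depth-restriction scenarios.
#' Writes `validation_report.csv`, `effect_table.csv`, `rate_table.csv`,
#' `scenario_table.csv` and a `manifest.json` (seed, package version,
#' configuration digest, timestamp) into `out_dir`. Reruns with the same
#' configuration and seed produce byte-identical tables. On failure the
#' completed artifacts are retained alongside a `FAILED` marker naming the
#' stage.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `status` (0 on success) and `artifacts`
#'   (named paths).
#' @export
run_all <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    validation = file.path(cfg$out_dir, "validation_report.csv"),
    effects = file.path(cfg$out_dir, "effect_table.csv"),
    rates = file.path(cfg$out_dir, "rate_table.csv"),
    scenarios = file.path(cfg$out_dir, "scenario_table.csv"),
    manifest = file.path(cfg$out_dir, "manifest.json"))
  marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  on_fail <- function(e) {
    writeLines(conditionMessage(e), marker)
    stop(e)
  }
  withCallingHandlers({
    d <- stage("data", read_trossa_table(cfg$data))
    rep <- stage("validate", validate_dataset(d))
    vr <- dplyr::bind_rows(rep$violations,
                           rep$flags[, c("record", "rule", "message")])
    readr::write_csv(vr, paths$validation, progress = FALSE)

    bcfg <- bootstrap_config(n_iter = cfg$n_iter, depth_sd = cfg$depth_sd,
                             seed = cfg$seed)
    eff <- stage("leb_effect", effect_table(d, cfg$groups, bcfg))
    readr::write_csv(eff, paths$effects, progress = FALSE)

    emp <- stage("rates", depth_binned_rates(d))
    write_rate_table(emp, paths$rates)

    if (!is.null(cfg$rates) && !is.null(cfg$landings)) {
      rt <- stage("scenario_rates", {
        r <- read_rate_table(cfg$rates)
        if ("annual_bird_bycatch" %in% names(r)) {
          e <- effort_from_landings(sum(r$annual_catch_tons), r)
          r <- unrounded_bird_rates(r, r$annual_bird_bycatch, e)
        }
        r
      })
      landings <- stage("landings",
                        readr::read_csv(cfg$landings,
                                        col_types = readr::cols(),
                                        progress = FALSE))
      sc <- stage("scenarios", scenario_table(landings, rt, cfg$scenario_depths))
      readr::write_csv(sc, paths$scenarios, progress = FALSE)
    } else {
      paths$scenarios <- NULL
    }

    manifest <- list(
      package = "trossa",
      version = as.character(utils::packageVersion("trossa")),
      seed = cfg$seed,
      config_digest = config_digest(cfg),
      n_records = nrow(d), n_trips = rep$n_trips, n_leb = rep$n_leb,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE)
  }, error = on_fail)
  invisible(list(status = 0L, artifacts = paths))
}

# Order-stable digest of the configuration (31-adic hash of its YAML text).
config_digest <- function(cfg) {
  txt <- yaml::as.yaml(cfg[sort(names(unclass(cfg)))])
  h <- 0
  for (code in utf8ToInt(txt)) h <- (h * 31 + code) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Create a demonstration workspace
#'
#' Writes into `dir`: a synthetic trossa table (`trossas.csv`, generated
#' with the study-shaped default configuration and the given seed), the
#' published depth rate table with landings proportions and per-bin annual
#' bycatch (`rates.csv`), the 2014-2021 landings series (`landings.csv`,
#' partly synthetic -- see [reference_landings()]), and a pipeline
#' configuration (`config.yml`). The rate and landings files are fixed
#' published constants and identical across seeds; only the synthetic fleet
#' varies. Running [run_all()] on the workspace reproduces the published
#' restriction-scenario means from the packaged rate inputs.
#'
#' @param dir Workspace directory (created if missing).
#' @param seed Integer seed for the synthetic fleet.
#' @return Invisibly, named paths of the created files.
#' @export
make_demo <- function(dir = "trossa-demo", seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fleet <- generate_fleet(fleet_config(seed = seed))
  paths <- list(data = file.path(dir, "trossas.csv"),
                rates = file.path(dir, "rates.csv"),
                landings = file.path(dir, "landings.csv"),
                config = file.path(dir, "config.yml"))
  write_trossa_table(fleet$dataset, paths$data)
  write_rate_table(reference_rate_table(), paths$rates)
  readr::write_csv(reference_landings()[, c("year", "tons")], paths$landings,
                   progress = FALSE)
  yaml::write_yaml(list(data = "trossas.csv", rates = "rates.csv",
                        landings = "landings.csv",
                        out_dir = file.path(dir, "out"),
                        n_iter = 1000, seed = seed),
                   paths$config)
  invisible(paths)
}
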