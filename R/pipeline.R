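# End-to-end analysis drivers: configuration, cohort simulation runs,
# and the consolidated cost-effectiveness report.

#' Read a run configuration
#'
#' Accepts a YAML or JSON file (by extension) or a ready-made list.
#' Recognised fields: `seed` (mandatory), `horizon` (default 30),
#' `n_reps`, `n_patients`, `matrix_csv_chg`, `matrix_csv_nonchg`
#' (defaults to the shipped calibrated synthetic matrices), `costs`
#' (named overrides for [cost_parameters()]) and `tornado_ranges`.
#'
#' @param config Path to a YAML/JSON file, or a list.
#' @return A validated configuration list of class `run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  if (is.null(config$seed)) {
    stop("run configuration must set a seed", call. = FALSE)
  }
  defaults <- list(horizon = 30L, n_reps = 1000L, n_patients = 1000L,
                   matrix_csv_chg = NULL, matrix_csv_nonchg = NULL,
                   costs = list(), tornado_ranges = NULL)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  structure(config, class = c("run_config", "list"))
}

# Resolve the per-arm matrices named by a config (fixtures by default).
config_matrices <- function(config) {
  load_arm <- function(path, arm) {
    if (is.null(path)) fixture_matrices(arm)
    else read_matrix_csv(path, arm = arm, horizon = config$horizon)
  }
  list(CHG = load_arm(config$matrix_csv_chg, "CHG"),
       nonCHG = load_arm(config$matrix_csv_nonchg, "nonCHG"))
}

config_costs <- function(config) {
  do.call(cost_parameters, config$costs)
}

# Reproducibility manifest: seed plus a complete parameter dump and its
# checksum.  Deliberately timestamp-free so identical runs are
# byte-identical.
write_manifest <- function(config, params, path) {
  dump <- list(
    seed = config$seed, horizon = config$horizon,
    n_reps = config$n_reps, n_patients = config$n_patients,
    matrix_csv_chg = config$matrix_csv_chg,
    matrix_csv_nonchg = config$matrix_csv_nonchg,
    cost_parameters = unclass(params)
  )
  txt <- yaml::as.yaml(dump)
  tmp <- tempfile()
  writeLines(txt, tmp)
  dump$config_md5 <- unname(tools::md5sum(tmp))
  unlink(tmp)
  yaml::write_yaml(dump, path)
  invisible(path)
}

#' Simulate one base-case cohort per arm and write summaries
#'
#' Runs a single cohort of `n_patients` per arm from the configured
#' matrices and writes, per arm, a cohort summary CSV (occupancy per
#' 1,000, ICU days, mean cost) plus a reproducibility manifest.
#'
#' @param config A [read_run_config()] input.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the two `cohort_result` objects and
#'   the written file paths.
#' @export
run_simulation <- function(config, out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  M <- config_matrices(config)
  params <- config_costs(config)
  res <- list()
  files <- character(0)
  for (arm in ARM_LEVELS) {
    costs <- build_state_costs(params, arm)
    r <- simulate_cohort(M[[arm]], costs, config$n_patients,
                         seed = config$seed + match(arm, ARM_LEVELS) - 1L)
    r$arm <- arm
    res[[arm]] <- r
    f <- file.path(out_dir, sprintf("cohort_summary_%s.csv",
                                    tolower(arm)))
    utils::write.csv(data.frame(
      name = c(paste0("ever_state", 1:8, "_per_1000"), "icu_days",
               "days_to_discharge", "days_to_death", "mean_cost",
               "n_patients", "seed"),
      value = c(1000 * r$ever_counts / r$n_patients, r$icu_days,
                r$days_to_discharge, r$days_to_death, r$mean_cost,
                r$n_patients, r$seed)
    ), f, row.names = FALSE)
    files <- c(files, f)
  }
  manifest <- file.path(out_dir, "run_manifest.yaml")
  write_manifest(config, params, manifest)
  invisible(list(results = res, files = c(files, manifest)))
}

#' Run the full cost-effectiveness analysis and write the report
#'
#' Drives the complete pipeline on the configured matrices: the
#' probabilistic sensitivity analysis ([run_psa()]), the mean-level
#' economic endpoints, the one-way tornado analysis ([tornado()]), and
#' a consolidated plain-text report.  Writes `ce_result.csv`,
#' `ce_plane.csv`, `tornado.csv`, `report.txt` and
#' `run_manifest.yaml`.
#'
#' @param config A [read_run_config()] input.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the `psa_result`, the base-case
#'   `ce_result`, the `tornado_result` and the written file paths.
#' @export
run_analysis <- function(config, out_dir) {
  config <- read_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  M <- config_matrices(config)
  params <- config_costs(config)

  psa <- run_psa(M$CHG, M$nonCHG, params, n_reps = config$n_reps,
                 n_patients = config$n_patients, seed = config$seed)
  chg <- simulate_cohort(M$CHG, build_state_costs(params, "CHG"),
                         config$n_patients, seed = config$seed)
  chg$arm <- "CHG"
  ref <- simulate_cohort(M$nonCHG, build_state_costs(params, "nonCHG"),
                         config$n_patients, seed = config$seed + 1L)
  ce <- compare_arms(chg, ref, wtp = params$wtp)
  torn <- tornado(params, M$CHG, M$nonCHG, ranges = config$tornado_ranges)

  f_ce <- file.path(out_dir, "ce_result.csv")
  write_ce_csv(ce, f_ce)
  f_plane <- file.path(out_dir, "ce_plane.csv")
  write_ce_plane_csv(psa, f_plane)
  f_torn <- file.path(out_dir, "tornado.csv")
  write_tornado_csv(torn, f_torn)
  f_report <- file.path(out_dir, "report.txt")
  writeLines(c(
    "Cost-effectiveness analysis: CHG vs non-antimicrobial dressing",
    strrep("-", 62),
    utils::capture.output(print(psa)),
    "",
    "Base-case single-cohort comparison:",
    utils::capture.output(print(ce)),
    "",
    utils::capture.output(print(torn))
  ), f_report)
  manifest <- file.path(out_dir, "run_manifest.yaml")
  write_manifest(config, params, manifest)

  invisible(list(psa = psa, ce = ce, tornado = torn,
                 files = c(f_ce, f_plane, f_torn, f_report, manifest)))
}
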