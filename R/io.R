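#' Read or write a trial configuration file
#'
#' Configurations travel as YAML (or JSON, chosen by extension) and
#' round-trip exactly: parse -> serialize -> parse is the identity.
#'
#' @param config A [trial_config()].
#' @param path File path ending in `.yml`/`.yaml` or `.json`.
#' @return `read_trial_config()` returns a validated [trial_config()];
#'   `write_trial_config()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_trial_config(trial_config(), f)
#' read_trial_config(f)
#' @export
write_trial_config <- function(config, path) {
  stopifnot(inherits(config, "trial_config"))
  fields <- config[c("dose_levels", "target", "tau", "f_star", "n_max",
                     "accrual_rate", "cohort_size")]
  fields <- fields[!vapply(fields, is.null, TRUE)]
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(fields, path, precision = 15L)
  }
  invisible(path)
}

#' @rdname write_trial_config
#' @export
read_trial_config <- function(path) {
  fields <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("dose_levels", "target", "tau", "f_star", "n_max",
             "accrual_rate", "cohort_size")
  unknown <- setdiff(names(fields), known)
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(trial_config, fields)
}

#' Write a design comparison to disk
#'
#' Writes the operating-characteristics table (`oc.csv`, one row per
#' scenario x design), the per-dose selection profile (`selection.csv`),
#' the cross-scenario contrasts (`contrasts.csv`, when present), a JSON
#' mirror of all three (`results.json`), and a run manifest
#' (`manifest.json`) recording the configuration, scenario and design
#' sets, replicate count, master seed and package version — enough to
#' reproduce the run exactly.
#'
#' @param comparison A [compare_designs()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_comparison <- function(comparison, dir) {
  stopifnot(inherits(comparison, "design_comparison"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(comparison$oc, file.path(dir, "oc.csv"), row.names = FALSE)
  write.csv(comparison$selection, file.path(dir, "selection.csv"),
            row.names = FALSE)
  if (!is.null(comparison$contrasts)) {
    write.csv(comparison$contrasts, file.path(dir, "contrasts.csv"),
              row.names = FALSE)
  }
  jsonlite::write_json(
    list(oc = comparison$oc, selection = comparison$selection,
         contrasts = comparison$contrasts),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  jsonlite::write_json(
    run_manifest(comparison$config,
                 scenarios = unique(comparison$oc$scenario),
                 designs = unique(comparison$oc$design),
                 n_reps = comparison$n_reps, seed = comparison$seed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

run_manifest <- function(config, scenarios, designs, n_reps, seed) {
  list(
    package = "titetrial",
    version = as.character(packageVersion("titetrial")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[c("dose_levels", "target", "tau", "f_star", "n_max",
                      "accrual_rate", "cohort_size")],
    scenarios = scenarios,
    designs = designs,
    n_reps = n_reps,
    seed = seed
  )
}
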