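# assemble the common single-trial result object
new_trial_result <- function(design, scenario, config, arrival, treat, dose,
                             tox, tox_time, mtd, constrained, duration,
                             audit = NULL) {
  m <- scenario$true_mtd
  alloc <- c(below = sum(dose < m), at = sum(dose == m), above = sum(dose > m))
  structure(
    list(
      design = design,
      scenario = scenario$name,
      true_mtd = m,
      mtd_index = as.integer(mtd),
      mtd_constrained = isTRUE(constrained),
      n_enrolled = length(dose),
      n_toxicities = sum(tox),
      duration = duration,
      allocation = alloc,
      roster = data.frame(
        id = seq_along(dose),
        arrival_time = arrival,
        treat_time = treat,
        dose_index = as.integer(dose),
        toxicity = as.integer(tox),
        toxicity_time = ifelse(tox, tox_time, NA_real_)
      ),
      audit = audit
    ),
    class = "trial_result"
  )
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("%s trial under %s\n", x$design, x$scenario))
  cat(sprintf("  declared MTD : dose %d%s (true MTD: dose %d)\n",
              x$mtd_index,
              if (x$mtd_constrained) " (safety-constrained)" else "",
              x$true_mtd))
  cat(sprintf("  enrolled     : %d patients, %d toxicities\n",
              x$n_enrolled, x$n_toxicities))
  cat(sprintf("  duration     : %.1f months (%.2f years)\n",
              x$duration, x$duration / 12))
  cat(sprintf("  allocation   : %d below / %d at / %d above the true MTD\n",
              x$allocation[["below"]], x$allocation[["at"]],
              x$allocation[["above"]]))
  invisible(x)
}

#' Serialize a trial result or its decision audit trail
#'
#' `trial_result_json()` renders the whole result as JSON.
#' `write_audit()` writes the per-decision audit log (one JSON record per
#' line: decision time, raw and isotonic estimates, the dose assigned and
#' whether a safety constraint bound) for trials run with `audit = TRUE`.
#'
#' @param x A `trial_result`.
#' @param path Output file path.
#' @return `trial_result_json()` a JSON string; `write_audit()` `path`,
#'   invisibly.
#' @export
trial_result_json <- function(x) {
  stopifnot(inherits(x, "trial_result"))
  jsonlite::toJSON(unclass(x[setdiff(names(x), "audit")]),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname trial_result_json
#' @export
write_audit <- function(x, path) {
  stopifnot(inherits(x, "trial_result"))
  if (is.null(x$audit)) {
    stop("trial was run without audit = TRUE", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in x$audit) {
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
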