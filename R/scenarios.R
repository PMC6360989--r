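# True toxicity-by-tau probabilities for the ten benchmark scenarios
# (six dose levels each).  Scenarios 1-8 follow the classical isotonic
# design literature; 9 and 10 are flatter / plateaued curves.
.scenario_probs <- matrix(c(
  0.05, 0.10, 0.20, 0.30, 0.50, 0.70,
  0.09, 0.16, 0.27, 0.38, 0.57, 0.75,
  0.30, 0.40, 0.52, 0.61, 0.76, 0.87,
  0.00, 0.00, 0.04, 0.09, 0.25, 0.49,
  0.20, 0.90, 0.90, 0.90, 0.90, 0.90,
  0.10, 0.20, 0.90, 0.90, 0.90, 0.90,
  0.30, 0.30, 0.50, 0.50, 0.50, 0.50,
  0.00, 0.00, 0.03, 0.05, 0.11, 0.33,
  0.12, 0.18, 0.22, 0.25, 0.33, 0.50,
  0.10, 0.10, 0.20, 0.20, 0.40, 0.40
), nrow = 10, byrow = TRUE)

#' The ten benchmark dose-toxicity scenarios
#'
#' Returns the ten true dose-toxicity curves used throughout the package's
#' operating-characteristics study: for each scenario, the true probability
#' of a dose-limiting toxicity by the follow-up window at each of six dose
#' levels.  All curves are non-decreasing in dose.
#'
#' @return Data frame with columns `scenario` (1..10) and `p1`..`p6`.
#' @examples
#' scenario_table()
#' @export
scenario_table <- function() {
  out <- data.frame(scenario = 1:10, .scenario_probs)
  names(out) <- c("scenario", paste0("p", 1:6))
  out
}

#' Construct a dose-toxicity scenario
#'
#' `scenario(id)` fetches one of the ten shipped benchmark scenarios;
#' `dose_scenario(probs)` builds a custom one.  The true MTD index — the
#' dose whose toxicity probability is closest to the target without
#' exceeding it, ties broken toward the highest dose, dose 1 when even the
#' lowest dose exceeds the target — is derived and cached on the object.
#'
#' @param id Scenario number, 1 to 10.
#' @param probs Numeric vector of toxicity-by-tau probabilities in `[0, 1]`,
#'   non-decreasing in dose.
#' @param name Identifier used in reports.
#' @param target Target toxicity probability used to derive the true MTD.
#'
#' @return An object of class `dose_scenario`: list with `name`,
#'   `true_probs`, `target` and `true_mtd`.
#' @examples
#' scenario(1)$true_mtd     # dose 4 (prob 0.30)
#' scenario(7)$true_mtd     # dose 2 (tie at 0.30 broken high)
#' dose_scenario(c(0.1, 0.2, 0.5), name = "steep")
#' @export
scenario <- function(id, target = 1 / 3) {
  if (length(id) != 1L || is.na(id) || !(id %in% 1:10)) {
    stop("id must be a single scenario number between 1 and 10", call. = FALSE)
  }
  dose_scenario(.scenario_probs[id, ], name = paste0("scenario-", id),
                target = target)
}

#' @rdname scenario
#' @export
dose_scenario <- function(probs, name = "custom", target = 1 / 3) {
  probs <- as.numeric(probs)
  if (length(probs) < 1L || anyNA(probs) || any(probs < 0 | probs > 1)) {
    stop("probs must be probabilities in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(probs)) {
    stop("toxicity probabilities must be non-decreasing in dose",
         call. = FALSE)
  }
  structure(list(name = as.character(name),
                 true_probs = probs,
                 target = target,
                 true_mtd = true_mtd_index(probs, target)),
            class = "dose_scenario")
}

#' True MTD index of a toxicity curve
#'
#' @param probs Non-decreasing vector of true toxicity probabilities.
#' @param target Target toxicity probability.
#' @return Index of the dose with probability closest to `target` without
#'   exceeding it, ties to the highest dose; 1 when all doses exceed the
#'   target.
#' @examples
#' true_mtd_index(c(0.05, 0.10, 0.20, 0.30, 0.50, 0.70), 1 / 3)
#' @export
true_mtd_index <- function(probs, target = 1 / 3) {
  ok <- which(probs <= target)
  if (length(ok) == 0L) return(1L)
  gap <- target - probs[ok]
  as.integer(max(ok[gap <= min(gap) + 1e-12]))
}

#' @export
print.dose_scenario <- function(x, ...) {
  cat(sprintf("dose-toxicity scenario '%s'\n", x$name))
  cat("  true probs:", paste(format(x$true_probs), collapse = " "), "\n")
  cat(sprintf("  true MTD  : dose %d (target %.3f)\n", x$true_mtd, x$target))
  invisible(x)
}

# accept a dose_scenario, a shipped scenario id, or a bare probability
# vector wherever an engine expects a scenario
as_dose_scenario <- function(x, target = 1 / 3) {
  if (inherits(x, "dose_scenario")) return(x)
  if (is.numeric(x) && length(x) == 1L && x %in% 1:10) {
    return(scenario(x, target))
  }
  dose_scenario(x, target = target)
}

#' Read or write scenario fixtures
#'
#' Scenarios travel as a small CSV (columns `scenario`, `p1`..`pJ`) or
#' YAML file, so that a simulation study's inputs can be archived next to
#' its outputs.
#'
#' @param path File path; format is chosen by extension (`.csv`, `.yml` /
#'   `.yaml`).
#' @param scenarios Data frame shaped like [scenario_table()].
#' @return `read_scenarios()` returns the data frame;
#'   `write_scenarios()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_scenarios(f)
#' identical(read_scenarios(f), scenario_table())
#' @export
write_scenarios <- function(path, scenarios = scenario_table()) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lapply(seq_len(nrow(scenarios)), function(i) {
      as.list(scenarios[i, ])
    }), path)
  } else {
    write.csv(scenarios, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    rows <- yaml::read_yaml(path)
    out <- do.call(rbind, lapply(rows, as.data.frame))
  } else {
    out <- read.csv(path)
  }
  out$scenario <- as.integer(out$scenario)
  pcols <- grep("^p\\d+$", names(out), value = TRUE)
  for (nm in pcols) out[[nm]] <- as.numeric(out[[nm]])
  out
}
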