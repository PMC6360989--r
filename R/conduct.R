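#' Dose recommendation for an ongoing trial
#'
#' The "running a real trial" mode: given the roster of patients enrolled
#' so far and a decision time, computes the partial-follow-up estimates
#' per tried dose, their isotonic fit, and the dose the TITE-IR rules
#' assign to the next patient — including the escalation safety
#' constraints (at least three patients at the current dose before
#' escalating, no escalation past an observed toxicity in the most recent
#' patient, one level at a time).  An empty roster recommends dose 1:
#' every trial starts at the lowest dose.
#'
#' @param roster Data frame with columns `id`, `arrival_time`,
#'   `dose_index`, `toxicity` and `toxicity_time` (months; doses
#'   1-based).  `toxicity` is the observed status at `decision_time`.
#' @param config A [trial_config()].
#' @param decision_time Months from trial start; defaults to just after
#'   the latest arrival.  Follow-ups are truncated at `tau`.
#' @return A `dose_decision` with the per-dose estimate table attached as
#'   `$estimates`.
#' @examples
#' cfg <- trial_config()
#' next_dose(data.frame(), cfg)                     # dose 1
#' r <- data.frame(id = 1:3, arrival_time = c(0, 0.5, 1), dose_index = 1,
#'                 toxicity = 0, toxicity_time = NA_real_)
#' next_dose(r, cfg, decision_time = 8)             # gate met: dose 2
#' @export
next_dose <- function(roster, config, decision_time = NULL) {
  stopifnot(inherits(config, "trial_config"))
  roster <- as.data.frame(roster)
  if (nrow(roster) == 0L) {
    dec <- new_dose_decision(1L, FALSE)
    dec$estimates <- NULL
    return(dec)
  }
  validate_roster(roster, config)
  if (is.null(decision_time)) decision_time <- max(roster$arrival_time)
  ev <- evaluate_roster(roster, config, decision_time)
  last <- which.max(roster$arrival_time)
  dec <- tite_decide(roster$dose_index, ev$obs, ev$fu, config,
                     last_dose = roster$dose_index[last],
                     last_tox = ev$obs[last])
  out <- new_dose_decision(dec$dose, dec$constrained)
  out$estimates <- data.frame(dose_index = seq_along(dec$qhat),
                              n = dec$n, y = dec$y,
                              qhat = dec$qhat, phat = dec$phat)
  out
}

#' Read a patient roster file
#'
#' Roster files are CSV with columns `id`, `arrival_time`, `dose_index`,
#' `toxicity`, `toxicity_time` — times in months, doses 1-based,
#' `toxicity_time` empty/NA for toxicity-free patients.
#'
#' @param path CSV file path.
#' @param config A [trial_config()] used for validation.
#' @return The roster data frame.
#' @export
read_roster <- function(path, config) {
  roster <- read.csv(path)
  validate_roster(roster, config)
  roster
}

validate_roster <- function(roster, config) {
  need <- c("arrival_time", "dose_index", "toxicity")
  miss <- setdiff(need, names(roster))
  if (length(miss)) {
    stop("roster is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(roster$dose_index)) ||
      any(roster$dose_index < 1 | roster$dose_index > config$n_doses)) {
    stop("dose_index must lie in 1..J", call. = FALSE)
  }
  if (!all(roster$toxicity %in% c(0, 1))) {
    stop("toxicity must be 0/1", call. = FALSE)
  }
  # doses must have been tried contiguously from dose 1
  tried <- sort(unique(roster$dose_index))
  if (!identical(as.integer(tried), seq_len(max(tried)))) {
    stop("doses must be tried contiguously starting from dose 1",
         call. = FALSE)
  }
  if (!is.null(roster$toxicity_time)) {
    bad <- roster$toxicity == 1 & !is.na(roster$toxicity_time) &
      (roster$toxicity_time <= 0 | roster$toxicity_time > config$tau)
    if (any(bad)) {
      stop("toxicity_time must lie in (0, tau]", call. = FALSE)
    }
  }
  invisible(roster)
}
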