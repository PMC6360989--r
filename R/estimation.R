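#' Raw partial-follow-up toxicity estimate for one dose
#'
#' Computes the raw toxicity-probability estimate `qhat_j` for the patients
#' treated at a single dose.  Each observed toxicity contributes 1 to the
#' numerator; each toxicity-free patient with follow-up `t` contributes the
#' discounted pseudo-toxicity `((tau - t) / tau) * (target + f_star)`,
#' reflecting a uniform prior on the time to toxicity over `(0, tau)`: the
#' closer a patient is followed to `tau` without an event, the less
#' toxicity probability remains.  With every patient fully followed the
#' estimate reduces to the plain proportion `y / n`.
#'
#' @param patients A data frame of patient records at one dose, evaluated
#'   at a decision time; must contain `toxicity` (0/1, observed status) and
#'   `followup` (elapsed evaluation time in `[0, tau]`, used for
#'   toxicity-free patients).  An optional `dose_index` column must be
#'   constant; an optional `toxicity_time` is validated against `tau`.
#' @param config A [trial_config()].
#'
#' @return The raw estimate, a single number (it can exceed 1 only if
#'   `target + f_star` would, which [trial_config()] rejects).
#' @examples
#' cfg <- trial_config()                       # tau = 6, target = 1/3, F* = 0.05
#' pts <- data.frame(toxicity = c(1, 0, 0), followup = c(2, 3, 6))
#' compute_qhat(pts, cfg)                      # (1 + 0.5 * (1/3 + 0.05)) / 3
#' @seealso [estimate_all()] for all tried doses at once.
#' @export
compute_qhat <- function(patients, config) {
  stopifnot(inherits(config, "trial_config"))
  patients <- as.data.frame(patients)
  if (nrow(patients) == 0L) {
    stop("no patients treated at this dose: the raw estimate is undefined",
         call. = FALSE)
  }
  if (!all(c("toxicity", "followup") %in% names(patients))) {
    stop("patients must have 'toxicity' and 'followup' columns", call. = FALSE)
  }
  if (!is.null(patients$dose_index) &&
      length(unique(patients$dose_index)) > 1L) {
    stop("all patient records must share one dose", call. = FALSE)
  }
  tox <- as.logical(patients$toxicity)
  fu <- patients$followup
  if (any(!tox & (is.na(fu) | fu < 0 | fu > config$tau))) {
    stop("follow-up must lie in [0, tau] for toxicity-free patients",
         call. = FALSE)
  }
  if (!is.null(patients$toxicity_time) &&
      any(tox & !is.na(patients$toxicity_time) &
            patients$toxicity_time > config$tau)) {
    stop("toxicity_time exceeds tau for a patient flagged toxic", call. = FALSE)
  }
  qhat_value(tox, fu, config$tau, config$target + config$f_star)
}

# bare-metal kernel shared with the trial engines: obs is the logical
# observed-toxicity vector, fu the follow-up (only used where !obs)
qhat_value <- function(obs, fu, tau, offset) {
  (sum(obs) + sum((tau - fu[!obs]) / tau) * offset) / length(obs)
}

#' Weighted isotonic regression by pool-adjacent-violators
#'
#' Computes the weighted least-squares non-decreasing fit of `values`:
#' whenever adjacent entries violate monotonicity they are pooled into a
#' block carrying their weighted mean, repeatedly, until the block means
#' are non-decreasing.  The result is the unique minimiser of
#' `sum(weights * (values - fit)^2)` over non-decreasing vectors, a step
#' function constant on the pooled blocks.
#'
#' @param values Numeric vector of raw estimates.
#' @param weights Positive weights, same length as `values`.  Defaults to
#'   equal weights.  The dose-finding designs weight each dose by its
#'   patient count.
#' @return Numeric vector of the same length, non-decreasing.
#' @examples
#' pava(c(0.4, 0.2), c(3, 3))        # pooled to (0.3, 0.3)
#' pava(c(0.5, 0.1, 0.3), c(3, 6, 3))
#' @export
pava <- function(values, weights = rep(1, length(values))) {
  n <- length(values)
  if (n == 0L) stop("values must be non-empty", call. = FALSE)
  if (length(weights) != n) {
    stop("values and weights must have equal length", call. = FALSE)
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive", call. = FALSE)
  }
  if (n == 1L) return(values)
  # stack of blocks: value, weight, index of last element covered
  bv <- numeric(n); bw <- numeric(n); bl <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    bv[nb] <- values[i]; bw[nb] <- weights[i]; bl[nb] <- i
    while (nb > 1L && bv[nb - 1L] > bv[nb]) {
      bv[nb - 1L] <- (bw[nb - 1L] * bv[nb - 1L] + bw[nb] * bv[nb]) /
        (bw[nb - 1L] + bw[nb])
      bw[nb - 1L] <- bw[nb - 1L] + bw[nb]
      bl[nb - 1L] <- bl[nb]
      nb <- nb - 1L
    }
  }
  rep(bv[seq_len(nb)], times = diff(c(0L, bl[seq_len(nb)])))
}

#' Dose-selection rule
#'
#' Picks from a set of admissible doses, carrying non-decreasing isotonic
#' toxicity estimates, the dose whose estimate is closest to the target
#' without exceeding it; ties are broken toward the highest dose.  When
#' every admissible dose exceeds the target the rule falls back to the
#' lowest admissible dose and flags the decision as constrained.
#'
#' @param phat Non-decreasing vector of isotonic toxicity estimates over
#'   the admissible doses.
#' @param config A [trial_config()]; only `target` is used.
#' @param dose_indices Actual dose indices (1-based) behind the positions
#'   of `phat`; defaults to `seq_along(phat)`.
#'
#' @return A `dose_decision`: list with `dose_index` (in `1..J`) and
#'   `constrained` (TRUE when the fallback overrode the unconstrained
#'   rule).
#' @examples
#' cfg <- trial_config()
#' select_dose(c(0.1, 0.2, 0.3, 0.5), cfg)   # dose 3
#' select_dose(c(0.5, 0.6), cfg)             # dose 1, constrained
#' @export
select_dose <- function(phat, config, dose_indices = seq_along(phat)) {
  stopifnot(inherits(config, "trial_config"))
  if (length(phat) == 0L) stop("admissible dose set is empty", call. = FALSE)
  if (length(dose_indices) != length(phat)) {
    stop("dose_indices must match phat in length", call. = FALSE)
  }
  ok <- which(phat <= config$target)
  if (length(ok) == 0L) {
    return(new_dose_decision(as.integer(dose_indices[1L]), TRUE))
  }
  gap <- config$target - phat[ok]
  best <- ok[gap <= min(gap) + 1e-12]
  new_dose_decision(as.integer(dose_indices[max(best)]), FALSE)
}

# position of the estimate closest to the target, ties to the highest dose
closest_to_target <- function(phat, target) {
  gap <- abs(target - phat)
  max(which(gap <= min(gap) + 1e-12))
}

# Terminal MTD declaration for the TITE-IR design, from full-follow-up
# per-dose counts: among tried doses whose isotonic estimate does not
# exceed target + f_star (the same conservatism band the estimator uses),
# the dose closest to the target, ties to the highest dose.  If every
# tried dose exceeds the band the lowest dose is declared, flagged.
final_select <- function(y, n, config) {
  phat <- pava(y / n, n)
  ok <- which(phat <= config$target + config$f_star + 1e-12)
  if (length(ok) == 0L) return(new_dose_decision(1L, TRUE))
  best <- ok[closest_to_target(phat[ok], config$target)]
  new_dose_decision(as.integer(best), FALSE)
}

new_dose_decision <- function(dose_index, constrained) {
  structure(list(dose_index = dose_index, constrained = constrained),
            class = "dose_decision")
}

#' @export
print.dose_decision <- function(x, ...) {
  cat(sprintf("recommended dose level: %d%s\n", x$dose_index,
              if (isTRUE(x$constrained)) " (safety-constrained)" else ""))
  if (!is.null(x$estimates)) {
    print(x$estimates, row.names = FALSE)
  }
  invisible(x)
}

#' Per-dose summaries and isotonic estimates for a roster
#'
#' Groups a patient roster by dose, computes the raw partial-follow-up
#' estimate for every tried dose, and smooths the raw estimates with
#' patient-count-weighted isotonic regression.  Untried doses carry no
#' estimate and are absent from the result.
#'
#' @param roster Data frame of patient records with columns `dose_index`,
#'   `toxicity` and either `followup` (elapsed evaluation time, when
#'   `decision_time` is `NULL`) or `arrival_time` plus `toxicity_time`
#'   (when a `decision_time` is supplied, follow-ups are computed as
#'   `min(decision_time - arrival_time, tau)` and a toxicity counts only
#'   once its time has been reached).
#' @param config A [trial_config()].
#' @param decision_time Optional decision time (months from trial start).
#'
#' @return Data frame with one row per tried dose, in dose order:
#'   `dose_index`, `n`, `y` (observed toxicities), `qhat` (raw estimate)
#'   and `phat` (isotonic estimate, non-decreasing).
#' @examples
#' cfg <- trial_config()
#' r <- data.frame(dose_index = c(1, 1, 1, 2, 2, 2),
#'                 toxicity   = c(0, 0, 0, 1, 1, 0),
#'                 followup   = c(6, 6, 6, 6, 6, 6))
#' estimate_all(r, cfg)
#' @export
estimate_all <- function(roster, config, decision_time = NULL) {
  stopifnot(inherits(config, "trial_config"))
  roster <- as.data.frame(roster)
  if (nrow(roster) == 0L) stop("roster is empty", call. = FALSE)
  ev <- evaluate_roster(roster, config, decision_time)
  doses <- sort(unique(roster$dose_index))
  n <- integer(length(doses)); y <- integer(length(doses))
  q <- numeric(length(doses))
  off <- config$target + config$f_star
  for (k in seq_along(doses)) {
    at <- roster$dose_index == doses[k]
    n[k] <- sum(at)
    y[k] <- sum(ev$obs[at])
    q[k] <- qhat_value(ev$obs[at], ev$fu[at], config$tau, off)
  }
  data.frame(dose_index = as.integer(doses), n = n, y = y,
             qhat = q, phat = pava(q, n))
}

# resolve observed toxicity status and follow-up at a decision time
evaluate_roster <- function(roster, config, decision_time = NULL) {
  if (is.null(decision_time)) {
    if (is.null(roster$followup)) {
      stop("roster needs a 'followup' column when no decision_time is given",
           call. = FALSE)
    }
    fu <- roster$followup
    if (any(fu < 0 | fu > config$tau)) {
      stop("follow-up outside [0, tau]", call. = FALSE)
    }
    obs <- roster$toxicity == 1
  } else {
    if (is.null(roster$arrival_time)) {
      stop("roster needs 'arrival_time' to evaluate at a decision time",
           call. = FALSE)
    }
    if (any(decision_time < roster$arrival_time)) {
      stop("decision_time precedes a patient's arrival", call. = FALSE)
    }
    fu <- pmin(decision_time - roster$arrival_time, config$tau)
    tt <- if (is.null(roster$toxicity_time)) rep(NA_real_, nrow(roster)) else
      roster$toxicity_time
    obs <- roster$toxicity == 1 & (is.na(tt) | tt <= fu)
  }
  list(obs = obs, fu = fu)
}

# Decision kernel shared by the TITE-IR engine and next_dose().  Doses are
# tried contiguously from dose 1, so `phat` positions map to dose indices.
# The next patient is assigned the tried dose whose isotonic estimate is
# closest to the target (ties broken to the highest dose); when that is
# the highest tried dose and its estimate is within the target, the next
# untried level is opened instead.  Safety rules: escalation above the
# previous patient's dose requires >= 3 patients treated there and is
# blocked outright while that patient has an observed toxicity; untried
# doses are never skipped.  The decision is flagged constrained when a
# safety rule bound, or when even the selected dose is estimated above
# the target (the trial is parked, typically at dose 1).
tite_decide <- function(dose, obs, fu, config, last_dose, last_tox) {
  mt <- max(dose)
  n <- tabulate(dose, mt)
  y <- tabulate(dose[obs], mt)
  w <- (config$tau - fu) / config$tau
  w[obs] <- 0
  wsum <- numeric(mt)
  for (d in seq_len(mt)) wsum[d] <- sum(w[dose == d])
  qhat <- (y + wsum * (config$target + config$f_star)) / n
  phat <- pava(qhat, n)
  cand <- closest_to_target(phat, config$target)
  constrained <- phat[cand] > config$target
  if (!constrained && cand == mt && mt < config$n_doses) cand <- mt + 1L
  if (cand > last_dose) {
    allowed <- if (last_tox || n[last_dose] < 3L) last_dose else
      min(cand, mt + 1L)
    if (allowed < cand) {
      cand <- allowed
      constrained <- TRUE
    }
  }
  list(dose = as.integer(cand), constrained = constrained,
       n = n, y = y, qhat = qhat, phat = phat)
}
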