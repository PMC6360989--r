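#' Conduct one TITE-IR trial
#'
#' Runs a single simulated trial of the time-to-event isotonic regression
#' design.  Patients are treated immediately on arrival (cohorts of 1):
#' the first at dose 1 at time 0, each later one at the tried dose whose
#' partial-follow-up isotonic estimate — frozen at the arrival instant —
#' is closest to the target (the next untried level is opened when the
#' highest tried dose is estimated within the target), subject to the
#' safety rules: escalation above the previous patient's dose requires at
#' least three patients treated there and is blocked while that patient
#' has an observed toxicity, and untried doses are never skipped.  After
#' `n_max` patients all are followed to `tau` and the MTD is declared
#' among the tried doses whose full-follow-up isotonic estimate does not
#' exceed `target + f_star`: the one closest to the target, ties to the
#' highest dose.
#'
#' @param scenario A [dose_scenario()], a shipped scenario id (1-10), or a
#'   bare probability vector.
#' @param config A [trial_config()]; `cohort_size`, if set, must be 1.
#' @param rng_seed Optional integer seed; a seeded run is exactly
#'   reproducible.
#' @param tox_time_fn Optional time-to-toxicity hook `(n, tau)` replacing
#'   the uniform draw, for early/late-onset sensitivity analyses.
#' @param audit Record one log entry per dose decision (see
#'   [write_audit()]).
#' @return A `trial_result`: declared MTD, patient roster, toxicity count,
#'   duration (months; equals last arrival + `tau`), and allocation of
#'   patients below/at/above the scenario's true MTD.
#' @examples
#' run_tite_ir(scenario(1), trial_config(), rng_seed = 7)
#' @export
run_tite_ir <- function(scenario, config = trial_config(), rng_seed = NULL,
                        tox_time_fn = NULL, audit = FALSE) {
  scenario <- as_dose_scenario(scenario, config$target)
  check_cohort_size(config, 1L)
  p <- scenario$true_probs
  if (length(p) != config$n_doses) {
    stop("scenario and config disagree on the number of doses", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  nmax <- config$n_max
  tau <- config$tau
  arr <- generate_arrivals(nmax, config$accrual_rate)
  u <- runif(nmax)
  tt <- draw_tox_times(nmax, tau, tox_time_fn)

  dose <- integer(nmax)
  tox <- logical(nmax)
  dose[1L] <- 1L
  tox[1L] <- u[1L] < p[1L]
  aud <- if (audit) vector("list", nmax) else NULL

  if (nmax > 1L) {
    for (k in 2:nmax) {
      now <- arr[k]
      idx <- seq_len(k - 1L)
      fu <- pmin(now - arr[idx], tau)
      obs <- tox[idx] & tt[idx] <= fu
      dec <- tite_decide(dose[idx], obs, fu, config,
                         last_dose = dose[k - 1L], last_tox = obs[k - 1L])
      dose[k] <- dec$dose
      tox[k] <- u[k] < p[dose[k]]
      if (audit) {
        aud[[k - 1L]] <- list(time = now, patient = k, qhat = dec$qhat,
                              phat = dec$phat, dose = dec$dose,
                              constrained = dec$constrained)
      }
    }
  }

  # everyone followed to tau: the raw estimates reduce to y / n
  mt <- max(dose)
  n <- tabulate(dose, mt)
  y <- tabulate(dose[tox], mt)
  sel <- final_select(y, n, config)
  if (audit) {
    aud[[nmax]] <- list(time = arr[nmax] + tau, patient = NA,
                        qhat = y / n, phat = pava(y / n, n),
                        dose = sel$dose_index, constrained = sel$constrained,
                        final = TRUE)
  }
  new_trial_result("TITE-IR", scenario, config,
                   arrival = arr, treat = arr, dose = dose, tox = tox,
                   tox_time = tt, mtd = sel$dose_index,
                   constrained = sel$constrained,
                   duration = arr[nmax] + tau, audit = aud)
}
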