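# Cohort designs (3+3, up-and-down D, isotonic regression A/B) share the
# same queued accrual: arrivals keep accumulating during follow-up, and a
# cohort of 3 starts at max(arrival time of its third patient, completion
# of the previous cohort's tau-long evaluation).

#' Conduct one 3+3 trial
#'
#' Classical rule-based design with cohorts of 3, each fully evaluated
#' over `tau` before the next decision: 0/3 toxicities escalate; more than
#' one declares the next-lower dose the MTD (dose 1 when already at the
#' bottom); exactly one triggers an expansion cohort at the same dose,
#' after which the trial escalates only if the expansion is toxicity-free
#' and otherwise declares the next-lower dose.  At the top dose the trial
#' stays put until termination.  If `n_max` patients are enrolled without
#' a declaration: zero toxicities at the current dose declare it the MTD;
#' exactly one buys a final expansion cohort (total `n_max + 3`) that
#' declares the current dose if toxicity-free and the next-lower dose
#' otherwise.
#'
#' @inheritParams run_tite_ir
#' @param config A [trial_config()]; `cohort_size`, if set, must be 3, and
#'   `n_max` must be a multiple of 3.
#' @return A `trial_result`.  Sample size is a multiple of 3, at most
#'   `n_max + 3`.
#' @examples
#' run_three_plus_three(scenario(5), trial_config(), rng_seed = 7)
#' @export
run_three_plus_three <- function(scenario, config = trial_config(),
                                 rng_seed = NULL, tox_time_fn = NULL) {
  st <- cohort_setup(scenario, config, rng_seed, tox_time_fn,
                     n_patients = config$n_max + 3L)
  J <- config$n_doses
  tau <- config$tau
  dose <- integer(0); tox <- logical(0); treat <- numeric(0)
  j <- 1L; n <- 0L; prev_end <- 0
  expansion <- FALSE     # current cohort is the expansion after a 1/3
  pending_final <- FALSE # endgame expansion beyond n_max
  mtd <- NA_integer_
  repeat {
    start <- max(st$arr[n + 3L], prev_end)
    ids <- (n + 1L):(n + 3L)
    ctox <- st$u[ids] < st$p[j]
    dose[ids] <- j; tox[ids] <- ctox; treat[ids] <- start
    n <- n + 3L
    prev_end <- start + tau
    c1 <- sum(ctox)
    if (pending_final) {
      mtd <- if (c1 == 0L) j else max(j - 1L, 1L)
      break
    }
    if (c1 >= 2L) {
      mtd <- max(j - 1L, 1L)
      break
    }
    if (c1 == 1L) {
      if (expansion) {           # 1/3 then a toxic expansion cohort
        mtd <- max(j - 1L, 1L)
        break
      }
      if (n >= config$n_max) {   # endgame: one extra expansion allowed
        pending_final <- TRUE
        next
      }
      expansion <- TRUE
      next
    }
    # zero toxicities in this cohort: escalate if the rules allow
    expansion <- FALSE
    if (j == J) {                # escalation indicated but impossible
      mtd <- J
      break
    }
    if (n >= config$n_max) {
      if (sum(tox[dose == j]) == 0L) {
        mtd <- j
        break
      }
      pending_final <- TRUE      # one earlier toxicity at this dose
      next
    }
    j <- j + 1L
  }
  new_trial_result("3+3", st$scenario, config,
                   arrival = st$arr[seq_len(n)], treat = treat, dose = dose,
                   tox = tox, tox_time = st$tt[seq_len(n)], mtd = mtd,
                   constrained = FALSE, duration = prev_end)
}

#' Conduct one up-and-down design D trial
#'
#' Storer's design D: cohorts of 3 fully evaluated over `tau`; zero
#' toxicities escalate (capped at the top dose), exactly one repeats the
#' dose, more than one de-escalates (floored at dose 1); the trial runs to
#' exactly `n_max` patients and the MTD is chosen by [fit_logistic_mtd()]
#' on the final roster.
#'
#' @inheritParams run_three_plus_three
#' @return A `trial_result`.
#' @examples
#' run_up_down_d(scenario(1), trial_config(), rng_seed = 7)
#' @export
run_up_down_d <- function(scenario, config = trial_config(),
                          rng_seed = NULL, tox_time_fn = NULL) {
  st <- cohort_setup(scenario, config, rng_seed, tox_time_fn,
                     n_patients = config$n_max)
  J <- config$n_doses
  tau <- config$tau
  ncoh <- config$n_max %/% 3L
  dose <- integer(config$n_max); tox <- logical(config$n_max)
  treat <- numeric(config$n_max)
  j <- 1L; prev_end <- 0
  for (ch in seq_len(ncoh)) {
    start <- max(st$arr[3L * ch], prev_end)
    ids <- (3L * ch - 2L):(3L * ch)
    ctox <- st$u[ids] < st$p[j]
    dose[ids] <- j; tox[ids] <- ctox; treat[ids] <- start
    prev_end <- start + tau
    c1 <- sum(ctox)
    j <- if (c1 == 0L) min(j + 1L, J) else if (c1 == 1L) j else max(j - 1L, 1L)
  }
  roster <- data.frame(dose_index = dose, toxicity = as.integer(tox))
  sel <- fit_logistic_mtd(roster, config)
  new_trial_result("UD", st$scenario, config,
                   arrival = st$arr, treat = treat, dose = dose, tox = tox,
                   tox_time = st$tt, mtd = sel$dose_index,
                   constrained = sel$constrained, duration = prev_end)
}

#' MTD from a terminal logistic dose-toxicity fit
#'
#' Fits a simple logistic regression of toxicity status on the raw dose
#' level (intercept and slope) by maximum likelihood and returns the
#' highest dose whose fitted toxicity probability is closest to the target
#' without exceeding it.  Small trials often break the fit — all-same
#' outcomes, complete separation, or a non-positive slope estimate that
#' violates monotonicity — in which case the rule falls back to
#' [select_dose()] applied to the isotonic fit of the empirical per-dose
#' proportions.
#'
#' @param roster Data frame with final `dose_index` and `toxicity` columns.
#' @param config A [trial_config()].
#' @return A `dose_decision` (MTD index plus constrained flag).
#' @examples
#' cfg <- trial_config()
#' r <- data.frame(dose_index = rep(1:3, each = 3),
#'                 toxicity   = c(0, 0, 0, 0, 0, 1, 1, 1, 1))
#' fit_logistic_mtd(r, cfg)
#' @export
fit_logistic_mtd <- function(roster, config) {
  stopifnot(inherits(config, "trial_config"))
  roster <- as.data.frame(roster)
  if (nrow(roster) == 0L) stop("roster is empty", call. = FALSE)
  ytox <- roster$toxicity == 1
  fallback <- function() {
    doses <- sort(unique(roster$dose_index))
    nj <- vapply(doses, function(d) sum(roster$dose_index == d), 0)
    props <- vapply(doses, function(d) mean(ytox[roster$dose_index == d]), 0)
    select_dose(pava(props, nj), config, dose_indices = doses)
  }
  if (length(unique(ytox)) < 2L) return(fallback())
  x <- config$dose_levels[roster$dose_index]
  degenerate <- FALSE
  fit <- withCallingHandlers(
    glm(ytox ~ x, family = binomial()),
    warning = function(w) {
      degenerate <<- TRUE       # non-convergence or separation
      invokeRestart("muffleWarning")
    }
  )
  b <- coef(fit)
  if (degenerate || !fit$converged || !all(is.finite(b)) || b[2L] <= 0) {
    return(fallback())
  }
  select_dose(plogis(b[1L] + b[2L] * config$dose_levels), config)
}

#' Conduct one isotonic-regression trial (IR-A / IR-B)
#'
#' Cohorts of 3, each fully followed for `tau` before the next assignment.
#' The next cohort's dose is the dose-selection rule applied to the
#' isotonic fit of the full-follow-up toxicity proportions over the tried
#' doses, escalating at most one level at a time starting from dose 1
#' (untried doses are never skipped).  With `early_stop = TRUE` (IR-A) the
#' trial stops and declares the MTD as soon as the same dose has been
#' given to 3 consecutive cohorts and is indicated for the next; with
#' `early_stop = FALSE` (IR-B) it runs to `n_max` and declares the MTD
#' from the final estimates.
#'
#' @inheritParams run_three_plus_three
#' @param early_stop Allow the IR-A stopping rule.
#' @return A `trial_result`.
#' @examples
#' run_ir(scenario(4), trial_config(), early_stop = FALSE, rng_seed = 7)
#' @export
run_ir <- function(scenario, config = trial_config(), early_stop = FALSE,
                   rng_seed = NULL, tox_time_fn = NULL) {
  st <- cohort_setup(scenario, config, rng_seed, tox_time_fn,
                     n_patients = config$n_max)
  tau <- config$tau
  ncoh <- config$n_max %/% 3L
  dose <- integer(0); tox <- logical(0); treat <- numeric(0)
  cohort_dose <- integer(ncoh)
  j <- 1L; n <- 0L; prev_end <- 0
  mtd <- NA_integer_; constrained <- FALSE
  for (ch in seq_len(ncoh)) {
    start <- max(st$arr[n + 3L], prev_end)
    ids <- (n + 1L):(n + 3L)
    ctox <- st$u[ids] < st$p[j]
    dose[ids] <- j; tox[ids] <- ctox; treat[ids] <- start
    cohort_dose[ch] <- j
    n <- n + 3L
    prev_end <- start + tau
    nd <- ir_decide(dose, tox, config, last_dose = j,
                    last_cohort_tox = any(ctox))
    if (early_stop && ch >= 3L &&
        length(unique(cohort_dose[(ch - 2L):ch])) == 1L &&
        nd$dose == cohort_dose[ch]) {
      mtd <- nd$dose
      constrained <- FALSE
      break
    }
    j <- nd$dose
  }
  if (is.na(mtd)) {
    mt <- max(dose)
    nj <- tabulate(dose, mt)
    yj <- tabulate(dose[tox], mt)
    # terminal declaration: the tried dose estimated closest to target
    phat <- pava(yj / nj, nj)
    mtd <- closest_to_target(phat, config$target)
    constrained <- phat[mtd] > config$target
  }
  new_trial_result(if (early_stop) "IR-A" else "IR-B", st$scenario, config,
                   arrival = st$arr[seq_len(n)], treat = treat, dose = dose,
                   tox = tox, tox_time = st$tt[seq_len(n)], mtd = mtd,
                   constrained = constrained, duration = prev_end)
}

# Next-cohort assignment for the IR designs: the highest dose whose
# full-follow-up isotonic proportion is closest to the target without
# exceeding it; when that is the highest tried dose (still within target)
# the next untried level is opened.  Escalation is blocked while the most
# recent cohort had a toxicity and proceeds at most one level at a time.
ir_decide <- function(dose, tox, config, last_dose, last_cohort_tox = FALSE) {
  mt <- max(dose)
  n <- tabulate(dose, mt)
  y <- tabulate(dose[tox], mt)
  phat <- pava(y / n, n)
  sel <- select_dose(phat, config)
  cand <- sel$dose_index
  if (!sel$constrained && cand == mt && mt < config$n_doses) cand <- mt + 1L
  if (last_cohort_tox && cand > last_dose) cand <- last_dose
  if (cand > last_dose + 1L) cand <- last_dose + 1L
  list(dose = as.integer(cand), constrained = sel$constrained, phat = phat)
}

# shared pre-draws for the cohort engines
cohort_setup <- function(scenario, config, rng_seed, tox_time_fn, n_patients) {
  scenario <- as_dose_scenario(scenario, config$target)
  check_cohort_size(config, 3L)
  if (config$n_max %% 3L != 0L) {
    stop("cohort designs need n_max to be a multiple of 3", call. = FALSE)
  }
  p <- scenario$true_probs
  if (length(p) != config$n_doses) {
    stop("scenario and config disagree on the number of doses", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  list(scenario = scenario,
       p = p,
       arr = generate_arrivals(n_patients, config$accrual_rate),
       u = runif(n_patients),
       tt = draw_tox_times(n_patients, config$tau, tox_time_fn))
}

#' Run one trial of any supported design
#'
#' Thin dispatcher over the single-trial engines.
#'
#' @param design One of `"TITE-IR"`, `"3+3"`, `"UD"`, `"IR-A"`, `"IR-B"`.
#' @inheritParams run_tite_ir
#' @return A `trial_result`.
#' @examples
#' run_trial("IR-A", scenario(5), trial_config(), rng_seed = 1)
#' @export
run_trial <- function(design, scenario, config = trial_config(),
                      rng_seed = NULL, tox_time_fn = NULL) {
  switch(match_design(design),
    "TITE-IR" = run_tite_ir(scenario, config, rng_seed, tox_time_fn),
    "3+3"     = run_three_plus_three(scenario, config, rng_seed, tox_time_fn),
    "UD"      = run_up_down_d(scenario, config, rng_seed, tox_time_fn),
    "IR-A"    = run_ir(scenario, config, TRUE, rng_seed, tox_time_fn),
    "IR-B"    = run_ir(scenario, config, FALSE, rng_seed, tox_time_fn)
  )
}

match_design <- function(design) {
  key <- toupper(gsub("[^0-9a-zA-Z+]", "", design))
  out <- switch(key,
    "TITEIR" = "TITE-IR",
    "TITE"   = "TITE-IR",
    "3+3"    = "3+3",
    "33"     = "3+3",
    "UD"     = "UD",
    "UDD"    = "UD",
    "IRA"    = "IR-A",
    "IRB"    = "IR-B",
    NULL
  )
  if (is.null(out)) {
    stop(sprintf("unknown design '%s' (use TITE-IR, 3+3, UD, IR-A or IR-B)",
                 design), call. = FALSE)
  }
  out
}
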