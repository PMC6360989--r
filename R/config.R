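#' Trial design configuration
#'
#' Bundles every parameter shared by the dose-finding designs: the raw dose
#' grid, the target toxicity probability, the follow-up window, the
#' conservatism offset of the partial-follow-up estimator, the sample-size
#' cap and the accrual process.  Defaults are the benchmark settings used
#' throughout the package's simulation study: six oral doses of
#' (5, 10, 15, 20, 30, 40) mg, target `pi* = 1/3` by `tau = 6` months,
#' offset `F* = 0.05`, at most 24 patients, and Poisson accrual of
#' 2 patients per month.
#'
#' @param dose_levels Strictly increasing numeric vector of raw dose values
#'   (e.g. mg).  Its length defines the number of dose levels `J`.
#' @param target Target toxicity probability `pi*`, strictly between 0
#'   and 1.  The MTD is the dose whose toxicity probability by `tau` is
#'   closest to `target` without exceeding it.
#' @param tau Follow-up window for toxicity, in months (> 0).
#' @param f_star Conservatism offset `F*` (>= 0) added to `target` in the
#'   pseudo-toxicity credited to partially followed patients.  Larger
#'   values make escalation harder; `target + f_star` must not exceed 1.
#' @param n_max Maximum number of patients (positive integer).  Cohort
#'   designs require a multiple of the cohort size 3.
#' @param accrual_rate Expected patients per month of the Poisson accrual
#'   process (> 0).
#' @param cohort_size Optional cohort size override.  Left `NULL`, each
#'   engine uses its canonical size (1 for TITE-IR, 3 for the
#'   comparators); if supplied it must equal that canonical size.
#'
#' @return An object of class `trial_config` (a named list, with
#'   `n_doses` added).
#' @examples
#' cfg <- trial_config()
#' cfg$target
#' @export
trial_config <- function(dose_levels = c(5, 10, 15, 20, 30, 40),
                         target = 1 / 3,
                         tau = 6,
                         f_star = 0.05,
                         n_max = 24L,
                         accrual_rate = 2,
                         cohort_size = NULL) {
  cfg <- structure(
    list(
      dose_levels = as.numeric(dose_levels),
      n_doses = length(dose_levels),
      target = target,
      tau = tau,
      f_star = f_star,
      n_max = as.integer(n_max),
      accrual_rate = accrual_rate,
      cohort_size = if (is.null(cohort_size)) NULL else as.integer(cohort_size)
    ),
    class = "trial_config"
  )
  validate_trial_config(cfg)
}

validate_trial_config <- function(cfg) {
  stopifnot(inherits(cfg, "trial_config"))
  if (cfg$n_doses < 1L || anyNA(cfg$dose_levels)) {
    stop("dose_levels must be a non-empty numeric vector", call. = FALSE)
  }
  if (cfg$n_doses > 1L && any(diff(cfg$dose_levels) <= 0)) {
    stop("dose_levels must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(cfg$target) || length(cfg$target) != 1L ||
      cfg$target <= 0 || cfg$target >= 1) {
    stop("target must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(cfg$tau) || length(cfg$tau) != 1L || cfg$tau <= 0) {
    stop("tau must be a positive follow-up window", call. = FALSE)
  }
  if (!is.numeric(cfg$f_star) || length(cfg$f_star) != 1L || cfg$f_star < 0) {
    stop("f_star must be non-negative", call. = FALSE)
  }
  if (cfg$target + cfg$f_star > 1) {
    stop("target + f_star exceeds 1: the pseudo-toxicity credit would not be a probability",
         call. = FALSE)
  }
  if (is.na(cfg$n_max) || cfg$n_max < 1L) {
    stop("n_max must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(cfg$accrual_rate) || cfg$accrual_rate <= 0) {
    stop("accrual_rate must be positive", call. = FALSE)
  }
  if (!is.null(cfg$cohort_size) && (is.na(cfg$cohort_size) || cfg$cohort_size < 1L)) {
    stop("cohort_size must be a positive integer when supplied", call. = FALSE)
  }
  cfg
}

#' @export
print.trial_config <- function(x, ...) {
  cat("Phase I trial configuration\n")
  cat("  dose levels :", paste(x$dose_levels, collapse = ", "), "\n")
  cat(sprintf("  target pi*  : %.4f\n", x$target))
  cat(sprintf("  tau         : %g months\n", x$tau))
  cat(sprintf("  F* offset   : %g\n", x$f_star))
  cat(sprintf("  N_max       : %d patients\n", x$n_max))
  cat(sprintf("  accrual     : %g patients/month\n", x$accrual_rate))
  if (!is.null(x$cohort_size)) cat(sprintf("  cohort size : %d\n", x$cohort_size))
  invisible(x)
}

# engines call this to enforce their canonical cohort size
check_cohort_size <- function(cfg, required) {
  if (!is.null(cfg$cohort_size) && cfg$cohort_size != required) {
    stop(sprintf("this design uses cohorts of %d (config requests %d)",
                 required, cfg$cohort_size), call. = FALSE)
  }
  invisible(cfg)
}
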