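#' Simulate patient arrival times
#'
#' Patient accrual is a Poisson process whose clock starts with the first
#' patient: the first arrival is at time 0 and subsequent inter-arrival
#' gaps are independent exponentials with mean `1 / rate`.
#'
#' @param n Number of patients (>= 1).
#' @param rate Expected patients per month (> 0).
#' @param rng_seed Optional integer seed for reproducibility.
#' @return Strictly increasing numeric vector of length `n`, starting at 0
#'   (months).
#' @examples
#' generate_arrivals(5, rate = 2, rng_seed = 1)
#' @export
generate_arrivals <- function(n, rate, rng_seed = NULL) {
  if (length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  if (length(rate) != 1L || is.na(rate) || rate <= 0) {
    stop("rate must be positive", call. = FALSE)
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- as.integer(n)
  if (n == 1L) return(0)
  c(0, cumsum(rexp(n - 1L, rate)))
}

#' Simulate toxicity outcomes and toxicity times
#'
#' Each patient's dose-limiting toxicity by the follow-up window is a
#' Bernoulli draw with the dose's true probability; toxic patients receive
#' a toxicity time drawn uniformly on `(0, tau)` by default.  A pluggable
#' time-to-toxicity hook can replace the uniform draw to study early- or
#' late-onset toxicity profiles.
#'
#' @param n Number of draws.
#' @param p True toxicity probability in `[0, 1]` (scalar, or length `n`).
#' @param tau Follow-up window (> 0).
#' @param rng_seed Optional integer seed.
#' @param tox_time_fn Optional function `(n, tau)` returning `n` toxicity
#'   times in `(0, tau)`; defaults to the uniform draw.
#' @return Data frame with columns `toxicity` (0/1) and `toxicity_time`
#'   (months, `NA` for toxicity-free patients).
#' @examples
#' draw_outcomes(4, p = 0.3, tau = 6, rng_seed = 1)
#' @export
draw_outcomes <- function(n, p, tau, rng_seed = NULL, tox_time_fn = NULL) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p must lie in [0, 1]", call. = FALSE)
  }
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- as.integer(n)
  tox <- runif(n) < p
  tt <- draw_tox_times(n, tau, tox_time_fn)
  data.frame(toxicity = as.integer(tox),
             toxicity_time = ifelse(tox, tt, NA_real_))
}

# one toxicity time per patient (used whether or not they turn out toxic,
# which keeps random-number streams comparable across design parameters)
draw_tox_times <- function(n, tau, tox_time_fn = NULL) {
  tt <- if (is.null(tox_time_fn)) runif(n, 0, tau) else tox_time_fn(n, tau)
  if (length(tt) != n || any(is.na(tt)) || any(tt <= 0 | tt >= tau)) {
    stop("toxicity times must lie strictly inside (0, tau)", call. = FALSE)
  }
  tt
}
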