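# Independent oracles used across the suite.

# Brute-force weighted least-squares isotonic fit: enumerate every
# partition of 1..n into consecutive blocks, fit each block at its
# weighted mean, keep monotone candidates, return the SSE minimiser.
iso_bruteforce <- function(v, w) {
  n <- length(v)
  if (n == 1L) return(v)
  best <- NULL
  best_sse <- Inf
  # each of the 2^(n-1) cut patterns defines a partition
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      fit[idx] <- sum(w[idx] * v[idx]) / sum(w[idx])
    }
    if (is.unsorted(fit)) next
    sse <- sum(w * (v - fit)^2)
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Brute-force Bernoulli maximum likelihood for logit(p) = a + b * x over a
# refined grid, returning the coefficients.
logistic_grid_mle <- function(x, y, a_lim = c(-30, 30), b_lim = c(-3, 3)) {
  loglik <- function(a, b) {
    p <- plogis(a + b * x)
    sum(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  }
  a_grid <- seq(a_lim[1], a_lim[2], length.out = 61)
  b_grid <- seq(b_lim[1], b_lim[2], length.out = 61)
  for (pass in 1:4) {
    ll <- outer(a_grid, b_grid, Vectorize(loglik))
    ij <- arrayInd(which.max(ll), dim(ll))
    a0 <- a_grid[ij[1]]; b0 <- b_grid[ij[2]]
    da <- diff(a_grid[1:2]); db <- diff(b_grid[1:2])
    a_grid <- seq(a0 - 2 * da, a0 + 2 * da, length.out = 41)
    b_grid <- seq(b0 - 2 * db, b0 + 2 * db, length.out = 41)
  }
  c(a = a0, b = b0)
}

# full-follow-up roster at a single dose
full_roster <- function(dose, tox, tau = 6) {
  data.frame(dose_index = dose, toxicity = as.integer(tox), followup = tau)
}
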