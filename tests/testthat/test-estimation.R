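cfg <- trial_config()   # pi* = 1/3, tau = 6, F* = 0.05

test_that("raw partial-follow-up estimate matches hand evaluation", {
  # full follow-up reduces to the plain proportion, F* irrelevant
  full <- data.frame(toxicity = c(1, 0, 0), followup = 6)
  expect_equal(compute_qhat(full, cfg), 1 / 3, tolerance = 1e-12)
  cfg2 <- trial_config(f_star = 0.4)
  expect_identical(compute_qhat(full, cfg), compute_qhat(full, cfg2))

  # worked example: toxic + half-followed + fully-followed patient
  pts <- data.frame(toxicity = c(1, 0, 0), followup = c(2, 3, 6))
  expect_equal(compute_qhat(pts, cfg), (1 + 0.5 * (1 / 3 + 0.05)) / 3,
               tolerance = 1e-12)
  expect_equal(compute_qhat(pts, cfg), 0.397222, tolerance = 1e-6)

  # zero follow-up returns the prior offset pi* + F*
  zero <- data.frame(toxicity = 0, followup = 0)
  expect_equal(compute_qhat(zero, cfg), 1 / 3 + 0.05, tolerance = 1e-12)
})

test_that("raw estimate is monotone in follow-up and validates its inputs", {
  set.seed(11)
  for (r in 1:20) {
    n <- sample(1:8, 1)
    tox <- rbinom(n, 1, 0.3)
    fu <- runif(n, 0, 6)
    base <- compute_qhat(data.frame(toxicity = tox, followup = fu), cfg)
    # extending any toxicity-free patient's follow-up cannot raise qhat
    i <- sample(n, 1)
    fu2 <- fu
    fu2[i] <- min(fu[i] + runif(1, 0, 6 - fu[i]), 6)
    more <- compute_qhat(data.frame(toxicity = tox, followup = fu2), cfg)
    if (tox[i] == 0) expect_lte(more, base + 1e-12) else
      expect_equal(more, base, tolerance = 1e-12)
  }
  expect_error(compute_qhat(data.frame(), cfg), "undefined")
  expect_error(
    compute_qhat(data.frame(toxicity = 0, followup = 7), cfg), "tau")
  expect_error(
    compute_qhat(data.frame(toxicity = 1, followup = 6, toxicity_time = 6.5),
                 cfg), "tau")
  expect_error(
    compute_qhat(data.frame(toxicity = c(0, 0), followup = c(1, 1),
                            dose_index = c(1, 2)), cfg), "share")
})

test_that("pava reproduces worked pooling examples", {
  expect_identical(pava(c(0.1, 0.2, 0.3), c(3, 3, 3)), c(0.1, 0.2, 0.3))
  expect_equal(pava(c(0.4, 0.2), c(3, 3)), c(0.3, 0.3), tolerance = 1e-12)
  expect_equal(pava(c(0.5, 0.1, 0.3), c(3, 6, 3)),
               c(7 / 30, 7 / 30, 0.3), tolerance = 1e-12)
  expect_error(pava(numeric(0)), "non-empty")
  expect_error(pava(c(1, 2), c(1, 2, 3)), "length")
  expect_error(pava(c(1, 2), c(1, 0)), "positive")
})

test_that("pava equals the brute-force weighted least-squares minimiser", {
  set.seed(42)
  for (r in 1:60) {
    n <- sample(1:6, 1)
    v <- round(runif(n), 3)
    w <- sample(1:9, n, replace = TRUE)
    fit <- pava(v, w)
    expect_false(is.unsorted(fit))
    expect_equal(fit, iso_bruteforce(v, w), tolerance = 1e-9)
    # idempotence and preservation of the total weighted mass
    expect_equal(pava(fit, w), fit, tolerance = 1e-12)
    expect_equal(sum(w * fit), sum(w * v), tolerance = 1e-9)
  }
})

test_that("dose selection takes the highest admissible dose nearest the target", {
  expect_identical(select_dose(c(0.1, 0.2, 0.3, 0.5), cfg)$dose_index, 3L)
  tie <- select_dose(c(0.3, 0.3, 0.5), cfg)
  expect_identical(tie$dose_index, 2L)     # tie broken to the higher dose
  fb <- select_dose(c(0.5, 0.6), cfg)
  expect_identical(fb$dose_index, 1L)
  expect_true(fb$constrained)
  expect_error(select_dose(numeric(0), cfg), "empty")

  # never an unconstrained pick above target, for arbitrary monotone input
  set.seed(7)
  for (r in 1:40) {
    phat <- sort(runif(sample(1:6, 1)))
    d <- select_dose(phat, cfg)
    if (!d$constrained) expect_lte(phat[d$dose_index], cfg$target)
  }
})

test_that("estimate_all groups, estimates and smooths per dose", {
  r <- data.frame(dose_index = c(1, 1, 1, 2, 2, 2),
                  toxicity = c(1, 1, 0, 1, 0, 0),
                  followup = 6)
  est <- estimate_all(r, cfg)
  expect_identical(est$dose_index, c(1L, 2L))
  expect_equal(est$qhat, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(est$phat, c(0.5, 0.5), tolerance = 1e-12)  # pooled violation

  one <- estimate_all(data.frame(dose_index = 1, toxicity = 0, followup = 2),
                      cfg)
  expect_equal(one$phat, one$qhat)

  # full-follow-up roster: phat is the isotonic fit of y/n
  set.seed(3)
  dose <- sample(1:3, 30, replace = TRUE)
  tox <- rbinom(30, 1, 0.3)
  est <- estimate_all(full_roster(dose, tox), cfg)
  yn <- vapply(1:3, function(d) mean(tox[dose == d]), 0)
  nj <- tabulate(dose, 3)
  expect_equal(est$phat, pava(yn, nj), tolerance = 1e-12)
  expect_error(estimate_all(r[0, ], cfg), "empty")
})

test_that("evaluation at a decision time truncates follow-up and defers pending toxicities", {
  r <- data.frame(dose_index = 1, arrival_time = c(0, 2),
                  toxicity = c(1, 1), toxicity_time = c(1, 5))
  est <- estimate_all(r, cfg, decision_time = 4)
  # patient 1's toxicity is observed (t = 1 <= 4); patient 2's is pending
  # (would occur at month 7), so they count as toxicity-free at 2 months
  expect_identical(est$y, 1L)
  expect_equal(est$qhat,
               (1 + (1 - 2 / 6) * (1 / 3 + 0.05)) / 2, tolerance = 1e-12)
  expect_error(estimate_all(r, cfg, decision_time = 1), "precedes")
})
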