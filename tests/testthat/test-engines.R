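cfg <- trial_config()
all_designs <- c("TITE-IR", "3+3", "UD", "IR-A", "IR-B")

test_that("degenerate scenarios force the MTD for every design", {
  none <- dose_scenario(rep(0, 6), name = "no-toxicity")
  all <- dose_scenario(rep(1, 6), name = "certain-toxicity")
  for (d in all_designs) {
    for (s in 1:3) {
      r0 <- run_trial(d, none, cfg, rng_seed = s)
      expect_identical(r0$mtd_index, 6L)
      expect_identical(r0$n_toxicities, 0L)
      r1 <- run_trial(d, all, cfg, rng_seed = s)
      expect_identical(r1$mtd_index, 1L)
      expect_identical(r1$n_toxicities, r1$n_enrolled)
    }
  }
})

test_that("no design skips an untried dose and doses start at 1", {
  set.seed(5)
  for (r in 1:6) {
    sc <- dose_scenario(sort(runif(6, 0, 0.8)), name = "random")
    for (d in all_designs) {
      res <- run_trial(d, sc, cfg, rng_seed = 100 + r)
      doses <- res$roster$dose_index
      expect_identical(doses[1], 1L)
      expect_true(all(doses[-1] <= cummax(doses)[-length(doses)] + 1L))
      tried <- sort(unique(doses))
      expect_identical(tried, seq_len(max(tried)))
    }
  }
})

test_that("TITE-IR treats on arrival, never escalates past a fresh toxicity, and gates on 3 treated", {
  for (seed in 1:8) {
    res <- run_tite_ir(scenario(2), cfg, rng_seed = seed)
    ro <- res$roster
    expect_identical(res$n_enrolled, cfg$n_max)
    expect_identical(ro$arrival_time, ro$treat_time)
    expect_equal(res$duration, max(ro$arrival_time) + cfg$tau)
    for (k in 2:nrow(ro)) {
      prev_obs_tox <- ro$toxicity[k - 1] == 1 &&
        ro$arrival_time[k - 1] + ro$toxicity_time[k - 1] <= ro$arrival_time[k]
      if (prev_obs_tox) {
        expect_lte(ro$dose_index[k], ro$dose_index[k - 1])
      }
      if (ro$dose_index[k] > ro$dose_index[k - 1]) {
        n_at <- sum(ro$dose_index[seq_len(k - 1)] == ro$dose_index[k - 1])
        expect_gte(n_at, 3)
      }
    }
  }
})

test_that("sample sizes respect each design's accounting", {
  for (seed in 11:16) {
    sc <- scenario((seed %% 10) + 1)
    n33 <- run_three_plus_three(sc, cfg, rng_seed = seed)$n_enrolled
    expect_identical(n33 %% 3L, 0L)
    expect_lte(n33, cfg$n_max + 3L)
    expect_identical(run_up_down_d(sc, cfg, rng_seed = seed)$n_enrolled,
                     cfg$n_max)
    expect_identical(run_ir(sc, cfg, FALSE, rng_seed = seed)$n_enrolled,
                     cfg$n_max)
    na <- run_ir(sc, cfg, TRUE, rng_seed = seed)$n_enrolled
    expect_identical(na %% 3L, 0L)
    expect_lte(na, cfg$n_max)
  }
})

test_that("identical seed, config and scenario give identical results", {
  for (d in all_designs) {
    a <- run_trial(d, scenario(6), cfg, rng_seed = 77)
    b <- run_trial(d, scenario(6), cfg, rng_seed = 77)
    expect_identical(a$roster, b$roster)
    expect_identical(a$mtd_index, b$mtd_index)
    expect_identical(a$duration, b$duration)
  }
})

test_that("allocation counts sum to the sample size and duration covers follow-up", {
  for (d in all_designs) {
    res <- run_trial(d, scenario(9), cfg, rng_seed = 3)
    expect_identical(sum(res$allocation), res$n_enrolled)
    expect_gte(res$duration, cfg$tau)
  }
})

test_that("3+3 rules play out as scripted on deterministic toxicity curves", {
  # clean escalation through doses 1-3, then 3/3 toxicities at dose 4:
  # de-escalate and declare dose 3
  sc <- dose_scenario(c(0, 0, 0, 1, 1, 1), name = "cliff")
  res <- run_three_plus_three(sc, cfg, rng_seed = 1)
  expect_identical(res$mtd_index, 3L)
  expect_identical(res$n_enrolled, 12L)
  # certain toxicity at dose 1 declares dose 1 after one cohort
  res1 <- run_three_plus_three(dose_scenario(rep(1, 6)), cfg, rng_seed = 1)
  expect_identical(res1$mtd_index, 1L)
  expect_identical(res1$n_enrolled, 3L)
})

test_that("up-and-down design walks and hands the MTD to the logistic fit", {
  sc <- dose_scenario(c(0, 0, 0, 1, 1, 1), name = "cliff")
  res <- run_up_down_d(sc, cfg, rng_seed = 2)
  # alternates 4 (3/3 toxic) and 3 (clean) after the initial climb
  expect_identical(res$n_enrolled, 24L)
  expect_identical(res$mtd_index, 3L)
  expect_equal(res$duration, with(res$roster, max(treat_time)) + cfg$tau)
})

test_that("terminal logistic fit matches a brute-force MLE and falls back sanely", {
  # clean rising toxicity: the fitted curve crosses the target between the
  # first and second dose level
  r <- data.frame(dose_index = rep(1:3, each = 3),
                  toxicity = c(0, 0, 0, 0, 1, 1, 1, 1, 1))
  dec <- fit_logistic_mtd(r, cfg)
  expect_identical(dec$dose_index, 1L)
  # cross-check the MLE route against a grid-search likelihood maximiser
  co <- logistic_grid_mle(cfg$dose_levels[r$dose_index], r$toxicity)
  fitted <- plogis(co["a"] + co["b"] * cfg$dose_levels)
  expect_identical(select_dose(fitted, cfg)$dose_index, dec$dose_index)

  # degenerate outcomes use the isotonic fallback
  all0 <- data.frame(dose_index = rep(1:6, 4), toxicity = 0)
  expect_identical(fit_logistic_mtd(all0, cfg)$dose_index, 6L)
  all1 <- data.frame(dose_index = rep(1:6, 4), toxicity = 1)
  d1 <- fit_logistic_mtd(all1, cfg)
  expect_identical(d1$dose_index, 1L)
  expect_true(d1$constrained)
  # non-monotone outcomes (toxicity decreasing in dose) also fall back
  dec_rev <- fit_logistic_mtd(
    data.frame(dose_index = rep(1:2, each = 3),
               toxicity = c(1, 1, 1, 0, 0, 0)), cfg)
  expect_identical(dec_rev$dose_index, 1L)
})

test_that("IR-A stops once a dose is given to 3 consecutive cohorts and re-indicated", {
  res <- run_ir(dose_scenario(rep(1, 6)), cfg, early_stop = TRUE, rng_seed = 4)
  expect_identical(res$n_enrolled, 9L)     # cohorts 1-3 at dose 1, then stop
  expect_identical(res$mtd_index, 1L)
  resb <- run_ir(dose_scenario(rep(1, 6)), cfg, early_stop = FALSE,
                 rng_seed = 4)
  expect_identical(resb$n_enrolled, 24L)   # IR-B never stops early
})

test_that("raising the conservatism offset does not push more patients above the MTD", {
  lo <- trial_config(f_star = 0.05)
  hi <- trial_config(f_star = 0.5)
  seeds <- 1:400
  above <- function(config) {
    mean(vapply(seeds, function(s) {
      r <- run_tite_ir(scenario(5), config, rng_seed = s)
      r$allocation[["above"]] / r$n_enrolled
    }, 0))
  }
  expect_lte(above(hi), above(lo))
})

test_that("the audit log records one decision per assignment", {
  res <- run_tite_ir(scenario(1), cfg, rng_seed = 9, audit = TRUE)
  aud <- res$audit
  expect_length(aud, cfg$n_max)
  expect_true(all(vapply(aud, function(a) !is.null(a$phat), TRUE)))
  expect_identical(vapply(aud[-length(aud)], `[[`, 0L, "dose"),
                   res$roster$dose_index[-1])
  f <- tempfile(fileext = ".jsonl")
  write_audit(res, f)
  lines <- readLines(f)
  expect_length(lines, cfg$n_max)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("time", "dose", "phat") %in% names(rec)))
  expect_error(write_audit(run_tite_ir(scenario(1), cfg, rng_seed = 9), f),
               "audit")
})
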