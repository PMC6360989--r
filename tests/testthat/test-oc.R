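cfg <- trial_config()

test_that("operating characteristics aggregate sanely on a degenerate scenario", {
  none <- dose_scenario(rep(0, 6), name = "no-toxicity")
  for (d in c("IR-B", "3+3")) {
    oc <- simulate_ocs(d, none, cfg, n_reps = 100, seed = 1)
    expect_equal(oc$pcd, 100)
    expect_equal(oc$mean_ntox, 0)
    expect_equal(oc$mc_se_pcd, 0)
    expect_equal(oc$alloc_below + oc$alloc_at + oc$alloc_above, 100,
                 tolerance = 1e-9)
    sel <- attr(oc, "selection")
    expect_equal(sum(sel), 100, tolerance = 1e-9)
    expect_equal(sel[6], 100)
  }
  expect_error(simulate_ocs("BOIN", scenario(1), cfg, 10, 1), "unknown")
})

test_that("replicate seeds derive deterministically from the master seed", {
  a <- simulate_ocs("IR-A", scenario(5), cfg, n_reps = 40, seed = 9)
  b <- simulate_ocs("IR-A", scenario(5), cfg, n_reps = 40, seed = 9)
  expect_equal(as.data.frame(a), as.data.frame(b))
  c <- simulate_ocs("IR-A", scenario(5), cfg, n_reps = 40, seed = 10)
  expect_false(isTRUE(all.equal(a$mean_n, c$mean_n)))
})

test_that("compare_designs assembles tables, profiles and contrasts", {
  cmp <- compare_designs(scenarios = c(5, 8), designs = c("TITE-IR", "3+3"),
                         config = cfg, n_reps = 50, seed = 2)
  expect_identical(nrow(cmp$oc), 4L)
  expect_identical(sort(unique(cmp$selection$design)), c("3+3", "TITE-IR"))
  # selection profile sums to 100% per scenario x design
  agg <- aggregate(pct ~ scenario + design, data = cmp$selection, sum)
  expect_true(all(abs(agg$pct - 100) < 1e-9))
  # contrasts equal the hand-computed cross-scenario means
  tite <- cmp$oc[cmp$oc$design == "TITE-IR", ]
  tpt <- cmp$oc[cmp$oc$design == "3+3", ]
  expect_equal(cmp$contrasts$pcd_advantage, mean(tite$pcd - tpt$pcd))
  expect_equal(cmp$contrasts$duration_saved_years,
               mean(tpt$mean_duration_years - tite$mean_duration_years))
  expect_error(compare_designs(scenarios = integer(0)), "non-empty")
})

test_that("PCD and the non-MTD selection percentages always total 100", {
  cmp <- compare_designs(scenarios = 9, designs = c("UD", "IR-B"),
                         config = cfg, n_reps = 60, seed = 3)
  for (d in c("UD", "IR-B")) {
    sel <- cmp$selection[cmp$selection$design == d, ]
    oc <- cmp$oc[cmp$oc$design == d, ]
    expect_equal(oc$pcd, sel$pct[sel$dose == scenario(9)$true_mtd])
    expect_equal(sum(sel$pct), 100, tolerance = 1e-9)
  }
})

test_that("calibration compares safety and accuracy across the offset grid", {
  one <- calibrate_fstar(0.05, config = cfg, n_reps = 30, seed = 4)
  expect_equal(one$f_star, 0.05)
  expect_identical(nrow(one$diagnostics), 1L)
  expect_error(calibrate_fstar(numeric(0)), "non-empty")
  expect_error(calibrate_fstar(c(-0.1, 0.05)), "non-negative")

  # a much larger offset cannot treat more patients above the MTD in the
  # all-toxic-above scenario (common random streams)
  cal <- calibrate_fstar(c(0, 0.5), config = cfg, n_reps = 300, seed = 5)
  d <- cal$diagnostics
  expect_lte(d$over_mtd_pct[d$f_star == 0.5],
             d$over_mtd_pct[d$f_star == 0])
})

test_that("deviation flagging reports cells against the benchmark table", {
  ref <- reference_ocs()
  expect_identical(nrow(ref), 50L)
  expect_identical(sort(unique(ref$design)),
                   c("3+3", "IR-A", "IR-B", "TITE-IR", "UD"))
  # a tiny run deviates wildly and every flagged row carries the metrics
  cmp <- compare_designs(scenarios = 1, designs = "3+3", config = cfg,
                         n_reps = 5, seed = 6)
  f <- flag_deviations(cmp)
  expect_true(all(c("design", "metric", "difference", "note") %in% names(f)))
})
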