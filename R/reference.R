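# Published benchmark operating characteristics for the ten scenarios and
# five designs (10,000 replicates at the default settings), against which
# this package's simulation study is validated: PCD (%), mean toxicities,
# mean sample size, mean duration (years), and mean % of patients treated
# below / at / above the true MTD.
.reference_cells <- local({
  m <- rbind(
    # scenario, pcd, ntox, n, dur, below, at, above  -- 3+3
    c(1, 24.8, 2.9, 14.9, 2.7, 76.6, 15.3, 8.1),
    c(2, 26.6, 2.8, 12.9, 2.3, 63.8, 22.5, 13.7),
    c(3, 85.1, 2.5, 7.1, 1.3, 0, 72.0, 28.0),
    c(4, 44.4, 2.7, 19.3, 3.4, 67.6, 19.4, 13.0),
    c(5, 99.9, 2.8, 6.4, 1.2, 0, 67.6, 32.4),
    c(6, 64.1, 2.9, 9.4, 1.7, 43.0, 37.7, 19.3),
    c(7, 19.7, 2.6, 7.7, 1.4, 69.7, 21.3, 9.0),
    c(8, 38.2, 2.0, 20.2, 3.6, 70.2, 19.8, 0),
    c(9, 9.9, 2.8, 13.6, 2.4, 91.7, 5.7, 2.6),
    c(10, 27.7, 2.8, 15.2, 2.7, 75.3, 12.7, 12.0),
    # UD
    c(1, 43.0, 5.1, 24.0, 4.1, 64.7, 25.2, 10.1),
    c(2, 39.4, 5.7, 24.0, 4.1, 46.4, 31.5, 22.1),
    c(3, 80.1, 8.6, 24.0, 4.1, 0, 56.0, 44.0),
    c(4, 58.3, 3.7, 24.0, 4.1, 59.8, 27.1, 13.1),
    c(5, 100, 10.1, 24.0, 4.0, 0, 68.3, 31.7),
    c(6, 74.9, 8.2, 24.0, 4.0, 23.2, 53.0, 23.8),
    c(7, 28.3, 8.1, 24.0, 4.1, 48.2, 34.4, 17.4),
    c(8, 47.1, 2.8, 24.0, 4.1, 75.5, 24.5, 0),
    c(9, 14.0, 5.0, 24.0, 4.1, 89.7, 8.2, 2.1),
    c(10, 42.4, 4.6, 24.0, 4.1, 63.2, 21.6, 15.2),
    # IR-A
    c(1, 41.4, 4.9, 22.5, 3.6, 65.5, 23.7, 10.8),
    c(2, 39.0, 5.1, 21.6, 3.4, 49.5, 29.5, 20.9),
    c(3, 75.7, 5.9, 16.5, 2.4, 0, 63.3, 36.7),
    c(4, 58.5, 3.93, 23.9, 4.0, 58.1, 26.7, 15.3),
    c(5, 100, 5.8, 18.5, 2.6, 0, 84.3, 15.7),
    c(6, 87.4, 5.8, 21.3, 3.2, 23.2, 64.3, 12.5),
    c(7, 33.4, 5.6, 17.0, 2.5, 59.0, 27.9, 13.1),
    c(8, 60.7, 2.9, 24.0, 4.1, 72.6, 27.4, 0),
    c(9, 19.3, 4.5, 21.5, 3.5, 89.7, 8.0, 2.3),
    c(10, 37.2, 4.3, 22.5, 3.7, 65.6, 18.7, 15.7),
    # IR-B
    c(1, 46.3, 5.3, 24.0, 4.1, 63.4, 25.5, 11.1),
    c(2, 40.6, 5.8, 24.0, 4.1, 45.8, 31.2, 23.0),
    c(3, 68.7, 8.5, 24.0, 4.1, 0, 57.9, 42.1),
    c(4, 60.5, 3.93, 24.0, 4.1, 57.7, 27.0, 15.3),
    c(5, 99.9, 7.2, 24.0, 4.0, 0, 85.5, 14.5),
    c(6, 92.2, 6.6, 24.0, 4.0, 20.0, 66.6, 13.5),
    c(7, 40.3, 8.0, 24.0, 4.1, 53.7, 30.7, 15.6),
    c(8, 60.6, 3.0, 24.0, 4.1, 72.8, 27.2, 0),
    c(9, 21.4, 5.0, 24.0, 4.1, 89.0, 8.6, 2.3),
    c(10, 43.0, 4.7, 24.0, 4.1, 63.7, 20.2, 16.1),
    # TITE-IR
    c(1, 40.3, 5.1, 24.0, 1.5, 68.7, 18.5, 12.8),
    c(2, 37.1, 5.8, 24.0, 1.5, 51.1, 25.4, 23.5),
    c(3, 63.3, 9.0, 24.0, 1.5, 0, 52.6, 47.4),
    c(4, 51.8, 2.95, 24.0, 1.5, 71.4, 17.5, 11.1),
    c(5, 99.9, 10.1, 24.0, 1.5, 0, 68.4, 31.6),
    c(6, 87.7, 8.6, 24.0, 1.5, 25.8, 47.6, 26.7),
    c(7, 38.9, 8.3, 24.0, 1.5, 48.3, 28.6, 23.1),
    c(8, 46.0, 1.9, 24.0, 1.5, 85.6, 14.4, 0),
    c(9, 22.0, 5.0, 24.0, 1.5, 88.6, 7.8, 3.6),
    c(10, 39.2, 4.4, 24.0, 1.5, 68.6, 16.9, 14.5)
  )
  data.frame(
    design = rep(c("3+3", "UD", "IR-A", "IR-B", "TITE-IR"), each = 10),
    scenario = as.integer(m[, 1]),
    pcd = m[, 2], mean_ntox = m[, 3], mean_n = m[, 4],
    mean_duration_years = m[, 5],
    alloc_below = m[, 6], alloc_at = m[, 7], alloc_above = m[, 8],
    stringsAsFactors = FALSE
  )
})

#' Benchmark operating characteristics
#'
#' The published benchmark operating characteristics (10,000 replicates at
#' the default settings of [trial_config()]) that this package's
#' simulation study is validated against, for the ten shipped scenarios
#' and five designs.
#'
#' @return Data frame with one row per design x scenario: `pcd`,
#'   `mean_ntox`, `mean_n`, `mean_duration_years`, and the allocation
#'   percentages below/at/above the true MTD.
#' @seealso [flag_deviations()] to compare a [compare_designs()] run
#'   against it.
#' @export
reference_ocs <- function() .reference_cells

# Conduct details that the available description of each design leaves
# open were resolved by simulation (see the methods vignette); the cells
# known to remain sensitive to those resolutions carry a note here.
.known_deviations <- local({
  tite <- "TITE-IR assignment and declaration rule reading (partial-follow-up argmin; declaration band target + F*); see the methods vignette"
  ir <- "IR escalation gate, toxicity block and early-stopping details are under-determined by the available description; see the methods vignette"
  ud <- "covariate scale of the terminal logistic fit (raw dose in mg); see the methods vignette"
  tpt <- "benchmark row for this cell does not sum to 100% (apparent misprint); cohort timing under queued accrual"
  rbind(
    data.frame(design = "TITE-IR", scenario = c(1L, 2L, 3L, 6L, 7L, 10L),
               note = tite),
    data.frame(design = "3+3", scenario = 1L,
               note = "cohort timing under queued accrual shortens early-stopped trials slightly"),
    data.frame(design = "3+3", scenario = 8L, note = tpt),
    data.frame(design = "UD", scenario = c(3L, 7L, 9L), note = ud),
    data.frame(design = "IR-A",
               scenario = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L, 10L), note = ir),
    data.frame(design = "IR-B",
               scenario = c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 10L), note = ir)
  )
})

#' Flag cells of a comparison run that deviate from the benchmark
#'
#' Compares the operating characteristics of a [compare_designs()] run on
#' the shipped scenarios against [reference_ocs()] and reports every cell
#' outside tolerance, annotated — where the deviation traces to a conduct
#' detail that the available design descriptions leave open — with the
#' design decision responsible (detailed in the methods vignette).
#'
#' @param comparison A [compare_designs()] result run on shipped scenarios.
#' @param tol Named tolerances: `pcd` and the allocation percentages
#'   (points), `ntox`, `n`, and `dur` (years).
#' @return Data frame of deviating cells: design, scenario, metric, value,
#'   reference, difference, and `note` (`NA` when no documented decision
#'   explains the cell).
#' @export
flag_deviations <- function(comparison,
                            tol = c(pcd = 3, ntox = 0.4, n = 0.5,
                                    dur = 0.15, alloc = 3)) {
  stopifnot(inherits(comparison, "design_comparison"))
  oc <- comparison$oc
  oc$scenario_id <- as.integer(sub("^scenario-", "", oc$scenario))
  ref <- reference_ocs()
  metrics <- c(pcd = "pcd", ntox = "mean_ntox", n = "mean_n",
               dur = "mean_duration_years",
               alloc = "alloc_below", alloc = "alloc_at",
               alloc = "alloc_above")
  out <- NULL
  for (i in seq_len(nrow(oc))) {
    r <- ref[ref$design == oc$design[i] &
               ref$scenario == oc$scenario_id[i], ]
    if (nrow(r) != 1L) next
    for (k in seq_along(metrics)) {
      col <- metrics[[k]]
      d <- oc[[col]][i] - r[[col]]
      if (abs(d) > tol[[names(metrics)[k]]]) {
        note <- .known_deviations$note[
          .known_deviations$design == oc$design[i] &
            .known_deviations$scenario == oc$scenario_id[i]]
        out <- rbind(out, data.frame(
          design = oc$design[i], scenario = oc$scenario_id[i],
          metric = col, value = oc[[col]][i], reference = r[[col]],
          difference = d,
          note = if (length(note)) note[1L] else NA_character_,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(design = character(), scenario = integer(),
                      metric = character(), value = numeric(),
                      reference = numeric(), difference = numeric(),
                      note = character(), stringsAsFactors = FALSE)
  }
  out
}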