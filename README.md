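# titetrial

Phase I oncology trials search a short grid of doses for the **maximum
tolerated dose (MTD)**: the highest dose whose probability of a
dose-limiting toxicity (DLT) by a follow-up window τ is closest to a
target π\* without exceeding it.  When τ is long — six months is typical
for late-onset toxicities — classical designs that fully evaluate each
cohort of three before the next assignment keep newly eligible patients
waiting and stretch a 24-patient trial past four years.

`titetrial` implements the **TITE-IR design** (time-to-event isotonic
regression dose finding), which treats every patient immediately on
arrival.  For dose *j* with *n<sub>j</sub>* patients, *Y<sub>j</sub>*
observed toxicities and follow-ups *t<sub>i</sub>*, the raw toxicity
estimate is

```
qhat_j = [ Y_j  +  Σ_{i: no toxicity} ((τ − t_i)/τ) · (π* + F*) ] / n_j
```

— each toxicity-free patient is booked with a pseudo-toxicity that
melts away linearly as their follow-up accrues (a uniform working prior
on the toxicity time), and the offset F\* ≥ 0 tunes how conservative
escalation is.  The raw estimates are made monotone in dose by weighted
pool-adjacent-violators (`pava()`), and the next patient is assigned the
dose whose smoothed estimate is closest to π\*, under explicit safety
rules (three patients treated at a dose before escalating above it, no
escalation past a fresh toxicity, no skipping of untried doses).  After
*N*<sub>max</sub> patients everyone is followed to τ and the MTD is
declared.

The package also provides the benchmark comparators — the classical
**3+3**, **Storer's up-and-down design D** (with its terminal logistic
fit), and the fully evaluated isotonic designs **IR-A / IR-B** — plus a
Monte Carlo harness for operating characteristics, an F\* calibration
routine, a real-trial conduct mode, and a command-line interface.

## A worked example

Simulate one TITE-IR trial under benchmark scenario 1 (true toxicity
probabilities 0.05 … 0.70 over six doses of 5–40 mg, true MTD dose 4):

```r
library(titetrial)
cfg <- trial_config()        # pi* = 1/3, tau = 6 mo, F* = 0.05, N = 24, 2 pts/mo
run_tite_ir(scenario(1), cfg, rng_seed = 7)
#> TITE-IR trial under scenario-1
#>   declared MTD : dose 4 (true MTD: dose 4)
#>   enrolled     : 24 patients, 6 toxicities
#>   duration     : 19.1 months (1.59 years)
#>   allocation   : 9 below / 11 at / 4 above the true MTD
```

The trial enrolled all 24 patients in 13 months and finished — last
patient fully followed — in 1.6 years, compared with ~4 years for a
fully evaluated cohort design; it declared the correct MTD.  Operating
characteristics aggregate over replicates:

```r
simulate_ocs("TITE-IR", scenario(5), cfg, n_reps = 2000, seed = 42)
#>    design   scenario n_reps  pcd mc_se_pcd mean_ntox mean_n mean_duration_years
#>   TITE-IR scenario-5   2000 99.8       0.1      9.83     24                1.45
#>   alloc_below alloc_at alloc_above
#>             0     70.2        29.8
```

In the "everything above dose 1 is 90% toxic" scenario the design still
names dose 1 in 99.8% of trials, with 70% of patients treated at the
MTD.  `compare_designs()` builds the full design × scenario table,
selection profiles and cross-design contrasts; `flag_deviations()`
annotates any cell outside Monte Carlo tolerance of the shipped
benchmark table (`reference_ocs()`).  `calibrate_fstar()` reruns the
offset calibration (it selects the default F\* = 0.05), and
`next_dose()` recommends a dose from a real trial roster.

## Command line

```sh
inst/cli/titetrial simulate  --designs TITE-IR,3+3 --scenarios 5 --reps 1000 --seed 7 --out out/
inst/cli/titetrial calibrate --grid 0,0.05,0.1,0.2 --reps 2000 --out cal/
inst/cli/titetrial conduct   --roster roster.csv --time 8.5
```

Every `simulate` output directory contains a `manifest.json` from which
the run is exactly reproducible.

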