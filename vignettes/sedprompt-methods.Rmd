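---
title: "Methods: the sedentary-behavior prompting engine, its metrics, and the cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sedentary-behavior prompting engine, its metrics, and the cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedprompt)
```

`sedprompt` implements a just-in-time adaptive intervention (JITAI) for
disrupting prolonged sedentary behavior (SB) around major abdominal surgery.
This vignette is the package's account of the underlying model: the
prompting rule and its state machine, the measurement rules behind the
outcome metrics, the statistical procedures, what the synthetic cohort
generator does and does not emulate, and the design decisions taken where
the procedure left genuine freedom.

## The prompting rule

The unit of time is the participant-minute. A minute with fewer than 10
recorded steps is *sedentary*; the 10-step cut tolerates incidental
stepping and arm movements miscounted as steps while still crediting very
slow postoperative walking as activity. Consecutive sedentary minutes
accumulate in a counter; when the counter reaches the active threshold
\(T\) and the minute lies inside the participant's self-set wake window, an
activity prompt is emitted.

The threshold is tailored to the day's symptom burden. Participants rate
ten symptoms (pain, fatigue, sleep disturbance, concentration, sadness,
anxiety, shortness of breath, numbness, nausea, bowel problems) each
morning on a 0–10 numeric scale. The engine always consults the most recent
rating at or before the current minute:

* all ten severities below 7 → \(T = 60\) minutes;
* any severity at or above 7 → \(T = 120\) minutes (fewer prompts on bad
  days);
* no rating ever submitted → \(T = 120\) minutes.

Steps in the 15 minutes strictly after a prompt, \((t, t+15]\), are
tallied; a total of at least 30 steps marks the prompt *responded* and
triggers the positive feedback message. All six quantities (step cut,
both thresholds, severity cut, response window, step goal) are fields of
`engine_config()` and validated jointly (`low_threshold <= high_threshold`,
severity cut in 1–10, the unrated default equal to one of the two
thresholds).

### State-machine semantics

Several aspects of the delivered intervention are not pinned down by a
one-paragraph description of the rule; the package fixes them as explicit,
configuration-visible policies:

* **Re-arm.** The accumulator resets to zero at prompt emission and must
  re-reach the full threshold before the next prompt ("reset-on-prompt"),
  rather than sliding-window logic. Consequently a fully sedentary waking
  day of \(W\) minutes at fixed threshold \(T\) produces exactly
  \(\lfloor W/T \rfloor\) prompts — the closed form the test suite checks —
  and consecutive prompts are separated by at least the threshold active at
  the later prompt.
* **Full reset on activity.** Any active minute (≥ 10 steps) clears the
  accumulator entirely; an unbroken run is required, with no partial credit.
* **Missing minutes are sedentary.** Inside the wake window, a minute with
  no recorded sample counts as zero steps. A wrist app sees zero steps when
  the wearer is idle or the device is off wrist, so non-wear can
  misclassify time as sedentary; the measurement layer mirrors the same
  assumption (below) and makes it switchable.
* **Threshold changes act immediately, without reset.** A new rating
  re-tailors the threshold from the minute it arrives and applies to the
  accumulation already in progress. If the threshold drops below the
  current accumulator value, the prompt fires at the next sedentary minute.
  Ratings carry forward indefinitely across days.
* **Response windows do not pause accumulation.** The 15-minute tally runs
  concurrently with further accumulation; injected walking resets the
  accumulator through the ordinary active-minute rule, not specially.
* **Wake-window gating only.** Prompts are gated on the wake window; the
  engine does not additionally suppress prompts during device-detected
  sleep inside the window (naps), since the delivered system's behavior
  there is unknown. Windows are effective-dated and may cross midnight.

The production engine scans maximal sedentary runs in closed form (within a
constant-threshold block entered with accumulator \(a\), the first prompt
falls at offset \(\max(1, T-a)\) and then every \(T\)); an independent
brute-force per-minute re-scan lives in the test helpers, and the two are
compared on 1,000 randomized days with random windows, gaps, naps, and
mid-day threshold changes.

## Measurement rules

* **Wear filter.** A day enters activity analyses when at least 480 minutes
  (8 h) carry a worn flag; wear need not be consecutive. `daily_wear_minutes`
  is a plain count, and the boundary (479 vs 480) is tested.
* **Bouts.** An SB bout is a maximal run of sedentary minutes within the
  waking day. Minutes inside device-detected sleep episodes are removed
  before run-finding, splitting runs at episode boundaries; runs truncate at
  the wake-window edges, so a run crossing bedtime belongs to the day that
  opened the window. With `treat_missing_as_sedentary = TRUE` (default)
  missing minutes extend runs, mirroring the engine; setting it `FALSE`
  breaks runs at gaps instead, the sensitivity configuration for non-wear
  misclassification.
* **Daily mean bout.** "Mean SB bout per day" averages over the bouts within
  a day, then phase summaries average those daily values over
  wear-included days. (Averaging over all phase bouts pooled is the other
  defensible reading; the per-day-first definition is used because every
  daily outcome here is defined per day before phase aggregation.)
* **Pooled fractions.** Phase- and cohort-level response fractions are
  ratio-of-sums (total responses over total prompts), not means of daily
  ratios, matching how engagement counts are conventionally reported; a
  phase with zero prompts yields `NA`, flagged rather than 0.
* **Phases.** Study days partition into preoperative (before surgery),
  inpatient (surgery day through discharge day, both inclusive), and
  postdischarge. The inclusive inpatient interval keeps inpatient-stay
  lengths consistent with counts that include the surgery and discharge
  days.
* **Printed precision.** Percentages round half away from zero to integers;
  test statistics print at 1 decimal and p values at 2, matching clinical
  reporting conventions (`round_half_up`).

## Trial statistics

`pearson_chi2` computes the uncorrected statistic
\(n(ad-bc)^2/(r_1 r_2 c_1 c_2)\) on a 2×2 arm-by-outcome table with df = 1.
The continuity correction is off by default — the uncorrected statistic is
what trial reports of this size print (for the readmission table 5/12 vs
4/12 the uncorrected value is 0.18, printed 0.2, while the Yates value
would be 0.0) — and available via `correct = TRUE`. A zero row or column
margin is an error, not a zero.

At trial scale the uncorrected test is mildly anticonservative. Its exact
size is computable by enumerating all table outcomes:

```{r exact-size}
exact_size <- function(n, p, alpha = 0.05) {
  size <- 0
  px <- dbinom(0:n, n, p)
  for (x in 0:n) for (y in 0:n) {
    if ((x + y) == 0 || (x + y) == 2 * n) next
    if (pearson_chi2(x, n - x, y, n - y)$p < alpha)
      size <- size + px[x + 1] * px[y + 1]
  }
  size
}
exact_size(12, 0.375)  # two arms of 12, readmission-like event rate
exact_size(80, 0.35)   # near-nominal by n = 80 per arm
```

The test suite verifies the Monte-Carlo rejection rate against this
enumeration at \(n = 80\) per arm, where the asymptotics hold; the
small-sample excess above 0.05 at \(n = 12\) is a property of the test
itself and is documented here rather than "fixed".

`two_sample_t_from_summary` reconstructs the independent two-tailed t test
from per-group \((n, \bar x, s)\). The pooled-variance Student form
(df \(= n_1+n_2-2\)) is the default because it reproduces the printed
usability-table p values; published reports of such tables rarely state
pooled versus Welch, so the choice is by agreement with the printed values,
and Welch is available via `pooled = FALSE`. Summary inputs printed at one
decimal limit reproduction to about ±0.01 in the p value, which is why one
of the six usability rows matches at that tolerance rather than exactly at
two decimals. Degenerate inputs: both SDs zero with equal means defines
\(t = 0\); with unequal means the statistic is undefined and errors.

## The cohort simulator

The generator exists so that every stage — engine, metrics, statistics — is
testable end-to-end with no external data, and so that known parameters can
be recovered from the pipeline's output.

**Structure.** Within each waking day, activity is a two-state
(sedentary/active) Markov chain at minute resolution, with phase-specific
transition probabilities. This is the minimal structure that produces the
geometric-tailed sedentary-run distributions the bout extractor must
handle. Sedentary minutes log 0 steps (85%) or 1–4 steps; active minutes
log 10 plus a Poisson count. Phase durations are right-skewed: a shifted
geometric truncated to the plausible range, with the success probability
solved (`uniroot`) so the *truncated* mean hits the target — preoperative
mean 19.6 days within 8–47, inpatient mean 10.9 within 5–24, and a fixed
30-day postdischarge follow-up. A uniform-integer spec is also available.

**Engine in the loop.** For intervention-arm participants the prompting
engine runs online during generation. At every emitted prompt the simulated
participant responds with the phase's response probability: a response
injects a walk of 30–60 total steps over the next three minutes (each ≥ 10
steps, hence active, recorded as worn); a decline zeroes the 15-minute
response window — someone who ignores a prompt while sitting keeps sitting.
Two consequences are deliberate:

* the per-prompt response indicator is *exactly* Bernoulli with the
  configured probability, making parameter recovery against an exact
  binomial interval well-posed; and
* intervention-arm streams are prompt-contingent — walking happens *because*
  prompts happened — reproducing the causal structure a JITAI assumes.
  Monitoring-arm timelines contain no prompt-contingent behavior.

An offline re-run of the engine over the written bundle reproduces the
online prompt sequence exactly (asserted in tests), so analyses of a stored
bundle see precisely the events the simulated participant experienced.

**Layered realism.** Daily symptom reports arrive mid-morning with a
phase-specific probability; one designated dimension (fatigue) carries a
two-point severe/not-severe mixture so that P(any severity ≥ 7) equals the
phase parameter exactly, and the other nine stay low. Wear is a contiguous
block from wake-up with Gaussian length, present on a phase-specific
fraction of days; unworn minutes are dropped from the written stream
(missing rows), exercising the missing-as-sedentary path. Naps and nightly
sleep become sleep episodes, exercising the exclusion path of the bout
extractor.

**Calibration.** Default phase parameters were calibrated once, against the
printed phase statistics of the motivating trial — roughly 3.3 / 7.8 / 6.2
prompts per day across preoperative / inpatient / postdischarge phases,
response fractions 0.49 / 0.06 / 0.18, symptom-reporting adherence around
62% of days overall, 77% worn days with 91% of them reaching 8 h, about
3,600 steps per included day, and daily mean/max SB bouts of roughly 61 and
248 minutes. With the defaults the simulator lands near those neighborhoods
(about 4 / 8.6 / 6.9 prompts per day; ≈3,700 steps; mean bout ≈59 min; max
bout ≈206 min at the default seed). These are generator conditions, not
fitted estimates: the defaults live in one place (`cohort_config()`), are
recorded in every bundle's manifest, and were not adjusted to make any test
pass.

**What the generator does not emulate.** Symptom trajectories have no
autocorrelation or postoperative drift beyond phase means; step magnitudes
have no diurnal profile; wear gaps are a single block rather than scattered
removals; response propensity is independent of simulated sleep and wear
(a prompt during a simulated nap can still be "answered"); and readmission
is not causally generated from activity. Passing tests on simulated
cohorts therefore demonstrate correctness of the *pipeline* — detection,
gating, tallying, filtering, aggregation — not fidelity of any particular
behavioral model of recovery. Trial-level outcome values that depend on the
real cohort (e.g. group effects on bout duration) are out of reach at desk
scale by design.

## Numerical and testing choices

* Timestamps are minute-granular, timezone-naive local time (stored as UTC
  `POSIXct`); there is no DST or timezone arithmetic anywhere.
* Determinism: a single integer seed drives every draw; identical seeds
  yield byte-identical bundles, manifests, and run outputs. Run logs carry
  an FNV-1a hash of the configuration.
* Problem sizes: property suites use 150 randomized days per module plus
  1,000 days in the end-to-end oracle-equivalence check; parameter recovery
  uses 100 seeded replicates of a 13-per-arm cohort, each phase supplying
  at least 400 prompt-level Bernoulli trials; the null-calibration study
  uses 20,000 simulated tables. These sizes give the binomial assertions
  comfortable margins (a 95% interval must cover the truth in ≥ 93 of 100
  replicates) while keeping the default test run in the minutes range.
* Degenerate inputs are first-class: zero-transition chains (absorbing
  states), empty days, empty event sets, zero-prompt phases (`NA`, not 0),
  and response probabilities of exactly 0 or 1 (recovered exactly).

## Known limitations

* The engine's closed-form scan assumes minute-aligned data; sub-minute
  device exports must be aggregated upstream.
* Wear is measured by an explicit flag; inferring wear from heart-rate or
  accelerometer density is out of scope (an importer may set
  worn = row-present for raw exports).
* The adherence table reports ≥ 8 h-among-worn and included-overall as
  separate ratios computed from its own inputs; published reports sometimes
  print inconsistent counts for these, and no reconciliation is attempted.
* Linear mixed modeling of phase trajectories is delegated to standard
  tools (`nlme`, `lme4`) on the exported daily summaries; the package
  supplies the per-day outcomes, not the models.
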