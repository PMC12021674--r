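---
title: "Methods: the screening cost-effectiveness model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the screening cost-effectiveness model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

## The model and its assumptions

`crcscreen` implements a deterministic Markov cohort model of colorectal
cancer (CRC) screening. A cohort (default 100,000 persons) enters at age 50
with no CRC history and is advanced through annual cycles to age 75, the
final screening age. Cohort mass is continuous ("fractional persons");
every tally is an exact expectation, so results are reproducible without
Monte-Carlo error. A companion microsimulation (`microsim_run()`) replays
the identical event logic with per-person Bernoulli draws and exists purely
to cross-validate the cohort engine.

State space: *well* (undiagnosed, eligible for primary screening); a
surveillance clock (0–2 years since polypectomy; colonoscopy at year 3); a
pause clock (0–9 years since a normal colonoscopy; primary testing resumes
at year 10); diagnosed CRC stages I–IV, each with a year-in-state clock;
*cured*; and three absorbing death states (CRC, other cause, colonoscopy
complication). The state space is a reconstruction: the minimal set that
supports every reported tally (cases by stage, deaths, procedure and
complication counts, the cost ledger, discounted life-years).

Within each cycle events occur in a fixed order: clock advance → scheduled
screening (with any triggered colonoscopies) → CRC incidence →
stage-specific CRC mortality → other-cause mortality → cost and life-year
accrual, discounted by `(1+r)^-(age-50)`. There is no half-cycle
correction, matching the spreadsheet-style cohort accounting this class of
analysis uses. After age 75 the cohort is followed to the closing age (110)
for *cancer-related life-year accounting only*: prevalent CRC keeps dying
at stage-specific rates under competing other-cause mortality, but no
screening, incidence, or costs accrue.

Disease natural history is deliberately reduced: there is no
adenoma–carcinoma submodel. Prevention by screening enters as an incidence
multiplier: mass attending a screening round incurs incidence
`rate × (1 − prevention)` with the strategy's published prevention fraction
(FIT 21%, stool-DNA 25%, colonoscopy 54%). Mass in the surveillance or
pause states has been protected by colonoscopy (with polypectomy where
indicated), so those states carry the *colonoscopy* prevention fraction
regardless of the primary test — the clinically coherent reading, chosen on
principle before any output was inspected.

Detection: incident cases among attendees are found with the test's
sensitivity and diagnosed with an earlier-stage distribution;
`shift_stage_distribution()` moves a configurable fraction (default 0.5) of
stage III/IV probability proportionally onto stages I/II. The source
analysis invokes earlier diagnosis but publishes no shifted distribution,
so the fraction is explicit, sweepable, and excluded from acceptance.
Missed cases and cases among non-attenders are diagnosed the same cycle
with the standard distribution (annual cycles make a sub-year diagnostic
delay unrepresentable). Cases arising in the surveillance/pause pool
present clinically at standard stages.

Treatment pathway: stage I–II patients are cured after 5 recurrence-free
years; stage III splits at diagnosis into a 70% cure track (cured after 5
years) and a 30% failure track that progresses to stage-IV-like mortality
after its clock expires; stage IV is never cured. Stage-specific annual
mortality (1.0/4.5/8.7/43.0%) applies from the diagnosis year. Care costs
are accrued once, at diagnosis, as the per-stage totals; for stage IV the
printed total (45,115 USD) is used even though the printed components sum
to 52,086 — totals feed the downstream arithmetic, so the total is treated
as authoritative and the components are stored for reference.

Colonoscopy consequences: every colonoscopy carries the procedure and
consultation cost; the polypectomy-rate share (14.05%) is therapeutic
(histopathology cost, entry to surveillance), the rest diagnostic (entry to
the pause). The therapeutic/diagnostic split is applied to *all*
colonoscopies, including confirmatory ones, so the engine's invariant
`therapeutic = 0.1405 × total` holds exactly. Perforations occur at 0.08%
and perforation deaths at 0.0029% per colonoscopy — the per-colonoscopy
basis is the only one consistent with the published complication counts.
The published bleeding counts imply roughly 0.2% per colonoscopy while the
published input table says 0.98% per polypectomy; the default is
`per_colonoscopy` at 0.002 with the per-polypectomy basis selectable
(`procedure.bleeding_basis`). Perforation deaths go to a separate death
state and are *not* added to cancer-related life-years lost, which is
defined as cancer-related only.

## Parameters that matter

All parameters live in one bundle (`default_parameters()`), are addressable
by dotted keys (`set_param()`, `load_config()`), and validate against typed
ranges (`validate_params()`).

| key | default | unit | why |
|---|---|---|---|
| `fit.sensitivity` / `fit.specificity` | 0.73 / 0.919 | prob. | published FIT accuracy for CRC |
| `colotect.sensitivity` / `colotect.specificity` | 0.88 / 0.92 | prob. | published mt-sDNA accuracy |
| `fit.compliance` / `colotect.compliance` / `colonoscopy.compliance` | 0.60 / 0.9698 / 0.989 | prob. per round | published compliance estimates |
| `fit.cost` / `colotect.cost` | 19 / 60 | USD per kit | published unit costs |
| `*.prevention` | 0.21 / 0.25 / 0.54 | fraction | published "cancer prevented by" fractions, applied as incidence multipliers |
| `procedure.cost` + `procedure.consultation` | 1259 + 96 | USD per colonoscopy | published procedure costs |
| `procedure.polypectomy_rate` | 0.1405 | per colonoscopy | published ACN polypectomy rate |
| `procedure.perforation_rate` / `perforation_mortality` | 8e-4 / 2.9e-5 | per colonoscopy | reproduce published complication counts |
| `stage.dist_*` | 11.2/24.5/31.5/32.8% | prob. | stage at diagnosis, unscreened |
| `stage.mortality_*` | 1.0/4.5/8.7/43.0% | per year | annual stage-specific mortality |
| `model.discount_rate` | 0.03 | per year | standard CEA discounting |
| `model.stage_shift` | 0.5 | fraction | package choice; unpublished (see above) |
| `model.stage3_cure_rate` | 0.70 | prob. | published adjuvant cure expectation |
| `model.attendance_model` | `independent_per_round` | — | see below |
| `colonoscopy.sensitivity` | 0.95 | prob. | package choice: field-standard colonoscopy sensitivity; the source publishes none. Used only for the detection context. |

Attendance: `independent_per_round` draws attendance afresh each round at
the compliance rate. `once_ever` models a fixed compliant subcohort and is
implemented as an exact linear mixture (compliant fraction at compliance 1
plus the no-screening remainder), valid because every tally is linear in
cohort mass. `geometric_attrition` decays per-round compliance by
`model.attrition` per year. The published kit counts cannot be reconciled
with any of these under the stated compliances, so kit counts are excluded
from acceptance and the mechanism is configurable rather than asserted.

## The synthetic epidemiology

The registry incidence curve and the standard life table behind the source
analysis are not deposited. `gen_incidence()` emulates a
Hong-Kong-registry-like curve, `rate(a) = b·exp(s·(a−50))` with defaults
`b = 6e-4`, `s = 0.055` — about 60 per 100,000 at age 50 rising roughly
four-fold by 75, the magnitude a high-incidence East-Asian registry
reports. Optional seeded log-normal jitter (`jitter_sd`) mimics sampling
noise; `jitter_sd = 0` (the default) is deterministic. `gen_life_table()`
uses Gompertz–Makeham mortality `q(a) = min(1, A + B·e^{c(a−50)})` with
defaults `A = 5e-4`, `B = 1.5e-3`, `c = 0.095`, giving a
long-lived-population schedule; remaining life expectancy is the curtate
expectation summed to the closing age 110 (contributions beyond are
negligible at realistic mortality). These defaults were chosen once, from
population magnitudes, and deliberately *not* calibrated to reproduce the
published absolute totals (3,233 baseline cases); with them the engine
happens to produce a baseline of the same order (~3,100), which is
reassuring but not asserted anywhere.

What a green test therefore establishes: the mechanics (conservation,
protocol scheduling, discounting, dominance analysis, the published
arithmetic identities) are correct, and the model responds to parameters
with the right signs and magnitudes. What it does not establish: agreement
with any real registry's absolute burden, or the source's absolute totals,
which depend on its private inputs. Quinquennial registry tables can be
supplied as two-column text and are expanded constant-within-band to the
annual grid the engine cycles on.

## Numerical choices

* Fractional persons throughout; rounding (half-up) only at report time in
  `render_table3()`: counts to integers, currency to whole USD, proportions
  to one decimal.
* Conservation is audited every cycle; the suite requires
  `|Σ masses − cohort| < 1e-6` persons over the full horizon.
* Ties: mass whose pause expires in a year it is also due for a primary
  test receives the primary test, not a colonoscopy.
* Degenerate inputs: zero incidence, zero mortality, zero compliance, and
  neutral tests (sensitivity 0, specificity 1, prevention 0) are exercised
  in tests and reproduce the no-screening tallies exactly.
* `efficiency_frontier()` removes strictly dominated points first (exact
  ties flag the later entry), then removes extended-dominated points
  iteratively until incremental ratios strictly increase; it is validated
  against an independent greedy lowest-incremental-ratio construction on
  random instances.
* Threshold search (`wtp_crossing()`) bisects the swept parameter to a
  configurable tolerance (default 1e-4 parameter units) and returns `NA`
  when the bracket does not straddle the threshold.
* Sweep ranges for the tornado default to ±20% of baseline for
  probabilities (clipped to [0,1]) and ±25% for costs; the source does not
  state its ranges.
* All randomness (jitter, microsimulation) is seeded and restores the
  caller's RNG state.

## Known limitations

* **One acceptance criterion is red by design of the stated world.** The
  source's sensitivity figure shows the stool-DNA ICER *decreasing* with
  compliance. In this model every cost (kits, false-positive colonoscopies)
  and every benefit (prevention, earlier detection) scales per person per
  round, so the ICER is near-constant in compliance with a weakly
  *increasing* second-order slope (~1% across compliance 0.5–1.0). A
  decreasing curve would need a fixed programme cost or attendance
  mechanics the source does not publish — its kit counts and prevented
  fractions are internally irreconcilable. The criterion is asserted as
  specified and left failing rather than loosened. (Under `once_ever`
  attendance the ICER is exactly constant in compliance, which would
  satisfy the weak inequality, but switching the default to achieve that
  would be calibration to the outcome.)
* Prevented proportions, kit counts, and absolute case/life-year totals of
  the source are not reproduction targets (private inputs, underdetermined
  mechanics); the reproduced quantities are its arithmetic identities.
* No QALY weighting (deliberately out of scope), no subgroup structure, no
  adenoma natural history, no indirect costs, and a single fixed currency
  conversion.
* Cured persons are assumed to leave the screening programme; competing
  screening after cure is not modelled.
* Care costs accrue once at diagnosis; a maintenance-cost stream would
  shift cost totals but none of the tested identities.
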