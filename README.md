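# echotrial

Computational machinery for designing a provider-cluster-randomized trial
of automated echocardiogram-based notifications in severe aortic stenosis
(AS) and moderate-to-severe or severe mitral regurgitation (MR).

Many patients whose echocardiograms already document severe valve disease
never reach a valve intervention or a multidisciplinary heart team (MHT)
evaluation. A pragmatic remedy is to screen finalized echo reports
automatically and alert the responsible provider; evaluating it requires a
cluster-randomized trial (providers, not patients, are randomized) with a
hierarchical composite endpoint over a 90-day window. This package
implements, end to end, what the design stage of such a trial needs:

* **Eligibility screening** — a deterministic rule engine over echo
  measurements (AVA, dimensionless index, gradients, jet velocity,
  qualitative MR grade) with the three-tier AS logic (including the
  discordant "POSSIBLE, needs human review" tier), the qualitative MR
  rule, AS-before-MR precedence, and target-valve-specific exclusions.
* **Assignment & randomization** — the inpatient/outpatient recipient
  hierarchy, stratified 1:1 tranche-1 randomization within echo-volume
  tertiles nested in site, and permuted-block tranche-2 allocation with
  immutable arms.
* **Synthetic trials** — exponential times to valve intervention and MHT
  visit joined by a Gumbel–Hougaard copula, calibrated so the 90-day
  incidences are exactly 5%/10% in control and +5 absolute points under
  notification, in 500 provider clusters; plus the repeat-echo censoring
  rule.
* **Stratified win ratio** — all cross-arm pairs compared in hierarchy
  (valve intervention first, then MHT visit) under shared-follow-up
  censoring; closed-form large-sample inference on the log win ratio via
  Hajek projections of the pairwise U-statistics, and a provider-cluster
  bootstrap.
* **Power simulation** — Monte-Carlo power and type-I error of the planned
  design (1246 patients / 500 clusters), with sensitivity sweeps over the
  copula dependence θ (Kendall's τ = 1 − 1/θ).

The win ratio for the composite is

  WR = (# pairs the notified patient wins) / (# pairs the control patient wins),

where a notification-arm patient wins a pair by having the valve
intervention first within the pair's shared follow-up or, if the valve
level is undecided, the MHT visit first; inference uses se(log WR) from
the pairwise U-statistic projections.

## Worked example

Simulate the planned trial once and analyze it:

```r
library(echotrial)

design <- trial_design(seed = 20260903)   # all defaults = planning assumptions
trial  <- generate_trial(design)
win_ratio_stratified(trial)
#> Stratified win ratio (closed_form, pooled_counts)
#>   stratum 1: n = 623 vs 623, wins 63060, losses 36066, ties 289003
#>   win ratio 1.7485  (95% CI 1.2812-2.3862)  p = 0.0004286
```

Of the 623 × 623 = 388,129 cross-arm pairs, 63,060 are wins for the
notification arm and 36,066 are losses (the remaining ~74% are ties —
typical when both 90-day event rates are low), giving a win ratio of 1.75:
notified patients' composite outcomes are preferred about 1.75 times as
often as controls'. The p-value tests WR = 1.

Power of the planned design, sweeping the copula dependence
(`analysis/05_power.R`, 1000 replicates each):

```text
theta = 1.0  (tau = 0.00)  power = 99.0% +- 0.3
theta = 1.5  (tau = 0.33)  power = 95.4% +- 0.7
theta = 2.0  (tau = 0.50)  power = 93.8% +- 0.8
theta = 3.0  (tau = 0.67)  power = 87.1% +- 1.1
```

Power declines as the two endpoint components become more dependent, and
the sweep is reported as a sensitivity table rather than a single number;
type-I error under zero effect is within Monte-Carlo error of the nominal
5% (0.041 ± 0.006 in the same run).

## Repository layout

The repository is organised as an analysis workflow: all computation lives
in the package (`R/`, `src/`), and the numbered drivers under `analysis/`
narrate one pass through it —

1. `01_screen_cohort.R` — screen a synthetic echo cohort, cross-checked
   against an independent re-encoding of the rule tables;
2. `02_randomize_providers.R` — two-tranche provider randomization on a
   synthetic roster;
3. `03_simulate_trial.R` — one planned-design trial, with calibration and
   repeat-echo censoring;
4. `04_win_ratio.R` — closed-form and cluster-bootstrap analysis of that
   trial;
5. `05_power.R` — the power sensitivity sweep and type-I error.

Each writes its tables to `results/`.

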