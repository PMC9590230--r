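---
title: "Decomposing HCW time and costing task-shifting in PrEP care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing HCW time and costing task-shifting in PrEP care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepshift)
```

## The problem

Oral HIV pre-exposure prophylaxis (PrEP) is largely delivered through
nurse-led primary care in high-burden settings, where skilled health-care
workers (HCWs) are scarce. Planning a PrEP scale-up therefore needs three
quantities: how much HCW time each PrEP activity takes, what that time costs
the health system at different cadres' salaries, and what would change if
activities were shifted from nurses to less expensive cadres — at the price
of interrupting the visit workflow when several HCWs share one client.

`prepshift` implements that analysis chain over time-and-motion records: one
record per HCW–client interaction with start/end clock times (minute
resolution), the PrEP activities performed, and the minutes of the
interaction spent on non-PrEP care.

## From records to visit sequences

Recorded interactions are processed in three steps.

* **PrEP minutes.** Each interaction contributes
  `(end - start) - nonprep_minutes`.
* **Consolidation.** Interactions for the same client, visit date and
  activity are merged into one episode carrying their summed PrEP time. An
  interaction covering $k$ activities splits its minutes evenly, $1/k$ each;
  this convention only affects episode-level reporting — the visit total,
  which is what the regression uses, is unchanged. The recording form's
  side-effect-treatment tick is mapped to follow-up counselling, since no
  separate time coefficient is estimated for it.
* **Visit building.** A client's earliest recorded visit is their first
  contact with PrEP and is classified an initiation visit irrespective of
  whether PrEP was actually initiated; later visits are follow-up visits. A
  visit's workflow counts as *interrupted* when more than one HCW saw the
  client, or one HCW did so in non-contiguous interactions. Because clock
  times are recorded at whole minutes, any positive gap (at least 1 minute)
  between same-HCW interactions counts; no threshold beyond that is imposed.

Descriptive summaries (count, mean, range, median, IQR per activity
signature) use type-7 quantiles (linear interpolation between order
statistics), fixed so that summary tests can be exact.

## The time decomposition

For visit $i$ with activity set $A_i$, total PrEP minutes $y_i$ are modelled
by ordinary least squares as

$$ y_i = \beta_0 + \sum_{a} \beta_a \, \mathbb{1}[a \in A_i]
   + \gamma_c \, c_i + \gamma_I \, I_i + \varepsilon_i $$

where $\beta_0$ is the *fixed time cost* — per-visit time not attributable
to any activity (finding files, administration) — $\beta_a$ the marginal
minutes of activity $a$, $c_i$ the number of recorded activity entries,
$I_i$ the interruption indicator, and $\varepsilon_i$ Gaussian noise.
*Model 1* keeps only the activity indicators and the constant; *Model 2*
adds $\gamma_c$ and $\gamma_I$. Extended specifications add months of
clinic PrEP experience, a promotion-package flag, nurse involvement and
clinic fixed effects (reference clinic: lexicographically first id).

One identification detail deserves emphasis. If $c_i$ counted the
*distinct* activities of a visit it would equal the row sum of the activity
indicators, and the Model 2 design would be rank deficient for any data set
whatsoever. The count therefore refers to activity *entries as recorded*,
before consolidation: when the same activity is recorded in two interactions
(one HCW interrupting it, or two HCWs joining it), it contributes two
entries. Entry counts exceed distinct counts exactly for those
duplicated-activity visits, which is what identifies $\gamma_c$ next to the
indicators. `build_visits()` carries both columns (`n_activities`,
`n_activity_entries`); predictions use the distinct count, matching how the
coefficients are combined in all downstream arithmetic.

Fits use classical homoskedastic covariance $\hat\sigma^2 (X'X)^{-1}$ with
$t_{n-k}$ 95% intervals — nothing in the source analysis suggests robust
errors were used, and the classical choice makes the interval arithmetic
reproducible; an HC1 sandwich covariance is available behind
`robust = TRUE`. AIC and BIC use the full Gaussian log-likelihood including
the $2\pi$ constant (and count the variance as a parameter), so absolute
values are comparable across software; model selection is by smallest BIC
and is invariant to that constant. Rank-deficient designs and $n \le k$ are
rejected with the offending columns named rather than silently dropped.

Visit predictions are linear combinations: for Model 1 an initiation visit
is $\beta_0 + \sum_{a \in \text{init}} \beta_a$; for Model 2 the convention
is all activities of the visit class plus $\gamma_c \cdot |A|$, with
$\gamma_I$ added for the interrupted variant. The CI uses
$\mathrm{Var}(c'\hat\beta) = c' \hat\Sigma c$ with the same $t$ quantile.

### Fits from published estimates

`fit_from_estimates()` (and the wrapper `eswatini_reference_fit()`)
reconstructs a fit object from printed coefficients and CI bounds. The
implied covariance is diagonal (`se = CI width / 2t`), because coefficient
correlations are not published. Point predictions and all point-cost
arithmetic are exact; *propagated* CI widths from such fits are
approximations and are treated as such — tests assert point arithmetic
against published values, never propagated widths.

## Costing and uncertainty intervals

Per-minute wages divide annual salary by 220 workdays × 8 hours × 60
minutes, optionally converting SZL to USD at the 2018 annual rate of
13.234. Each cadre carries a wage triple (low, mid, high salary level); the
mid wage is the cadre's 2018 average and prices all point estimates, while
the extremes only drive uncertainty intervals (UIs):

* cost point = time point × mid wage;
* UI upper = CI upper × high wage; UI lower = CI lower × low wage, floored
  at zero when the CI bound is negative.

UIs of sums add componentwise; UIs of differences take the extreme values
attainable within the operands' bounds (`a.low − b.high`, `a.high − b.low`)
and are *not* floored — savings may be negative. Costs are computed at full
precision; the printing convention (2 decimals at or above \$0.10, 2
significant figures below) is applied only at presentation via
`format_cost()`/`round_cost()`.

## Task-shifting scenarios

A scenario assigns each activity to a cadre. The built-in catalogue holds
the nurse base case and five alternatives: everything shifted up to a
nursing sister (1); counselling and risk assessment shared with an HTS
counselor, blood testing with a phlebotomist (2) or the HTS counselor (3);
follow-up counselling additionally moved to a nurse assistant (4); and
counselling/risk assessment moved further down to a peer supporter (5).
Scenarios sharing a visit's activities across two or more cadres are
derived *interrupted* (overridable, e.g. to model non-staffing
interruptions).

Activity time is valued at the assigned cadre's mid wage. Non-activity time
— $\beta_0 + \gamma_c |A| + \gamma_I I$ — belongs to no single cadre under
task sharing, so it is valued at both the lowest and the highest mid wage
among the involved cadres, making the per-visit cost a *range* (degenerate
for single-cadre scenarios). The $\gamma_c$ adjustment is bundled with this
overhead rather than with individual activities because it is a property of
the sequence, not of any activity. UI bounds assemble per component:
activity CIs at the assigned cadre's wage extremes, the overhead CI at the
involved cadres' extremes, lower bounds floored at zero, then summed.

Savings against the base case are interval differences, with the point
range crossed (base low − scenario high, base high − scenario low). Freed
nurse time is reported as a range over attribution conventions: writing
$S$ for the shifted activities' time including their share of the count
adjustment ($\sum_{a \in S}\beta_a + \gamma_c\,n_S$), the lower end charges
the interruption penalty that task sharing induces to the nurse
($S - \gamma_I$), and the upper end moves the fixed time cost off the nurse
as well with no penalty charged ($S + \beta_0$). With the published
process-model estimates this spans 3.7–16.0 minutes for an initiation visit
and 2.3–14.6 for a follow-up visit with both activities shifted, matching
the sign pattern of reported results (the negative lower ends arise for
scenarios that shift only blood testing). CIs come from the corresponding
linear combinations.

## The synthetic generator

Since the raw records cannot be bundled, `generate_records()` produces
seeded data sets with the exact statistical structure the analysis assumes,
together with a ground-truth ledger. Defaults are the study conditions:

* 250 visits (initiation fraction 130/213) across 6 clinics;
* activity signatures drawn from the observed common sequences with their
  observed frequencies;
* interruption probability 0.56;
* generating coefficients equal to the published Model-2-shaped estimates
  ($\beta_0 = 8.9$, activity times 4.3/3.3/3.8/11/4.7/4.0, $\gamma_c =
  -1.5$, $\gamma_I = 3.4$); experience and clinic offsets default to zero
  since those terms belong to extended specifications;
* Gaussian noise with sd 5 minutes on visit totals, resampled below 1
  minute and rounded to whole minutes (clock times have minute resolution);
* months of experience uniform on 2–18, matching the exclusion of the
  earliest project phase.

Interrupted visits are realised as two interactions — by two HCWs, or by
one HCW with a positive gap — and uninterrupted visits as one contiguous
interaction, so interruption flags survive the pipeline exactly
(`roundtrip_check()` asserts this, along with exact minute conservation).
Single-activity interrupted visits record the activity in both
interactions; with probability 0.15 a longer interrupted sequence also
splits one activity across the break. These duplicated entries are the
realistic feature that identifies $\gamma_c$ (see above).

What the generator does *not* emulate: heteroskedastic or skewed durations,
HCW-level and client-level heterogeneity, recording bias from self-timed
forms, and seasonal staffing patterns. Passing tests therefore demonstrate
the correctness of the estimator and the arithmetic under the assumed error
model, not robustness of the published estimates to violations of it.

## Numerical and design choices

* Quartiles: type 7, fixed for exact test oracles.
* Degenerate inputs: empty activity sets, negative non-PrEP time, non-PrEP
  time exceeding the interaction, and end-before-start are validation
  errors naming the rows; all-zero activity columns (activity never
  observed) are dropped from designs; genuine collinearity is an error, not
  a silent drop.
* Ties in interruption detection: interactions sorted by start then end;
  back-to-back interactions (end equals next start) are contiguous.
* Problem sizes in the test suite: oracle comparisons on 50 random
  instances; coverage on 500 replicates of 300 visits; bias comparison at
  200 vs 2000 visits over 5 seeds — sizes at which each check is
  informative while the whole suite stays quick to run.
* All randomness flows from explicit integer seeds; repeated pipeline runs
  are byte-identical.

## Worked example

```{r example, eval = FALSE}
sim <- generate_records(generator_config(), seed = 20180101)
visits <- build_visits(sim$records)
fit2 <- fit_decomposition(visits, model_spec("2"))
compare_models(fit_decomposition(visits, model_spec("1")), fit2,
               names = c("activities_only", "with_process_terms"))
scenario_table(fit2, eswatini_salaries())
```

The `analysis/` scripts run this sequence end to end (simulate, summarise,
decompose, cost, scenarios) and write their tables under `results/`.

## Limitations

The uncertainty intervals are interval arithmetic, not a joint probability
statement: they ignore coefficient correlations when built from published
estimates and treat salary extremes as bounds rather than distributions.
Scenario costs inherit the published convention of leaving overhead time
unassigned under task sharing, so multi-cadre scenarios yield ranges whose
width is a modelling convention, not sampling uncertainty. No waiting-time,
queueing or quality-of-care effects of task shifting are modelled.
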