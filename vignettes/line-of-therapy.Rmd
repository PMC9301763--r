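---
title: "Constructing treatment lines from dispensing claims: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing treatment lines from dispensing claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxlines)
```

## What the pipeline estimates, and from what

Subsidised-dispensing claims record *supply events*, not treatment
decisions: patient id, year of birth, sex, region, dispensing date,
molecule, tablet strength, prescriber type. `rxlines` reconstructs the
clinical objects a drug-utilisation analysis needs — new users, numbered
treatment lines, persistence times, treatment-free intervals — from those
events alone, and quantifies them with standard right-censored survival
methods.

Antidepressants are analysed by pharmacological class rather than by
molecule: class is the unit at which switching, combination and
augmentation are clinically meaningful, and molecule-level churn within a
class (e.g. sertraline to escitalopram) is logged but never treated as a
new treatment. The formulary shipped with the package is an illustrative
catalogue covering all the marketed antidepressant classes plus a small
antipsychotic and mood-stabiliser list; real analyses should supply their
own. Mood stabilisers (lithium, valproate, carbamazepine, oxcarbazepine,
lamotrigine) are loadable and classifiable but excluded from every
antidepressant rule: they identify different treatment intent, not
antidepressant exposure.

## Cohort: the new-user design

The index is the **first antidepressant dispensing inside the accrual
window**. Inclusion then requires:

* a washout — no antidepressant *or* antipsychotic dispensing in the 12
  months before index. The look-back is measured in calendar months
  (month-length-aware date arithmetic), not 365 days, because clean
  periods in this literature are phrased in months. Two readings are
  supported behind `washout_mode`: a per-patient *rolling* 12-month
  look-back (default) and a *fixed window* shared by all patients (the
  year immediately before accrual opens). They coincide for patients
  indexed in the first accrual year and diverge afterwards; the rolling
  form is stricter for late entrants and is the more common operational
  choice, so it is the default rather than a guess silently baked in.
* no antipsychotic on or before the index date, however long before —
  this removes treatment patterns resembling management of psychosis.
* age at index of at least 16, computed as dispensing year minus year of
  birth. Year precision is deliberate: the data carry year of birth only,
  so "age 16" means the year arithmetic reaches 16, with the boundary
  inclusive.

Patients whose only qualifying dispensing predates the accrual window are
excluded rather than re-indexed, mirroring a fixed study entry design.

## Episodes: the line-of-therapy sweep

Dispensings are swept per patient in time order (date, antidepressants
before antipsychotics on ties, then molecule — a total order, so results
are invariant to file row order). The treatment number increments when:

1. **Restart after discontinuation.** A gap of *more than* 183 days
   (six months) between consecutive antidepressant dispensings — or
   between the last dispensing and the end of data — means therapy
   stopped. Any antidepressant after a confirmed gap starts the next
   line, *even the same class*: resumption after six months off therapy
   is a new treatment decision. A gap of exactly 183 days does not
   qualify.
2. **Class switch.** A class not in the current set appears and the old
   class is *not* dispensed again within the concurrency window after it.
3. **Combination.** A new class appears and the old class *does*
   continue within the window: the new class was added, not substituted.
4. **Augmentation.** An antipsychotic is dispensed within the
   concurrency window of an antidepressant dispensing.

In every case the change date is the date the new prescription was
dispensed. Two different classes dispensed on an episode's start date are
treated as one multi-class episode (flagged), not an instant new line.

### Tunable constants

| Parameter | Default | Units | Why |
|---|---|---|---|
| `discontinuation_gap_days` | 183 | days | six months of no supply; strict inequality |
| `concurrency_window_days` | 30 | days | one nominal pack; claims carry no days-supplied field, so "concurrent prescriptions" must be operationalised from dates alone. This is the single most consequential constant in the pipeline and is deliberately configurable |
| `pack_days` | 30 | days | nominal supply of one dispensing |
| `disc_end` | `last_plus_pack` | — | a discontinued episode ends one pack after its last dispensing. The alternative (`last_dispensing`) is retained for sensitivity analysis; it pushes short-persistence classes to sub-month medians because a single dispensing then contributes zero duration |
| `months_per_unit` | 30.44 | days/month | calendar-average month, used for all duration reporting |

Dose escalation is inferred from a step-up in dispensed tablet strength
*within the same molecule*, against the immediately previous dispensing
of that molecule (strengths are not comparable across molecules, and an
episode-initial baseline would misread titration patterns). Only the
first increase per patient is kept. This is a proxy — a patient may
take more tablets of a lower strength — so dose-change outputs warrant
cautious interpretation.

## Survival machinery

Persistence (time from line start to line change, censored at the end of
data) is analysed with a product-limit estimator written directly from
its definition: $\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)$ with
Greenwood variance $\hat S(t)^2 \sum_{t_i \le t} d_i / (n_i(n_i - d_i))$.
Conventions, chosen once and tested:

* ties between events and censorings: censored observations remain at
  risk at their own time (events first);
* the median is the smallest observed event time with
  $\hat S(t) \le 0.5$, reported as "not reached" when the curve never
  gets there;
* the two-group log-rank test uses the hypergeometric variance at pooled
  event times and a $\chi^2_1$ reference; times with a single subject at
  risk contribute no variance;
* the risk ratio at horizon $t$ is
  $(1-\hat S_A(t))/(1-\hat S_B(t))$ — the direction is chosen so a class
  with *worse* persistence gets RR > 1 — with a log-Wald interval whose
  variance comes from the delta method applied to the two Greenwood
  variances. When a curve has fallen to exactly zero at the horizon its
  Greenwood variance is degenerate; the in-sample risk of 1 then
  contributes no variance term. A survival-ratio definition
  ($\hat S_A/\hat S_B$) is available behind `type = "survival"` because
  published horizon RRs are not always derivable from one definition;
  p-values are reported unadjusted.

Treatment-free episodes run from the discontinuation date (as defined by
`disc_end`) to the next antidepressant dispensing, censored at end of
data. The clock could alternatively start at gap confirmation six months
later; the discontinuation date is the default because it is the natural
zero of "time off therapy", and the whole interval is shifted by a
constant either way. The headline summary is the *conditional* median
time to return among episodes that returned, alongside the unconditional
KM median and the cumulative return proportion $1-\hat S(h)$, because
"how long until returners return" and "how many return" answer different
questions.

Reporting tables use censoring-aware cumulative incidences
($1-\hat S(h)$ at 6/12/24 months) rather than naive fractions, because
patients enter throughout accrual and late entrants cannot contribute a
full horizon. Age bins (16–25, 26–45, 46–65, >65, inclusive upper
bounds) are a documented convention anchored at "up to 25" and "over 65";
age groups are non-exclusive by design — a patient followed across a
boundary appears in both groups, classified within each group by their
first antidepressant dispensing while in it.

## The synthetic-data generator

The generator exists so that the episode logic can be validated *exactly*
rather than approximately. Per patient it draws demographics, an index
date, and a sequence of episodes; each single-class episode's ending is a
competition between an exponential discontinuation time (class-specific
hazard, parameterised as `log(2)/median`) and optional planted
switch / combination / augmentation events at uniform 1–12 month times.
Refills follow a 30-day pack cadence with at most ±5 days of jitter.
Defaults emulate an Australian antidepressant cohort: accrual July 2013 –
June 2019 over a one-year clean period, first-line class shares of 52%
SSRI / 25% TCA / 13% SNRI with the remainder spread over the minor
classes, class median persistence from 5.8 months (SSRI) down to 0.9
months (TCA), 56% female, three quarters of prescriptions by GPs, ages
uniform 16–85 with year-of-birth storage only.

Every planted event is constructed to satisfy the detection rules by a
safe margin, and the realized (post-jitter) dates are recorded as ground
truth:

* planted restarts occur at least `pack_days` + 5.2 months after the last
  dispensing, clearing the 183-day gap with margin;
* planted combinations force a dispensing of the old class 14 days after
  the new class appears (inside the 30-day window);
* planted augmentations co-dispense the antipsychotic with an
  antidepressant refill;
* planted dose steps move to the next strength on the molecule's ladder,
  in the first episode only.

This makes the central test property exact: running the cohort and
episode modules on generated records must reproduce the ground-truth
episode numbers, boundaries and end reasons with **zero** mismatches,
across scenarios that isolate each event type and a mixed scenario, over
many seeds. Return behaviour is planted as a 36% return probability with
conditional median 12.8 months (a minimum delay of 5.2 months keeps
restarts rule-conformant; the remainder is exponential).

What the generator does *not* emulate — and hence what passing tests do
not show about real data: dispensing-date seasonality (end-of-year
stockpiling under co-payment safety nets), quantity/repeat variation and
true days-supplied, near-threshold gaps from irregular refilling (the
generator plants only margin-safe gaps; the 183/184-day boundary is
exercised by hand-built fixtures instead), in-hospital supply invisible
to claims, and any dependence of behaviour on unobserved severity. Real
claims will sit *near* the rule thresholds far more often than the
generator does, so sensitivity of real results to `gap` and `window`
should always be checked with the provided configuration switches.

## Numerical and degenerate-input choices

* Dates are integer days internally; months are days / 30.44 everywhere.
* Sample sizes used by the validation suite were chosen to keep the whole
  suite comfortably interactive while leaving Monte-Carlo error far below
  the asserted tolerances: 200 patients × 10 seeds × 5 scenarios for the
  exact-recovery oracle, n = 20 000 for median recovery (KM median SE
  ≈ 0.05 months there), n = 10 000 for distributional checks
  (three-binomial-SE bands, a 95% DKW band of half-width 0.0136, return
  recovery within ±2 points / ±1 month), and 10 000 label permutations
  for log-rank calibration (SE of the rejection rate ≈ 0.002 against an
  acceptance band of 0.04–0.06).
* Empty inputs return empty, well-typed tables (no division by zero in
  share denominators); an all-censored KM input yields a flat curve with
  no event times; a log-rank call with no pooled events or one group is
  an error, and degenerate zero-variance configurations return `NA`
  rather than a fabricated statistic.
* Unknown molecules are a hard error at classification time; silent
  dropping of unclassifiable dispensings would bias every downstream
  count.

## Known limitations

The concurrency window and pack length stand in for the missing
days-supplied field; quantity × strength daily-dose modelling is out of
scope. The dose-increase proxy undercounts true escalation. Episode
attribution after complex multi-class histories (e.g. a switch out of an
augmented combination) follows simple set rules that have no single
authoritative definition in the literature; the configuration switches
exist precisely so such choices can be stress-tested. The generator's
ground truth validates the *rules as specified*, not the clinical
fidelity of the rules themselves.
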