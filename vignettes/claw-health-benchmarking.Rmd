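---
title: "Benchmarking dairy-herd claw health from routine records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking dairy-herd claw health from routine records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clawbench)
```

## The problem

Claw disorders and lameness are among the costliest and most welfare-relevant
health problems of dairy cows. Where professional hoof trimmers document
lesions electronically at every trimming visit, and milk-recording staff score
locomotion at routine performance tests, those records can be turned into
herd-level key performance indicators (KPIs) and a *benchmark*: each farm sees
the population distribution of every KPI alongside its own value, with the
best decile ("best in class") as the reference point.

`clawbench` implements that pipeline end to end: validated ingestion of four
record streams (hoof-trimming lesions, locomotion scorings, herd rosters,
culling records), interobserver-reliability gating of the people producing
the records, per-herd KPI computation, and percentile benchmark tables with a
MY FARM comparison column. Because the original national data sets are not
publicly deposited, the package also ships a seeded synthetic-population
generator that emulates their statistical structure; everything downstream of
ingestion is exercised, and tested, against it.

## KPIs

Three KPI families are computed per herd and year.

**Lameness incidence risk.** Locomotion is scored on the five-point Sprecher
scale (1 = sound, 5 = severely lame). At every scoring date, each cow at or
above a threshold counts as a new case. For threshold $t$ and cow group $G$:

$$\mathrm{IR}_{\mathrm{Lame}}(t, G) \;=\;
  \frac{\text{lame cows in } G \text{ at the scorings of the year}}
       {\text{cows in } G \text{ scored at those dates}}\times 100,$$

averaged over the year's scoring dates. Thresholds $\ge 2$, $\ge 3$ and
$\ge 4$ are reported for three cow groups: all lactating cows, dry cows
(between dry-off and next calving) and cows in their first 100 days in milk.
Cows present but not scored at a date are excluded from that date's
denominator; a group never scored in a herd is flagged, not zero.

**Claw-lesion incidence risks.** Lesions are coded with an ICAR Claw Health
Atlas style vocabulary and grouped into 13 benchmark categories (see
`benchmark_groups()`), plus an aggregate of all *always-painful* ("alarm")
lesions: ulcers and toe necrosis, white line abscesses (white line disease of
severity 2–3), deep-sepsis swellings of coronet/bulb, interdigital phlegmon,
penetrating infected horn fissures, acute (M2) digital dermatitis and all
DD-associated claw horn lesions. For group $g$:

$$\mathrm{IR}_{\mathrm{ClawL}}(g) \;=\;
  \frac{\text{new cases of } g \text{ within the year}}
       {\text{mean cow number}}\times 100,
\qquad
\text{mean cow number} = \frac{\sum_{\text{cows}} \text{days present}}
                              {\text{days in the year}}.$$

Because distinct cows ever present exceed the mean cow number in herds with
turnover, individual herd values can exceed 100%; that is a property of the
estimator, not an error. Digital dermatitis is benchmarked only in
*endemically infected* herds: herds with more than two distinct cows showing
any M1–M4.1 record in the year.

**Annual culling risk due to claw and limb disorders.** Among the ten coded
culling reasons, the share of culls attributed to claw & limb disorders, in
percent of all culls of the herd-year. Herds with no culls report 0 (flagged):
half of typical farms cull no cow for claw reasons in a year, and the
population median of this KPI is genuinely 0.

### Counting mode

Routine data support two readings of a "new case": once per cow, group and
year (*cow-year*), or once per affected cow and visit date (*cow-visit*,
since visits are 4–6 months apart). Both are implemented and labelled
(`mode=` in `ir_clawl()` and the pipeline); *cow-year* — the share of cattle
with at least one documented lesion — is the default. Cow-visit counts are
never smaller, which the test suite asserts.

### Severity recoding

Trimmers score severity 1–3. Mild (severity-1) records of four lesions that
are usually non-painful at that grade — sole haemorrhage, double sole, white
line disease, heel horn erosion — are dropped before KPI computation.
White line disease of severity 2–3 is regrouped as white line abscess (WLA).
Farmer-app records carry no severity; they are assigned severity 2 by
convention (the app is used to record noteworthy lesions), configurable via
`farmer_severity`.

## Observer reliability gating

Recorders qualify through a rating exam against reference material. Agreement
is measured with the weighted Cohen's kappa

$$\kappa_w = 1 - \frac{\sum_{ij} w_{ij} O_{ij}}{\sum_{ij} w_{ij} E_{ij}},
\qquad w_{ij} = \left(\frac{|i-j|}{k-1}\right)^d,$$

with $d = 1$ (linear weights, default) or $d = 2$ (quadratic). The weight
scheme behind published kappa values from standard statistical software is
often unstated; linear is this package's documented default and results are
labelled with the scheme used, so externally reported kappas should not be
expected to reproduce exactly under either choice. Observers pass at
$\kappa \ge 0.61$ ("substantial" on the Landis–Koch bands, which are shipped
as labels for reporting only). For locomotion, kappa is also computed after
merging the five scores to three categories (1+2, 3, 4+5), the merge that in
practice lifts agreement across the hard-to-separate score pairs. The passed
observer set feeds the validation module's trained-recorder registry.

Degenerate tables (both raters constant and equal) return $\kappa = 1$ with a
flag, since there is no disagreement to correct for chance.

## Validation cascade

Record-level rules, in fixed reporting order: `animal-id` (the cow must be on
the herd roster and present at the record date), `date-window` (inside the
study year), `lesion-code` (resolvable against the vocabulary). A record is
dropped when any rule fails, so the accepted set is order-independent; the
rejection ledger stores the first-failing and all failing rules per record.

Herd-level inclusion criteria (all inclusive "at least" thresholds):

* `recorder-share`: ≥ 95% of the herd's records from trained recorders;
* `trim-share`: distinct cows trimmed ≥ 50% of the mean cow number (the
  ratio base is the mean cow number of the farm, so values above 1 are
  possible);
* `lesion-free`: at least one explicit no-lesion (`NL`) documentation,
  evidence that healthy cows are documented too;
* `min-diagnoses`: at least five distinct lesion groups among the records.

Herds with records but no roster are excluded with rule `no-roster` rather
than causing an error. Relaxing any threshold can only grow the included set,
and validating already-validated data changes nothing; both properties are
tested.

## The synthetic population

`simulate_population()` draws, under one seed expanded into per-stream
substreams (so adding a stream never perturbs another):

* **Herds:** truncated-lognormal sizes, mean ≈ 34.8 cows, range 16–163
  (512 herds by default).
* **Cow timelines:** ~380-day calving interval, dry-off 60 days before the
  next calving (chosen as ordinary reproduction figures for these breeds;
  the sources describing the data give none), 25% annual culling with
  replacement heifers entering shortly after each cull.
* **Trimming:** two visits per herd-year (30% of herds get three) at 4–6
  month spacing, 80% of present cows trimmed per visit; lesion-free trimmed
  cows are documented as `NL`.
* **Lesion events:** per herd and group, a cow-level annual incidence
  $p_{hg}$ from a zero-inflated beta prior whose per-group means equal the
  published population means and whose zero mass and shape were chosen once
  so the percentile spread across herds resembles published benchmark tables
  (many all-zero herds for rare lesions, long right tails for common ones).
  A cow present for a fraction $f$ of the year develops the lesion with
  probability $1-(1-p_{hg})^f$, so the cow-year incidence-risk estimator is
  unbiased for $p_{hg}$; events are documented at a trimming visit inside the
  cow's presence window. Mild severity-1 records of the severity-sensitive
  lesions are added as noise at a low rate (they are dropped again during
  recoding). Late-entering cows whose presence covers no visit generate no
  record, leaving a ≈1% downward bias — well inside the Monte-Carlo tolerance
  of the recovery tests.
* **Digital dermatitis:** 55.8% of herds are endemically infected. Within an
  endemic herd the incidence is drawn from a beta on top of a floor of
  $\max(0.2,\ 8/\text{herd size})$: an "endemic" herd in which fewer than a
  handful of cows would ever be affected is a contradiction of the
  herd-level detection rule (more than two affected cows), so the floor makes
  truly endemic herds almost surely detectable at any herd size. Non-endemic
  herds have zero DD incidence.
* **Locomotion:** scoring dates every 35 days in a subset of herds (default
  fraction 99/512, mirroring the typical coverage of lameness scoring
  relative to trimming data); 70% of present lactating and 25% of dry cows
  scored per date, giving ≈ 6.7 scorings per cow-year. A cow's lameness
  propensity is beta-distributed around a beta-distributed herd level, with
  the marginal score distribution fixed at (61.7, 24.2, 8.8, 4.3, 1.0)% for
  scores 1–5; scores above 1 are split by the renormalised upper-tail
  multinomial. Reported per-herd and per-cow scoring intensities in routine
  data are not perfectly consistent with each other, so both knobs
  (`scoring_interval_days`, `p_scored_*`) are exposed rather than resolved.
* **Culling:** the annual cull hits 25% of cows; a herd's claw/limb share
  among culls is zero with probability 0.52, otherwise beta with mean 0.177,
  reproducing a zero median and a population mean claw-culling risk of ≈ 8.5%.
* **Truth tables:** per-herd generating parameters (lesion probabilities,
  lameness propensity, endemic flag, claw-cull share) for parameter-recovery
  testing.

`simulate_raters()` draws observer responses under any row-stochastic
confusion matrix; `adjacent_confusion()` provides a five-point model with
errors confined to adjacent scores and concentrated on the 1/2 and 4/5
boundaries — the structure that makes the 12|3|45 merge genuinely informative.

**What the generator does not emulate:** biologically mechanistic lesion
progression or recurrence, within-lactation autocorrelation of lameness
beyond the per-cow random effect, seasonality, correlations between lesion
groups within a cow, breed/housing/yield covariates, and recorder error in
the record streams themselves (recorder quality enters only through the
rater-exam module). Tests passing on synthetic data therefore demonstrate
the correctness and statistical calibration of the *pipeline*, not the
epidemiology of any real population.

## Numerical choices

* **Percentiles:** linear interpolation between order statistics
  (`stats::quantile` type 7), fixed and documented; published tables rarely
  state their estimator, so all distributional checks are stated relative to
  this choice. Tests verify it against an independent sort-and-interpolate
  oracle.
* **Bands:** six contiguous bands (≤P10, (P10,P25], (P25,P50], (P50,P75],
  (P75,P90], >P90); boundary values go to the better (lower) band, matching
  the inclusive "good ≤ 10th percentile" convention. The conventional
  good/moderate/poor labels are attached secondarily; a value exactly at the
  median sits in band (P25,P50] while still labelled "poor" by the ≥P50 rule,
  and the (P10,P25) interval is deliberately unlabelled.
* **Rounding:** to one decimal only at rendering, never in computation.
* **Leap years:** the mean-cow-number denominator uses the calendar length of
  the study year (366 for 2020), configurable.
* **"More than two animals":** the endemicity phrase is read strictly as
  > 2, i.e. at least three distinct cows; the threshold is exposed as
  `dd_min_cows`.
* **Zero-cull herds:** ACR is 0 (flagged), not undefined, so they enter the
  benchmark distribution — consistent with a population median of 0.
* **Degenerate inputs:** empty record streams validate to empty outputs with
  empty ledgers; a KPI with fewer than two defined herd values produces an
  `empty`-flagged benchmark row; an unknown herd in the report is an error.

## Sizes used by the test suite

The packaged tests run the generator at 500 herds for distribution-level
checks (threshold monotonicity, parameter recovery, endemic-share recovery,
band occupancy) and at 20–60 herds for structural and determinism checks;
the kappa oracle is verified exhaustively on all 262,143 non-empty 3×3
tables with cell counts ≤ 3 and on 1,000 random 5×5 tables. These sizes were
chosen as the smallest at which the Monte-Carlo tolerances are meaningful.

## Known limitations

* The shipped lesion vocabulary is a synthetic reconstruction in the style of
  the ICAR Atlas (the exact Appendix-2 list of DD-associated horn lesions is
  not enumerated in the public sources); codes are stable strings and the
  table is a plain-text data file, so a site can substitute its own.
* Animal-id plausibility is checked as roster membership and presence only;
  national id checksum rules could be added at ingestion.
* MY FARM reports compare a farm against the same study year as the
  benchmark population; rolling windows are out of scope.
* Sub-population benchmarks (by breed, yield, housing) and year-over-year
  trends are not implemented.
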