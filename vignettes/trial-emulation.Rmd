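---
title: "Emulating prn anti-VEGF trial arms from registry data: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating prn anti-VEGF trial arms from registry data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical procedure it
implements, the assumptions behind it, the parameters that matter, and the
design decisions taken where the underlying methodology left choices open.

## The estimation problem

A randomized nAMD trial compares anti-VEGF agents under monthly or
as-needed (*pro re nata*, prn) dosing. A deidentified EHR registry holds
many more treated eyes, observed under routine care. The package builds
*external comparator arms*: registry eyes filtered to the trial's
eligibility rules and prn treatment pattern, then aligned to a monthly
trial arm on the three covariates available in both sources — age,
gender, and baseline visual acuity — by 1:1 caliper matching or by
inverse propensity score weighting (IPSW). The identifying assumptions
are the usual ones for external controls and are *not* testable inside
the package: outcome measurement comparability between settings, and no
unmeasured confounding beyond the three alignment covariates. The
synthetic-data tests establish that the machinery recovers known
quantities when those assumptions hold by construction — nothing more.

## Visual acuity scale

Registry acuities are Snellen chart lines; the analysis scale is
approximated ETDRS letters,

$$\mathrm{letters} = 85 + 50\,\log_{10}(\mathrm{fraction}),$$

rounded *half away from zero* to the nearest letter and clamped to
[0, 100]. Half-to-even rounding (R's default) would silently shift chart
lines, so the package rounds explicitly. 20/20 gives 85; 20/200 gives 35.
The "best documented" acuity on a day is the maximum converted score over
that day's measurements. Baseline acuity is the index-day value, else the
nearest measurement up to 14 days *prior* (pre-treatment by
construction; the source methodology names no window). The one-year
endpoint is the measurement nearest day 365 within ±56 days, later date
on ties (an 8-week window, the widest that cannot reach the 6-month or
18-month visit of a monthly schedule).

## Attrition engine

Eligibility is evaluated per candidate eye (any eye with an in-window
study-drug injection) in a fixed row order; the attrition table reports
cumulative patient/eye counts per row. Because every criterion is a pure
predicate on the eye's records, the final cohort is the set intersection
of all criteria — row order shapes per-row drops, never the survivors
(this is tested). Interval conventions, stated nowhere in the source
material, are fixed and documented here:

* lookbacks are half-open: `(index - N, index]`;
* the treatment-naive lookback excludes the index injection:
  `[index - 365, index)`;
* follow-up is closed: `[index, index + 365]`;
* "within 2 months" (intraocular surgery washout) is 60 days pre-index;
* "history of" exclusions (retinal detachment/macular hole, vitrectomy,
  prior PDT/anti-VEGF) apply to any pre-index date; dated comorbidity
  exclusions use the 365-day diagnosis lookback; CNV of another cause
  applies to either eye.

The visit-cadence rule ("every 4–6 weeks for a year") is enforced as:
first retina visit within 42 days of index, all consecutive gaps ≤ 42
days, last visit on/after day 323. No minimum gap is imposed by default
(real visits can be closer than 4 weeks); `cadence_min_gap_days = 28`
gives the strict reading. Acuity eligibility (20/25–20/320) is tested on
the baseline measurement's *Snellen fraction*, not on converted letters,
to avoid rounding artifacts at the bounds. One study eye per patient
(earlier index date, right eye on same-day ties) is enforced at the
fellow-eye-exclusion row, where the published table's patient and eye
counts converge. The endophthalmitis outcome flag uses a 42-day
post-injection attribution window (none is stated at the source).

## Matching

The stated rules — gender exact, age within 5 years with ages ≥ 90 as a
single top-coded category, acuity within 5 letters — define a bipartite
compatibility graph, and "exact matching" with calipers, 1:1 without
replacement, is maximum-cardinality matching on that graph. The package
solves it by successive shortest augmenting paths with dual potentials
(compiled): each trial participant, in id order, is matched via a
minimum-reduced-cost augmenting path or left permanently unmatched (by
Berge's lemma no later augmentation can rescue it, so cardinality is
maximal — verified against an exhaustive bitmask-DP oracle on 1,000
random instances). The edge cost ranks ties: letter difference dominates,
then age difference, then an epsilon on eye id order. Among exactly tied
optima the deterministic processing order fixes the result; full
lexicographic optimality of the id tie-break is not claimed. A greedy
closest-candidate matcher is retained as a sensitivity baseline; its size
never exceeds the solver's (tested), and the crossing instance in the
test suite shows it can be strictly smaller. Whether the original
analysis maximized matches or matched greedily is not stated; the solver
is the default because the match *rate* is the headline quantity of this
arm.

## Weighting

A logistic regression predicts trial membership (monthly trial arm = 1,
registry prn arm = 0). The registry eye's weight is the ATT odds
$p/(1-p)$, rescaled so weights sum to the registry arm size — weighted
subgroup tallies are then fractional counts directly comparable to the
cohort N. This reweights the registry arm toward the trial population,
which matches the emulation aim; the source description states neither
the weight formula nor the normalization, so this reading is flagged as
an interpretation. Fitted probabilities above 0.999 are capped and the
cap count reported, never silent. Non-convergence or quasi-complete
separation refuses to produce weights.

The fit itself is an in-package iteratively reweighted least squares
implementation (coefficient max-change ≤ 1e-10, ≤ 100 iterations) so that
the estimator under test stays independent of the general GLM machinery,
which serves as the oracle in the test suite (log-likelihood agreement to
1e-8 on 50 fixtures).

**Covariate coding.** Age in years, female indicator, baseline letters —
plus an indicator for the top-coded age category (≥ 90). The indicator is
a deliberate deviation from a purely linear age term: deidentified
registries report every age ≥ 90 as one value, and when a shifted
registry places ~20% of its mass on that point against ~5–7% in the
trial, a linear term provably cannot balance the spike (the score
equations hold exactly, yet the age SMD stayed above 0.1 in one of
twenty test seeds). Treating the top-code as its own category — exactly
as the matching rules already do — restores balance; the acceptance
suite verifies post-weighting |SMD| < 0.1 for all three covariates
across 20 seeds at the published arm sizes (286 trial participants
versus 771 eligible eyes). Constant or collinear columns are dropped via
pivoted QR before fitting, so single-gender cohorts fit on the remaining
covariates.

Balance is reported as standardized mean differences
$(\bar x_A - \bar x_B)/\sqrt{(s_A^2+s_B^2)/2}$ before and after
weighting, with Kish's effective sample size $(\sum w)^2/\sum w^2$.
Weighted SDs use the frequency-weight convention (denominator
$\sum w - 1$), so unit weights reproduce ordinary sample statistics
bit-for-bit (tested).

## Outcomes and comparisons

Acuity-change summaries are computed over eyes with both baseline and
one-year measurements (`n_va`), reported separately from the arm size, so
denominator discrepancies are explicit rather than silent; eyes lacking
the endpoint still contribute to injection, cost, and safety outcomes.
Drug cost is the arm's *full-precision* mean injection count times the
unit cost ($2000 ranibizumab, $50 bevacizumab per dose); rounding to one
decimal happens only in the text report layer. (Published tables that
multiply a *rounded* mean by unit cost can therefore disagree with their
own injection row by design; this package never does.) Responder flags
use inclusive bounds: gain ⇔ change ≥ +15, loss ⇔ change ≤ −15.

Two-sample comparisons default to the pooled-variance unpaired t-test:
recomputing the published exact-matching-vs-IPSW p-values from their
printed summary triples yields 0.43 under both variants but 0.79 only
under pooling (Welch gives 0.78), so pooling best reproduces the source
analysis; Welch is available via `method = "welch"`. Weighted tests use
the weighted mean/SD with the effective sample size as the degrees-of-
freedom input — a documented approximation. Note the exact-matching arm
is a subset of the weighting arm's source cohort, yet the comparison is
run unpaired, as published; the p-value for that contrast should be read
descriptively.

## The synthetic world

`sim_config()` defaults state the emulated world once:

| parameter | default | why |
|---|---|---|
| index window | 2015-10-01..2019-12-31 | the study's enrollment window |
| age at index | N(81, 8), truncated [50, 97], top-coded 90 | registry arm means ~81; deidentification top-code |
| female fraction | 0.63 | between the published arms' 61.8–68.9% |
| baseline letters | N(60, 13) truncated to chart range 20/25–20/320 | published means ~60.1–60.3, SD 12.5–14.3 |
| arm split | 64/36 bevacizumab/ranibizumab | the 771:427 eligible-eye ratio |
| 1-year change | N(2.1, 16) / N(2.8, 15) letters per arm | the weighted prn arm results |
| injections | ~N(7.7, 3.6) / N(9.0, 3.4), capped by visits | published prn means; the cap keeps ≥1 non-injection visit |
| visit gaps | uniform 28–42 days | the 4–6-week cadence |
| violation mix | 2% of eyes per criterion | exercises every attrition row |

Truncation is by rejection (renormalized density), not clamping, so no
probability mass piles up at the bounds; the observed baseline mean is
therefore the *truncated*-normal mean (~1.6 letters below the latent 60),
and tests check against that closed form. All randomness flows from one
seed through named substreams, so adding a field does not reshuffle the
others, and runs are byte-identical across repeats.

Two generator choices deserve emphasis:

* **Measurement chart.** Follow-up acuities are measured on a chart
  extended above 20/20 (20/16, 20/12.5, 20/10 — 90/95/100 letters), as
  real Snellen charts are. With a chart topping out at 85 letters, gains
  in eyes starting near 20/25 would be ceiling-censored, biasing the mean
  one-year change downward by more than a letter and making mean-recovery
  tests unattainable in principle. Eligibility bounds still use
  20/25–20/320. This was decided from the censoring analysis, not tuned
  to any test.
* **Violation seeding.** Each seeded eye is a minimal mutation of an
  eligible-by-construction eye so that it fails exactly its assigned
  criterion, with one documented exception: a pre-index injection inside
  the naive lookback is necessarily also "previous anti-VEGF treatment",
  so the ground truth marks both flags failed; the prior-treatment
  violation itself is seeded via a PDT procedure older than the naive
  window so it trips only its own row. The engine's per-criterion
  verdicts are asserted equal to the ground-truth flags for *every*
  generated eye.

What the generator does **not** emulate: real ICD-10/CPT coding (an
enumerated category vocabulary stands in), measurement error structure of
routine Snellen testing, informative missingness of follow-up, fellow-eye
correlation, imaging findings, and calendar-time treatment drift. A green
test therefore establishes correctness of the machinery under the stated
generative model — it cannot validate the external-control assumptions on
real data.

## Numerical choices

* IRLS convergence 1e-10 on the coefficient max-change; weight floor
  1e-12 on $p(1-p)$; separation flagged when any fitted probability
  reaches the 1e-10 boundary.
* Matching cost epsilon $1/((n_p+1)(n_e+1))$ — summed over any matching
  it stays below 1, so it can never disturb the letter/age keys.
* Costs are computed in cents and rounded once.
* Match rates round half away from zero to integer percent.
* The enrollment window is passed explicitly to the attrition engine;
  deriving it from the observed injection range would let a pre-window
  injection extend the window and silently shift an eye's index date.

## Known limitations

* The registry arm's injection means realize about one injection below
  the configured prn parameter, because the visit-schedule cap binds in
  the upper tail; the parameter is a target intensity, not the realized
  mean.
* Weighted degrees of freedom via effective sample size is an
  approximation without a variance-estimation theory behind it; bootstrap
  variance is left as future work.
* The maximum-cardinality tie-break guarantees minimum total letter and
  age differences through its cost, but the id-order tie-break among
  exactly tied optima is procedural, not proven lexicographically
  minimal.
* No multiplicity adjustment, survival analysis, nonparametric tests,
  k:1 or with-replacement matching, or stabilized/doubly-robust weights.
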