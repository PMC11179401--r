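# trialemulate

Emulating clinical-trial treatment arms from routinely collected
ophthalmology registry data.

## The problem

Randomized trials in neovascular age-related macular degeneration (nAMD)
compare anti-VEGF dosing regimens — e.g. monthly versus *pro re nata*
(prn, as-needed) bevacizumab or ranibizumab — under idealized conditions.
Electronic-health-record registries hold orders of magnitude more treated
eyes, but real-world patients differ systematically from trial
participants. `trialemulate` implements, end to end, the target-trial
emulation workflow used to build *external comparator arms* from such a
registry and align them with monthly trial arms:

1. **Eligibility attrition.** A rule engine applies the trial's
   non-imaging inclusion/exclusion criteria and the prn
   treatment-pattern requirements (treatment-naive lookback, nAMD
   documentation, age ≥ 50, baseline Snellen acuity in 20/25–20/320, a
   retina-specialist visit every 4–6 weeks for a year, single-agent
   bevacizumab-only or ranibizumab-only therapy, eleven exclusion rules,
   ≥ 1 non-injection visit) cumulatively, in a fixed order, and reports a
   cohort-attrition table.
2. **Alignment.** Two alternatives:
   * 1:1 *caliper matching* — gender exact, age within ±5 years (ages
     ≥ 90 form one top-coded category), baseline acuity within ±5
     letters — solved as maximum-cardinality bipartite matching
     (augmenting paths, compiled), with a greedy matcher as a
     sensitivity baseline;
   * *inverse propensity score weighting* (IPSW) — a self-contained
     maximum-likelihood logistic model of trial membership on age,
     gender, and baseline acuity, converted to ATT odds weights
     `p/(1-p)` that reweight the registry arm to the trial population,
     normalized to the arm size, with standardized-mean-difference
     balance diagnostics.
3. **Outcomes and comparison.** One-year change in approximated ETDRS
   letters (`85 + 50·log10(Snellen fraction)`, rounded), ±15-letter
   responder proportions, injection counts, annual drug cost (unit cost ×
   mean injections), endophthalmitis incidence, and unpaired two-sample
   t-tests (pooled or Welch) computed from raw samples or from printed
   summary statistics.

Because the real registry is proprietary, the package ships a
**synthetic-data module**: a generator for longitudinal event tables
(patients, encounters, injections, diagnoses, procedures, acuities, IOP)
plus trial rosters, with configurable per-criterion violation fractions
and a ground-truth manifest, so every stage is testable without any
download.

## Worked example

```r
library(trialemulate)

cfg <- pipeline_config(sim = sim_config(n_patients = 600, seed = 7), seed = 7)
res <- run_pipeline(cfg, quiet = TRUE)
print(render_attrition_text(res$attrition))
```

The attrition table drops ~2% of eyes per criterion (the generator's
default violation mix) from 610 candidate eyes down to 377 eligible prn
eyes:

```
Selection criteria                                              Patients      Eyes  % Eyes
Injection of bevacizumab or ranibizumab in study window              600       610  100.0%
Documentation of nAMD within 1 year preindex                         591       591   96.9%
...
Anti-VEGF treatment in the fellow eye during follow-up               383       383   62.8%
>=1 retina specialist visit without an anti-VEGF injection           377       377   61.8%
```

```r
print(render_outcomes_text(res$outcomes))
```

```
Arm                                 N      dVA     %+15     %-15      Inj       Cost      AE%
ranibizumab_monthly/trial       301.0      8.2     31.9      5.0     11.7   23401.99     1.00
ranibizumab_prn_em/em           130.0      1.7     25.4     18.5      8.2   16476.92     0.00
ranibizumab_prn_ipsw/ipsw       134.0      1.0     23.8     18.0      8.2   16420.87     0.00
bevacizumab_monthly/trial       286.0      8.0     34.6      6.6     11.9     594.76     1.75
bevacizumab_prn_em/em           225.0      1.3     22.2     20.4      7.1     353.56     0.00
bevacizumab_prn_ipsw/ipsw       243.0      1.1     21.9     19.7      7.1     354.86     0.00
```

Read: the synthetic monthly trial arms gain ~8 letters at one year while
the emulated real-world prn arms gain 1–2 letters (the generator's
configured real-world effect), at ~8 versus ~12 injections; cost is mean
injections × $2000 (ranibizumab) or $50 (bevacizumab) per dose. Exact
matching (`em`) and weighting (`ipsw`) agree closely with each other —
the central methodological observation this workflow supports:

```r
res$comparisons[, c("a", "b", "p")]
#>                   a                b        p
#> 1    ranibizumab_em ranibizumab_ipsw 7.17e-01   # EM vs IPSW: equivalent
#> 4    bevacizumab_em bevacizumab_ipsw 9.16e-01
#> 2 ranibizumab_trial ranibizumab_ipsw 1.15e-06   # trial vs real world
#> ...
res$balance$bevacizumab
#>          covariate  smd_before    smd_after
#> 1              age -0.16446180  0.007085812
#> 2           female  0.05081935 -0.002409920
#> 3 baseline_letters -0.04258607  0.007718800
```

Weighting reduces every covariate's standardized mean difference to
< 0.01 here. (Match rates in this toy run are low because a 600-patient
synthetic registry offers far fewer compatible eyes than a
multimillion-patient registry would.)

A command-line front end with per-stage subcommands lives at
`inst/cli/emulate.R`:

```sh
Rscript inst/cli/emulate.R simulate  --seed 7 --out fixtures/
Rscript inst/cli/emulate.R attrition --registry fixtures/ --out out/
Rscript inst/cli/emulate.R run       --seed 7 --out out/
```

## Scope notes

Imaging-based (OCT/angiography) eligibility criteria and anatomic
outcomes are out of scope by design, as are survival analysis,
multiplicity adjustment, k:1 or with-replacement matching, and stabilized
or doubly-robust weighting. See `vignettes/trial-emulation.Rmd` for the
model, parameter and design discussion.
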