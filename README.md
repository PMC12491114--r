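# lupsmacua

Cost-utility cohort models for ^177^Lu-PSMA-617 radioligand therapy (PRLT)
in metastatic castration-resistant prostate cancer (mCRPC), from the German
statutory health insurance perspective.

The package is aimed at health-economic modellers who want to reproduce,
stress-test or extend the comparison of PRLT against its comparators in the
late-line mCRPC treatment sequence:

* **Model I**: PRLT plus standard of care (SoC) versus SoC alone as
  third-line treatment — four health states (treatment, stable after
  treatment, progression, death).
* **Model II**: PRLT versus cabazitaxel as second-line treatment — six
  health states, with the cohort splitting 75%/25% into SoC/PRLT third-line
  sub-models after first progression.

## The model

Both models are time-inhomogeneous Markov cohort simulations (1,000
patients, 60 monthly cycles, tunnel states for the 8- or 7-month treatment
period, life-table within-cycle correction, 3% annual discount). Monthly
transition probabilities are read off parametric survival curves: with
overall survival S_OS and progression-free survival S_PFS,

    p_death(t)    = 1 − S_OS(t+1) / S_OS(t)        (from every alive state)
    p_progress(t) = 1 − S_PFS(t+1) / S_PFS(t)      (from treatment/stable)

Two PFS curves are piecewise, stitched by conditional survival at knots of
3.6 and 4.5 months. Discounted per-patient costs C and QALYs E per arm give
the incremental cost-effectiveness ratio

    ICER = (C_PRLT − C_comp) / (E_PRLT − E_comp)   [EUR per QALY]

or a dominance label when one strategy is both cheaper and more effective.
Around the base case the package provides one-way (tornado) sensitivity
analysis, probabilistic sensitivity analysis (gamma costs, beta utilities,
survival-parameter resampling on the unconstrained scale), a scenario
catalogue, Kaplan–Meier pseudo-IPD reconstruction from digitized curves
with numbers-at-risk tables, parametric AFT fitting with AIC/BIC ranking,
and synthetic-data generators that make the whole chain testable without
access to trial or claims data.

## Worked example

```r
library(lupsmacua)

rep_I <- run_base("I")
rep_I
#> <run_report> Model I (60 cycles, 3.0% discount, cohort 1000)
#>   PRLT_SoC   cost EUR    97491   1.1372 QALYs   death at horizon 93.1%
#>   SoC        cost EUR    70366   0.7464 QALYs   death at horizon 99.6%
#> <incremental_result> PRLT_SoC vs SoC
#>   incremental cost:   EUR 27125
#>   incremental effect: 0.3908 QALYs
#>   ICER: EUR 69414 per QALY (NE quadrant)
```

Third-line PRLT buys 0.39 QALYs per patient at an extra €27,125 — about
€69,000 per QALY gained. As second line it dominates cabazitaxel (cheaper
and more effective):

```r
run_base("II")$incremental
#> <incremental_result> PRLT_SoC vs cabazitaxel
#>   incremental cost:   EUR -1457
#>   incremental effect: 0.1071 QALYs
#>   dominant (SE quadrant)
```

Scenarios and sensitivity analyses work off the same parameter object:

```r
run_scenario("commercial_price", model = "I")$icer   # 264409 EUR/QALY
head(run_dsa("I"), 3)                                # tornado, widest bars first
run_psa("II", n_iter = 1000, seed = 1)               # probabilistic analysis
```

All inputs live in a packaged, human-readable YAML file
(`system.file("extdata", "parameters.yaml", package = "lupsmacua")`); pass
an edited copy via `default_parameters("my.yaml")` to override anything.

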