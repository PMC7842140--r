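# dvrmodel

Dose–volume response modelling of radiation-induced blood–brain-barrier
damage in mouse brain.

After focal (e.g. proton) irradiation of a brain subvolume, breakdown of
the blood–brain barrier shows up on contrast-enhanced T1-weighted MRI as
a contrast-enhancing (CE) lesion that appears after a dose-dependent
latency and then grows. `dvrmodel` is for preclinical radiation
researchers who want to fit, validate, transfer and simulate the
two-equation description of that process:

- **Onset** — the first appearance of enhancement decreases
  logarithmically with dose *D*:

  t_on(D) = t₁ + t₂ ln(D/Gy),  t₂ < 0 (clamped at 0 weeks)

- **Growth** — from onset onwards, log lesion volume grows linearly with
  dose above a threshold dose D₀ and as a power *b* of follow-up time
  *t*:

  log₁₀(V/µl) = a (D − D₀) (t/week)^b

The reference parameterisation (radiosensitive C3H/He vs radioresistant
C57BL/6 mice) is a = 0.0155 /Gy, D₀ = 30 Gy, t₁ = 55.75 weeks,
t₂ = −12.5 weeks, and b = 0.40 vs 0.28 — the whole strain difference is
one exponent.

The package provides:

- pure model evaluation with analytic inversion (`onset_time`,
  `predict_volume`, `time_to_volume`);
- the fitting pipeline (`fit_onset_model`, `validate_onset_model`,
  `fit_volume_model` with free/fixed parameter control for the
  one-parameter cross-strain transfer, `r_squared`);
- a seeded virtual-cohort generator emulating a two-strain MRI follow-up
  study — biweekly scans, detection and sacrifice thresholds, censoring
  at 26 weeks (`sim_config`, `simulate_cohort`);
- Kaplan–Meier / log-rank survival analysis (`km_curve`,
  `logrank_test`);
- CSV/JSON readers and writers, an import adapter for externally
  contoured volume tables, an end-to-end `run_report()`, and a CLI
  (`exec/dvrmodel`, subcommands `simulate`, `fit-onset`, `fit-volume`,
  `transfer`, `predict`, `survival`, `report`).

## Worked example

```r
library(dvrmodel)
p <- reference_params("C3H/He")

onset_time(c(40, 60, 80), p)
#> [1] 9.6390068 4.5706930 0.9746671

predict_volume(80, c(1, 5, 9), p)
#> [1]  5.956621 29.876643 73.514690

time_to_volume(60, 80, p)
#> [1] 7.97384
```

An 80 Gy lesion appears ~1 week after irradiation and a 40 Gy lesion
after ~10 weeks; at 80 Gy the lesion reaches 60 µl (the simulator's
health-deterioration surrogate) just before week 8. The full pipeline —
simulate a noise-free cohort, fit the training strain, validate and
transfer to the second strain, compare survival:

```r
run_report(sim_config(sigma_log10 = 0, seed = 7))
#> # Dose-volume response report
#>
#> Cohort: 20 mice, seed 7.
#>
#> ## Onset model (t_on = t1 + t2 ln D)
#> - Training strain C3H/He: t1 = 56.33 weeks, t2 = -12.44 weeks, R^2 = 0.9798 (n = 9)
#> - Validation on the second strain: R^2 = 0.9718 (n = 9)
#>
#> ## Volume growth law (log10 V = a (D - D0) t^b)
#> - Training strain C3H/He: a = 0.0155 /Gy, b =   0.4, D0 =    30 Gy, R^2 =     1 (n = 54)
#> - Transfer to C57BL/6 (b refitted, a and D0 held): b =  0.28, R^2 =     1 (n = 66)
#>
#> ## Survival (highest vs lowest dose, log-rank)
#> - C3H/He: 80 Gy vs 40 Gy, chi-square = 5.213, p = 0.02242
#> - C57BL/6: 85 Gy vs 45 Gy, chi-square = 4.738, p = 0.02951
```

With noise off the fit is a closure: a, b and D₀ come back at their
generating values (R² = 1), the transfer recovers the resistant strain's
b = 0.28, and the onset regression reproduces the generating line up to
the scan-grid discretisation (onsets are only observed at scheduled
scans). The methods vignette
(`vignettes/dose-volume-response.Rmd`) documents the model, the
generator's assumptions and the numerical protocol in detail.

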