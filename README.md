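# bmitraject

Estimation of longitudinal BMI trajectories before and after a diagnosis of
type 2 diabetes from electronic-medical-record (EMR) style data: irregular
clinic BMI measurements, laboratory HbA1c series and community dispensing
records. The package is aimed at biostatisticians and epidemiologists who
want to (a) derive per-individual annual weight-change rates around a
diagnosis event, (b) quantify how clinical covariates shift those rates, and
(c) separate weight change from the pharmacological and glycaemic changes
that accompany it — all on data where individuals are measured at arbitrary
times, a different number of times, with serially correlated errors.

Because real diabetes-registry data of this kind cannot be redistributed,
the package ships a synthetic EMR generator with a truth ledger, so every
estimation component can be validated by parameter recovery.

## The model

For individual *i* with BMI measurements *y\_ij* at times *t\_ij* (years
relative to diagnosis), the trajectory model is a linear mixed-effects model
with a random intercept and slope and a continuous-time "spatial power"
residual correlation:

    y_ij = x_ij' beta + b0_i + b1_i t_ij + e_ij
    (b0_i, b1_i)' ~ N(0, G),   Cov(e_ij, e_ik) = sigma^2 * rho^|t_ij - t_ik|

estimated by REML. The likelihood is evaluated block-diagonally per
individual (the cohort-level covariance matrix is never formed), with the
fixed effects and residual scale profiled out, leaving a four-parameter
optimisation (log-Cholesky of G/sigma^2 and a logit of rho). After an
initial fit, observations with an internally studentised residual beyond 3
SD are removed and the model is refitted once. The individual annual rate
of BMI change is the population (fixed) time slope plus the individual's
BLUP slope deviation, and is classified into seven categories (rapid /
moderate / slow loss, stable, slow / moderate / rapid gain) with boundaries
at 0.1, 0.3 and 0.5 kg/m²/year.

Two analyses are orchestrated on top of this engine:

* **pre-diagnosis** (observations from 3 years to 6 months before
  diagnosis): base trajectory model plus covariate-by-time interaction
  models (sex, age band, BMI band, deprivation quintile, calendar period),
  univariable then multivariable;
* **post-diagnosis** (1 to 5 years after diagnosis): the base model is
  additionally time-dependently adjusted for the treatment regimen active
  at each measurement (drug classes grouped as untreated / monotherapy /
  dual / triple, with any insulin-containing regimen pooled) and for the
  HbA1c percentage-change category at each measurement; covariate models
  add the pre- and peri-diagnosis weight-change categories.

Cohort construction follows fixed windowing rules: four anchor BMI
measurements (closest to −3 years in [−3, −2], to −0.5 in [−1.5, −0.5], to
+1 in [1, 2] and to +5 in [4, 5]), diagnosis age ≥ 35, BMI ≥ 25 kg/m² at
the +1 year anchor, and an HbA1c measurement 1–2 years after diagnosis.
The peri-diagnosis rate is (BMI₁ − BMI₋₀.₅)/Δt.

## Worked example

```r
library(bmitraject)
cfg <- pipeline_config(overrides = list(
  simulate = list(n_individuals = 1000, seed = 42)))
res <- run_pipeline(file.path(tempdir(), "demo"), cfg)
```

This simulates 1000 individuals, applies the eligibility filters, and runs
both analyses. On this seed the console summary is:

```
cohort: 222
                          filter n_excluded
1    diagnosis_year_out_of_range          0
2              age_under_minimum          0
3  missing_pre_diagnosis_anchors        574
4 missing_post_diagnosis_anchors        150
5            bmi_1_below_minimum         19
6          no_hba1c_1_to_2_years         35

pre:  median 0.23 kg/m2/yr, 96.8% gaining
post: median -0.20 kg/m2/yr, 72.4% losing
post model: sigma2 0.864 rho 0.423, outliers removed 11
```

222 of 1000 simulated individuals satisfy every eligibility rule — sparse
pre-diagnosis BMI coverage is, as in real registries, the dominant
exclusion. The median estimated rate is weight gain before diagnosis and
weight loss after it, matching the generator's latent slopes (+0.25 and
−0.14 kg/m²/year); the residual variance and correlation decay are close to
the generating values (1.0 and 0.5). The exposure-offset table from the
same run (kg/m² versus untreated / no HbA1c change):

```
    exposure             level n_obs estimate   ci_lo    ci_hi
2    regimen        mono:dpp4i    38   0.2595 -0.7058  1.22476
3    regimen    mono:metformin   330  -0.0292 -0.2974  0.23907
7  hba1c_cat          dec_0_10   561  -0.2069 -0.3344 -0.07934
9  hba1c_cat          inc_0_10   615   0.1503  0.0329  0.26766
10 hba1c_cat          inc_ge10    66   0.4912  0.2276  0.75472
```

At this small cohort the confidence intervals are wide (the metformin
offset, generated at −0.32, is here estimated near zero with a ±0.27
interval); the parameter-recovery tests in `tests/testthat/` run the same
estimators at the cohort sizes where they are expected to be accurate.

A command-line wrapper is provided in `inst/cli/`:

```sh
inst/cli/bmi-traject all --n 1000 --seed 42 --output out/
```

writes the bundle CSVs, `cohort.csv`, `exclusions.csv`, `design_post.csv`,
`table1.csv`, `table2.csv`, `exposure_effects.csv`, `trajectories.csv`,
`category_summary.csv` and a `manifest.json` with checksums; re-running
with the same seed reproduces identical files.

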