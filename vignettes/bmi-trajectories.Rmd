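---
title: "Modelling BMI trajectories around type 2 diabetes diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling BMI trajectories around type 2 diabetes diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmitraject)
```

## The problem

Weight change around the diagnosis of type 2 diabetes is clinically
informative in both directions: gain in the years before diagnosis reflects
the metabolic path into the disease, and change after diagnosis reflects
management, medication and glycaemic control. Estimating per-individual
annual BMI-change rates from routine electronic medical records is harder
than it sounds: individuals are measured at irregular times, a handful of
times each, with errors that are serially correlated (a clinic's scale, a
patient's hydration and clothing persist over nearby visits), and the
period immediately around diagnosis shows abrupt weight loss that would
contaminate any straight-line summary crossing it.

The package addresses this with a fixed windowing scheme and a linear
mixed-effects model. Time is measured in years relative to diagnosis.
Observations in the *peri-diagnosis* interval (−0.5 to +1) are never
modelled; the pre-diagnosis trajectory uses observations in [−3, −0.5] and
the post-diagnosis trajectory uses [1, 5]. Eligibility requires four anchor
measurements (the observation closest to −3 within [−3, −2], to −0.5
within [−1.5, −0.5], to +1 within [1, 2], to +5 within [4, 5]), age at
diagnosis ≥ 35 years, BMI ≥ 25 kg/m² at the +1 anchor, and an HbA1c
measurement in [1, 2) years. The peri-diagnosis period is summarised by the
simple rate (BMI₁ − BMI₋₀.₅)/Δt rather than modelled.

## The model and its estimation

For individual $i$, $y_{ij} = x_{ij}'\beta + b_{0i} + b_{1i} t_{ij} +
e_{ij}$ with $(b_{0i}, b_{1i})' \sim N(0, G)$ and
$\mathrm{Cov}(e_{ij}, e_{ik}) = \sigma^2 \rho^{|t_{ij}-t_{ik}|}$ — the
continuous-time analogue of AR(1), appropriate when gaps are fractional and
irregular. Estimation is REML. The implementation evaluates the likelihood
per individual (block-diagonal), profiles $\beta$ by generalised least
squares and $\sigma^2$ analytically, and optimises the remaining
parameters through an unconstrained reparameterisation: the log-Cholesky
factors of $G/\sigma^2$ and a logistic transform of $\rho$.

Choices worth making explicit:

* **$\rho$ is constrained to $[0, 1)$.** For fractional time gaps $d$,
  $\rho^d$ with $\rho < 0$ is not a real number, so negative decay is not
  representable in continuous time; the same constraint applies in the
  standard implementations of this correlation family. The logistic
  transform keeps the optimiser unconstrained.
* **Starting values** come from per-subject ordinary least squares (the
  variance of subject intercepts and slopes over the pooled residual
  variance), with a conservative fixed fallback start used if the first
  does not converge. A quasi-Newton optimiser (`nlminb`) with a relative
  tolerance of 1e-10 is used; a "false convergence" return is accepted
  only if a restart from that solution no longer moves the objective
  (relative change below 1e-6).
* **Duplicate observation times** within an individual would make the
  correlation matrix singular; they are perturbed apart by one day and
  counted.
* **Rank-deficient fixed designs** are an error naming the aliased
  columns; the pipeline passes `on_rank_deficient = "drop"` so that empty
  factor cells in small cohorts degrade gracefully.
* **Confidence intervals** for fixed effects are Wald intervals from the
  GLS information at the REML variance parameters. No Satterthwaite or
  Kenward-Roger small-sample correction is applied; at the cohort sizes
  this package targets (hundreds to thousands of individuals) the
  difference is negligible, but intervals on very small fixtures are
  anti-conservative.
* **Outlier handling**: after the base fit, observations whose marginal
  residual exceeds 3 in internally studentised units (residual divided by
  the square root of the fitted marginal variance, the diagonal of
  $Z_i G Z_i' + \sigma^2 R_i$) are removed and the model is refitted
  exactly once. Covariate models reuse the cleaned observation set from
  the base model, so every model of an analysis is fitted to the same
  rows. A single pass (rather than iteration to convergence) is a
  deliberate choice; with Gaussian data roughly 0.3% of observations are
  flagged, and the refit moves parameters by well under one standard
  error.

Per-individual trajectories are $\hat\beta_{time} + \hat b_{1i}$ (fixed
slope plus BLUP slope deviation), categorised into seven levels with
boundaries at ±0.1, ±0.3 and ±0.5 kg/m²/year: "stable" is the closed
interval [−0.1, 0.1], each loss/gain band is half-open with its boundary
belonging to the band nearer zero, and anything beyond ±0.5 is "rapid".
Trajectories are only defined for base models with a single common time
slope; asking for them from a covariate-interaction model is refused,
because there the population slope is covariate-dependent and adding one
BLUP to one fixed slope is no longer meaningful. The post-diagnosis base
model does include the exposure offsets (which shift levels, not slopes),
matching the idea of a treatment- and HbA1c-adjusted trajectory.

## Time-varying exposures

Each post-diagnosis BMI observation is annotated with the treatment
regimen active on its date — the set of drug classes whose dispensing
episode covers the date, labelled canonically (`none`, `mono:<class>`,
`dual:<a>+<b>` with alphabetical ordering, `triple:...`, `quad_plus` for
four or more agents) with any insulin-containing set pooled into
`insulin_any` — and with an HbA1c change category: the percentage change
of the paired HbA1c from the individual's baseline (first measurement
after 1 year), cut at 0 and ±10% into five categories, with the ±10%
boundaries belonging to the "≥10%" categories and exactly 0 mapping to the
reference `no_change`. Pairing is most-recent-at-or-before the BMI date,
falling back to the nearest measurement within 90 days; unpairable
observations keep the reference category and are flagged. Carrying the
last category forward (rather than interpolating) reflects how a clinician
would see the record. A `grace_days` option extends episode coverage for
dispensing dialects with gaps between refills; the default is 0 because
the synthetic episodes are exact. Regimen levels with fewer than
`min_regimen_obs` observations (default 30) are pooled into `other` before
fitting.

## The synthetic EMR generator

The generator produces data *from the analysis model*, so that parameter
recovery is a meaningful test of the estimation machinery. Each individual
has a latent piecewise-linear BMI trajectory with knots at −0.5 and +1
years and three slopes (pre, peri, post); the observed value adds the
active regimen offset, the HbA1c-category offset (coded exactly as the
analysis codes them, including the carry-forward pairing), and Gaussian
error with correlation $\rho^{gap}$. Visit times are Poisson processes
(BMI: 1.2/year before and 1.8/year after diagnosis; HbA1c: 2/year after),
thinned by a 10% missingness probability. HbA1c itself is a random walk
drifting downward while on treatment and slowly upward otherwise; drug
therapy starts at a random time in half of the individuals,
metformin-dominant, with occasional intensification or a switch to
insulin. Dates are emitted as calendar days (365.25 days/year); a truth
ledger records every latent quantity per observation and is written to
`truth.csv`, which no analysis function reads.

Default parameter values describe a realistic incident type 2 diabetes
population: diagnosis uniformly in 2003–2014; age at diagnosis N(65.6,
10.1²) floored at 35; 43% female; deprivation quintile probabilities
(0.223, 0.234, 0.188, 0.174, 0.181) with 2.2% missing; latent BMI at +1
year N(33, 5.9²) floored at 25 (the eligibility floor); slopes
N(0.25, 0.51²) pre, N(−0.23, 0.76²) peri and N(−0.14, 0.44²) post
kg/m²/year — the pre and post moments chosen so that medians and
interquartile ranges match what is reported for such cohorts, and the peri
moments solved so that the normal tails give ≈36% rapid peri-diagnosis
loss and ≈17% rapid gain; residual SD 1.0 kg/m² with ρ = 0.5/year. Drug
and HbA1c offsets default to plausible magnitudes for their classes
(metformin monotherapy −0.32 kg/m², sulfonylurea +0.31, thiazolidinedione
+1.22, insulin +0.29, metformin combinations with SGLT2i/GLP-1RA/DPP4i
−1.04/−0.79/−0.39; ≥10% HbA1c decrease −0.43, increase +0.48, with ±0.20
for the sub-10% bands). These are simulation inputs, not estimates, and
the recovery tests treat them as ground truth. Age-band slope effects
(`covariate_slope_effects`) attach to the band at 2.75 years before
diagnosis — the middle of the anchor window where the analysis bands age —
so the generating and analysis covariates coincide up to anchor-timing
jitter.

What the generator does *not* emulate — and therefore what passing tests
cannot certify about real data: informative visit processes (in reality
heavier patients are weighed more often), digit preference and device
changes in BMI measurement, realistic prescribing sequences and adherence
gaps, comorbidity-driven weight loss, and any COVID-era censoring.
Conclusions about estimator correctness transfer; conclusions about
clinical effect sizes do not.

## Identifiability of the variance components

A finding from the validation work worth knowing before interpreting
individual-level output: with only ~3 observations per individual over the
2.5-year pre-diagnosis window, the random-slope variance and a strong
serial correlation are nearly exchangeable descriptions of the data — a
large $\rho$ with inflated $\sigma^2$ can absorb most of the slope
heterogeneity, and at moderate cohort sizes REML sometimes genuinely
prefers that solution (multiple optimiser starts, including one at the
generating truth, reach the same optimum; an independent implementation
agrees). The consequence is not bias in the population slope — fixed
effects remain well estimated — but strong shrinkage of the individual
BLUP rates, which compresses the seven-category distribution toward the
centre and inflates the share on the majority side of zero. The
post-diagnosis window (~7 observations over 4 years) does not suffer from
this; its variance components and individual rankings are recovered
reliably. Per-individual pre-diagnosis categories should therefore be read
as heavily regularised at small cohort sizes.

## Covariate modelling strategy

Covariate effects on the rate of change enter as covariate-by-time
interactions (each model also carries the covariate main effect). All
banding uses fixed, pre-specified cut-points, never data-driven quantiles:
age <50 / 50–<60 / 60–<70 / ≥70; BMI <30 / 30–<35 / 35–<40 / ≥40 before
diagnosis and 25–<30 upward after; HbA1c <43 / 43–<48 / 48–<54 / ≥54
mmol/mol; calendar periods <2006 / 2006–07 / 2008–09 / 2010–11 (pre,
at the −3 anchor) and 2003–08 / 2009–10 / 2011–12 / 2013–14 (post, at
diagnosis). Missing deprivation is kept as its own level. Univariable
models are fitted per covariate; the multivariable model includes every
covariate with any interaction p < 0.05 plus the always-retained
confounders (age band and sex by default, configurable), mirroring common
epidemiological practice. No multiple-testing correction is applied — the
coefficient tables are descriptive, and readers should treat borderline
p-values accordingly.

Conventions adopted where reasonable alternatives exist (each is
deterministic and covered by a boundary test): anchor windows are closed
on both ends and an equidistant tie goes to the earlier observation
(favouring a longer measurement span); the HbA1c eligibility window is
[1, 2) so that adjacent yearly windows stay disjoint; age is continuous
(days/365.25) with no flooring before banding; calendar bands are
exhaustive, with years beyond the printed upper band folded into it.

## Problem sizes used in validation

The suite validates the likelihood against a dense whole-matrix oracle on
fixtures of ≤ 20 individuals (tolerance 1e-8); cross-checks the ρ = 0 case
against `lme4` on 200 individuals (agreement to 1e-3) and the spatial-power
case against `nlme::corCAR1`; runs variance-component recovery on 20
replicates of 500 individuals (ρ = 0.5, σ = 1, slope SD 0.3); recovers the
exposure offsets from 2000 simulated individuals and an age-band slope
excess of +0.38 kg/m²/year from a cohort of ~3000 eligible individuals
(the scale of the registry study this design mirrors); and checks the
outlier machinery at its nominal false-positive rate and against 2%
injected gross contamination. These sizes were chosen as the smallest at
which each property is statistically decidable.
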