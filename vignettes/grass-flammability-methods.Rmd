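---
title: "Quantifying grass flammability from traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying grass flammability from traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(grassflam)
```

`grassflam` treats flammability as three measurable components —
ignitability (ease of ignition), sustainability (persistence of burning) and
combustibility (intensity of burning) — and links them to five explanatory
plant traits through burn-curve extraction, a surface fire-spread model and
phylogenetic comparative statistics. This vignette documents the models, the
assumptions behind them, the tunable parameters and the design choices where
the methodology was genuinely open.

## Flammability components from burn records

### Leaf scale

Epiradiator tests yield three event times per sample: application, first
flaming and flame extinction. `leaf_metrics()` derives time to ignition
(TTI = first flaming − application), flaming time (FT = extinction − first
flaming), and the average combustion rate as sample mass / FT (samples
combust completely, so the average rate is well defined). A record with zero
flaming time is flagged excluded with the reason "no sustained flaming"
rather than silently dropped; exclusion counts are carried through every
stage so that input = retained + excluded always holds.

The effect of moisture on leaf flammability is measured on paired fresh/dry
samples of the same individual (`moisture_effect()`): the per-individual
difference fresh − dry for each metric, averaged per species, plus the mean
fresh/dry TTI ratio expressed as a percent increase in ignition delay.
Unpaired individuals are excluded with a warning, keeping the design
balanced.

### Plant scale

A burning clump on a balance produces a sigmoidal mass-loss record, logged
at 0.2-s intervals. `fit_boltzmann()` fits

$$m(t) = A_2 + \frac{A_1 - A_2}{1 + e^{(t - t_0)/dx}}$$

by Levenberg–Marquardt nonlinear least squares. The parameterisation is the
standard Boltzmann sigmoid: $A_1$ and $A_2$ are the upper and lower mass
asymptotes (g), $t_0$ the inflection time (s) and $dx > 0$ the width
parameter (s). The width parameter measures the time window in which most
mass is lost and is used directly as the plant-scale flaming time
(sustainability). Mass burned is $A_1 - A_2$.

*Initialisation.* Nonlinear sigmoid fits are sensitive to starting values,
so the fitter seeds $t_0$ at the steepest observed mass drop, $A_1$/$A_2$ at
head/tail medians, and $dx$ at the 10–90% transit time divided by
$2\ln 9$ (the exact relation for a noiseless Boltzmann), then runs a small
multi-start over width multipliers $e^{-1} \ldots e^{1}$ (default 5 starts)
and keeps the lowest residual sum of squares.

*Lack-of-fit exclusion.* Burns in which material falls off the balance leave
a record no sigmoid can describe. The exclusion rule is $R^2 < 0.95$
(configurable, `boltzmann$r2_min`): a qualitative "too noisy to fit"
criterion made reproducible by a fixed threshold. The threshold was chosen
once, a priori, as a conventional goodness-of-fit floor.

*Maximum combustion rate.* `max_combustion_rate()` selects the observations
within ±3 s of the fitted inflection and reports the absolute OLS slope of
mass on time (g/s). The window is a measurement convention, not an estimate
of the tangent slope: on a noiseless curve the windowed slope is slightly
below the analytic tangent rate $(A_1 - A_2)/(4\,dx)$ because the window
averages over curvature, and the tests assert agreement with an independent
windowed-regression oracle rather than with the tangent formula.

### Intrinsic combustibility

Maximum combustion rate scales strongly with how much mass was burned, so
between-species comparisons must standardise for mass.
`intrinsic_combustibility()` regresses $\log_{10}$(max rate) on
$\log_{10}$(mass burned) within each species, for fresh, dry and combined
data (balanced to fresh/dry pairs). Nested-model F-tests at $\alpha = 0.05$
compare state-specific slopes to a common slope and state-specific
intercepts to a common intercept. The species' intrinsic combustibility is
the combined-data intercept — the expected log rate at 1 g burned — unless
the fresh and dry intercepts differ significantly, in which case the
fresh-data intercept is used (fresh material being the field-relevant
state). Base-10 logarithms are used throughout; the base only shifts
intercepts and is applied consistently.

Open choices resolved here: "mass change" in this regression is taken as
$A_1 - A_2$ (total mass burned) rather than initial sample mass, because it
is the quantity the sigmoid actually explains; the F-test is used for the
slope/intercept equality decisions because the equality rule needed *some*
concrete test and the nested-model F-test is the textbook choice for
comparing OLS fits.

### Whole-plant extrapolation

`whole_plant_rate()` combines a species' intrinsic combustibility
(intercept) with the common across-species allometric slope $b$ from the
bivariate mixed model: $\log_{10}(\text{rate}) = \text{intercept} + b
\log_{10}(\text{total biomass})$. This predicts what the whole plant would
do, standardised to the species' mean total biomass, and is monotone
increasing in biomass for $b > 0$.

## Explanatory traits

- **Moisture content** (g water / g dry mass): $(m_\text{fresh} -
  m_\text{dry}) / m_\text{dry}$, with a 1% tolerance for weighing noise
  before an error is raised; small negative values clamp to 0.
- **Leaf SA/V ratio** (mm⁻¹): the measurement protocol records leaf area and
  thickness but no formula is standard for grass laminae, so the flat-slab
  model is adopted: both faces contribute area, edges are neglected, giving
  $SA/V = 2/\text{thickness}$. Area is accepted as an argument (the protocol
  measures it, and alternative conventions need it) but cancels.
- **Biomass density slope**: a clump is cut at 5+ equal height intervals
  (2.5, 5, 10 or 15 cm depending on height) and each interval weighed.
  `density_slope()` fits OLS to $\log_{10}$(cumulative dry mass from the
  ground) against interval-top height. High slopes mean biomass concentrated
  low and densely. Two conventions are first-class: `log-linear` (default;
  the literal reading of "logged cumulative biomass against height") and
  `log-log` (slope is a dimensionless packing exponent; uniform vertical
  density gives exactly 1). The reported field values for this trait are
  dimensionally ambiguous between the two, so neither is asserted as *the*
  convention; the choice is a config switch and the default is the literal
  one. Points with zero cumulative mass are dropped with a warning; fewer
  than 3 usable points is an error.
- **Leaf EHoC** (kJ/g): microscale combustion calorimetry heat release
  divided by sample mass, averaged over duplicate replicates per individual
  (calorimetry covers 3 individuals per species; the others inherit the
  species mean).
- **Fuel load** (g/cm²): total dry biomass divided by cover area, the area
  of a circle with the measured maximum horizontal spread as diameter.

`aggregate_species()` reports per-species arithmetic means and CVs
(sd/mean, in percent, matching how within-species repeatability is usually
quoted for these measurements).

## The surface fire-spread model

`spread_rate()` implements the classic single-fuel-class steady-state
surface fire-spread equation chain: packing ratio $\beta = \rho_b/\rho_p$
and its optimum $\beta_{op} = 3.348\,\sigma^{-0.8189}$, maximum and actual
reaction velocity, mineral damping $\eta_s = \min(0.174\,S_e^{-0.19}, 1)$,
moisture damping

$$\eta_M = 1 - 2.59 r + 5.11 r^2 - 3.52 r^3, \qquad r = M_f / M_x,$$

clamped to $[0,1]$ and identically 0 for $r \ge 1$ (the polynomial itself
has a zero at $r = 1$, so damping is continuous at extinction), reaction
intensity $I_R$, propagating flux ratio $\xi$, effective heating number
$\varepsilon = e^{-138/\sigma}$, heat of preignition $Q_{ig} = 250 +
1116 M_f$, wind and slope factors, and finally

$$R = \frac{I_R\, \xi\, (1 + \phi_w + \phi_s)}{\rho_b\, \varepsilon\, Q_{ig}}.$$

Computation runs internally in the source model's imperial units — the
empirical constants above are only valid there — with SI conversion at the
boundary (conversions derived from the exact definitions 1 ft = 0.3048 m,
1 lb = 0.45359237 kg, 1 BTU/lb = 2.326 kJ/kg); spread rate is reported in
m/min. All intermediates are returned so `sensitivity()` can show how each
trait propagates through the chain.

Choices: the whole grass clump is treated as a single dead fuel class (the
experiment burned whole fresh or dry clumps; no live/dead partition is
meaningful there). Environment constants not measured on plants default to
standard values — moisture of extinction 0.25, total mineral content 0.0555,
effective mineral content 0.010, particle density 512.6 kg/m³, no wind, flat
ground — all overridable in `run_config()`, since published applications of
the model vary in these.

## Phylogenetic comparative statistics

### Covariance and PGLS

Under Brownian motion the expected trait covariance of two species equals
their shared root-to-ancestor path length; Pagel's λ multiplies the
off-diagonal entries, so λ = 0 is a star phylogeny (no signal) and λ = 1
plain Brownian motion. `pgls_fit()` runs GLS with covariance
$\sigma^2 V(\lambda)$ via Cholesky whitening (the tests cross-check against
the direct matrix-inverse formula), with λ fixed or profiled over $[0, 1]$
by bounded 1-D optimization. With λ = 0 the fit collapses exactly to OLS.
The reported $R^2$ analog is $1 - RSS_V/RSS_{V,0}$ against the GLS
intercept-only model under the same covariance.

### Signal estimation and boundary tests

`estimate_lambda()` maximises the ML profile likelihood of λ. For
ultrametric trees with equal tip depths, $V(\lambda) = (1-\lambda)\,d\,I +
\lambda V_1$ shares $V_1$'s eigenvectors, so a single eigendecomposition
makes each λ evaluation O(n); non-ultrametric trees fall back to a Cholesky
factorisation per evaluation.

Both null hypotheses of interest (λ = 0, λ = 1) sit on the boundary of the
parameter space. Two references for the likelihood-ratio test are provided:

- `"mixture"` (default): the conventional asymptotic 50:50 mixture of a
  point mass at 0 and $\chi^2_1$, i.e. $p = \tfrac12 P(\chi^2_1 > LR)$, with
  $p = 1$ at $LR = 0$. This is what comparative-methods software
  conventionally reports.
- `"bootstrap"`: a parametric bootstrap of the same LR statistic against the
  fitted boundary model. The asymptotic mixture is measurably conservative
  for this statistic at realistic tree sizes — on 100-tip unit-depth pure-birth
  trees the null LR has a point mass at zero near 0.75 rather than the
  asymptotic 0.5, so the mixture test rejects at roughly 1% when 5% is
  intended (an independent comparative-methods implementation shows the same
  behaviour, so this is a property of the asymptotic reference, not of this
  implementation). The bootstrap reference restores close-to-nominal size
  and is what the calibration checks in the test suite use; the mixture
  remains the default because it is the convention readers of λ tables
  expect.

### The bivariate phylogenetic mixed model

Combustion rate and biomass vary both within species (different subsamples
of a clump) and across species. To separate those slopes, individual-level
$(x, y) = (\log_{10}\text{mass burned}, \log_{10}\text{max rate})$ records
are modelled as

$$ (x,y)_{ij} = \mu + u_{s(i)} + e_{ij}, \qquad
\mathrm{vec}(U) \sim N(0,\ \Sigma_{sp} \otimes C), \qquad
e_{ij} \sim N(0, \Sigma_{res}), $$

where $C$ is the Brownian tree correlation among species. The derived
within-species slope is $\Sigma_{res}[xy]/\Sigma_{res}[xx]$ and the
across-species slope $\Sigma_{sp}[xy]/\Sigma_{sp}[xx]$; their difference
$\Delta b$ measures whether species share the within-species allometry.

`bivariate_mixed_model()` samples this model with a conjugate Gibbs sampler:
Gaussian full conditionals for $\mu$ and the species effects (the Kronecker
precision $\Sigma_{sp}^{-1} \otimes C^{-1} + \Sigma_{res}^{-1} \otimes
\mathrm{diag}(n_s)$ is factorised directly; at 25 species this is a 50×50
Cholesky per sweep), and inverse-Wishart conditionals for both covariances.
Priors follow the weakly-informative convention of MCMC mixed-model software
— scale $\nu V$ with $V = \mathrm{diag}(2)$ and $\nu = 0.002$ — read as
inverse-Wishart parameters. Posterior summaries are means, shortest-interval
95% HPDs, effective sample sizes (initial positive-sequence estimator) and
split-$\hat R$, with a warning above 1.1.

Default chain settings are desk-scale (50 000 iterations, burn-in 1000,
thinning 50); the analyses in the test suite use shorter chains
(3000–10 000 iterations) after checking that effective sizes stay in the
hundreds and split-$\hat R$ near 1 — the conditionals are conjugate and mix
fast. Full-length chains are a config change
(`mcmc = list(n_iter = 500000, burnin = 1000, thin = 500)`).

The trait-contribution tables (`run_pipeline()`'s `pgls` output) are fitted
as species-mean PGLS with ML λ, separated into leaf-scale responses (TTI,
FT, leaf rate against moisture, SA/V, log EHoC) and plant-scale responses
(flaming time, max rate, spread rate against all five traits, logging the
strictly positive ones). Species-mean PGLS is an approximation to
individual-level phylogenetic mixed models; it was chosen as the primary
method because it is transparent, fast and adequate for sign-and-magnitude
tables, with the individual-level machinery available through the bivariate
model where the within/across decomposition actually matters.

## The synthetic-study generator

`gen_study()` produces a complete study with known ground truth, emulating
the design the analysis expects:

- **Design**: 25 species × 7 individuals, fresh and dry clump pairs; a
  pure-birth (Yule) phylogeny rescaled to unit depth.
- **Species traits** evolve by Brownian motion with per-trait λ transforms,
  affinely rescaled into realistic ranges (affine maps preserve λ): biomass
  10–160 g (log-uniform-ish), density slope 0.02–0.08 per cm, moisture
  0.05–0.22 g/g, SA/V 4–20 mm⁻¹ (the one trait generated with λ = 1, so the
  signal-recovery loop closes), EHoC 16–22 kJ/g, height 25–90 cm. One
  designated species gets moisture 0.45 g/g — above the 0.25 moisture of
  extinction — so the spread model predicts no fire for it, reproducing the
  qualitative behaviour of a wet invasive grass in an otherwise cured
  community.
- **Within-species variation**: multiplicative lognormal noise with unit
  mean, CV 15% for biomass and ignition times and half that for the more
  repeatable traits. These CVs sit inside the 5–30% range reported for such
  measurements.
- **Vertical profiles** are generated exactly log-linear in height with the
  species' slope, so `density_slope()` recovers the generating slope to
  machine precision at zero noise — the trait-extraction loop closes
  analytically.
- **Leaf events**: fresh TTI = dry TTI × 1.42 per individual (a 42% mean
  ignition delay under field moisture — the generator's headline effect
  size, recovered end-to-end by `moisture_effect()`), fresh FT = dry FT ×
  1.07.
- **Mass-loss series**: Boltzmann curves with $A_1$ = the burned subsample
  mass (a uniform 30–90% fraction of the clump, giving the within-species
  mass range the intrinsic-combustibility regression needs), $A_2$ = 8% ash
  residual, and width $dx$ coupled monotonically to traits — increasing in
  moisture, decreasing in SA/V, with a mild mass allometry. These couplings
  are deliberately simple monotone forms: they exist to give the synthetic
  data realistic covariance structure, not to model combustion physics.
  Gaussian noise (sd 0.01 g) at 0.2-s sampling.
- **Seeding**: each stage draws from a fixed offset of the master seed so
  stages can be regenerated independently; a fixed seed gives byte-identical
  output files.

What the generator does *not* emulate — and hence what passing tests do and
do not show: real burn records have heteroscedastic, autocorrelated balance
noise and occasional fuel collapse (the generator's exclusions are driven by
the same $R^2$ rule but are rare at the default noise level); real traits
have measurement error and covary for physiological reasons the generator
does not encode; and the empirical distributions of the original field data
are not matched, only their design, scales and effect directions. Green
tests demonstrate that the estimators recover known generating values under
the stated noise model, not that the field values themselves are reproduced.

## Numerical choices and degenerate inputs

- Boltzmann fits bound $dx \ge 10^{-6}$ s and $t_0$ within one record-length
  of the data; non-convergent or sub-threshold fits are excluded, never
  silently kept.
- The inflection window requires ≥ 5 observations; an inflection outside the
  recorded time range is an error ("inflection outside series").
- Degenerate mass ranges (all burns equal) make the intrinsic-combustibility
  intercept unidentifiable and error out.
- GLS uses Cholesky whitening, never explicit inverses; profile-likelihood
  optimization is bounded on $[0,1]$ with endpoints checked explicitly so
  boundary maxima are found exactly.
- Inverse-Wishart draws are produced via Wishart draws on the inverted scale
  matrix; non-finite or non-positive-definite draws (numerically possible at
  tiny prior degrees of freedom) are rejected and logged, never used.
- Star trees make λ unidentifiable; the estimate is returned with an
  explicit flat-likelihood warning.
- All validation errors are row-addressable (they name the offending row or
  column) so bad input files can be fixed without bisection.

## Problem sizes used in the checks

The test suite and the acceptance script run: 1000-model agreement checks of
the spread-model equation chain against an independently coded
transcription; 100-replicate Boltzmann recovery at 1% noise; 200-replicate
PGLS slope-coverage and λ-recovery studies on 100-tip trees; a
100–200-replicate bootstrap-calibration study of the no-signal test; a
50-replicate HPD-coverage study of the bivariate model at 25 species × 14
records; and the full 25 × 7 synthetic pipeline. These sizes were chosen so
Monte-Carlo error is small relative to the tolerances being asserted while
the whole suite stays desk-scale.

## Known limitations

- The spread model is steady-state, single-class and wind/slope-homogeneous;
  it predicts *potential* spread from plant traits, not fire behaviour in a
  mixed community.
- Species-mean PGLS discards within-species variance in the
  trait-contribution tables (see above for why; the bivariate model is the
  remedy where it matters).
- The λ boundary tests are low-powered on small phylogenies (25 tips);
  estimates of exactly 0 or 1 with wide likelihood plateaus are expected
  there, and the bootstrap reference tells you how little the data constrain
  λ.
- The flat-slab SA/V model neglects leaf edges and ridging; for strongly
  involute grass leaves it overestimates SA/V by up to a factor ~2. Since it
  enters analyses monotonically, rankings are unaffected.
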