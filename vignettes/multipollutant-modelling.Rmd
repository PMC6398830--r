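---
title: "Joint hierarchical modelling of multi-pollutant time series and daily health counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint hierarchical modelling of multi-pollutant time series and daily health counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Short-term air-pollution epidemiology regresses daily event counts (deaths,
admissions) on daily ambient concentrations, controlling for season and
weather, so that only day-to-day variation identifies the effect. Two things
make the multi-pollutant version of this regression hard:

* **measurement error** — a monitor reading `Y[p, t]` is a noisy version of
  the concentration that matters, and plugging it in attenuates effect
  estimates and understates uncertainty;
* **collinearity** — urban pollutants are strongly cross-correlated
  (combustion tracers positively among themselves, ozone negatively with
  them), so single-pollutant models confound one pollutant's effect with its
  neighbours'.

`multipoll` implements a two-component Bayesian hierarchical model that
addresses both at once, together with the two natural comparison estimators
and a replicated simulation framework for judging them.

## The model

**Pollutant component.** Measured standardized concentrations get a Normal
measurement layer over a latent field,

$$Y_{pt} \sim N(\mu_{pt}, \sigma_p^2),$$

with the latent mean decomposed into a quadratic weather trend and residual
temporal effects,

$$\mu_{pt} = \gamma_{0p} + \gamma_{1p} X_{temp,t} + \gamma_{2p} X^2_{temp,t}
  + \gamma_{3p} X_{rhum,t} + \gamma_{4p} X^2_{rhum,t} + \theta_{pt},$$

and the residual vector following a driftless multivariate random walk at lag
$\ell$ (default 1),

$$(\theta_{1t},\dots,\theta_{Pt})' \sim
  \mathrm{MVN}\big((\theta_{1,t-\ell},\dots,\theta_{P,t-\ell})',\, \Sigma_P\big).$$

$\Sigma_P$ carries both each pollutant's temporal persistence (diagonal) and
the cross-pollutant dependence (off-diagonals). Missing measurement cells are
unknowns in the graph: the sampler imputes them through the temporal and
cross-pollutant structure, so days with a recorded outcome but no readings
are retained rather than dropped.

**Health component.** Daily counts are Poisson around a fixed expected count
$E$ (the study-period mean by default),

$$O_t \sim \mathrm{Poisson}(\lambda_t E), \qquad
\log \lambda_t = \beta_0 + \sum_p \beta_p \mu_{p(t-1)}
  + \sum_i s(X_{ti}, \psi_i) + \delta I_t + \epsilon_t,$$

with exposure entering at a 1-day lag on its **original** units (the latent
concentrations are back-transformed before entering the health model, so
$\exp(\beta_p)$ is the relative rate per concentration unit), low-rank
thin-plate spline smoothers

$$s(x, \psi_i) = \alpha_i x + \sum_{k=1}^{K_i} b_{ki} |x - \kappa_{ki}|^3$$

for calendar time, temperature and relative humidity, a workday vs
weekend/holiday term $\delta I_t$, and a daily Normal overdispersion effect
$\epsilon_t \sim N(0, \sigma^2_\epsilon)$.

**Priors.** Regression coefficients other than $\beta$ get minimally
informative $N(0, 10^3)$ priors. Each $\beta_p$ gets an informative
$N(0, 0.1^2)$ prior — a deliberate constraint whose implied 95% relative-rate
range per unit, $\exp(\pm 1.96 \times 0.1) \approx (0.82, 1.22)$, spans what
is plausible for cardio-respiratory outcomes; this is what keeps the
collinear coefficients jointly estimable. Process and overdispersion standard
deviations get Uniform(0, 100) priors; $\Sigma_P$ gets an inverse-Wishart
IW($D$, $d$) with $d = P$ and $D$ equal to $d$ times the pairwise-complete
empirical correlation matrix of the standardized measurements
(`default_iw_scale()`); spline coefficients are penalized through
$b_{ki} \sim N(0, \sigma_{bi}^{-2})$ with a Gamma(1, 0.001) prior on the
precision. A sensitivity variant (`prior_config("sensitivity")`) widens the
coefficient priors to variance $10^6$, switches the variance priors to
inverse-Gamma(1, 0.001), and uses Gamma(0.001, 0.001) on the spline
precisions — all expressible through configuration alone.

## Three estimators

```{r}
library(multipoll)
panel <- read_panel("panel.csv")

fit_joint <- fit_h2mjoint(panel)   # joint posterior, feedback allowed
fit_cut   <- fit_h2m(panel)        # two stages, uncertainty fed forward only
fit_plug  <- fit_me(panel)         # measured concentrations plugged in
```

* **H2Mjoint** samples pollutant and health components in a single graph:
  concentration uncertainty feeds forward into the health effects *and* the
  outcome feeds back into the latent concentrations.
* **H2M** cuts the feedback: stage 1 fits the pollutant component alone;
  stage 2 samples the health component while drawing one stage-1 realization
  of the latent field per conditional chain (multiple-imputation pooling).
* **ME** is the conventional benchmark: lagged measured concentrations are
  covariates in a Bayesian Poisson regression, complete cases only.

## Sampling machinery and numerical choices

The fitting functions build JAGS graphs (Gibbs/slice sampling) for the full
confounder-adjusted models (splines, holiday term, overdispersion, covariate
trends). For the simulation-form model — no confounders, lag-1 latent walk —
the package ships its own two-block Gibbs engine (`engine = "gibbs"`,
auto-selected when the requested model qualifies): a Laplace independence
Metropolis step for the regression block (Newton mode and Hessian of the
ridge-penalized Poisson log-posterior, ~80–95% acceptance) alternating with a
red-black (odd/even day) sweep of the latent field in which each day's
Gaussian part is exact and the day's single Poisson term enters the proposal
through its quadratic approximation at the Gaussian conditional mean, leaving
a scalar Metropolis correction. This engine exists because componentwise
graph samplers cannot traverse the ridge that collinear pollutants create
between the health coefficients and the latent field: on strongly collinear
instances the graph sampler can fail its own Gelman–Rubin and MC-error checks
even after very long runs, while the native engine passes them in comparable
wall time, and under-converged runs understate credible-interval widths
exactly where honesty matters most. The two engines are cross-checked against
each other in the test suite on instances where both mix.

H2M stage 2 cannot be expressed as a single JAGS graph —
no joint density corresponds to "mu follows its stage-1 posterior untouched
by the outcome" — so the package ships a dedicated cut sampler: per stage-1
imputation of the latent field, an independence Metropolis chain whose
proposal is the Laplace approximation (warm-started Newton mode and Hessian
of the ridge-penalized Poisson log-posterior, covariance inflated 1.3x)
re-equilibrates essentially instantly, and pooled retained draws reproduce
both the within- and between-imputation variance. A random-walk update here
would understate the between-imputation spread substantially — the chain
equilibrates to an effectively averaged likelihood instead of the mixture —
which is why the independence sampler is not optional; the test suite checks
the sampler against an independent fit on a degenerate (single-imputation)
instance.

Other numerical decisions, all reparameterizations or standard defaults
rather than model changes:

* Pollutants are standardized internally to mean 0, sd 1 over observed cells
  (sample sd); health effects are reported per original unit by
  back-transforming inside the sampler, so published IQRs apply directly.
* Covariates in the pollutant component are centered (linear and quadratic
  columns) by default: the raw-scale columns (humidity squared reaches
  thousands) are nearly collinear with the intercept and the random-walk
  level, and mixing of the trend coefficients improves by an order of
  magnitude. `center_covariates = FALSE` restores the raw measured scale.
* Spline covariates are affinely scaled to [0, 1] before knot placement (at
  equally spaced quantiles) and basis construction, because the radial cubic
  basis on raw day indices spans ~1e8; basis columns are sample-centered so
  the smooth is identifiable next to the intercept. The fitted smooth is
  unchanged as a function of the covariate.
* The first `lag` rows of the latent walk get a diffuse N(0, 10^2)
  initialization prior, keeping the joint density proper.
* The additive level of the random walk and the pollutant intercepts
  $\gamma_{0p}$ are only softly identified (both priors are diffuse); their
  chains mix slowly, which is intrinsic to this model class and why long
  burn-ins (tens of thousands of iterations, as in `mcmc_config()` defaults)
  are conventional for production fits. The latent field $\mu$, the health
  coefficients and the reported tables are unaffected.
* With a single pollutant the inverse-Wishart degenerates to an
  inverse-gamma; the same code path serves the single-pollutant suite.
* Equal-tailed credible intervals (2.5/97.5 percentiles) everywhere; percent
  increases per IQR are computed per draw and then summarized, so
  concentration uncertainty propagates into the reported interval.
* `dic()` uses the plug-in-mean form $p_D = \bar D - D(\bar\theta)$ with the
  deviance taken from the outcome likelihood at the posterior mean of the
  log relative risk.

## Convergence checks

`gelman_rubin()` implements the classic between/within-chain potential scale
reduction; `mc_error_ok()` implements the batch-means Monte Carlo error rule
(MC error below 5% of the posterior sd; batches of size ~sqrt(n), since no
particular estimator is canonical). Every fit carries a per-parameter
diagnostics table and `glance()` summarizes the worst R-hat and the MC-error
pass rate. These rules are necessary, not sufficient: for production
inference use at least two chains and the default chain lengths.

## The synthetic-data generator and the simulation study

`simulate_panel()` generates the study conditions used for estimator
comparison: P = 6 latent series from a lag-1 multivariate random walk whose
innovation correlation is the London North Kensington matrix
(`london_corr()`; CO, NO2, O3, SO2, PCNT, PM2.5), measurement noise of
variance 0.1, and Poisson counts with

$$\log \lambda_t = 1 + 0.2\,\mu_{t1} + 0.2\,\mu_{t2} - 0.2\,\mu_{t3}
  + 0\,(\mu_{t4} + \mu_{t5} + \mu_{t6})$$

around an expected count of 37 (a typical median daily cardiovascular
mortality count for a large city; the generator exposes it as
`expected_count`). Two generator choices deserve comment:

* `latent_standardize = TRUE` (default): a driftless random walk over
  thousands of days wanders to $|\mu|$ in the tens and overflows
  $\exp(\log\lambda)$; standardizing each latent column after generation
  preserves the autoregressive and cross-correlation structure while keeping
  rates finite. The measurement variance then applies on the standardized
  scale.
* The outcome is generated from *contemporaneous* concentrations
  (`outcome_lag = 0`) and the fitted models in the study use the
  generator-matched lag, so the estimand is well defined; both lags are
  supported if the lagged variant is wanted.

What the generator deliberately does **not** emulate: seasonal/weather
confounding (the study fits exclude the splines and the holiday term
accordingly), overdispersion beyond Poisson, instrument-specific error,
missing data (available through masking, but the study conditions are
complete), and spatial structure. Passing the study therefore demonstrates
correct handling of measurement error and collinearity, not robustness to
confounding misspecification.

Two prior choices are specific to the replicated study, and both are the
package's own measured decisions rather than new model structure:

* **Health-coefficient prior in the study fits.** The informative
  $N(0, 0.1^2)$ default is a collinearity control for real data; in the
  study design the truth (0.2) sits two prior standard deviations out, and at
  250 days the data information on the most collinear coefficient is weak
  enough that prior shrinkage alone visibly biases it toward zero and
  degrades its coverage. So that the study measures how the estimators
  handle **measurement error**, not prior shrinkage, the study fits default
  to a weakly informative $N(0, 10)$ prior (the same number read in the
  precision convention of the classic BUGS engines); pass `priors =` to
  `run_study()` to override. All three estimators use the same prior, so the
  comparison is fair either way.
* **Inverse-Wishart scale in the study fits.** With standardized latent
  columns, the true innovation variance of the walk is about $3/T$ (0.012 at
  250 days) — far below the unit-ish diagonal of a level-correlation scale
  matrix. An IW($d \cdot \hat R_{levels}$, $d = P$) prior places essentially
  no mass ($\propto e^{-3/0.012}$) on such small variances, forces the latent
  walk rough, under-smooths $\mu$ and re-creates plug-in-style attenuation on
  the most collinear coefficient: we measured joint-model bias of -0.05 and
  65% coverage on that coefficient before diagnosing this. The study fits
  therefore use `innovation_iw_scale()`: a method-of-moments estimate of the
  innovation covariance from the differenced standardized series
  ($\widehat{\Sigma} = \mathrm{Cov}(\Delta Y) + C_1 + C_1'$, where the lag-1
  autocovariance $C_1$ of the differences removes the $2\sigma^2 I$
  measurement term). With it the process sd and the health coefficients are
  recovered without the attenuation. For real data, where day-to-day
  pollutant innovations are of
  the same order as the level variance, the level-correlation scale
  `default_iw_scale()` remains the default.

`run_study()` repeats simulate-fit-summarize over replicates with
deterministic per-replicate seeds, records posterior means and equal-tailed
95% intervals per coefficient, tolerates isolated sampler failures (a failed
replicate is excluded and counted; more than 10% failures aborts), and
`study_metrics()` reports bias, across-replicate variance, MSE, RMSE
(= sqrt(MSE), so never below |bias|; all four are persisted because
publication conventions differ), mean CI width and coverage.

Problem sizes: the full design (2000 days, 100 replicates, two chains of
60,000 iterations each) is cluster-scale. The shipped `desk_preset()` — 250
days, 20 replicates, single chains of 3,000 burn-in + 12,000 retained on the
native engine (whose iterations are roughly an order of magnitude cheaper
than the graph sampler's; chain lengths were set so the slowest coefficient
keeps an effective sample size near or above ~150, the point at which
equal-tailed interval endpoints stabilize) — runs the three-estimator
comparison in roughly a quarter of an hour on one core and already separates
the estimators cleanly: the plug-in model's coverage collapses on the
strongly collinear coefficients while the hierarchical estimators stay near
nominal with honest (wider) intervals, and the cut and joint variants give
intervals of comparable width. Two desk-scale caveats are worth stating
plainly. First, with only 250 days the idiosyncratic (per-pollutant)
information is weak, and occasional replicates produce posteriors that
confidently reallocate effect between strongly correlated pollutants — these
are converged posteriors, verified against independent long runs, not sampler
artifacts; per-coefficient coverage for the joint model therefore sits near,
but not always at, the nominal level. Second, the across-replicate bias of
the joint model is statistically indistinguishable from zero at 20
replicates (Monte Carlo standard error about 0.013 on coefficients of size
0.2), so ratio summaries that divide by it — such as fold-reductions in
absolute bias relative to the plug-in model — are noise-floored and vary
substantially from seed to seed. Relatedly, on the occasional weakly
identified replicate the cut model's intervals come out 10–25% narrower than
the joint model's: feedback lets the joint posterior explore attribution
ambiguity that outcome-blind imputations never see. At the full design all
of these differences wash out. The package's tests and the acceptance
script use the desk preset; `sim_config()` defaults remain the full design.

```{r}
dp <- desk_preset(seed = 1)
study <- run_study(dp$sim, estimators = c("me", "h2m", "h2mjoint"),
                   mcmc = dp$mcmc, seed = 1)
study$metrics
autoplot(study)
```

## Design choices that were genuinely open

* **AR on residuals vs on the latent mean.** The autoregression is placed on
  the residual effects $\theta$, with the covariate trend on top; with the
  trend switched off (`pollutant_covariates = FALSE`) the two formulations
  coincide, which is exactly the simulation design. This nests both readings.
* **Standardization estimator.** The sample (n-1) standard deviation of
  observed cells, matching mainstream statistics software.
* **E.** The mean observed count over the study period, overridable via
  `expected_count`.
* **Knot placement.** Counts are fixed (3 for temperature and humidity, 6
  for time by default; a denser 9/9/14 configuration for sensitivity), and
  locations sit at equally spaced quantiles — the standard mixed-model
  default.
* **beta prior scale.** $N(0, 0.1)$ is read as standard deviation 0.1, not
  variance: only that reading yields the documented 0.82-1.22 relative-rate
  range.
* **H2M forward-feeding.** One stage-1 draw of the latent field per
  conditional chain, pooled multiple-imputation style — the standard way to
  propagate uncertainty without feedback.
* **Outcome-likelihood start.** The first `health_lag` days are excluded
  rather than padding day-0 exposure.

## Limitations

* Single monitoring site; no spatial structure or exposure (personal-level)
  modelling.
* Additive Normal measurement error only — no multiplicative or Berkson
  mechanisms.
* Linear concentration-response; no distributed lags or thresholds.
* The level of the latent walk is only weakly identified next to the
  pollutant intercepts (see above); plan long burn-ins for fits with
  covariates.
* DIC is reported in its plug-in-mean form; the half-variance variant can
  differ for strongly skewed posteriors.
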