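---
title: "Functional-response inference for depletion predation trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional-response inference for depletion predation trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcresp)
```

## The problem

A predator is confined for a fixed time $T$ (here one day) in an arena with
$N_0$ prey which are not replaced as they are eaten. The *functional
response* — how the number eaten $N_e$ depends on $N_0$ — is the core
quantity of biological-control assessments: its shape (hyperbolic type II
versus sigmoidal type III or intermediate) determines whether predation is
destabilizing or stabilizing at low pest densities, and its plateau sets the
maximum kill rate. funcresp fits and compares these models on trial counts,
with the experimental structure typical of such studies: several prey
densities (default 5, 10, 25, 50, 80), a handful of replicates per density
(default 6), optional alternative-prey treatments, and an optional
intraguild-predation context in which the focal prey are
parasitoid-parasitized.

## Models

All consumption models predict the expected number eaten out of $N_0$ in
time $T$:

* **Holling type II (disc equation)** — no depletion:
  $N_e = a N T / (1 + a h N)$, with attack rate $a$ (day$^{-1}$) and
  handling time $h$ (days/prey). Only appropriate when prey are replaced.
* **Rogers type II (random-predator equation)** — the depletion-corrected
  form, defined implicitly by
  $N_e = N_0\,(1 - \exp(a (h N_e - T)))$.
  The unique root in $[0, N_0]$ has the closed form
  $N_e = N_0 - W(a h N_0 e^{-a(T - h N_0)})/(a h)$
  with $W$ the principal Lambert branch.
* **Flexible-exponent (generalized) family** — the attack rate becomes
  density dependent, $a = b N_0^{\,q}$, inside the Rogers equation. $q = 0$
  reduces exactly to Rogers type II with $a = b$; $q = 1$ gives type III
  behaviour; intermediate $q$ interpolates. Some printed forms of this
  family omit depletion; because the arenas deplete, the package uses the
  depletion-consistent reading (density-dependent attack rate substituted in
  the random-predator equation), and documents the exponent convention here.
* **Hassell type III** — a saturating density-dependent attack rate
  $a_{\mathrm{eff}} = (d + b N_0)/(1 + c N_0)$ in the Rogers equation.
  $b = c = 0$ recovers type II with $a = d$; $c = d = 0$ recovers the
  $q = 1$ flexible model.

The maximum feeding rate is the plateau $\mathrm{MFr} = 1/(hT)$ (prey/day),
conventionally rounded to an integer in reports.

### Numerical solution

The Lambert $W$ kernel is a vectorized Halley iteration started at
$\log(1+x)$ with a relative $10^{-14}$ stopping rule; it satisfies
$w e^w = x$ to near machine precision over at least $[0, 10^{300}]$. When
the $W$ argument would overflow (`exponent > 700`), the root of
$w + \log w = \log x$ is found by Newton iteration in the log domain, so
extreme parameter combinations met during optimization remain finite. Every
returned $N_e$ is verified against the implicit equation (residual below
$10^{-10}$); the rare ill-conditioned cases fall back to interval bisection
on $[0, N_0]$. Bisection, not damped fixed-point iteration, is the fallback
because the map $N_e \mapsto N_0(1 - \exp(a(hN_e - T)))$ has slope
$-a h N_0 e^{(\cdot)}$ at the root, which exceeds one in magnitude for steep
responses (e.g. effective attack rates of tens per day at $N_0 = 80$), where
any fixed damping oscillates. For such steep responses the residual check is
normalized by the slope $1 + a h N_0$, since a root accurate to machine
precision still leaves a raw residual amplified by that factor.

## The three-step selection procedure

1. **Shape test (advisory).** A binomial logistic regression of
   (consumed, survived) counts on polynomial terms in density, cubic first,
   backward-eliminating the top term while non-significant (the linear term
   is always kept). A significantly negative linear term means the
   proportion consumed falls from the lowest densities (hyperbolic, type II
   candidate); positive means it first rises (sigmoidal). The test cannot
   separate true type III from the generalized family, so it never picks the
   final model. Internally the polynomial is built on centered/scaled
   density for conditioning; coefficients are reported on that standardized
   scale (the convention under which published tables of this test are
   order one) and also mapped exactly, covariance included, to raw density
   powers.
2. **AIC comparison.** The flexible-$q$ fit is compared with the fixed
   $q = 0$ (Rogers) fit by AIC. If the fixed model wins, type II is final.
   If the flexible model wins, the Hassell type III model is also fitted and
   the generalized response is retained only when its AIC also beats the
   type III AIC. Ties within $\Delta\mathrm{AIC} = 2$ go to the model with
   fewer parameters — the standard information-theoretic convention, chosen
   here because the original procedure states only "best AIC".
3. **Uncertainty.** Nonparametric bootstrap: trials are resampled with
   replacement across the experiment, the model is refitted per resample
   from the point estimates, and 95% percentile intervals are taken from
   the converged resamples. Resampling is *not* stratified by density by
   default: with strata of only six trials, within-stratum resampling
   shrinks the bootstrap variance by the small-stratum factor
   $(n_s - 1)/n_s = 5/6$ per stratum (roughly a 9% narrowing of every
   interval), a material miscalibration at this design; `stratify = TRUE`
   restores design-preserving resampling for larger strata. Percentile
   intervals are the default as the simplest method whose only tuning knob
   is the resample count; even so, they run a few points below nominal
   coverage here — see Known limitations.

### Likelihood and optimization

The fitting likelihood is binomial: each trial contributes
$\log \mathrm{Binom}(n_e \mid n_0, \hat p)$ with
$\hat p = \hat N_e/n_0$ clipped to $[10^{-9}, 1-10^{-9}]$. This is the
standard likelihood for depletion designs; it treats trials as independent
and within-trial captures as exchangeable. Optimization is Nelder-Mead on
$\log a$ (or $\log b$, $\log c$, $\log d$) and $\log h$, with $q$
unconstrained — positivity without boundary pathologies, while allowing the
negative $q$ interval bounds that published tables show. Starting values
follow the field convention $a = b = 1$ and $h = 1/F_{\max}$ with
$F_{\max}$ the mean consumption at the highest density; if the first
attempt fails to produce a positive-definite Hessian, up to 10 restarts
jitter the positive starts by $\mathrm{U}(0.5, 2)$ factors. Standard errors
are delta-transformed from the inverse numerical Hessian; Wald $z$ and
two-sided normal $p$ values follow. A selected fit whose non-$q$ parameters
are not all significant at $\alpha = 0.05$ is reported as
"no evidence of any functional response type" — the reporting convention
for treatments whose consumption carries no usable density signal.

## The synthetic generator

`synthetic_config()` / `generate_experiment()` reproduce the arena design:
5 densities $\times$ 6 replicates per treatment, alternative-prey offers of
0/5/25/80, both IGP contexts, $T = 1$ day. Two noise models:

* `binomial` (default): $n_e \sim \mathrm{Binom}(n_0, \hat N_e/n_0)$ around
  the deterministic prediction — exactly the sampling model the likelihood
  assumes, which makes recovery tests well-posed tests of the estimator
  rather than of model misspecification.
* `exact_depletion`: the mechanistic search-and-handle renewal process
  (exponential waiting times at rate $a_{\mathrm{eff}} N$ over surviving
  prey; each capture spends $h$ days of the remaining budget). Its mean
  sits about 0.3% above the implicit-equation value at realistic
  parameters: the deterministic Rogers curve is the mean-field
  approximation of this stochastic process, and that small systematic
  offset is expected and documented rather than a solver error.

Alternative-prey consumption is drawn independently of focal consumption as
$\mathrm{Binom}(\text{offered}, f)$ with $f = 0.92, 0.80, 0.65$ for offers
of 5, 25, 80 — once-chosen values echoing the near-saturating aphid
consumption reported at those offers — and is never used in fitting,
mirroring the analysis it emulates (alternative prey enter only as
treatment labels). An optional beta-binomial `theta` adds overdispersion;
it is off by default because no variance model for real trials is
available. What passing recovery tests on these data do **not** show:
robustness to overdispersed or behaviourally correlated real trials,
arena-position effects, or day-block effects (the analysis, like its
reference, fits none).

## Problem sizes used in validation

The packaged checks run at deliberately chosen scales: solver agreement on
a 1000-point randomized parameter grid ($a \le 3$, $h \le 0.5$,
$N_0 \le 200$); estimator calibration on 500 simulated experiments at the
study design with 500 bootstrap resamples each; selection consistency on
200 seeds per generating family at 20 replicates per density, with the
6-replicate rate reported descriptively rather than asserted — at the
study's own replication, correct family selection is not guaranteed, and
the observed rate is part of the report, not a pass/fail bound.

## Worked example

```{r example, eval = FALSE}
library(funcresp)

trials <- generate_experiment(synthetic_config(
  family = "rogers2", pars = list(a = 0.98, h = 0.0104), seed = 1))

fit_shape_test(trials)            # step 1: advisory curve shape
sel <- select_model(trials)       # step 2: AIC-based family choice
tidy(sel)
bootstrap_ci(trials, fit = sel$chosen_fit, n_boot = 2000, seed = 2)

autoplot(sel$chosen_fit)          # data + fitted depletion-corrected curve
```

## Known limitations

* Single-prey functional responses only: alternative prey are treatment
  labels, not a second consumption equation (no prey-choice models).
* No random effects for blocks; no type I (linear) family.
* Percentile bootstrap intervals undercover for the skewed attack-rate and
  handling-time sampling distributions at 30 trials — the calibration test
  quantifies the shortfall at the design scale (a few points below the
  nominal 95%), and no percentile-family setting closes it; BCa-type
  corrections would, but are deliberately not the default.
* The `exact_depletion` mode treats a capture as occurring when the search
  completes within the time budget, with handling then consuming budget;
  other conventions (requiring handling to finish within $T$) shift means
  by a fraction of one prey.
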