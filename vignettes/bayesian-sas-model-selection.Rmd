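---
title: "Bayesian model selection for small-angle scattering: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian model selection for small-angle scattering: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasbayes)
```

# The problem

A small-angle scattering (SAXS/SANS) measurement yields intensities at a set
of scattering-vector magnitudes $q$. Interpreting the curve requires choosing
a structural model — how many particle species, what shapes — before fitting
its parameters, and the choice is usually made informally or by comparing
goodness-of-fit statistics that reward over-parameterized models. `sasbayes`
treats the choice itself as an inference problem: candidate models are
compared through their posterior probabilities, computed from marginal
likelihoods estimated by replica-exchange Monte Carlo (REMC), with parameter
estimation falling out of the same posterior samples.

The package's built-in model family is a dilute mixture of $K$ monodisperse
spheres. Candidates differ in $K$ (1–4 by default), so the question "how
many particle species does this specimen contain?" gets a probabilistic
answer.

# The forward model

For radii $R_k$ (nm), scale parameters $\tilde S_k$ and background $B$, the
model intensity is

$$
I_K(q) = \sum_{k=1}^{K} \tilde S_k \, V(R_k)\, \Phi(qR_k)^2 + B,
\qquad
\Phi(x) = \frac{3(\sin x - x\cos x)}{x^3},
\qquad
V(R) = \tfrac{4}{3}\pi R^3 .
$$

$\Phi$ is the normalized amplitude of a uniform sphere ($\Phi(0)=1$);
$\tilde S_k$ is proportional to the squared scattering-length-density
contrast times the volume fraction of component $k$. The sphere volume is
kept explicit so that, at equal $\tilde S$, larger spheres scatter more
strongly — as they do physically, since forward scattering grows with the
square of particle volume at fixed total volume fraction. This convention
also makes the benchmark grids behave sensibly: a component whose scale is
scaled down fades out of the data at rates consistent with the
signal-to-noise arithmetic of Poisson counting (see "Detection limits"
below). Models are kept behind a small registry
(`register_sas_model()`), so other form factors (cylinders, core–shell
particles) can be added behind the same `intensity()` contract; none is
built in.

Components are stored with radii in non-increasing order. The mixture is
invariant under permuting component labels; fixing the order removes this
label-switching symmetry from the posterior.

# Observation model

Measured intensities are detector counts, so the package models them as
Poisson: $y_i \sim \mathrm{Poisson}(T\, I_K(q_i))$, where the
pseudo-measurement time $T$ converts model intensity to expected counts
(smaller $T$ = noisier data). The working quantity is the mean Poisson cost

$$
E(\Xi) = \frac{1}{N}\sum_{i=1}^{N}\big[\lambda_i - y_i\log\lambda_i\big],
\qquad \lambda_i = T I_K(q_i,\Xi),
$$

so that $p(D\mid\Xi,K) = C(D)\,e^{-NE}$ with $C(D)=\prod_i 1/y_i!$ a
data-only constant. The constant is identical across candidate models and
cancels from model probabilities; `log_data_constant()` restores it when
absolute evidence values are needed. The $1/N$ normalization keeps $E$ on a
per-point scale; $N$ reappears explicitly in the tempered posterior and the
exchange rule.

# Priors

All parameters get independent Gamma priors (strictly positive support), with
defaults

| parameter | prior | mode | mean |
|---|---|---|---|
| radius $R_k$ | Gamma(shape 2, scale 5) | 5 nm | 10 nm |
| scale $\tilde S_k$ | Gamma(shape 2, scale 100) | 100 | 200 |
| background $B$ | Gamma(shape 1, scale 100) | 0 | 100 |

and a discrete uniform prior over the candidate set $K \in \{1,\dots,4\}$.

The radius and scale priors are weakly informative, mode-anchored at the
magnitudes typical of the benchmark specimens. The background prior is
deliberately much broader than the nominal background (0.01): when a mixture
contains a very small sphere ($qR \ll 1$ across the whole window), its
scattering is a nearly flat pedestal that a reduced model can only absorb
into $B$. A background prior pinned near the nominal value would make that
absorption impossible and force the selector to keep a component the data
cannot actually resolve; the broad exponential prior lets the "fewer
components + larger background" explanation compete on the evidence, which
is exactly the comparison the selector is meant to adjudicate.

The prior is defined on the ordered-radius region and carries the $K!$
order-statistics normalization, so it integrates to one there and the
marginal likelihood equals that of the equivalent exchangeable mixture
prior.

Prior choices move the model-complexity penalty (see below), so for real
analyses they should be set from instrument knowledge and checked by
preliminary runs on synthetic data with noise and magnitudes similar to the
measurement — `scenario()` + `generate_curve()` exist for exactly that.

# Replica-exchange sampling

Each candidate $K$ is sampled by REMC over an inverse-temperature ladder
$0=\beta_1<\dots<\beta_L=1$, targeting
$\pi_\beta(\Xi)\propto e^{-\beta N E(\Xi)}\varphi(\Xi)$ at each rung:

* **Ladder.** $\beta_1 = 0$ (the prior; it anchors the evidence telescope at
  $Z=1$), then geometric spacing from `beta_min` to 1. Geometric spacing
  approximately equalizes exchange rates and stepping-stone variances when
  the tempered posteriors are near their quadratic regime. `beta_min`
  defaults to $10^{-9}$: with forward-scattering counts reaching $10^6$, the
  spread of $NE$ across prior draws is of order $10^7$–$10^8$, and the
  prior-to-first-rung stepping-stone term is only well estimated when
  $\beta_2$ times that spread is order one. Defaults: $L=32$ for
  production, smaller ladders for the packaged experiments (below).
* **Updates.** Single-parameter Metropolis proposals, multiplicative
  (Gaussian random walk on $\log$ scale) so positivity needs no boundary
  handling and parameters spanning decades mix at a scale-free rate; the
  log-normal Jacobian is part of the acceptance ratio. Radius proposals that
  would violate the non-increasing ordering are rejected — equivalent to
  restricting the prior to the ordered region, and preserving detailed
  balance exactly (no re-sorting projection is needed).
* **Exchanges.** Every sweep, alternating even/odd adjacent pairs, accepted
  with $\min\{1, \exp[N(\beta_{l+1}-\beta_l)(E_{l+1}-E_l)]\}$ (prior factors
  cancel since both replicas share $\varphi$).
* **Adaptation.** Per-replica, per-parameter step sizes follow a
  Robbins–Monro recursion toward 30% acceptance during burn-in only, then
  freeze, so the retained phase is exactly Markovian.
* **Initialization.** Independent prior draws per replica; exchanges move
  good states down the ladder during burn-in.

# Evidence and model probabilities

The marginal likelihood at $\beta=1$ is estimated by stepping stone:

$$
\log Z(K) = \sum_{l=1}^{L-1} \log\left\langle
  e^{-(\beta_{l+1}-\beta_l) N E(\Xi)}\right\rangle_{\beta_l},
$$

with each expectation over the retained trace at $\beta_l$ and computed via
log-sum-exp. This is the natural estimator when the evidence identity is
written as a telescoping product of adjacent-rung expectations;
trapezoidal thermodynamic integration of $\langle NE\rangle_\beta$ is also
provided (`method = "ti"`) and serves as a ladder-resolution cross-check —
on a conjugate test model the stepping-stone estimate matches the closed
form within Monte Carlo error while the trapezoid shows visible
discretization bias at coarse ladders, which is why stepping stone is the
default. A moving-block bootstrap (`evidence_mc_error()`) supplies standard
errors that respect the chains' autocorrelation.

Free energies $F(K)=-\log Z(K)$ combine with the model prior through a
max-shifted softmax into $P(K\mid D)$; the shared data constant and any
common shift cancel. The Bayesian selector reports
$\arg\max_K P(K\mid D)$.

**Detection limits and the complexity penalty.** Adding a component can only
increase the maximized likelihood, but the evidence integrates over the
prior: an extra component costs roughly the log of the prior-to-posterior
volume ratio of its parameters. With the default priors this penalty is a
few nats per component. A second component is therefore selected only when
its log-likelihood signal exceeds that penalty — which is what produces the
benchmark behavior where the true two-sphere model wins until the second
sphere's scale ratio falls to a few times $10^{-4}$ (at $T=1$), or its
radius ratio approaches 1 (indistinguishable shapes) or 0 (a flat pedestal
degenerate with background). These flips are detection limits of the data,
not failures of the selector, and their location depends on the priors as
any Bayes-factor threshold does.

# Parameter estimates and fit summaries

From the $\beta=1$ trace: the MAP point (trace argmax of
$-NE+\log\varphi$), equal-tailed credible intervals, posterior fit-curve
envelopes (intensity quantile bands over posterior draws — the band width is
the pointwise confidence of the fitted curve), and Poisson-standardized
residuals $\Delta_i = (y_i - \lambda_i)/\sqrt{\lambda_i}$, which have unit
variance under the true model so misfit shows as structure outside
$\pm 2$. The residual normalization uses the model mean (not the data),
consistent with the Poisson noise model; the same choice gives the Pearson
chi-squared below.

# The reduced chi-squared baseline

The conventional selector computes
$\chi^2 = \sum_i (y_i-\lambda_i)^2/\lambda_i$, minimized per candidate over
the retained posterior samples (a global search standing in for quasi-Newton
fitting, which is easily trapped in local minima on these oscillatory
models), divides by $\mathrm{dof} = N-(2K+1)$, and picks the candidate
closest to 1. It is included because its failure mode motivates the
Bayesian selector: chasing Poisson noise with extra components keeps pulling
$\chi^2_\nu$ toward (and past) 1, so the baseline systematically prefers
more components than the truth, while the evidence-based selector does not.
A data-weighted denominator $\max(y_i,1)$ is available as a robustness
variant.

# Synthetic data

`generate_curve()` implements the benchmark generator: $N=400$ equally
spaced $q$ points on $[0.1, 3]$ nm$^{-1}$, noiseless two-sphere intensity
from the scenario truth, scaled by $T\in\{1, 0.1\}$, then independent
Poisson draws per point. `scale_ratio_scenarios()` fades the larger sphere
out through scale ratios $\{1.0, 0.4, 0.08, 0.002, 4\times10^{-4},
2\times10^{-4}\}$; `radius_ratio_scenarios()` moves one radius through
$\{9.9, 9.7, 9.5, 5, 0.5, 0.4, 0.3\}$ nm against a 10 nm reference (radius
ratios 0.99–0.03). Ten data sets per scenario use fixed seeds 0–9 so sweeps
are exactly re-runnable.

What the generator does *not* emulate: instrument resolution smearing,
interparticle structure factors (the dilute-limit assumption),
polydispersity, dark current, or absolute-intensity calibration. Passing the
packaged experiments therefore demonstrates correct inference under the
stated Poisson count model, not robustness to those real-data effects.

# Numerical choices

* $\Phi(x)$ switches to its alternating series below $x=0.35$:
  $\sin x - x\cos x \approx x^3/3$ loses up to half its digits to
  cancellation well beyond tiny $x$, while six series terms are exact to
  $10^{-16}$ on $[0, 0.35)$.
* The sampler's inner loop evaluates $\sum_i y_i\log\lambda_i$ once per
  proposal. The compiled core uses a 128-bin table-plus-polynomial natural
  log (absolute error $\sim10^{-15}$, no division) and, on equally spaced
  grids, a rotation recurrence for $\sin/\cos$ along the $q$ axis; Poisson
  means and their sums are updated incrementally per accepted proposal and
  refreshed exactly every 1000 sweeps to stop floating-point drift.
* Evidence terms and model probabilities always go through max-shifted
  log-sum-exp.
* Degenerate inputs: out-of-support proposals reject via $-\infty$ rather
  than erroring; a non-finite cost aborts the run; ladders must start at 0
  (telescope anchor) and end at 1; tie-breaks (MAP, chi-squared selection)
  go to the earliest sweep / smaller $K$.

# Problem sizes in the packaged experiments

Production-scale analyses should use the defaults ($L=32$, $10^5$ burn-in
and $10^5$ retained sweeps — `sampler_config()`'s production settings, with
`scale = 0.1` as a quick desk mode). The packaged test suite and the
acceptance script run the same pipelines at reduced sizes chosen so the
whole suite completes on a single CPU while the quantities being checked
remain stable: tally experiments in the test suite use $L=16$ and
$4\times10^3 + 4\times10^3$ sweeps; the acceptance script uses $L=24$ and
$10^4 + 10^4$. At these sizes the bootstrap standard error of $\log Z$ is a
fraction of a nat — small against the multi-nat free-energy gaps that decide
the tallies — and the conjugate-model oracle check confirms the estimator's
accuracy at exactly these settings. Ten-data-set tallies at reduced settings
still carry binomial noise, so the tests accept 9/10 where the expected
separation is complete, and a 6–10/10 band on the knife-edge scale-ratio
row.

# Known limitations

* Evidence values are reported without the data constant
  $-\sum_i \log y_i!$; absolute comparisons across *different data sets*
  need `include_data_constant = TRUE`.
* The complexity penalty, and therefore the exact location of the
  selection flips, is prior-dependent; the defaults are a documented,
  configurable choice, not a calibration to any external reference.
* Only the sphere-mixture family ships with the package; the registry
  accepts other form factors but resolution smearing and structure factors
  are out of scope.
* $K$ is fixed within each run (model selection across runs); there are no
  transdimensional moves.
* Runs are seed-deterministic but single-threaded; replica parallelism is
  not implemented.
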