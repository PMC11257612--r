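---
title: "Causal-filtering information rates for bacterial chemosensing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal-filtering information rates for bacterial chemosensing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemosense)
```

This vignette is the package's own account of its models, numerical choices,
and the design decisions that were genuinely open. Everything quantitative
below is computed by the code shown; no number is quoted that the package does
not itself produce.

## The model

**Signal.** A run-and-tumble swimmer in a static exponential gradient of
steepness $g = d\log c/dx$ experiences the behaviorally-relevant signal
$s(t) = g\,v_x(t)$, the temporal derivative of log concentration along its
path. In shallow gradients the feedback of behavior on the signal is
negligible and $s$ is well approximated by a stationary Gaussian process with
autocovariance $g^2\sigma_v^2 e^{-|\Delta t|/\tau_v}$, i.e. an
Ornstein-Uhlenbeck (OU) process. $\sigma_v^2$ (units $(\mu m/s)^2$) is the
variance of the up-gradient velocity component; $\tau_v$ (s) is its
correlation time, set jointly by run duration, tumble persistence and
rotational diffusion.

**Molecule arrivals.** Ligand molecules reach the receptor array by diffusion
as a Poisson process with rate $k_D c(t)$, $k_D = 4 D l$ for a perfectly
absorbing disk of radius $l$ (the default $D = 800\,\mu m^2/s$,
$l = 0.06\,\mu m$ gives $k_D \approx 1.16\times 10^5\,s^{-1}\mu M^{-1}$).
When many molecules arrive per correlation time ($r_0\tau_v \gg 1$, which
holds at all the backgrounds considered here), the counting process is
Gaussian: the relative arrival-rate deviation is the integrated signal plus
white noise of spectral density $1/r_0$, $r_0 = k_D c_0$. Re-binding of
already-counted molecules would lower the limit by an order-one prefactor and
is not modeled; spatial (body-length) sensing is likewise out of scope.

**Kinase activity.** Receptor-kinase activity responds linearly to
arrival-rate deviations through the adaptive bilobed kernel
$K_r(t) = G_r\left[\tfrac{1}{\tau_1}e^{-t/\tau_1} -
\tfrac{1}{\tau_2}e^{-t/\tau_2}\right]\Theta(t)$ — both lobes integrate to
$G_r$, so step responses adapt perfectly — plus internal noise $\eta_n(t)$,
an OU process with correlation $D_n\tau_n e^{-|\Delta t|/\tau_n}$. The
written form of that correlation is typographically ambiguous between a
$D_n\tau_n$ and a $D_n/\tau_n$ prefactor; the $D_n\tau_n$ (stationary
variance) convention is adopted because it is what "diffusivity" means for an
OU process and because it gives an activity standard deviation of
$\sqrt{8.1\times10^{-4}\times 8.7}\approx 0.084$, the scale on which slow
kinase-activity fluctuations are actually observed. The gain follows the
two-state receptor (MWC) picture, $G(c_0) = G_\infty c_0/(c_0+K_i)$ and
$G_r = G(c_0)/r_0$: constant gain in the linear-sensing regime
$c_0 \ll K_i$, gain $\propto 1/c_0$ in the log-sensing regime.

**Information.** For jointly Gaussian signal and observations, the
behaviorally-relevant (transfer-entropy) rate equals a predictive-information
decay rate and depends only on the squared correlation $\rho^2$ between
$s(t)$ and its optimal causal estimate:
$\dot I = \tfrac{1}{\tau_v}\,\rho^2/(1-\rho^2)$ nats/s
(`info_rate_from_rho()`). The package treats this exact relation as primary
and the commonly written $\dot I \approx \rho^2/\tau_v$ as its small-$\rho^2$
form. Units are nats internally, bits on request, because the closed
small-signal forms $\gamma_r/(4\tau_v)$ and $\gamma_a/(4\tau_v)$ carry no
$\log 2$.

## The two causal filters

Both channels are solved as steady-state Kalman-Bucy problems in
nondimensionalized coordinates (states scaled to unit stationary deviation),
which keeps the algebra well conditioned from $\gamma_r \sim 10^{-7}$ to
$\gamma_r \sim 10^{3}$.

*Physical limit*: states $(s, x=\int s\,dt)$; observation $x$ + white noise
$1/r_0$. *Kinase channel* ($\tau_1 = 0$ branch): the instantaneous kernel
lobe makes the observation noise white and perfectly correlated with the
drive of the adaptation state $m$. Because the integrator $x$ enters the
observation only through $q = m/r_0 - x$, the filter is reduced to the three
stable states $(s, q, \eta_n)$ with correlated process/observation noise —
equivalent to the four-state correlated-noise form but solvable in every
regime. The algebraic Riccati equation is solved by the Hamiltonian
invariant-subspace method polished with Newton/Lyapunov iterations;
$\rho^2$ is evaluated from the filter gain as
$\mathrm{Var}(\hat s) = K_1^2 R\,\tau_v/2$ (exact, because the $\hat s$ row of
the closed-loop dynamics is autonomous), which avoids the catastrophic
cancellation of $1 - P_{11}/\sigma_s^2$ at small $\gamma$.

An independent Wiener-Hopf route (`method = "spectral"`) factorizes the
rational observation spectrum on polynomial coefficients, projects the
cross-spectrum onto its causal part by partial fractions, and evaluates the
estimator variance by residues. The two routes agree to better than $10^{-6}$
relative across the measured condition grid (tested), which is the package's
main defense against algebra errors in either derivation.

Numerical tie-breaks: coincident time constants ($\tau_n = \tau_2$ or
$=\tau_v$) make the Hamiltonian defective and are nudged by $10^{-6}$
relative; the $g\to 0^+$ limit is evaluated at $g = 10^{-4}\,mm^{-1}$, deep
in the $g^2$ regime yet far from double-precision limits.

Two analytic facts worth recording. First, the exact solution of the
physical-limit Riccati reduces to the scalar cubic
$p + \sqrt{\gamma_r}\,p^{3/2} + \tfrac{\gamma_r}{4}p^2 = 1$ with
$\rho^2 = \tfrac{\gamma_r}{4}p^2$: the leading saturation correction to the
small-signal form is $2\sqrt{\gamma_r}$, not $O(\gamma_r)$. "Proportional to
$g^2$" therefore holds only as a leading-order statement — at
$g = 0.05\,mm^{-1}$ ($\gamma_r = 0.14$) the rate per $g^2$ already sits ~40%
below its limit — and the property tests check $g^2$ scaling over
$g \le 10^{-3}\,mm^{-1}$ while checking the saturation trend (rate per $g^2$
decreasing in $g$) over the measured range. Second, in the
internal-noise-dominated limit $\gamma_a/\gamma_r \to 0$ the kinase rate
approaches $\gamma_a/(4\tau_v)$ **exactly when $\tau_2 = \tau_n$** (the
regime in which that closed form is stated); at the measured
$\tau_2 = 7.4\,s \ne \tau_n = 8.7\,s$ the limit constant is $\approx 0.96$.
The state-space solution is treated as ground truth and the closed forms are
verified only in their stated regimes.

## Parameters, units, defaults

Everything internal is in seconds, micrometers and micromolar; gradient
steepness is accepted in $mm^{-1}$ at interfaces (`g_per_um()`). The bundled
`params_published.yaml` carries the measured population medians per
background: gains $G_r k_D \in \{3.2, 2.28, 0.251\}$ at
$c_0 \in \{0.1, 1, 10\}\,\mu M$, and at $c_0 = 1\,\mu M$
$\sigma_v^2 = 146$, $\tau_v = 1.19$, $\tau_2 = 7.4$,
$D_n = 8.1\times10^{-4}$, $\tau_n = 8.7$. The remaining backgrounds' weakly
background-dependent parameters are stand-ins copied from the 1 uM column
(noted in the file). The steady-state activity `a0 = 0.33` is a typical
FRET-derived level; it does not enter the information rates (linear theory),
only trace generation. $\tau_1 = 0$ is the default for all information
calculations — the measured fast time mostly reflects reporter
(CheY/CheZ) kinetics and folding it out only slightly overestimates the
kinase rate; $\tau_1 > 0$ is supported in simulation and fitting.

The cross-background efficiency curves produced by `reproduce_comparison()`
use the fitted MWC gain with the remaining parameters measured at
$1\,\mu M$ — the only construction available between measured backgrounds —
while the "measured" table uses the per-background gains. The quoted
steep-gradient efficiency ($\eta \approx 0.1$ at $g = 0.4\,mm^{-1}$) is a
curve-construction value; the same quantity computed with the measured point
gain at $1\,\mu M$ is $\approx 0.12$.

```{r eta, eval = FALSE}
params <- load_params()
ph <- published_phenotype(params, 1)
efficiency_eta(ph$env, ph$swim, ph$kin, g = 0)    # shallow limit, ~0.0145
rc <- reproduce_comparison(params, g_mm = 0.4, c0_grid = c(0.1, 1, 10))
max(rc$curves$eta)                                # steepest gradient, ~0.10
```

## What the synthetic data emulate — and what they do not

`generate_track_dataset()` produces 2D run-tumble kinematics: exponential run
and tumble bouts, rotational diffusion during runs, tumbles as brief
low-speed (25% of run speed) bouts of fast angular diffusion whose
diffusivity is set so the mean reorientation cosine equals the persistence.
Only the $v_x$ statistics matter downstream, so 2D is sufficient. Because
$\sigma_v^2$ and $\tau_v$ are emergent, `calibrate_swim_phenotype()` tunes
speed and rotational diffusivity until the pipeline's own exponential ACF fit
on a long simulated track returns the targets; the calibrated values shipped
in the YAML (speed $18.2\,\mu m/s$, $d_{rot} = 0.18\,rad^2/s$, with mean run
1 s, mean tumble 0.15 s, persistence 0.33) are calibration outputs, not
measured claims. Cell-to-cell variability is lognormal with independent
marginals — the same independence assumed when propagating phenotype
diversity to $\eta$ — with default coefficients of variation of 20% for
behavioral timing and signaling parameters and 10% for swimming speed and
rotational diffusion (speed is the least variable motility trait across
cells).

`generate_step_response_dataset()` simulates the alternating up/down
concentration-step protocol (7.5 s imaged baseline, 30 s imaged step, 65 s
unimaged recovery, ten repeats per direction, 0.75 s sampling, total imaged
time < 2200 s) through the full kinase model, with illumination gaps realized
as unsampled stretches; `generate_noise_dataset()` produces 1200 s
constant-background recordings at 1 Hz. Both add white measurement noise
(default sd 0.02 activity units, a typical shot-noise scale).

Not emulated: image-level effects (photobleaching, segmentation errors),
tracking localization noise, field-of-view loss biased by run fraction (the
run-fraction distribution is therefore used without the diffusivity-bias
correction the real analysis would need), ligand consumption, and any
correlation between swimming and signaling phenotypes. Passing recovery tests
therefore validate the estimators against the stated stochastic models, not
against every artifact of real recordings.

## Estimation choices

* **Tumble detection**: a sample is a tumble candidate when its speed falls
  below 0.5 of the cell median or its turn rate exceeds 6 rad/s; run gaps
  shorter than 0.1 s between candidates are merged. Validated against
  generator ground truth (>90% of samples). Cells with fewer than two
  detected tumbles are dropped; retained cells are binned to within ±0.01 of
  the population-median run fraction.
* **Velocity ACF**: per-cell raw second moment of $v_x$ (no per-track mean
  subtraction, which would bias long lags by $O(\tau_v/T)$; $v_x$ has zero
  mean by symmetry at $g=0$), unbiased $1/(n-k)$ normalization,
  duration-weighted pooling. Per-lag standard errors use the effective sample
  size $T/(2\hat\tau_v)$ (first-pass fit, iterated once), capped at the
  sample count so white-velocity edge cases keep valid errors.
* **Fits**: Gaussian likelihoods, log-uniform priors spanning ±3 decades
  around moment-based initializations, MAP by Nelder-Mead (restarted from the
  best posterior draw when the sampler finds a better mode), uncertainties as
  $1.4826\,\mathrm{mad}$ of affine-invariant ensemble-MCMC draws (32
  walkers, 2000 steps, half burn-in; acceptance checked against the 0.1–0.7
  band). The exponential ACF fit runs over lags $[2\Delta t, 10\,s]$,
  excluding lag 0. The response-kernel fit is joint over the averaged up and
  down responses with $\tau_2 > \tau_1$ enforced through the prior support
  and the fast time bounded above at 2 s (it is physically sub-second, far
  below $\tau_2$; without the bound, weak responses admit spurious high-gain
  fits with nearly cancelling lobes). Pointwise errors estimated from ten
  repeats are too noisy to serve as weights (pooled per direction instead),
  and because the internal noise has a correlation time comparable to the
  adaptation time, the default response likelihood whitens the residuals
  with the full noise covariance (OU plus measurement noise over the repeat
  average, baseline projection applied), taking the noise parameters from
  the constant-background stage. The OU-noise likelihood is an exact
  two-state Kalman filter (compiled) with the unknown mean as a diffuse
  level state — subtracting the sample mean instead would bias $\tau_n$
  downward on 1200 s traces. The MWC fit minimizes squared log-gain
  residuals, weighted by the measurement uncertainties when supplied (this
  weighting is what reproduces the measured-gain constants
  $G_\infty = 3.5$, $K_i = 0.81$; the unweighted log-space optimum sits at
  $G_\infty \approx 3.1$, $K_i \approx 0.77$ and is available with
  `weighted = FALSE`).
* **Aggregation**: population medians of per-cell point estimates with the
  two-term variance $\tfrac{1}{N}(1.4826\,\mathrm{mad}(\hat\theta))^2 +
  \tfrac{1}{N^2}\sum_k\sigma_k^2$; the two terms scale as $1/N$ and $1/N^2$
  (tested). The default per-cell point estimate is the posterior median
  rather than the joint MAP: on the response fits the gain/fast-time
  likelihood ridge is skewed and the optimizer mode over-estimates the gain
  of weak responses by tens of percent, while the posterior median is
  unbiased (verified against generator truth); both summaries are kept in
  every fit object. Per-cell adaptation times remain weakly identified
  (~35% posterior width) because internal noise mimics adaptation, so the
  30-cell population median of $\tau_2$ carries an intrinsic ~10% sampling
  spread — reflected honestly in its reported uncertainty. For the pooled
  track fit, whose likelihood ignores correlations between ACF lags,
  parameter uncertainties come instead from a bootstrap over the cells in
  the median bin.
* **Error propagation**: first-order with central-difference gradients,
  correlations between parameter uncertainties neglected.

## Agent simulations and the information-drift relation

Agents run-and-tumble in an exponential gradient and carry the exact
discrete-time steady-state Kalman recursion of their channel's filter
(transition and noise moments from Van Loan discretization; gain from the
converged discrete Riccati iteration), rather than an Euler discretization of
the continuous filter — so the estimator-correlation checks compare the
empirical $\hat\rho^2$ against the discrete filter's own analytic value with
no $O(\Delta t)$ bias. In `signal_mode = "ou"` the jointly-Gaussian model the
filter assumes is simulated exactly (per-step process and observation noise
drawn from their joint covariance), isolating the estimator from run-tumble
model mismatch; the run-tumble mode drives the same filters with the
idealized local signal $s = g v_x$ and, for kinase agents, the full
adaptation + internal-noise dynamics.

The tumble policy is a linear hazard modulation
$\lambda = \lambda_0\max(0, 1 - \beta\hat s)$. By default $\beta$ is scaled
to the estimator, $\beta = \chi/\mathrm{sd}(\hat s)$ with modulation depth
$\chi = 0.5$ for both agent types: matched dimensionless modulation keeps
both agents in the linear-response regime where drift is proportional to the
signal-estimate correlation, which is precisely the regime in which
$v_a/v_r = \sqrt{\dot I_a/\dot I_r}$ holds. A grid search over $\chi$
(`tune_policy_gain()`) is provided but not used by default: maximizing raw
drift pushes $\chi$ into the clipped, nonlinear regime where the square-root
relation need not survive. Simulations discard a transient of
$10\tau_2$ before measuring drift; reflecting boundaries sit at $\pm 20/g$,
far beyond any excursion at the simulated durations. The default problem
sizes (500 agents, 500 s, 10 ms steps per condition) resolve the drift ratio
to a few percent at the steeper gradients while keeping a full five-gradient,
two-agent comparison within a few minutes on one CPU.

## Known limitations

* The full-filter efficiencies rest on the package's own re-derivation of
  the causal filters; the kinase-channel solution is validated against its
  stated limits and by the dual Riccati/spectral route, but not against an
  external reference implementation.
* Population-variability percentiles use independent lognormal marginals
  fitted by spread parameters — a Monte-Carlo propagation, not a
  maximum-likelihood population model; correlations between swimming and
  signaling phenotypes, if any, are outside the model.
* The linear, Gaussian theory is a shallow-gradient approximation throughout;
  at $g = 0.4\,mm^{-1}$ a swimming cell can change $\log c$ by order one
  within a long simulation, and the package warns accordingly.
* Recovered $\tau_n$ carries the small negative bias of maximum-likelihood
  time-constant estimation on finite traces (a few percent at 1200 s).
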