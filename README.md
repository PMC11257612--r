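# chemosense

Tools for asking a sharp question about bacterial chemotaxis: **is a swimming
cell's chemosensing limited by the physics of molecules diffusing to its
receptors, or by its own signal processing?**

A run-and-tumble bacterium climbing a static exponential gradient of
steepness `g = d log c / dx` needs to estimate the behaviorally-relevant
signal — the temporal derivative of log concentration along its own path,
`s(t) = g · vx(t)`, where `vx` is the up-gradient velocity. In shallow
gradients `s` is well approximated as a Gaussian process with autocovariance
`g² σv² exp(−|Δt|/τv)`.

Two observers of that signal are compared by the **behaviorally-relevant
information rate** — a transfer-entropy rate that, for Gaussian processes,
reduces to a function of the squared correlation ρ² between the signal and its
optimal causal estimate, `İ = (1/τv) · ρ²/(1−ρ²)` nats/s:

* **The physical limit** `İ_r`: an ideal observer of the stochastic molecule
  arrivals at the receptor array, a Poisson process of rate `k_D c(t)` with
  `k_D = 4 D l` (diffusive capture). The dimensionless arrival
  signal-to-noise ratio is `γ_r = 2 r₀ g² σv² τv³`.
* **The cell** `İ_a`: an observer of receptor-kinase activity, which responds
  to arrivals through an adaptive bilobed kernel
  `K_r(t) = G_r [(1/τ₁)e^{−t/τ₁} − (1/τ₂)e^{−t/τ₂}]` and carries slow internal
  (Ornstein-Uhlenbeck) noise with diffusivity `D_n` and correlation time
  `τ_n`. Its signal-to-noise ratio is `γ_a = (G_r²/D_n) r₀² g² σv² τv`.

Both rates are computed exactly by steady-state causal filtering: an algebraic
Riccati solver (primary) cross-checked against an independent Wiener-Hopf
spectral-factorization route to 1e−6 relative. The ratio
`η = İ_a / İ_r ≤ 1` is the sensing efficiency. With population-median
parameters measured in single-cell experiments, η is of order 1% in shallow
gradients — chemosensing is internally limited, far from the molecule-counting
limit — and the lost information propagates to gradient-climbing speed:
run-tumble agent simulations reproduce `v_a/v_r = sqrt(İ_a/İ_r)`.

The package also ships the full measurement pipeline the comparison rests on,
together with synthetic-data generators that emulate the three calibration
experiments (swimming-track videos, concentration-step responses recorded by
FRET, and long constant-background activity recordings), so every estimation
stage is testable end to end:

* tumble detection, run-fraction binning, duration-weighted velocity
  autocorrelation, exponential fits → `σv², τv`
* step-response averaging and response-kernel fits → `G_r·k_D, τ₁, τ₂`
* Kalman-filter marginal likelihood for the internal noise → `D_n, τ_n`
* two-state receptor (MWC) gain fit across backgrounds → `G_inf, K_i`
* population medians with the two-term (cell variation + single-cell
  uncertainty) error formula, and first-order uncertainty propagation

All fits carry log-uniform priors, MAP and posterior-median point estimates,
and affine-invariant ensemble-MCMC uncertainties; the response fit whitens
its residuals with the internal-noise covariance measured in the noise stage.

## Worked example

```r
library(chemosense)

params <- load_params()                       # bundled measured medians
ph <- published_phenotype(params, c0 = 1)     # 1 uM background

# signal-to-noise of molecule arrivals at g = 0.05 / mm
env <- environment_spec(c0 = 1, g = 0.05)
gamma_r(env, ph$swim)
#> [1] 0.1422381
berg_purcell_check(env, ph$swim)$passes       # far below the 16/3 threshold
#> [1] FALSE

# information rates and efficiency at g = 0.2 / mm
env2 <- environment_spec(c0 = 1, g = 0.2)
ir <- solve_physical_limit_filter(env2, ph$swim)
ia <- solve_kinase_filter(env2, ph$swim, ph$kin)
c(I_r = ir$info_rate, I_a = ia$info_rate, eta = ia$info_rate / ir$info_rate)
#>         I_r         I_a         eta
#> 0.105717599 0.006832933 0.064633825

# shallow-gradient efficiency: about 1.4% of the physical limit
efficiency_eta(ph$env, ph$swim, ph$kin, g = 0)
#> [1] 0.01448557
```

`gamma_r = 0.142` says that at this background and gradient the arrival
signal is weak (γ_r ≪ 1): even a perfect molecule counter would gain
information slowly. The efficiency values say the cell extracts only ~1.4%
(shallow limit) to ~6.5% (g = 0.2/mm) of even that — internal kinase noise,
not molecule arrivals, is the bottleneck.

To regenerate the comparison tables behind the information-rate and
efficiency figures, and the kinase-noise power-spectrum decomposition:

```r
rc <- reproduce_comparison(params)
head(rc$curves)     # c0 x g grid of I_r/g^2, I_a/g^2, eta
rc$psd              # internal vs filtered-arrival noise spectra at 1 uM
```

The end-to-end pipeline (synthesize → fit → information rates → agent
simulations → drift comparison) runs from a single configuration:

```r
report <- run_full_pipeline(pipeline_config(seed = 1))
```

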