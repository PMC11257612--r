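# Forward models: signal statistics, molecule arrivals, kinase response and
# noise.

# Molecules per um^3 at 1 uM: 6.022e17 molecules/L / 1e15 um^3/L.
MOLECULES_PER_UM3_PER_UM <- 602.214

#' Signal autocovariance
#'
#' Autocovariance of the behaviorally-relevant signal `s = g * vx` in a static
#' exponential gradient: `g^2 * sigma_v2 * exp(-|lag|/tau_v)` (units s^-2).
#'
#' @param swim a [swimming_phenotype()]
#' @param g gradient steepness, um^-1
#' @param lag time lag, s (any real; the function is even in `lag`)
#' @return covariance value(s), s^-2
#' @export
signal_autocovariance <- function(swim, g, lag) {
  stopifnot(inherits(swim, "swimming_phenotype"))
  stop_if_not_finite(lag, "lag")
  stop_if_not_finite(g, "g")
  if (any(g < 0)) stop("`g` must be >= 0", call. = FALSE)
  g^2 * swim$sigma_v2 * exp(-abs(lag) / swim$tau_v)
}

#' Diffusive capture-rate constant
#'
#' Rate constant of ligand capture by a perfectly absorbing circular sensor of
#' radius `l_sensor`: `k_D = 4 * D * l`, converted from um^3/s to s^-1 uM^-1
#' (602.214 molecules per um^3 per uM).
#'
#' @param D_ligand ligand diffusivity, um^2/s
#' @param l_sensor sensor radius, um
#' @return `k_D` in s^-1 uM^-1
#' @export
capture_rate_constant <- function(D_ligand, l_sensor) {
  if (D_ligand <= 0) stop("`D_ligand` must be > 0", call. = FALSE)
  if (l_sensor < 0) stop("`l_sensor` must be >= 0", call. = FALSE)
  4 * D_ligand * l_sensor * MOLECULES_PER_UM3_PER_UM
}

#' Sample molecule arrivals along a concentration trace
#'
#' Molecule arrivals at the sensor follow an inhomogeneous Poisson process
#' with rate `k_D * c(t)`. `mode = "poisson_events"` draws per-bin Poisson
#' counts; `mode = "gaussian_rate"` uses the diffusion (Gaussian) approximation
#' `r(t) = k_D * c(t) + sqrt(r0/dt) * z`, valid when many molecules arrive per
#' bin (`r0 * dt >> 1`).
#'
#' @param c_trace a [time_series()] of concentrations, uM
#' @param env an [environment_spec()]
#' @param mode `"poisson_events"` or `"gaussian_rate"`
#' @param seed integer seed (same seed, same output)
#' @return a [time_series()]; `values` are arrival counts per bin
#'   (`poisson_events`) or instantaneous rates in s^-1 (`gaussian_rate`)
#' @export
sample_arrivals <- function(c_trace, env,
                            mode = c("poisson_events", "gaussian_rate"),
                            seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(c_trace, "time_series"), inherits(env, "environment_spec"))
  if (any(c_trace$values < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  dt <- c_trace$dt
  rate <- env$k_D * c_trace$values
  set.seed(seed)
  if (mode == "poisson_events") {
    v <- stats::rpois(length(rate), rate * dt)
  } else {
    if (env$r0 * dt < 10)
      warning("r0*dt = ", signif(env$r0 * dt, 3),
              " < 10: Gaussian rate approximation is poor", call. = FALSE)
    v <- rate + sqrt(env$r0 / dt) * stats::rnorm(length(rate))
  }
  time_series(c_trace$t, v, meta = c(c_trace$meta, list(mode = mode, seed = seed)))
}

#' Kinase response kernel
#'
#' Linear response kernel of kinase activity to molecule arrival-rate
#' deviations: `Kr(t) = G_r * [(1/tau_1) e^(-t/tau_1) - (1/tau_2) e^(-t/tau_2)]`
#' for `t >= 0`. Both lobes integrate to `G_r`, so the kernel integrates to
#' zero: responses adapt perfectly. With `tau_1 = 0` the fast lobe is a Dirac
#' impulse, returned as an explicit impulse weight rather than a narrow
#' exponential.
#'
#' The equivalent signal-domain kernel `K` (response to `s` rather than `r`)
#' satisfies `Kr(t) = (1/r0) dK/dt`.
#'
#' @param kin a [kinase_phenotype()]; gain must be resolved (`G_r` set) or
#'   `G_r` supplied explicitly
#' @param t times at which to evaluate the smooth part, s
#' @param G_r optional gain override, s
#' @return list with `t`, `smooth` (the lobe values at `t`, 0 for `t < 0`) and
#'   `impulse_weight` (`G_r` when `tau_1 = 0`, else 0)
#' @export
response_kernel <- function(kin, t, G_r = NULL) {
  stopifnot(inherits(kin, "kinase_phenotype"))
  if (is.null(G_r)) G_r <- kin$G_r
  if (is.na(G_r)) stop("gain `G_r` is not resolved", call. = FALSE)
  tau1 <- kin$tau_1; tau2 <- kin$tau_2
  pos <- as.numeric(t >= 0)
  slow <- -(G_r / tau2) * exp(-pmax(t, 0) / tau2) * pos
  if (tau1 > 0) {
    fast <- (G_r / tau1) * exp(-pmax(t, 0) / tau1) * pos
    list(t = t, smooth = fast + slow, impulse_weight = 0)
  } else {
    list(t = t, smooth = slow, impulse_weight = G_r)
  }
}

#' Two-state receptor (MWC) gain
#'
#' Gain of the kinase response as a function of background concentration under
#' the two-state (Monod-Wyman-Changeux) receptor model:
#' `G(c0) = G_inf * c0 / (c0 + K_i)`. The corresponding arrival-rate gain is
#' `G_r = G(c0) / r0`, so `G_r * k_D = G_inf / (c0 + K_i)`: constant in the
#' linear-sensing regime `c0 << K_i` and proportional to `1/c0` in the
#' log-sensing regime `c0 >> K_i`.
#'
#' @param c0 background concentration, uM
#' @param G_inf gain plateau constant
#' @param K_i inactive-state dissociation constant, uM
#' @param k_D capture-rate constant, s^-1 uM^-1 (needed for `G_r`)
#' @return list with `G` (dimensionless), `G_r_kD = G_r * k_D` and, when `k_D`
#'   is given and `c0 > 0`, `G_r` (s)
#' @export
mwc_gain <- function(c0, G_inf, K_i, k_D = NULL) {
  if (any(c0 < 0)) stop("`c0` must be >= 0", call. = FALSE)
  G <- G_inf * c0 / (c0 + K_i)
  out <- list(G = G, G_r_kD = G_inf / (c0 + K_i))
  if (!is.null(k_D)) {
    if (any(c0 == 0))
      stop("`G_r` is undefined at c0 = 0 (division by zero)", call. = FALSE)
    out$G_r <- G / (k_D * c0)
  }
  out
}

# Exact update of an exponential smoother (1/tau) e^(-t/tau) * u for
# piecewise-constant input. Returns the filtered series with initial state s0.
exp_smooth <- function(u, dt, tau, s0 = 0) {
  if (tau <= 0) return(u)
  phi <- exp(-dt / tau)
  as.numeric(stats::filter(u * (1 - phi), phi, method = "recursive",
                           init = s0))
}

# Exact stationary OU sample path: correlation D*tau*exp(-|dt|/tau).
ou_path <- function(n, dt, D, tau, init = NULL) {
  if (D <= 0) return(rep(0, n))
  phi <- exp(-dt / tau)
  svar <- D * tau
  x0 <- if (is.null(init)) stats::rnorm(1, 0, sqrt(svar)) else init
  innov <- stats::rnorm(n, 0, sqrt(svar * (1 - phi^2)))
  as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
}

#' Simulate kinase activity along a concentration trace
#'
#' Linear-response model of receptor-kinase activity:
#' `a(t) = a0 - int Kr(t - t') (r(t') - r0) dt' + eta_n(t)`, with the bilobed
#' adaptive kernel of [response_kernel()] and internal noise `eta_n` an
#' Ornstein-Uhlenbeck process with stationary variance `D_n * tau_n` and
#' correlation time `tau_n`. Arrival noise enters through `r` when
#' `include_arrival_noise = TRUE` (Gaussian rate approximation). The OU update
#' and the exponential response lobes use exact discrete-time recursions, so
#' results are dt-robust. Activity is not clipped to `[0, 1]` (linear
#' small-signal theory); see `meta$clipped`.
#'
#' @param c_trace a [time_series()] of concentrations, uM
#' @param kin a [kinase_phenotype()]
#' @param env an [environment_spec()]
#' @param include_arrival_noise,include_internal_noise logical flags
#' @param seed integer seed
#' @param clip clip activity to `[0, 1]` for display (default `FALSE`)
#' @return a [time_series()] of kinase activity
#' @export
simulate_kinase <- function(c_trace, kin, env, include_arrival_noise = TRUE,
                            include_internal_noise = TRUE, seed = 1L,
                            clip = FALSE) {
  stopifnot(inherits(c_trace, "time_series"), inherits(kin, "kinase_phenotype"),
            inherits(env, "environment_spec"))
  if (any(c_trace$values < 0)) stop("concentrations must be >= 0", call. = FALSE)
  dt <- c_trace$dt
  varying <- include_arrival_noise || any(c_trace$values != c_trace$values[1])
  if (varying && dt > kin$tau_2 / 20)
    stop("`dt` must be <= tau_2/20 for adequate discretization", call. = FALSE)
  Tlen <- c_trace$t[length(c_trace$t)] - c_trace$t[1]
  if (Tlen < 5 * kin$tau_2)
    warning("trace shorter than 5*tau_2: adaptation transient not settled",
            call. = FALSE)
  G_r <- resolve_gain(kin, env)
  set.seed(seed)
  r <- env$k_D * c_trace$values
  if (include_arrival_noise)
    r <- r + sqrt(env$r0 / dt) * stats::rnorm(length(r))
  dr <- r - env$r0
  fast <- if (kin$tau_1 > 0) exp_smooth(dr, dt, kin$tau_1, s0 = dr[1]) else dr
  slow <- exp_smooth(dr, dt, kin$tau_2, s0 = dr[1])
  a <- kin$a0 - G_r * (fast - slow)
  if (include_internal_noise && kin$D_n > 0)
    a <- a + ou_path(length(a), dt, kin$D_n, kin$tau_n)
  clipped <- FALSE
  if (clip) {
    clipped <- any(a < 0 | a > 1)
    a <- pmin(pmax(a, 0), 1)
  }
  time_series(c_trace$t, a,
              meta = c(c_trace$meta,
                       list(seed = seed, clip_policy = if (clip) "clipped to [0,1]" else "not clipped",
                            clipped = clipped)))
}
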