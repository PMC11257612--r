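# Domain types. Plain S3 lists with validating constructors; all quantities in
# s, um, uM internally. Gradient steepness g is accepted in mm^-1 at user-facing
# interfaces and converted with g_per_um().

#' Convert gradient steepness from mm^-1 to um^-1
#'
#' All internal computations use um^-1; published gradient steepnesses are
#' quoted in mm^-1.
#'
#' @param g_per_mm gradient steepness d(log c)/dx in mm^-1
#' @return steepness in um^-1
#' @export
g_per_um <- function(g_per_mm) g_per_mm * 1e-3

stop_if_not_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("`", name, "` must be finite numeric", call. = FALSE)
  invisible(x)
}

#' Swimming (motility) phenotype
#'
#' Run-tumble motility parameters of a single cell or a population median.
#' `sigma_v2` and `tau_v` describe the exponential autocovariance of the
#' up-gradient velocity component, `V(t) = sigma_v2 * exp(-|t|/tau_v)`, which
#' together with the gradient steepness sets the statistics of the
#' behaviorally-relevant signal `s = g * vx`.
#'
#' @param sigma_v2 variance of the up-gradient velocity component, (um/s)^2
#' @param tau_v velocity (signal) correlation time, s
#' @param speed 3D-projected swimming speed during runs, um/s
#' @param p_run fraction of time in the run state, in `[0, 1]`
#' @param mean_run mean run duration, s
#' @param mean_tumble mean tumble duration, s
#' @param persistence mean cosine of the tumble reorientation angle, in `[-1, 1]`
#' @param d_rot rotational diffusivity during runs, rad^2/s
#' @return an object of class `swimming_phenotype`
#' @export
swimming_phenotype <- function(sigma_v2, tau_v, speed = NA_real_,
                               p_run = NA_real_, mean_run = NA_real_,
                               mean_tumble = NA_real_, persistence = NA_real_,
                               d_rot = NA_real_) {
  stop_if_not_finite(sigma_v2, "sigma_v2"); stop_if_not_finite(tau_v, "tau_v")
  if (sigma_v2 <= 0) stop("`sigma_v2` must be > 0", call. = FALSE)
  if (tau_v <= 0) stop("`tau_v` must be > 0", call. = FALSE)
  if (!is.na(p_run) && (p_run < 0 || p_run > 1))
    stop("`p_run` must lie in [0, 1]", call. = FALSE)
  if (!is.na(mean_run) && mean_run <= 0) stop("`mean_run` must be > 0", call. = FALSE)
  if (!is.na(mean_tumble) && mean_tumble <= 0) stop("`mean_tumble` must be > 0", call. = FALSE)
  if (!is.na(persistence) && abs(persistence) > 1)
    stop("`persistence` must lie in [-1, 1]", call. = FALSE)
  structure(list(sigma_v2 = sigma_v2, tau_v = tau_v, speed = speed,
                 p_run = p_run, mean_run = mean_run, mean_tumble = mean_tumble,
                 persistence = persistence, d_rot = d_rot),
            class = "swimming_phenotype")
}

#' Sensing environment
#'
#' Background ligand concentration, gradient steepness, and the diffusive
#' capture-rate constant that converts concentration into a molecule arrival
#' rate, `r0 = k_D * c0`.
#'
#' @param c0 background ligand concentration, uM
#' @param g gradient steepness d(log c)/dx, mm^-1 (converted internally)
#' @param k_D capture-rate constant, s^-1 uM^-1; computed from `D_ligand` and
#'   `l_sensor` when missing
#' @param D_ligand ligand diffusivity, um^2/s
#' @param l_sensor effective sensor (receptor-array) radius, um
#' @return an object of class `environment_spec` with fields `c0`, `g`
#'   (um^-1), `k_D`, `r0`, `D_ligand`, `l_sensor`
#' @export
environment_spec <- function(c0, g = 0, k_D = NULL, D_ligand = 800,
                             l_sensor = 0.06) {
  stop_if_not_finite(c0, "c0")
  if (c0 < 0) stop("`c0` must be >= 0", call. = FALSE)
  stop_if_not_finite(g, "g")
  if (g < 0) stop("`g` must be >= 0", call. = FALSE)
  if (is.null(k_D)) k_D <- capture_rate_constant(D_ligand, l_sensor)
  if (k_D <= 0) stop("`k_D` must be > 0", call. = FALSE)
  structure(list(c0 = c0, g = g_per_um(g), k_D = k_D, r0 = k_D * c0,
                 D_ligand = D_ligand, l_sensor = l_sensor),
            class = "environment_spec")
}

#' Kinase (signaling) phenotype
#'
#' Parameters of the linear response of receptor-kinase activity to molecule
#' arrival rate and of its internal (signal-independent) noise. The response
#' kernel is a bilobed difference of exponentials with perfect adaptation;
#' internal noise is an Ornstein-Uhlenbeck process with stationary variance
#' `D_n * tau_n`.
#'
#' Either `G_r` (gain in response to arrival rate, units s) or the pair
#' (`G_inf`, `K_i`) of the two-state receptor (MWC) gain model may be given;
#' when both are present `G_r` wins.
#'
#' @param G_r response gain to arrival-rate deviations, s
#' @param G_inf MWC gain plateau constant, dimensionless
#' @param K_i inactive-state dissociation constant, uM
#' @param tau_1 fast response time, s (0 allowed: instantaneous lobe)
#' @param tau_2 slow adaptation time, s; must exceed `tau_1`
#' @param D_n internal-noise diffusivity, s^-1
#' @param tau_n internal-noise correlation time, s
#' @param a0 steady-state kinase activity, dimensionless
#' @return an object of class `kinase_phenotype`
#' @export
kinase_phenotype <- function(G_r = NA_real_, G_inf = NA_real_, K_i = NA_real_,
                             tau_1 = 0, tau_2, D_n, tau_n, a0 = 1 / 3) {
  stop_if_not_finite(tau_2, "tau_2")
  stop_if_not_finite(tau_1, "tau_1")
  if (tau_1 < 0) stop("`tau_1` must be >= 0", call. = FALSE)
  if (tau_2 <= tau_1) stop("`tau_2` must exceed `tau_1`", call. = FALSE)
  if (D_n < 0) stop("`D_n` must be >= 0", call. = FALSE)
  if (tau_n <= 0) stop("`tau_n` must be > 0", call. = FALSE)
  if (is.na(G_r) && (is.na(G_inf) || is.na(K_i)))
    stop("either `G_r` or both `G_inf` and `K_i` must be supplied", call. = FALSE)
  structure(list(G_r = G_r, G_inf = G_inf, K_i = K_i, tau_1 = tau_1,
                 tau_2 = tau_2, D_n = D_n, tau_n = tau_n, a0 = a0),
            class = "kinase_phenotype")
}

# Resolve the arrival-rate gain of a kinase phenotype in environment env:
# measured G_r wins; otherwise MWC gain G(c0)/r0.
resolve_gain <- function(kin, env) {
  if (!is.na(kin$G_r)) return(kin$G_r)
  mwc_gain(env$c0, kin$G_inf, kin$K_i, k_D = env$k_D)$G_r
}

#' Regularly sampled time series
#'
#' @param t sample times, s (strictly increasing, uniformly spaced)
#' @param values samples
#' @param meta named list of labels (cell id, block id, channel, ...)
#' @return an object of class `time_series`
#' @export
time_series <- function(t, values, meta = list()) {
  if (length(t) < 2) stop("a time series needs at least 2 samples", call. = FALSE)
  if (length(t) != length(values)) stop("`t` and `values` lengths differ", call. = FALSE)
  dts <- diff(t)
  if (any(dts <= 0)) stop("`t` must be strictly increasing", call. = FALSE)
  dt <- stats::median(dts)
  uniform <- all(abs(dts - dt) < 1e-9 + 1e-9 * dt)
  structure(list(t = t, values = values, dt = dt, uniform = uniform,
                 meta = meta), class = "time_series")
}

#' Swimming track
#'
#' @param t sample times, s
#' @param x,y positions, um
#' @param state per-sample `"run"`/`"tumble"` label (optional)
#' @param meta named list of labels
#' @return an object of class `track`; velocities `vx`, `vy` (um/s, forward
#'   differences, last value repeated) and `speed` are derived
#' @export
track <- function(t, x, y, state = NULL, meta = list()) {
  n <- length(t)
  if (n < 2) stop("a track needs at least 2 samples", call. = FALSE)
  stopifnot(length(x) == n, length(y) == n)
  if (!is.null(state) && !all(state %in% c("run", "tumble")))
    stop('`state` entries must be "run" or "tumble"', call. = FALSE)
  dt <- stats::median(diff(t))
  vx <- c(diff(x), NA) / dt; vx[n] <- vx[n - 1]
  vy <- c(diff(y), NA) / dt; vy[n] <- vy[n - 1]
  if (any(!is.finite(vx)) || any(!is.finite(vy)))
    stop("track velocities must be finite", call. = FALSE)
  structure(list(t = t, x = x, y = y, state = state, vx = vx, vy = vy,
                 speed = sqrt(vx^2 + vy^2), dt = dt, duration = t[n] - t[1],
                 meta = meta), class = "track")
}

#' Step-stimulus protocol
#'
#' Timing of the alternating up/down concentration-step imaging protocol:
#' each block images `pre_s` seconds of baseline followed by `step_s` seconds
#' at the stepped concentration; blocks are separated by an unimaged
#' `recover_s` adaptation gap; up and down steps alternate, `n_steps` repeats
#' per direction.
#'
#' @param pre_s baseline imaging duration before the step, s
#' @param step_s step duration (imaged), s
#' @param recover_s unimaged adaptation gap between blocks, s
#' @param n_steps repeats per direction
#' @param delta_up,delta_down concentration steps, uM (signed)
#' @param sample_dt imaging sampling interval, s
#' @return an object of class `step_protocol`
#' @export
step_protocol <- function(pre_s = 7.5, step_s = 30, recover_s = 65,
                          n_steps = 10, delta_up = 0.1, delta_down = -0.1,
                          sample_dt = 0.75) {
  if (any(c(pre_s, step_s, recover_s, sample_dt) <= 0))
    stop("protocol durations must be > 0", call. = FALSE)
  if (n_steps < 1) stop("`n_steps` must be >= 1", call. = FALSE)
  structure(list(pre_s = pre_s, step_s = step_s, recover_s = recover_s,
                 n_steps = n_steps, delta_up = delta_up,
                 delta_down = delta_down, sample_dt = sample_dt),
            class = "step_protocol")
}

#' Population specification for synthetic datasets
#'
#' A clonal population with lognormal cell-to-cell variation around a median
#' phenotype. Each varying parameter gets an independent lognormal marginal
#' with the given coefficient of variation, matching the independence
#' assumption used when propagating phenotype diversity to sensing efficiency.
#'
#' @param swim median [swimming_phenotype()]
#' @param kin median [kinase_phenotype()]
#' @param cv coefficient of variation of the lognormal cell-to-cell
#'   variation: a scalar applied to every varying parameter, or a named
#'   vector overriding individual parameters (`speed`, `mean_run`,
#'   `mean_tumble`, `d_rot`, `G_r`, `tau_1`, `tau_2`, `D_n`, `tau_n`). The
#'   default varies behavioral timing and signaling parameters by 20% and
#'   swimming speed and rotational diffusion by 10% (speed is the least
#'   variable motility trait across cells)
#' @param n_cells number of cells
#' @param measurement_noise_sd additive white measurement noise on recorded
#'   activity, activity units
#' @return an object of class `population_spec`
#' @export
population_spec <- function(swim, kin = NULL, cv = NULL, n_cells = 50,
                            measurement_noise_sd = 0.02) {
  stopifnot(inherits(swim, "swimming_phenotype"))
  if (!is.null(kin)) stopifnot(inherits(kin, "kinase_phenotype"))
  base <- c(speed = 0.1, mean_run = 0.2, mean_tumble = 0.2, d_rot = 0.1,
            G_r = 0.2, tau_1 = 0.2, tau_2 = 0.2, D_n = 0.2, tau_n = 0.2)
  if (is.null(cv)) {
    cv <- base
  } else if (is.null(names(cv))) {
    base[] <- cv[1]
    cv <- base
  } else {
    base[names(cv)] <- cv
    cv <- base
  }
  if (any(cv < 0)) stop("`cv` must be >= 0", call. = FALSE)
  if (n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  structure(list(swim = swim, kin = kin, cv = cv, n_cells = n_cells,
                 measurement_noise_sd = measurement_noise_sd),
            class = "population_spec")
}

# Draw one lognormal deviate of `x` with coefficient of variation `cv`,
# preserving the median.
lognormal_jitter <- function(x, cv) {
  if (cv <= 0 || is.na(x)) return(x)
  sdlog <- sqrt(log(1 + cv^2))
  x * exp(stats::rnorm(length(x), 0, sdlog))
}

#' @export
print.swimming_phenotype <- function(x, ...) {
  cat("swimming phenotype: sigma_v2 =", x$sigma_v2, "(um/s)^2, tau_v =",
      x$tau_v, "s\n")
  if (!is.na(x$speed))
    cat("  speed =", signif(x$speed, 4), "um/s, p_run =", signif(x$p_run, 4),
        ", mean_run =", x$mean_run, "s\n")
  invisible(x)
}

#' @export
print.environment_spec <- function(x, ...) {
  cat("environment: c0 =", x$c0, "uM, g =", x$g * 1e3, "mm^-1, k_D =",
      signif(x$k_D, 4), "s^-1 uM^-1, r0 =", signif(x$r0, 4), "s^-1\n")
  invisible(x)
}

#' @export
print.kinase_phenotype <- function(x, ...) {
  cat("kinase phenotype: tau_1 =", x$tau_1, "s, tau_2 =", x$tau_2,
      "s, D_n =", x$D_n, "s^-1, tau_n =", x$tau_n, "s\n")
  if (!is.na(x$G_r)) cat("  G_r =", signif(x$G_r, 4), "s\n")
  if (!is.na(x$G_inf)) cat("  MWC: G_inf =", x$G_inf, ", K_i =", x$K_i, "uM\n")
  invisible(x)
}
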