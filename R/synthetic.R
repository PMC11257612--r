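# Synthetic datasets with the statistical structure of the three calibration
# experiments: zero-gradient swimming tracks, FRET-like step-response series,
# and long constant-background kinase noise traces.

#' Exponential concentration gradient
#'
#' Static exponential ligand profile `c(x) = c0 * exp(g * x)`, the profile in
#' which the log-slope `d log c / dx = g` is position-independent.
#'
#' @param c0 background concentration at `x = 0`, uM
#' @param g gradient steepness; `units` says whether it is given per mm
#'   (interface convention) or per um (internal convention)
#' @param units `"per_mm"` (default) or `"per_um"`
#' @return a function of position `x` (um) returning concentration (uM); the
#'   steepness in um^-1 is attached as attribute `"g_per_um"`
#' @export
exponential_gradient <- function(c0, g, units = c("per_mm", "per_um")) {
  units <- match.arg(units)
  g_um <- if (units == "per_mm") g_per_um(g) else g
  f <- function(x) c0 * exp(g_um * x)
  attr(f, "g_per_um") <- g_um
  f
}

# Run-tumble kinematics of one cell in 2D, zero gradient. Exponential run and
# tumble durations; rotational diffusion d_rot during runs; tumbles modeled as
# fast angular diffusion at reduced speed, with the tumble angular diffusivity
# set so that the mean reorientation cosine over an exponential tumble equals
# `persistence`: E[cos dtheta] = 1/(1 + d_tum * mean_tumble).
# Fully vectorized; returns a track with ground-truth state labels.
simulate_run_tumble_track <- function(speed, mean_run, mean_tumble,
                                      persistence, d_rot, duration, dt,
                                      tumble_speed_frac = 0.25,
                                      meta = list()) {
  n <- ceiling(duration / dt)
  # renewal sequence of run/tumble bouts covering the track
  n_bouts <- max(16, ceiling(2.5 * duration / (mean_run + mean_tumble)) * 2)
  repeat {
    durs <- cbind(stats::rexp(n_bouts, 1 / mean_run),
                  stats::rexp(n_bouts, 1 / mean_tumble))
    bounds <- cumsum(as.vector(t(durs)))
    if (bounds[length(bounds)] > duration + dt) break
    n_bouts <- n_bouts * 2
  }
  tt <- (seq_len(n) - 1) * dt
  idx <- findInterval(tt, c(0, bounds))        # 1-based bout index
  running <- idx %% 2 == 1                     # odd bouts are runs
  d_tum <- if (persistence >= 1) 0 else
    (1 / max(persistence, 1e-6) - 1) / mean_tumble
  sd_theta <- ifelse(running, sqrt(2 * d_rot * dt), sqrt(2 * d_tum * dt))
  theta <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(n, 0, sd_theta))
  v <- ifelse(running, speed, tumble_speed_frac * speed)
  vx <- v * cos(theta); vy <- v * sin(theta)
  # position k accumulates velocities of earlier intervals, so the velocity
  # derived from diff(x) aligns with the state label of the same sample
  x <- c(0, cumsum(vx[-n])) * dt; y <- c(0, cumsum(vy[-n])) * dt
  track(tt, x, y, state = ifelse(running, "run", "tumble"), meta = meta)
}

# Plain least-squares exponential fit V(t) ~ A exp(-t/tau) used internally for
# calibration; initialized by log-linear regression on the positive lags.
fit_exp_ls <- function(lag, V) {
  pos <- V > 0 & lag > 0
  if (sum(pos) < 3) stop("too few positive ACF values for initialization")
  init <- stats::lm(log(V[pos]) ~ lag[pos])
  p0 <- c(log(max(exp(stats::coef(init)[1]), 1e-12)),
          log(max(-1 / stats::coef(init)[2], 1e-3)))
  obj <- function(p) sum((V - exp(p[1]) * exp(-lag / exp(p[2])))^2)
  fit <- stats::optim(p0, obj, control = list(reltol = 1e-12, maxit = 2000))
  c(A = exp(fit$par[1]), tau = exp(fit$par[2]))
}

# Single-track autocovariance of vx up to max_lag. Raw second moment (vx has
# zero mean by symmetry in zero gradient; per-track demeaning would bias the
# long-lag covariance by O(tau_v/T)), unbiased normalization 1/(n-k) so short
# tracks do not shrink long lags.
track_vx_acf <- function(vx, dt, max_lag) {
  n <- length(vx)
  nl <- min(n - 2, floor(max_lag / dt + 1e-9))
  a <- stats::acf(vx, lag.max = nl, plot = FALSE, demean = FALSE,
                  type = "covariance")$acf[, 1, 1]
  a <- a * n / (n - 0:nl)
  list(lag = (0:nl) * dt, acov = a, n = n)
}

#' Calibrate a run-tumble phenotype to target velocity statistics
#'
#' The up-gradient velocity variance and correlation time of a run-tumble
#' swimmer are emergent: `sigma_v2` is set mainly by the speed and the run
#' fraction, `tau_v` by run duration, tumble persistence and rotational
#' diffusion. This routine fixes the bout statistics and tunes `speed` and
#' `d_rot` so that the exponential fit to the simulated velocity
#' autocovariance recovers the requested `(sigma_v2, tau_v)`. Deterministic
#' (internal fixed seed).
#'
#' @param sigma_v2 target velocity variance, (um/s)^2
#' @param tau_v target correlation time, s
#' @param mean_run,mean_tumble,persistence bout statistics (defaults are
#'   field-typical values)
#' @param tumble_speed_frac speed during tumbles as a fraction of run speed
#' @param n_iter calibration iterations
#' @param T_cal simulated time per iteration, s
#' @param dt simulation time step, s
#' @return a [swimming_phenotype()] with calibrated `speed` and `d_rot`
#' @export
calibrate_swim_phenotype <- function(sigma_v2 = 146, tau_v = 1.19,
                                     mean_run = 1.0, mean_tumble = 0.15,
                                     persistence = 0.33,
                                     tumble_speed_frac = 0.25, n_iter = 4,
                                     T_cal = 12000, dt = 0.05) {
  p_run <- mean_run / (mean_run + mean_tumble)
  # stationary heading is uniform: E[cos^2] = 1/2
  speed <- sqrt(2 * sigma_v2 / (p_run + tumble_speed_frac^2 * (1 - p_run)))
  d_rot <- max(1 / tau_v - (1 - persistence) / mean_run, 1e-3)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (i in seq_len(n_iter)) {
    set.seed(20231000 + i)
    tr <- simulate_run_tumble_track(speed, mean_run, mean_tumble, persistence,
                                    d_rot, T_cal, dt, tumble_speed_frac)
    ac <- track_vx_acf(tr$vx, dt, max_lag = 10)
    keep <- ac$lag >= 2 * dt & ac$lag <= 10
    # measure the emergent statistics with the same weighted objective the
    # estimation pipeline uses, so calibration and recovery agree
    fit0 <- fit_exp_ls(ac$lag[keep], ac$acov[keep])
    n_eff <- min(T_cal / (2 * fit0[["tau"]]), T_cal / dt)
    se <- sqrt((ac$acov[1]^2 + ac$acov[keep]^2) / n_eff)
    wf <- stats::optim(log(fit0), function(p)
      sum(((ac$acov[keep] - exp(p[1]) * exp(-ac$lag[keep] / exp(p[2]))) / se)^2),
      control = list(reltol = 1e-12, maxit = 3000))
    fit <- c(A = unname(exp(wf$par[1])), tau = unname(exp(wf$par[2])))
    speed <- speed * sqrt(sigma_v2 / fit[["A"]])
    d_rot <- max(d_rot + (1 / tau_v - 1 / fit[["tau"]]), 1e-3)
  }
  swimming_phenotype(sigma_v2 = sigma_v2, tau_v = tau_v, speed = speed,
                     p_run = p_run, mean_run = mean_run,
                     mean_tumble = mean_tumble, persistence = persistence,
                     d_rot = d_rot)
}

provenance <- function(seed, ...) {
  list(seed = seed,
       version = as.character(utils::packageVersion("chemosense")),
       params = list(...))
}

#' Generate a zero-gradient swimming-track dataset
#'
#' Run-tumble tracks for a clonal population with lognormal cell-to-cell
#' variation in speed, bout durations and rotational diffusivity. The median
#' cell's emergent velocity autocovariance is approximately
#' `sigma_v2 * exp(-|t|/tau_v)` when the median phenotype was produced by
#' [calibrate_swim_phenotype()].
#'
#' @param pop a [population_spec()] whose `swim` phenotype carries calibrated
#'   kinematic fields (`speed`, `mean_run`, `mean_tumble`, `persistence`,
#'   `d_rot`)
#' @param env an [environment_spec()]; must have `g = 0` (calibration
#'   experiments are in uniform background)
#' @param duration_s track duration, s; with
#'   `heterogeneous_duration = TRUE`, exponential with this mean (truncated
#'   below at 20 samples) to mimic cells leaving the tracking volume
#' @param dt sampling interval, s; must be <= 0.1 * tau_v
#' @param seed integer seed
#' @param heterogeneous_duration logical
#' @return list of [track()] objects; provenance in `attr(, "provenance")`
#' @export
generate_track_dataset <- function(pop, env, duration_s = 60, dt = 0.05,
                                   seed = 1L, heterogeneous_duration = FALSE) {
  stopifnot(inherits(pop, "population_spec"))
  if (env$g != 0)
    stop("track calibration datasets are generated in uniform background (g = 0)",
         call. = FALSE)
  sw <- pop$swim
  if (any(is.na(c(sw$speed, sw$mean_run, sw$mean_tumble, sw$persistence,
                  sw$d_rot))))
    stop("`pop$swim` must carry calibrated kinematic fields; ",
         "see calibrate_swim_phenotype()", call. = FALSE)
  if (dt > 0.1 * sw$tau_v)
    stop("`dt` must be <= 0.1 * tau_v", call. = FALSE)
  set.seed(seed)
  cv <- pop$cv
  tracks <- lapply(seq_len(pop$n_cells), function(i) {
    dur <- if (heterogeneous_duration)
      max(stats::rexp(1, 1 / duration_s), 20 * dt) else duration_s
    simulate_run_tumble_track(
      speed = lognormal_jitter(sw$speed, cv[["speed"]]),
      mean_run = lognormal_jitter(sw$mean_run, cv[["mean_run"]]),
      mean_tumble = lognormal_jitter(sw$mean_tumble, cv[["mean_tumble"]]),
      persistence = sw$persistence,
      d_rot = lognormal_jitter(sw$d_rot, cv[["d_rot"]]),
      duration = dur, dt = dt,
      meta = list(cell = i))
  })
  attr(tracks, "provenance") <- provenance(seed, duration_s = duration_s,
                                           dt = dt, n_cells = pop$n_cells,
                                           cv = as.list(cv))
  tracks
}

# per-cell kinase phenotype draw
draw_kinase <- function(kin, cv) {
  kinase_phenotype(
    G_r = lognormal_jitter(kin$G_r, cv[["G_r"]]),
    tau_1 = if (kin$tau_1 > 0) lognormal_jitter(kin$tau_1, cv[["tau_1"]]) else 0,
    tau_2 = lognormal_jitter(kin$tau_2, cv[["tau_2"]]),
    D_n = lognormal_jitter(kin$D_n, cv[["D_n"]]),
    tau_n = lognormal_jitter(kin$tau_n, cv[["tau_n"]]),
    a0 = kin$a0)
}

#' Generate a step-response dataset
#'
#' Emulates the alternating up/down concentration-step FRET protocol: each
#' cell's kinase activity is simulated with its own phenotype through the full
#' stimulus sequence (including unimaged adaptation gaps), sampled only during
#' the imaged blocks, and corrupted with white measurement noise. Block
#' metadata labels each sample with block index, direction, and time relative
#' to step onset.
#'
#' @param pop a [population_spec()] with a `kin` phenotype
#' @param env an [environment_spec()]
#' @param protocol a [step_protocol()]
#' @param seed integer seed
#' @param include_arrival_noise simulate molecule-arrival noise too (default
#'   FALSE: its contribution is far below measurement noise at these
#'   backgrounds)
#' @return list of per-cell [time_series()] with `meta$blocks` (data frame:
#'   `block`, `direction`, `onset`) and `meta$truth` (generating parameters)
#' @export
generate_step_response_dataset <- function(pop, env, protocol = step_protocol(),
                                           seed = 1L,
                                           include_arrival_noise = FALSE) {
  stopifnot(inherits(pop, "population_spec"), inherits(protocol, "step_protocol"))
  if (is.null(pop$kin)) stop("`pop$kin` must be supplied", call. = FALSE)
  set.seed(seed)
  pr <- protocol
  block_len <- pr$pre_s + pr$step_s
  cycle <- block_len + pr$recover_s
  n_blocks <- 2 * pr$n_steps
  total_t <- n_blocks * cycle
  sim_dt <- min(0.25, pop$kin$tau_2 / 20,
                if (pop$kin$tau_1 > 0) pop$kin$tau_1 / 4 else Inf)
  t_sim <- seq(0, total_t, by = sim_dt)
  # block b (1-based): starts at (b-1)*cycle; step from pre_s to pre_s+step_s
  onsets <- (seq_len(n_blocks) - 1) * cycle + pr$pre_s
  dirs <- rep(c("up", "down"), pr$n_steps)
  deltas <- ifelse(dirs == "up", pr$delta_up, pr$delta_down)
  conc <- rep(env$c0, length(t_sim))
  # the exact exponential update treats the input as held over the interval
  # ending at each sample, so a step applied strictly after the onset sample
  # reproduces the continuous-time response to a step at the onset exactly
  for (b in seq_len(n_blocks)) {
    in_step <- t_sim > onsets[b] + 1e-9 & t_sim <= onsets[b] + pr$step_s + 1e-9
    conc[in_step] <- env$c0 + deltas[b]
  }
  if (any(conc < 0)) stop("step protocol drives concentration negative", call. = FALSE)
  c_trace <- time_series(t_sim, conc)
  # imaged samples: pre + step windows of each block
  n_samp <- floor(block_len / pr$sample_dt)
  t_block <- (seq_len(n_samp) - 1) * pr$sample_dt
  imaged_t <- as.vector(outer(t_block, (seq_len(n_blocks) - 1) * cycle, `+`))
  block_of <- rep(seq_len(n_blocks), each = n_samp)
  # total imaged time per cell (protocol bookkeeping)
  imaged_total <- n_blocks * block_len
  cells <- lapply(seq_len(pop$n_cells), function(i) {
    kin_i <- draw_kinase(pop$kin, pop$cv)
    G_eff <- resolve_gain(kin_i, env) * env$k_D * max(abs(deltas))
    lin_warn <- G_eff > min(kin_i$a0, 1 - kin_i$a0)
    a <- simulate_kinase(c_trace, kin_i, env,
                         include_arrival_noise = include_arrival_noise,
                         include_internal_noise = TRUE,
                         seed = sample.int(.Machine$integer.max, 1))
    idx <- round(imaged_t / sim_dt) + 1
    vals <- a$values[idx] +
      stats::rnorm(length(idx), 0, pop$measurement_noise_sd)
    time_series(imaged_t, vals,
                meta = list(cell = i, truth = kin_i,
                            linearity_warning = lin_warn,
                            blocks = data.frame(block = seq_len(n_blocks),
                                                direction = dirs,
                                                onset = onsets),
                            block_of = block_of,
                            protocol = pr,
                            imaged_total_s = imaged_total))
  })
  attr(cells, "provenance") <- provenance(seed, protocol = unclass(pr),
                                          n_cells = pop$n_cells,
                                          measurement_noise_sd = pop$measurement_noise_sd)
  cells
}

#' Generate constant-background kinase noise traces
#'
#' Long constant-concentration recordings of kinase activity: per-cell OU
#' internal noise (parameters drawn from the population spec) plus white
#' measurement noise, sampled uniformly.
#'
#' @param pop a [population_spec()] with a `kin` phenotype
#' @param env an [environment_spec()]
#' @param duration_s recording length, s
#' @param dt sampling interval, s
#' @param seed integer seed
#' @return list of per-cell [time_series()] with `meta$truth`
#' @export
generate_noise_dataset <- function(pop, env, duration_s = 1200, dt = 1.0,
                                   seed = 1L) {
  stopifnot(inherits(pop, "population_spec"))
  if (is.null(pop$kin)) stop("`pop$kin` must be supplied", call. = FALSE)
  set.seed(seed)
  n <- ceiling(duration_s / dt)
  tt <- (seq_len(n) - 1) * dt
  cells <- lapply(seq_len(pop$n_cells), function(i) {
    kin_i <- draw_kinase(pop$kin, pop$cv)
    eta <- ou_path(n, dt, kin_i$D_n, kin_i$tau_n)
    vals <- kin_i$a0 + eta +
      stats::rnorm(n, 0, pop$measurement_noise_sd)
    time_series(tt, vals, meta = list(cell = i, truth = kin_i))
  })
  attr(cells, "provenance") <- provenance(seed, duration_s = duration_s,
                                          dt = dt, n_cells = pop$n_cells,
                                          measurement_noise_sd = pop$measurement_noise_sd)
  cells
}
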