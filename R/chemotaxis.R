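# Agent-based run-and-tumble chemotaxis in exponential gradients. Ideal agents
# observe the (Gaussianized) molecule arrival rate; kinase agents carry the
# adaptive response and internal noise and observe only their own activity.
# Both run the exact discrete-time steady-state Kalman recursion of the
# corresponding causal filter and modulate their tumble rate with the running
# signal estimate.

# Exact discretization of a scaled filter model (Van Loan), its steady-state
# discrete Riccati solution and predictor gain, and the joint per-step noise
# covariance used to simulate the model exactly in "ou" mode.
make_discrete_filter <- function(ss, dt, max_iter = 200000, tol = 1e-13) {
  A <- ss$A; n <- nrow(A)
  C <- matrix(ss$C, nrow = 1)
  M <- rbind(cbind(-A, ss$Q), cbind(matrix(0, n, n), t(A))) * dt
  Fm <- as.matrix(Matrix::expm(M))
  F22 <- Fm[n + seq_len(n), n + seq_len(n)]
  Ad <- t(F22)
  Qd <- Ad %*% Fm[seq_len(n), n + seq_len(n)]
  Qd <- (Qd + t(Qd)) / 2
  Psi <- as.matrix(Matrix::expm(rbind(cbind(A, diag(n)),
                                      matrix(0, n, 2 * n)) * dt))[seq_len(n),
                                                                  n + seq_len(n)]
  Sd <- Psi %*% matrix(ss$S, ncol = 1) / dt
  Rd <- ss$R / dt
  # discrete Riccati (predictor form, correlated noise)
  P <- diag(n) * c(1, rep(1e6, n - 1))
  for (i in seq_len(max_iter)) {
    Lam <- as.numeric(C %*% P %*% t(C) + Rd)
    K <- (Ad %*% P %*% t(C) + Sd) / Lam
    Pn <- Ad %*% P %*% t(Ad) + Qd - K %*% t(K) * Lam
    Pn <- (Pn + t(Pn)) / 2
    if (max(abs(Pn - P)) < tol * max(abs(Pn), 1)) { P <- Pn; break }
    P <- Pn
  }
  Lam <- as.numeric(C %*% P %*% t(C) + Rd)
  K <- (Ad %*% P %*% t(C) + Sd) / Lam
  J <- rbind(cbind(Qd, Sd), cbind(t(Sd), Rd))
  list(Ad = Ad, C = C, K = K, P = P, Rd = Rd, Sd = Sd, Qd = Qd,
       innovation_var = Lam,
       rho2_pred = max(0, min(1, 1 - P[1, 1])),
       joint_chol = tryCatch(chol(J + diag(nrow(J)) * 1e-14 * max(diag(J))),
                             error = function(e) NULL))
}

#' Agent configuration for chemotaxis simulations
#'
#' @param cell_type `"ideal"` (observes arrival rate) or `"ecoli"` (observes
#'   kinase activity)
#' @param swim a [swimming_phenotype()] with calibrated kinematic fields
#' @param kin a [kinase_phenotype()] (`ecoli` only; `tau_1 = 0` branch)
#' @param policy_gain tumble-modulation strength `beta` (s): the tumble hazard
#'   is `lambda0 * max(0, 1 - beta * s_hat)`. `NULL` (default) scales the
#'   policy to the estimator: `beta = modulation / sd(s_hat)`, giving both
#'   agent types the same dimensionless modulation depth
#' @param modulation dimensionless modulation depth used when
#'   `policy_gain = NULL`
#' @return an object of class `agent_config`
#' @export
agent_config <- function(cell_type = c("ideal", "ecoli"), swim, kin = NULL,
                         policy_gain = NULL, modulation = 0.5) {
  cell_type <- match.arg(cell_type)
  stopifnot(inherits(swim, "swimming_phenotype"))
  if (cell_type == "ecoli") {
    stopifnot(inherits(kin, "kinase_phenotype"))
    if (kin$tau_1 > 0)
      stop("agents use the tau_1 = 0 kinase branch", call. = FALSE)
  }
  if (!is.null(policy_gain) && policy_gain < 0)
    stop("`policy_gain` must be >= 0", call. = FALSE)
  structure(list(cell_type = cell_type, swim = swim, kin = kin,
                 policy_gain = policy_gain, modulation = modulation),
            class = "agent_config")
}

#' Simulate run-and-tumble agents with online signal estimation
#'
#' Agents swim in an exponential gradient of steepness `g` (from `env`),
#' experience the idealized local signal `s = g * vx`, and update an online
#' estimate `s_hat` with the exact discrete-time steady-state Kalman recursion
#' of their channel's causal filter (ideal: arrivals; ecoli: kinase activity
#' with internal noise). The tumble hazard is
#' `lambda0 * max(0, 1 - beta * s_hat)` during runs.
#'
#' `signal_mode = "ou"` replaces the run-tumble kinematics by the exact
#' jointly-Gaussian discrete model the filter assumes (no behavior); use it to
#' validate estimator correlations against the analytic `rho2`.
#'
#' @param cfg an [agent_config()]
#' @param env an [environment_spec()] (its `g` is used)
#' @param n_agents number of agents
#' @param T simulated time, s
#' @param dt time step, s; must satisfy `dt <= 0.01 * tau_v` in
#'   `"run_tumble"` mode
#' @param seed integer seed
#' @param signal_mode `"run_tumble"` or `"ou"`
#' @param keep_traces number of agents whose full traces are returned
#' @return an object of class `agent_sim`: per-agent up-gradient positions
#'   sampled at ~1 s (`xs`, agents x samples, with `ts`), empirical and
#'   analytic estimator correlations (`rho2_hat`, `rho2_pred`,
#'   `rho2_continuous`), swimming speed `v0`, and `traces` (list of data
#'   frames: `t`, `x`, `s`, `s_hat`, `obs`)
#' @export
simulate_agents <- function(cfg, env, n_agents = 100, T = 500, dt = 0.01,
                            seed = 1L,
                            signal_mode = c("run_tumble", "ou"),
                            keep_traces = 2) {
  signal_mode <- match.arg(signal_mode)
  stopifnot(inherits(cfg, "agent_config"), inherits(env, "environment_spec"))
  sw <- cfg$swim
  if (signal_mode == "run_tumble" && dt > 0.01 * sw$tau_v + 1e-12)
    stop("`dt` must be <= 0.01 * tau_v in run-tumble mode", call. = FALSE)
  if (env$g * sw$speed * T > 1 && signal_mode == "run_tumble")
    warning("|log c| can change by > 1 over the simulation: ",
            "local linearization is strained", call. = FALSE)
  set.seed(seed)
  g <- env$g
  sig_s2 <- g^2 * sw$sigma_v2
  if (sig_s2 == 0 && signal_mode == "ou")
    stop("`signal_mode = \"ou\"` needs g > 0", call. = FALSE)
  zero_signal <- sig_s2 == 0
  if (zero_signal) sig_s2 <- 1e-30  # dummy scale; the filter gain is zeroed
  sig_s <- sqrt(sig_s2)
  ss <- if (cfg$cell_type == "ideal") {
    ss_physical_limit(env$r0, sig_s2, sw$tau_v)
  } else {
    G_r <- resolve_gain(cfg$kin, env)
    ss_kinase(env$r0, sig_s2, sw$tau_v, G_r, cfg$kin$tau_2, cfg$kin$D_n,
              cfg$kin$tau_n)
  }
  fl <- make_discrete_filter(ss, dt)
  if (zero_signal) fl$K[] <- 0
  sol_cont <- if (cfg$cell_type == "ideal") {
    solve_physical_limit_filter(env, sw, g = g * 1e3)
  } else {
    solve_kinase_filter(env, sw, cfg$kin, g = g * 1e3)
  }
  sd_shat <- sig_s * sqrt(fl$rho2_pred)
  beta <- if (is.null(cfg$policy_gain)) {
    if (sd_shat > 0) cfg$modulation / sd_shat else 0
  } else cfg$policy_gain
  n_steps <- ceiling(T / dt)
  nz <- nrow(fl$Ad)
  zhat <- matrix(0, nz, n_agents)
  keep_traces <- min(keep_traces, n_agents)
  trace_idx <- seq_len(keep_traces)
  trace_every <- max(1, round(0.1 / dt))
  traces <- if (keep_traces > 0)
    vector("list", floor(n_steps / trace_every)) else NULL
  # accumulators for the estimator correlation
  acc <- c(ss_ = 0, hh = 0, sh = 0, s1 = 0, h1 = 0, n = 0)
  burn <- ceiling(min(50, T / 5) / dt)

  if (signal_mode == "ou") {
    if (is.null(fl$joint_chol))
      stop("joint noise covariance not positive definite", call. = FALSE)
    z <- matrix(stats::rnorm(nz * n_agents), nz, n_agents)
    # start from the stationary prior of z1 only; others relax over burn-in
    L <- fl$joint_chol
    for (k in seq_len(n_steps)) {
      noise <- t(matrix(stats::rnorm((nz + 1) * n_agents), n_agents) %*% L)
      y <- as.numeric(fl$C %*% z) + noise[nz + 1, ]
      s_true <- sig_s * z[1, ]
      s_hat <- sig_s * zhat[1, ]
      if (k > burn) {
        acc["ss_"] <- acc["ss_"] + sum(s_true^2)
        acc["hh"] <- acc["hh"] + sum(s_hat^2)
        acc["sh"] <- acc["sh"] + sum(s_true * s_hat)
        acc["s1"] <- acc["s1"] + sum(s_true)
        acc["h1"] <- acc["h1"] + sum(s_hat)
        acc["n"] <- acc["n"] + n_agents
      }
      zhat <- fl$Ad %*% zhat + fl$K %*% (y - as.numeric(fl$C %*% zhat))
      z <- fl$Ad %*% z + noise[seq_len(nz), ]
    }
    rho2_hat <- {
      nobs <- acc[["n"]]
      cv <- acc[["sh"]] / nobs - acc[["s1"]] * acc[["h1"]] / nobs^2
      vs <- acc[["ss_"]] / nobs - (acc[["s1"]] / nobs)^2
      vh <- acc[["hh"]] / nobs - (acc[["h1"]] / nobs)^2
      cv^2 / (vs * vh)
    }
    return(structure(list(mode = "ou", rho2_hat = rho2_hat,
                          rho2_pred = fl$rho2_pred,
                          rho2_continuous = sol_cont$rho2,
                          n_agents = n_agents, T = T, dt = dt,
                          n_eff = acc[["n"]] * dt / (2 * sw$tau_v)),
                     class = "agent_sim"))
  }

  # run-tumble mode -------------------------------------------------------
  lambda0 <- 1 / sw$mean_run
  d_tum <- (1 / max(sw$persistence, 1e-6) - 1) / sw$mean_tumble
  sd_run <- sqrt(2 * sw$d_rot * dt); sd_tum <- sqrt(2 * d_tum * dt)
  tumble_speed_frac <- 0.25
  x <- numeric(n_agents); y_pos <- numeric(n_agents)
  theta <- stats::runif(n_agents, 0, 2 * pi)
  running <- stats::runif(n_agents) < sw$p_run
  x_int <- numeric(n_agents)          # integrated signal (log c deviation)
  m <- numeric(n_agents)              # adaptation state (ecoli)
  nn <- if (cfg$cell_type == "ecoli" && cfg$kin$D_n > 0) {
    stats::rnorm(n_agents, 0, sqrt(cfg$kin$D_n * cfg$kin$tau_n))
  } else numeric(n_agents)
  if (cfg$cell_type == "ecoli") {
    G_r <- resolve_gain(cfg$kin, env)
    phi2 <- exp(-dt / cfg$kin$tau_2)
    phin <- exp(-dt / cfg$kin$tau_n)
    sdn <- sqrt(cfg$kin$D_n * cfg$kin$tau_n * (1 - phin^2))
  }
  obs_sd <- sqrt(1 / (env$r0 * dt))   # relative rate noise per step
  x_bound <- if (g > 0) 20 / g else Inf
  keep_every <- max(1, round(1 / dt))
  n_keep <- floor(n_steps / keep_every)
  xs <- matrix(NA_real_, n_agents, n_keep)
  ts <- seq_len(n_keep) * keep_every * dt
  col <- 0L; trow <- 0L
  for (k in seq_len(n_steps)) {
    v <- ifelse(running, sw$speed, tumble_speed_frac * sw$speed)
    vx <- v * cos(theta)
    s_true <- g * vx
    x_int <- x_int + s_true * dt
    eps <- stats::rnorm(n_agents, 0, obs_sd)
    if (cfg$cell_type == "ideal") {
      y_obs <- x_int + eps               # relative arrival-rate deviation
      y_scaled <- y_obs / ss$y_scale
      obs_store <- y_obs
    } else {
      u <- env$r0 * (x_int + eps)        # arrival rate deviation
      a_dev <- -G_r * (u - m) + nn       # a - a0
      m <- phi2 * m + (1 - phi2) * u
      if (cfg$kin$D_n > 0) nn <- phin * nn + stats::rnorm(n_agents, 0, sdn)
      y_scaled <- a_dev / ss$y_scale
      obs_store <- cfg$kin$a0 + a_dev
    }
    s_hat <- sig_s * zhat[1, ]
    if (k > burn) {
      acc["ss_"] <- acc["ss_"] + sum(s_true^2)
      acc["hh"] <- acc["hh"] + sum(s_hat^2)
      acc["sh"] <- acc["sh"] + sum(s_true * s_hat)
      acc["s1"] <- acc["s1"] + sum(s_true)
      acc["h1"] <- acc["h1"] + sum(s_hat)
      acc["n"] <- acc["n"] + n_agents
    }
    if (keep_traces > 0 && k %% trace_every == 0) {
      trow <- trow + 1L
      traces[[trow]] <- cbind(t = k * dt, agent = trace_idx,
                              x = x[trace_idx], s = s_true[trace_idx],
                              s_hat = s_hat[trace_idx],
                              obs = obs_store[trace_idx])
    }
    zhat <- fl$Ad %*% zhat + fl$K %*% (y_scaled - as.numeric(fl$C %*% zhat))
    # behavior: modulated run->tumble hazard, constant tumble->run rate
    hazard <- lambda0 * pmax(0, 1 - beta * s_hat)
    u01 <- stats::runif(n_agents)
    start_tumble <- running & (u01 < hazard * dt)
    end_tumble <- !running & (u01 < dt / sw$mean_tumble)
    running <- (running & !start_tumble) | end_tumble
    theta <- theta + stats::rnorm(n_agents, 0,
                                  ifelse(running, sd_run, sd_tum))
    x <- x + vx * dt
    y_pos <- y_pos + v * sin(theta) * dt
    over <- abs(x) > x_bound
    if (any(over)) x[over] <- sign(x[over]) * (2 * x_bound) - x[over]
    if (k %% keep_every == 0) { col <- col + 1L; xs[, col] <- x }
  }
  nobs <- acc[["n"]]
  cv <- acc[["sh"]] / nobs - acc[["s1"]] * acc[["h1"]] / nobs^2
  vs <- acc[["ss_"]] / nobs - (acc[["s1"]] / nobs)^2
  vh <- acc[["hh"]] / nobs - (acc[["h1"]] / nobs)^2
  tr_out <- NULL
  if (keep_traces > 0) {
    tr_all <- as.data.frame(do.call(rbind, traces[seq_len(trow)]))
    tr_out <- split(tr_all[, c("t", "x", "s", "s_hat", "obs")], tr_all$agent)
  }
  structure(list(mode = "run_tumble", xs = xs, ts = ts,
                 rho2_hat = cv^2 / (vs * vh), rho2_pred = fl$rho2_pred,
                 rho2_continuous = sol_cont$rho2,
                 v0 = sw$speed, g = g, beta = beta,
                 cell_type = cfg$cell_type,
                 info_rate = sol_cont$info_rate,
                 tau_2 = if (cfg$cell_type == "ecoli") cfg$kin$tau_2 else NA,
                 n_agents = n_agents, T = T, dt = dt, seed = seed,
                 traces = tr_out),
            class = "agent_sim")
}

#' @export
print.agent_sim <- function(x, ...) {
  cat(sprintf("agent simulation (%s): n = %d, T = %g s, rho2_hat = %.4g (analytic %.4g)\n",
              x$mode, x$n_agents, x$T, x$rho2_hat, x$rho2_pred))
  invisible(x)
}

#' Chemotactic drift speed
#'
#' Mean up-gradient drift speed over agents, `v_d = mean[(x(T) - x(t0)) / (T -
#' t0)]`, with the standard error over agents. The transient `t0` defaults to
#' `10 * tau_2` for kinase agents (adaptation settling) and `10 * tau_v`
#' otherwise.
#'
#' @param sim an `agent_sim` from [simulate_agents()] (run-tumble mode)
#' @param discard_s transient to discard, s
#' @return list of class `drift_result`: `v_d`, `sem`, `v0`, `n_agents`, `T`
#' @export
drift_speed <- function(sim, discard_s = NULL) {
  stopifnot(inherits(sim, "agent_sim"))
  if (sim$mode != "run_tumble")
    stop("drift is defined for run-tumble simulations", call. = FALSE)
  if (sim$n_agents < 10) stop("need at least 10 agents", call. = FALSE)
  if (is.null(discard_s))
    discard_s <- if (!is.na(sim$tau_2)) 10 * sim$tau_2 else 10
  i0 <- max(1, which(sim$ts >= discard_s)[1])
  iT <- ncol(sim$xs)
  span <- sim$ts[iT] - sim$ts[i0]
  vd_i <- (sim$xs[, iT] - sim$xs[, i0]) / span
  structure(list(v_d = mean(vd_i), sem = stats::sd(vd_i) / sqrt(length(vd_i)),
                 v0 = sim$v0, n_agents = sim$n_agents, T = span,
                 g = sim$g, cell_type = sim$cell_type,
                 info_rate = sim$info_rate),
            class = "drift_result")
}

#' @export
print.drift_result <- function(x, ...) {
  cat(sprintf("drift (%s, g = %g /um): v_d = %.4g +/- %.2g um/s (v0 = %.3g)\n",
              x$cell_type, x$g, x$v_d, x$sem, x$v0))
  invisible(x)
}

#' Information-drift consistency
#'
#' Compares the drift-speed ratio of kinase-observing to ideal agents with the
#' square root of their information-rate ratio, condition by condition:
#' theory predicts `v_a / v_r = sqrt(Idot_a / Idot_r)`.
#'
#' @param drift_ideal,drift_ecoli lists of `drift_result` objects over the
#'   same gradient conditions (matched `env`, `swim`)
#' @return data frame with per-condition `g_mm`, `v_r`, `v_a`, `ratio_drift`,
#'   `se_ratio`, `ratio_info` (`sqrt(Idot_a/Idot_r)`), and `agreement`
#'   (`ratio_drift / ratio_info`) with its standard error
#' @export
info_drift_consistency <- function(drift_ideal, drift_ecoli) {
  stopifnot(length(drift_ideal) == length(drift_ecoli))
  rows <- lapply(seq_along(drift_ideal), function(i) {
    dr <- drift_ideal[[i]]; da <- drift_ecoli[[i]]
    if (abs(dr$g - da$g) > 1e-12)
      stop("mismatched gradient conditions", call. = FALSE)
    ratio <- da$v_d / dr$v_d
    se_ratio <- abs(ratio) *
      sqrt((da$sem / da$v_d)^2 + (dr$sem / dr$v_d)^2)
    ratio_info <- sqrt(da$info_rate / dr$info_rate)
    data.frame(g_mm = dr$g * 1e3, v_r = dr$v_d, v_r_sem = dr$sem,
               v_a = da$v_d, v_a_sem = da$sem,
               ratio_drift = ratio, se_ratio = se_ratio,
               ratio_info = ratio_info,
               agreement = ratio / ratio_info,
               agreement_se = se_ratio / ratio_info)
  })
  do.call(rbind, rows)
}

#' Tune the tumble-policy modulation depth
#'
#' Small grid search over the dimensionless modulation depth maximizing drift
#' at a given gradient; the resulting depth is then held fixed across
#' gradients.
#'
#' @param cfg an [agent_config()]
#' @param env an [environment_spec()]
#' @param depths candidate modulation depths
#' @param n_agents,T,dt,seed simulation settings
#' @return list with `modulation` (best depth) and the search `table`
#' @export
tune_policy_gain <- function(cfg, env, depths = c(0.25, 0.5, 1, 2),
                             n_agents = 200, T = 300, dt = 0.01, seed = 1L) {
  res <- lapply(depths, function(d) {
    cfg$modulation <- d
    sim <- simulate_agents(cfg, env, n_agents = n_agents, T = T, dt = dt,
                           seed = seed, keep_traces = 0)
    dr <- drift_speed(sim)
    data.frame(modulation = d, v_d = dr$v_d, sem = dr$sem)
  })
  tab <- do.call(rbind, res)
  list(modulation = tab$modulation[which.max(tab$v_d)], table = tab)
}
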