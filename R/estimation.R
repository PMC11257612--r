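# Parameter-estimation pipeline: tumble detection, run-fraction binning,
# duration-weighted velocity autocorrelation with exponential fits,
# step-response averaging and kernel fits, OU noise fits by Kalman-filter
# marginal likelihood, the MWC gain fit, and population aggregation with the
# two-term median-uncertainty formula.

wrap_angle <- function(x) atan2(sin(x), cos(x))

#' Detect tumbles in a swimming track
#'
#' A sample is a tumble candidate when its speed drops below
#' `speed_drop_frac` times the cell's median speed or its turn rate exceeds
#' `turn_rate_thresh`. Runs of non-candidates shorter than `min_bout` seconds
#' squeezed between candidates are merged into the surrounding tumble.
#'
#' @param tr a [track()]
#' @param speed_drop_frac speed threshold as a fraction of the median speed
#' @param turn_rate_thresh turn-rate threshold, rad/s
#' @param min_bout shortest bout kept distinct, s
#' @return the track with detected `state` labels; the original labels (if
#'   any) are kept in `meta$state_truth`; attributes `n_tumbles` and `kept`
#'   (TRUE when at least two tumble bouts were detected)
#' @export
detect_tumbles <- function(tr, speed_drop_frac = 0.5, turn_rate_thresh = 6,
                           min_bout = 0.1) {
  stopifnot(inherits(tr, "track"))
  n <- length(tr$t)
  if (n < 3) stop("track shorter than 3 samples", call. = FALSE)
  dt <- tr$dt
  heading <- atan2(tr$vy, tr$vx)
  turn <- c(abs(wrap_angle(diff(heading))), 0) / dt
  med_speed <- stats::median(tr$speed)
  cand <- tr$speed < speed_drop_frac * med_speed | turn > turn_rate_thresh
  # merge run gaps shorter than min_bout between tumble candidates
  r <- rle(cand)
  if (length(r$lengths) > 2) {
    for (i in 2:(length(r$lengths) - 1)) {
      if (!r$values[i] && r$lengths[i] * dt < min_bout &&
          r$values[i - 1] && r$values[i + 1])
        r$values[i] <- TRUE
    }
  }
  cand <- inverse.rle(r)
  out <- tr
  out$meta$state_truth <- tr$state
  out$state <- ifelse(cand, "tumble", "run")
  bouts <- rle(cand)
  attr(out, "n_tumbles") <- sum(bouts$values)
  attr(out, "kept") <- sum(bouts$values) >= 2
  out
}

#' Run fraction and median-bin selection
#'
#' Computes the fraction of time each cell spends in the run state and keeps
#' the cells whose run fraction lies within `half_width` of the population
#' median -- the subset over which velocity statistics are pooled. Cells for
#' which tumble detection kept fewer than two tumbles are dropped first. When
#' the window is empty it is widened (doubling, with a warning) until it is
#' not.
#'
#' @param tracks list of labeled tracks (from [detect_tumbles()] or with
#'   ground-truth labels)
#' @param half_width bin half-width on the run fraction
#' @return list with `p_run` (per retained cell), `median_p_run`, `subset`
#'   (tracks in the median bin), `indices`, `half_width_used`
#' @export
prun_and_bin <- function(tracks, half_width = 0.01) {
  kept <- vapply(tracks, function(tr) {
    k <- attr(tr, "kept")
    is.null(k) || isTRUE(k)
  }, logical(1))
  tracks <- tracks[kept]
  if (!length(tracks)) stop("no tracks retained", call. = FALSE)
  p_run <- vapply(tracks, function(tr) mean(tr$state == "run"), numeric(1))
  med <- stats::median(p_run)
  hw <- half_width
  repeat {
    sel <- abs(p_run - med) <= hw
    if (any(sel)) break
    hw <- hw * 2
    warning("median run-fraction bin empty; widened to +/- ", hw, call. = FALSE)
  }
  list(p_run = p_run, median_p_run = med, subset = tracks[sel],
       indices = which(sel), half_width_used = hw)
}

#' Duration-weighted velocity autocorrelation
#'
#' Per-cell autocovariance of the velocity component `vx`, pooled across the
#' supplied cells as a duration-weighted average at each lag. Per-lag standard
#' errors use the effective sample size `T_total / (2 tau_hat)`, where
#' `tau_hat` comes from a first-pass exponential fit (iterated once).
#'
#' @param tracks list of tracks (typically the median run-fraction subset)
#' @param max_lag_s largest lag, s; truncated with a message if it exceeds the
#'   longest track
#' @return data frame with `lag`, `V`, `se`, plus attributes `total_time` and
#'   `tau_hat`
#' @export
velocity_acf <- function(tracks, max_lag_s = 10) {
  stopifnot(length(tracks) >= 1)
  dt <- tracks[[1]]$dt
  longest <- max(vapply(tracks, function(tr) tr$duration, numeric(1)))
  if (max_lag_s > longest) {
    message("lag grid truncated to the longest track (", signif(longest, 3), " s)")
    max_lag_s <- longest
  }
  nl <- floor(max_lag_s / dt + 1e-9)
  Vmat <- matrix(NA_real_, length(tracks), nl + 1)
  w <- numeric(length(tracks))
  for (i in seq_along(tracks)) {
    ac <- track_vx_acf(tracks[[i]]$vx, dt, max_lag_s)
    Vmat[i, seq_along(ac$acov)] <- ac$acov
    w[i] <- tracks[[i]]$duration
  }
  V <- vapply(seq_len(nl + 1), function(j) {
    ok <- !is.na(Vmat[, j])
    sum(w[ok] * Vmat[ok, j]) / sum(w[ok])
  }, numeric(1))
  lag <- (0:nl) * dt
  T_total <- sum(w)
  tau_hat <- tryCatch({
    keep <- lag >= 2 * dt
    fit_exp_ls(lag[keep], V[keep])[["tau"]]
  }, error = function(e) max(lag[which(V < V[1] / exp(1))[1]], dt))
  for (pass in 1:2) {
    # effective sample count cannot exceed the number of samples pooled
    n_eff <- min(T_total / (2 * tau_hat), T_total / dt)
    se <- sqrt((V[1]^2 + V^2) / n_eff)
    if (pass == 1) {
      keep <- lag >= 2 * dt
      tau_hat <- tryCatch(fit_exp_ls(lag[keep], V[keep])[["tau"]],
                          error = function(e) tau_hat)
    }
  }
  out <- data.frame(lag = lag, V = V, se = se)
  attr(out, "total_time") <- T_total
  attr(out, "tau_hat") <- tau_hat
  out
}

#' Exponential fit of the velocity autocorrelation
#'
#' Fits `V(t) = sigma_v2 * exp(-t / tau_v)` over `fit_range` (excluding lag 0,
#' which carries localization and discretization artifacts) with a Gaussian
#' likelihood using the per-lag standard errors, log-uniform priors, MAP by
#' optimization, and uncertainties from ensemble MCMC.
#'
#' @param V_table output of [velocity_acf()]
#' @param fit_range lag window, s
#' @param seed integer seed
#' @param n_steps MCMC steps
#' @return a `fit_result` with parameters `sigma_v2` and `tau_v`
#' @export
fit_exponential_acf <- function(V_table, fit_range = NULL, seed = 1L,
                                n_steps = 2000) {
  lag <- V_table$lag; V <- V_table$V; se <- V_table$se
  dt <- lag[2] - lag[1]
  if (is.null(fit_range)) fit_range <- c(2 * dt, 10)
  keep <- lag >= fit_range[1] - 1e-12 & lag <= fit_range[2] + 1e-12
  if (sum(keep) < 5) stop("fewer than 5 lags in the fit range", call. = FALSE)
  lag <- lag[keep]; V <- V[keep]; se <- se[keep]
  if (V_table$V[1] <= 0) stop("V(0) must be positive", call. = FALSE)
  init <- fit_exp_ls(lag, V)
  log_lik <- function(th) -0.5 * sum(((V - th[1] * exp(-lag / th[2])) / se)^2)
  fit_map_mcmc(log_lik, c(max(init[["A"]], 1e-12), max(init[["tau"]], 1e-3)),
               names = c("sigma_v2", "tau_v"), seed = seed, n_steps = n_steps)
}

#' Average step responses of one cell
#'
#' Baseline-aligns each imaged block on its pre-step window and averages the
#' responses per direction, with pointwise standard errors over repeats.
#' Blocks with missing samples are tolerated; a direction with fewer than two
#' usable repeats is flagged.
#'
#' @param cell_ts a per-cell [time_series()] from
#'   [generate_step_response_dataset()] (or equivalently structured data with
#'   `meta$blocks`, `meta$block_of`, `meta$protocol`)
#' @return list with elements `up` and `down` (data frames `t_rel`, `mean`,
#'   `sem`, `n`), and `flagged` (directions with < 2 repeats)
#' @export
average_step_response <- function(cell_ts) {
  stopifnot(inherits(cell_ts, "time_series"))
  blocks <- cell_ts$meta$blocks
  block_of <- cell_ts$meta$block_of
  pr <- cell_ts$meta$protocol
  if (is.null(blocks) || is.null(block_of) || is.null(pr))
    stop("time series lacks block metadata", call. = FALSE)
  out <- list(); flagged <- character(0)
  for (dir in c("up", "down")) {
    bs <- blocks$block[blocks$direction == dir]
    curves <- list()
    for (b in bs) {
      sel <- block_of == b & !is.na(cell_ts$values)
      if (!any(sel)) next
      t_rel <- cell_ts$t[sel] - blocks$onset[blocks$block == b]
      v <- cell_ts$values[sel]
      base <- mean(v[t_rel < 0])
      if (!is.finite(base)) next
      curves[[length(curves) + 1]] <- data.frame(t_rel = round(t_rel, 9),
                                                 resp = v - base)
    }
    if (length(curves) < 2) flagged <- c(flagged, dir)
    all_t <- sort(unique(unlist(lapply(curves, `[[`, "t_rel"))))
    M <- vapply(curves, function(cu)
      cu$resp[match(all_t, cu$t_rel)], numeric(length(all_t)))
    M <- matrix(M, nrow = length(all_t))
    mn <- rowMeans(M, na.rm = TRUE)
    nn <- rowSums(!is.na(M))
    sdv <- apply(M, 1, stats::sd, na.rm = TRUE)
    out[[dir]] <- data.frame(t_rel = all_t, mean = mn,
                             sem = sdv / sqrt(pmax(nn, 1)), n = nn)
  }
  out$flagged <- flagged
  out
}

#' Fit the kinase response kernel to averaged step responses
#'
#' Joint MAP fit of the bilobed adaptive response model to the up and down
#' averaged responses of one cell: for a concentration step `delta` at time 0,
#' the predicted activity deviation is
#' `-(G_r kD) * delta * (exp(-t/tau_2) - exp(-t/tau_1))` for `t >= 0`.
#' Gaussian likelihood with the pointwise standard errors, log-uniform priors,
#' `tau_2 > tau_1` enforced through the prior support. The gain is reported in
#' `1/k_D` units (`G_r_kD = G_r * k_D`), which is what step experiments
#' measure without knowledge of `k_D`.
#'
#' @param avg output of [average_step_response()]
#' @param protocol the [step_protocol()] (for the step sizes)
#' @param seed integer seed
#' @param n_steps MCMC steps
#' @param tau1_init initial guess for the fast time, s
#' @param tau1_max upper prior bound on the fast time, s; the fast response is
#'   physically sub-second (far below the adaptation time), and without this
#'   bound weak responses admit spurious high-gain fits with nearly cancelling
#'   lobes
#' @param pool_sem use one pooled standard error per direction when no noise
#'   model is given: the noise is stationary across the block, and pointwise
#'   errors estimated from ten repeats are too noisy to serve as weights
#' @param noise optional correlated-noise model, a list with `D_n`, `tau_n`
#'   (the slow internal-noise parameters, e.g. from the constant-background
#'   noise fits) and `meas_sd`. When supplied, the Gaussian likelihood uses
#'   the full covariance of the repeat-averaged, baseline-subtracted response
#'   (OU internal noise plus white measurement noise, divided by the repeat
#'   count, with the baseline-window projection applied) instead of pointwise
#'   weights -- internal noise has a correlation time comparable to the
#'   adaptation time, so whitening it sharpens `tau_2` considerably
#' @return a `fit_result` with parameters `G_r_kD`, `tau_1`, `tau_2`;
#'   `diagnostics$flat_response` is TRUE when the response amplitude is below
#'   twice the mean standard error (wide posteriors expected)
#' @export
fit_response_kernel <- function(avg, protocol, seed = 1L, n_steps = 2000,
                                tau1_init = 0.5, tau1_max = 2,
                                pool_sem = TRUE, noise = NULL) {
  stopifnot(inherits(protocol, "step_protocol"))
  if (is.null(noise) && pool_sem) {
    for (d in c("up", "down"))
      avg[[d]]$sem <- sqrt(mean(avg[[d]]$sem^2, na.rm = TRUE))
  }
  dat <- rbind(cbind(avg$up, delta = protocol$delta_up),
               cbind(avg$down, delta = protocol$delta_down))
  dat <- dat[is.finite(dat$mean) & is.finite(dat$sem) & dat$sem > 0, ]
  if (max(dat$t_rel) < 10)
    stop("response must include at least 10 s after the step", call. = FALSE)
  amp <- max(abs(dat$mean))
  flat <- amp < 2 * mean(dat$sem)
  whiten <- NULL
  if (!is.null(noise)) {
    # whitening transform per direction from the known noise covariance
    whiten <- list()
    for (d in c("up", "down")) {
      tt <- avg[[d]]$t_rel
      n_rep <- max(stats::median(avg[[d]]$n), 1)
      Sig <- (noise$D_n * noise$tau_n *
                exp(-abs(outer(tt, tt, "-")) / noise$tau_n) +
                diag(length(tt)) * noise$meas_sd^2) / n_rep
      pre <- which(tt < 0)
      A <- diag(length(tt))
      A[, pre] <- A[, pre] - 1 / length(pre)
      Sig <- A %*% Sig %*% t(A) + diag(length(tt)) * 1e-10
      whiten[[d]] <- backsolve(chol(Sig), diag(length(tt)), transpose = TRUE)
    }
  }
  model_dir <- function(th, tt, delta) {
    pred <- numeric(length(tt))
    pos <- tt >= 0
    pred[pos] <- -th[1] * delta *
      (exp(-tt[pos] / th[3]) - exp(-tt[pos] / max(th[2], 1e-12)))
    pred
  }
  log_lik <- if (is.null(noise)) {
    function(th) {
      # identifiability: tau_2 > tau_1, and the fast lobe stays fast
      if (th[3] <= th[2] || th[2] > tau1_max) return(-Inf)
      pred <- c(model_dir(th, avg$up$t_rel, protocol$delta_up),
                model_dir(th, avg$down$t_rel, protocol$delta_down))
      obs <- c(avg$up$mean, avg$down$mean)
      sem <- c(avg$up$sem, avg$down$sem)
      ok <- is.finite(obs) & is.finite(sem) & sem > 0
      -0.5 * sum(((obs[ok] - pred[ok]) / sem[ok])^2)
    }
  } else {
    function(th) {
      if (th[3] <= th[2] || th[2] > tau1_max) return(-Inf)
      ll <- 0
      for (d in c("up", "down")) {
        delta <- if (d == "up") protocol$delta_up else protocol$delta_down
        r <- avg[[d]]$mean - model_dir(th, avg[[d]]$t_rel, delta)
        ll <- ll - 0.5 * sum((whiten[[d]] %*% r)^2)
      }
      ll
    }
  }
  init <- c(max(amp / abs(protocol$delta_up), 1e-6), tau1_init,
            max(protocol$step_s / 4, 2 * tau1_init))
  fit <- fit_map_mcmc(log_lik, init, names = c("G_r_kD", "tau_1", "tau_2"),
                      seed = seed, n_steps = n_steps)
  fit$diagnostics$flat_response <- flat
  fit
}

#' Fit OU internal-noise parameters by Kalman-filter likelihood
#'
#' Marginal likelihood of `(D_n, tau_n)` for a stationary OU process observed
#' with known white measurement noise, computed exactly by a discrete-time
#' Kalman filter (compiled); log-uniform priors, MAP + ensemble-MCMC
#' uncertainties. The trace mean is removed (the OU level is not a parameter
#' of interest). `NA` values are treated as unobserved samples, supporting
#' blockwise-uniform records; genuinely non-uniform sampling is rejected.
#'
#' @param a_trace a [time_series()] of kinase activity
#' @param dt sampling interval, s (checked against the trace)
#' @param measurement_noise_sd known measurement noise sd, activity units
#' @param seed integer seed
#' @param n_steps MCMC steps
#' @return a `fit_result` with parameters `D_n` and `tau_n`;
#'   `diagnostics$at_prior_edge` flags posteriors piling at the prior bounds
#'   (e.g. a noiseless generator)
#' @export
fit_ou_noise <- function(a_trace, dt = NULL, measurement_noise_sd = 0.02,
                         seed = 1L, n_steps = 2000) {
  stopifnot(inherits(a_trace, "time_series"))
  if (is.null(dt)) dt <- a_trace$dt
  if (!isTRUE(a_trace$uniform))
    stop("non-uniform sampling: resample to a uniform grid (NA for gaps)",
         call. = FALSE)
  y <- a_trace$values - mean(a_trace$values, na.rm = TRUE)
  # moment-based initialization
  v_tot <- stats::var(y, na.rm = TRUE)
  v_ou <- max(v_tot - measurement_noise_sd^2, 0.1 * v_tot)
  ac1 <- tryCatch(stats::acf(stats::na.omit(y), lag.max = 5, plot = FALSE)$acf[2],
                  error = function(e) 0.5)
  tau0 <- max(-dt / log(min(max(ac1, 0.05), 0.95)), dt)
  init <- c(v_ou / tau0, tau0)
  fit <- fit_map_mcmc(
    function(th) ou_kalman_loglik(y, dt, th[1], th[2], measurement_noise_sd),
    init, names = c("D_n", "tau_n"), seed = seed, n_steps = n_steps)
  n_t <- sum(!is.na(y))
  if (n_t * dt < 50 * fit$map_estimate[["tau_n"]])
    warning("trace shorter than 50 * tau_n: estimates may be poorly constrained",
            call. = FALSE)
  fit
}

#' Fit the two-state receptor (MWC) gain model across backgrounds
#'
#' Least squares on the logarithms of the measured arrival-rate gains
#' (`G_r * k_D`) against `G_inf / (c0 + K_i)`, with multi-start optimization.
#' When a `sigma` column is present and `weighted = TRUE` (default), the
#' squared log-residuals are weighted by `1/sigma_log^2` with
#' `sigma_log = sigma / G_r_kD`; otherwise all residuals get unit weight
#' (working in log space already balances gains spanning decades).
#'
#' @param gain_table data frame with columns `c0` (uM), `G_r_kD` and
#'   optionally `sigma` (same units as `G_r_kD`)
#' @param weighted use the `sigma` column when present
#' @return list with `G_inf`, `K_i`, `residuals` (log space), `weighted`, and
#'   the objective value
#' @export
fit_mwc <- function(gain_table, weighted = TRUE) {
  stopifnot(all(c("c0", "G_r_kD") %in% names(gain_table)))
  if (nrow(gain_table) < 2) stop("need gains in at least 2 backgrounds", call. = FALSE)
  if (any(gain_table$G_r_kD <= 0)) stop("gains must be positive", call. = FALSE)
  c0 <- gain_table$c0; gkd <- gain_table$G_r_kD
  w <- if (weighted && !is.null(gain_table$sigma)) {
    (gkd / gain_table$sigma)^2
  } else rep(1, length(gkd))
  used_weights <- weighted && !is.null(gain_table$sigma)
  obj <- function(p) sum(w * (log(gkd) - p[1] + log(c0 + exp(p[2])))^2)
  starts <- expand.grid(lG = log(c(0.5, 2, 10) * max(gkd)),
                        lK = log(c(0.1, 1, 10) * stats::median(c0)))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), obj,
                        control = list(reltol = 1e-14, maxit = 5000))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  G_inf <- exp(best$par[1]); K_i <- exp(best$par[2])
  list(G_inf = G_inf, K_i = K_i,
       residuals = log(gkd) - log(G_inf / (c0 + K_i)),
       weighted = used_weights, objective = best$value)
}

#' Population-median estimate with two-term uncertainty
#'
#' For each parameter: the population median of the per-cell point estimates,
#' with variance
#' `(1/N) (1.4826 mad(theta_hat))^2 + (1/N^2) sum_k sigma_k^2`,
#' where `sigma_k = 1.4826 mad(posterior samples of cell k)`. The first term
#' (cell-to-cell variation) scales as `1/N`; the second (single-cell
#' uncertainty) as `1/N^2`.
#'
#' By default the per-cell point estimate is the posterior median rather than
#' the MAP: on weakly identified response fits the optimizer mode sits on a
#' skewed gain/fast-time ridge and is biased upward for weak responses, while
#' the posterior median is stable (both are available in each `fit_result`).
#'
#' @param fits list of `fit_result` objects, one per cell
#' @param parameters parameter names (default: all in the first fit)
#' @param point per-cell point estimate: `"posterior_median"` (default) or
#'   `"map"`
#' @return data frame with `parameter`, `median`, `sem2`, `sem`, `n_cells`
#' @export
population_median_uncertainty <- function(fits, parameters = NULL,
                                          point = c("posterior_median",
                                                    "map")) {
  point <- match.arg(point)
  stopifnot(length(fits) >= 2)
  if (is.null(parameters)) parameters <- names(fits[[1]]$map_estimate)
  N <- length(fits)
  field <- if (point == "map") "map_estimate" else "posterior_median"
  rows <- lapply(parameters, function(p) {
    est <- vapply(fits, function(f) {
      v <- f[[field]]
      if (is.null(v)) v <- f$map_estimate
      v[[p]]
    }, numeric(1))
    sig2 <- vapply(fits, function(f) robust_sd(f$samples[, p])^2, numeric(1))
    sem2 <- (1 / N) * robust_sd(est)^2 + (1 / N^2) * sum(sig2)
    data.frame(parameter = p, median = stats::median(est), sem2 = sem2,
               sem = sqrt(sem2), n_cells = N)
  })
  do.call(rbind, rows)
}

#' First-order uncertainty propagation
#'
#' `sigma_f^2 = sum_i (df/dtheta_i)^2 sigma_i^2` with numeric central-difference
#' gradients, neglecting correlations between parameter uncertainties. Works
#' for scalar- and vector-valued `f` (applied pointwise).
#'
#' @param f function of a named parameter vector
#' @param theta named parameter vector
#' @param sigma_theta named per-parameter standard deviations
#' @param rel_step relative step for the central differences
#' @return list with `value = f(theta)`, `sigma_f`, and the `gradient` matrix
#' @export
propagate_uncertainty <- function(f, theta, sigma_theta, rel_step = 1e-4) {
  f0 <- f(theta)
  grads <- matrix(NA_real_, length(f0), length(theta),
                  dimnames = list(NULL, names(theta)))
  for (i in seq_along(theta)) {
    h <- rel_step * max(abs(theta[i]), 1e-12)
    up <- theta; up[i] <- up[i] + h
    dn <- theta; dn[i] <- dn[i] - h
    gi <- tryCatch((f(up) - f(dn)) / (2 * h), error = function(e) {
      warning("gradient failed for `", names(theta)[i], "`: ",
              conditionMessage(e), call. = FALSE)
      rep(NA_real_, length(f0))
    })
    grads[, i] <- gi
  }
  var_f <- as.vector(grads^2 %*% (sigma_theta[colnames(grads)]^2))
  list(value = f0, sigma_f = sqrt(var_f), gradient = grads)
}

#' Convert a FRET trace to kinase activity
#'
#' Affine normalization between the FRET levels at minimum and maximum kinase
#' activity: `a(t) = (FRET(t) - FRET_min) / (FRET_max - FRET_min)`. Values may
#' exceed `[0, 1]` because of noise and are deliberately not clipped.
#'
#' @param fret_trace a [time_series()] of (photobleach-corrected) FRET values
#' @param fret_min,fret_max anchor levels; `fret_max > fret_min` required
#' @return a [time_series()] of kinase activity
#' @export
fret_to_activity <- function(fret_trace, fret_min, fret_max) {
  stopifnot(inherits(fret_trace, "time_series"))
  if (!(fret_max > fret_min))
    stop("`fret_max` must exceed `fret_min`", call. = FALSE)
  time_series(fret_trace$t,
              (fret_trace$values - fret_min) / (fret_max - fret_min),
              meta = fret_trace$meta)
}

#' FRET anchor levels from saturating-stimulus blocks
#'
#' The minimum-activity anchor is the mean FRET during the saturating
#' stimulus; the maximum-activity anchor is the mean over the first quarter
#' (default 2.5 s) of the response to stimulus removal.
#'
#' @param sat_block FRET values recorded during the saturating stimulus
#' @param removal_block FRET values after stimulus removal (uniform sampling)
#' @param dt sampling interval of `removal_block`, s
#' @param quarter_s averaging window at the start of the removal response, s
#' @return list with `fret_min` and `fret_max`
#' @export
fret_anchors <- function(sat_block, removal_block, dt, quarter_s = 2.5) {
  k <- max(1, floor(quarter_s / dt))
  list(fret_min = mean(sat_block),
       fret_max = mean(removal_block[seq_len(min(k, length(removal_block)))]))
}
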