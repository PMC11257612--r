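# Estimation pipeline: tumble detection, run-fraction binning, velocity ACF,
# exponential/kernel/OU fits, MWC fit, aggregation and error propagation.

test_that("tumble detection recovers generator ground truth", {
  set.seed(1)
  acc <- replicate(20, {
    tr <- chemosense:::simulate_run_tumble_track(
      speed = 18.2, mean_run = 1, mean_tumble = 0.15, persistence = 0.33,
      d_rot = 0.18, duration = 60, dt = 0.05)
    lab <- detect_tumbles(tr)
    mean(lab$state == lab$meta$state_truth)
  })
  expect_gt(mean(acc), 0.9)
})

test_that("degenerate tracks are labeled sensibly", {
  tt <- seq(0, 20, by = 0.05)
  # straight constant-speed track: no tumbles, cell dropped
  straight <- track(tt, 20 * tt, rep(0, length(tt)))
  lab <- detect_tumbles(straight)
  expect_equal(attr(lab, "n_tumbles"), 0)
  expect_false(attr(lab, "kept"))
  # jittering near-zero speed: all samples tumble-labeled via turn rate
  set.seed(2)
  wob <- track(tt, cumsum(rnorm(length(tt), 0, 0.02)),
               cumsum(rnorm(length(tt), 0, 0.02)))
  lab2 <- detect_tumbles(wob)
  expect_gt(mean(lab2$state == "tumble"), 0.95)
  expect_error(detect_tumbles(track(c(0, 1), c(0, 1), c(0, 1))), "3 samples")
})

test_that("run-fraction binning keeps the median bin", {
  set.seed(3)
  pop <- population_spec(swim_calibrated, cv = 0, n_cells = 30)
  tracks <- generate_track_dataset(pop, environment_spec(1, 0),
                                   duration_s = 40, seed = 4)
  # ground-truth labels, identical phenotypes: most cells near the median
  bin <- prun_and_bin(tracks, half_width = 1)   # window spans everything
  expect_equal(length(bin$subset), length(bin$p_run))
  # all-run cell has run fraction one
  tt <- seq(0, 20, by = 0.05)
  allrun <- track(tt, 18 * tt, rep(0, length(tt)),
                  state = rep("run", length(tt)))
  expect_equal(mean(allrun$state == "run"), 1)
  bin2 <- prun_and_bin(list(allrun, allrun, allrun))
  expect_equal(length(bin2$subset), 3)
  expect_equal(bin2$median_p_run, 1)
})

test_that("velocity ACF pools with duration weights", {
  # white-noise velocity: V(t != 0) ~ 0 within its standard error
  set.seed(5)
  tt <- seq(0, 60, by = 0.05)
  x <- cumsum(rnorm(length(tt), 0, 10)) * 0.05
  wn <- track(tt, x, x * 0)
  Vt <- velocity_acf(list(wn), max_lag_s = 5)
  expect_true(all(abs(Vt$V[-1]) < 4 * Vt$se[-1]))
  # duration weighting: pooled V tracks the long cell when the two differ
  mk <- function(speed, dur) {
    t2 <- seq(0, dur, by = 0.05)
    track(t2, speed * 0.05 * cumsum(cos(0.3 * t2)),
          speed * 0.05 * cumsum(sin(0.3 * t2)))
  }
  short <- mk(5, 10); long <- mk(30, 1000)
  V_long <- velocity_acf(list(long), max_lag_s = 3)
  V_pool <- velocity_acf(list(short, long), max_lag_s = 3)
  expect_lt(max(abs(V_pool$V - V_long$V) / abs(V_long$V[1])), 0.02)
  # lag grid truncation for short tracks
  expect_message(velocity_acf(list(mk(10, 4)), max_lag_s = 10), "truncated")
})

test_that("exponential ACF fit recovers noiseless parameters exactly", {
  lag <- seq(0, 10, by = 0.05)
  V <- 146 * exp(-lag / 1.19)
  tab <- data.frame(lag = lag, V = V, se = rep(1e-4, length(lag)))
  fit <- fit_exponential_acf(tab, fit_range = c(0.1, 10), seed = 1,
                             n_steps = 200)
  expect_equal(unname(fit$map_estimate["sigma_v2"]), 146, tolerance = 1e-6)
  expect_equal(unname(fit$map_estimate["tau_v"]), 1.19, tolerance = 1e-6)
  # lag 0 is excluded by construction: corrupting it changes nothing
  tab2 <- tab; tab2$V[1] <- 1e4
  fit2 <- fit_exponential_acf(tab2, fit_range = c(0.1, 10), seed = 1,
                              n_steps = 200)
  expect_equal(fit2$map_estimate, fit$map_estimate, tolerance = 1e-9)
  expect_error(fit_exponential_acf(data.frame(lag = c(0, 1), V = c(-1, 0),
                                              se = c(1, 1))), "5 lags|positive")
})

test_that("step-response averaging flags too few repeats and zero noise", {
  kin <- kinase_phenotype(G_r = 2.28 / kD_ref, tau_1 = 0, tau_2 = 7.4,
                          D_n = 0, tau_n = 8.7, a0 = 0.33)
  pop <- population_spec(swim_calibrated, kin, cv = 0, n_cells = 1,
                         measurement_noise_sd = 0)
  pr <- step_protocol(n_steps = 1)
  cells <- generate_step_response_dataset(pop, environment_spec(1, 0), pr,
                                          seed = 6)
  avg <- average_step_response(cells[[1]])
  expect_setequal(avg$flagged, c("up", "down"))
})

test_that("response-kernel fit recovers noiseless parameters", {
  pr <- step_protocol()
  t_rel <- seq(-7.5, 29.25, by = 0.75)
  model <- function(delta) {
    r <- numeric(length(t_rel)); p <- t_rel >= 0
    r[p] <- -2.28 * delta * (exp(-t_rel[p] / 7.4) - exp(-t_rel[p] / 0.5))
    r
  }
  avg <- list(up = data.frame(t_rel = t_rel, mean = model(pr$delta_up),
                              sem = 1e-5, n = 10),
              down = data.frame(t_rel = t_rel, mean = model(pr$delta_down),
                                sem = 1e-5, n = 10))
  fit <- fit_response_kernel(avg, pr, seed = 1, n_steps = 300)
  expect_equal(unname(fit$map_estimate["G_r_kD"]), 2.28, tolerance = 1e-4)
  expect_equal(unname(fit$map_estimate["tau_2"]), 7.4, tolerance = 1e-4)
  expect_equal(unname(fit$map_estimate["tau_1"]), 0.5, tolerance = 1e-3)
  # identifiability tie-break: every posterior draw satisfies tau_2 > tau_1
  expect_true(all(fit$samples[, "tau_2"] > fit$samples[, "tau_1"]))
  # flat response is flagged
  avg0 <- avg
  set.seed(3)
  avg0$up$mean <- rnorm(length(t_rel), 0, 1e-5); avg0$up$sem <- 1e-4
  avg0$down$mean <- rnorm(length(t_rel), 0, 1e-5); avg0$down$sem <- 1e-4
  fit0 <- fit_response_kernel(avg0, pr, seed = 1, n_steps = 200)
  expect_true(fit0$diagnostics$flat_response)
})

test_that("OU Kalman likelihood equals the dense-covariance oracle", {
  set.seed(7)
  n <- 100; dt <- 1; D <- 8.1e-4; tau <- 8.7; sdm <- 0.02
  y <- as.numeric(arima.sim(list(ar = exp(-1 / tau)), n)) * 0.05 + 0.3
  diffuse <- 1e6
  ll_k <- chemosense:::ou_kalman_loglik(y, dt, D, tau, sdm, diffuse = diffuse)
  # dense MVN with the same proper diffuse-level prior (variance diffuse*var(y))
  vy <- var(y) * (n - 1) / n
  S <- D * tau * exp(-abs(outer(1:n, 1:n, "-")) * dt / tau) +
    diag(n) * sdm^2 + diffuse * vy
  mu <- rep(mean(y), n)
  ll_d <- as.numeric(-0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                               t(y - mu) %*% solve(S, y - mu)))
  expect_equal(ll_k, ll_d, tolerance = 1e-8)
})

test_that("OU noise fit is time-reversal invariant and flags D_n = 0", {
  env0 <- environment_spec(1, 0)
  kin <- kin_median()
  pop <- population_spec(swim_calibrated, kin, cv = 0, n_cells = 1)
  tr <- generate_noise_dataset(pop, env0, duration_s = 600, seed = 8)[[1]]
  ll <- function(v) chemosense:::ou_kalman_loglik(v, 1, 8.1e-4, 8.7, 0.02)
  expect_equal(ll(tr$values), ll(rev(tr$values)), tolerance = 1e-6)
  # noiseless generator: D_n posterior piles at the lower prior edge
  kin0 <- kinase_phenotype(G_r = kin$G_r, tau_2 = 7.4, D_n = 0, tau_n = 8.7,
                           a0 = 0.33)
  pop0 <- population_spec(swim_calibrated, kin0, cv = 0, n_cells = 1)
  tr0 <- generate_noise_dataset(pop0, env0, duration_s = 400, seed = 9)[[1]]
  fit0 <- suppressWarnings(fit_ou_noise(tr0, measurement_noise_sd = 0.02,
                                        seed = 1, n_steps = 300))
  expect_true(fit0$diagnostics$at_prior_edge[["D_n"]])
  # non-uniform sampling rejected
  bad <- time_series(c(0, 1, 3, 7, 8), rnorm(5))
  expect_error(fit_ou_noise(bad, dt = 1), "uniform")
})

test_that("OU noise fit handles illumination gaps as missing samples", {
  env0 <- environment_spec(1, 0)
  pop <- population_spec(swim_calibrated, kin_median(), cv = 0, n_cells = 1)
  tr <- generate_noise_dataset(pop, env0, duration_s = 1200, seed = 10)[[1]]
  gap <- tr
  gap$values[seq(100, 1200, by = 100)] <- NA   # periodic interruptions
  fit <- fit_ou_noise(gap, measurement_noise_sd = 0.02, seed = 2,
                      n_steps = 300)
  expect_lt(abs(log(fit$map_estimate[["tau_n"]] / 8.7)), log(2))
  expect_lt(abs(log(fit$map_estimate[["D_n"]] / 8.1e-4)), log(2.5))
})

test_that("MWC fit recovers exact model data and distinguishes weighting", {
  tab <- data.frame(c0 = c(0.1, 0.5, 2, 10),
                    G_r_kD = 3.5 / (c(0.1, 0.5, 2, 10) + 0.81))
  fit <- fit_mwc(tab)
  expect_equal(fit$G_inf, 3.5, tolerance = 1e-6)
  expect_equal(fit$K_i, 0.81, tolerance = 1e-6)
  expect_false(fit$weighted)
  # asymmetric-error fixture: weighting changes the optimum
  tab2 <- data.frame(c0 = c(0.1, 1, 10), G_r_kD = c(3.2, 2.28, 0.251),
                     sigma = c(0.1, 0.05, 0.009))
  fw <- fit_mwc(tab2, weighted = TRUE)
  fu <- fit_mwc(tab2, weighted = FALSE)
  expect_gt(abs(fw$G_inf - fu$G_inf), 0.1)
  # independent grid oracle for the unweighted optimum
  gr <- expand.grid(Gi = seq(2.5, 4, by = 0.01), Ki = seq(0.4, 1.2, by = 0.01))
  ss <- mapply(function(a, b)
    sum((log(tab2$G_r_kD) - log(a / (tab2$c0 + b)))^2), gr$Gi, gr$Ki)
  best <- gr[which.min(ss), ]
  expect_equal(fu$G_inf, best$Gi, tolerance = 0.01)
  expect_equal(fu$K_i, best$Ki, tolerance = 0.02)
  expect_error(fit_mwc(data.frame(c0 = 1, G_r_kD = 2)), "2 backgrounds")
  expect_error(fit_mwc(data.frame(c0 = c(1, 2), G_r_kD = c(-1, 1))), "positive")
})

test_that("population median uncertainty follows the two-term formula", {
  mk_fit <- function(map, sigma) {
    # samples engineered so 1.4826*mad equals sigma
    s <- map + sigma / 1.4826 * rep(c(-1, 1), 500) * (1 + 1e-12)
    structure(list(map_estimate = c(theta = map),
                   samples = matrix(s, ncol = 1,
                                    dimnames = list(NULL, "theta")),
                   uncertainty = c(theta = sigma)), class = "fit_result")
  }
  fits <- list(mk_fit(1, 0.2), mk_fit(3, 0.3))
  out <- population_median_uncertainty(fits)
  term1 <- (1 / 2) * (1.4826 * 1)^2      # mad of {1, 3} is 1
  term2 <- (1 / 4) * (0.04 + 0.09)
  expect_equal(out$sem2, term1 + term2, tolerance = 1e-6)
  expect_equal(out$median, 2)
  # robust scale matches the Gaussian sd at large n
  set.seed(11)
  x <- rnorm(1e5)
  expect_equal(robust_sd(x), 1, tolerance = 0.02)
  # identical cells with zero posterior spread
  fits0 <- list(mk_fit(2, 0), mk_fit(2, 0))
  expect_equal(population_median_uncertainty(fits0)$sem2, 0)
  # term scalings with N: first ~ 1/N, second ~ 1/N^2
  fitsN <- function(N) lapply(seq_len(N), function(i)
    mk_fit(c(1, 3)[1 + i %% 2], 0.3))
  s4 <- population_median_uncertainty(fitsN(4))$sem2
  s8 <- population_median_uncertainty(fitsN(8))$sem2
  t1_4 <- (1 / 4) * (1.4826 * 1)^2; t2_4 <- (1 / 16) * 4 * 0.09
  t1_8 <- (1 / 8) * (1.4826 * 1)^2; t2_8 <- (1 / 64) * 8 * 0.09
  expect_equal(s4, t1_4 + t2_4, tolerance = 1e-6)
  expect_equal(s8, t1_8 + t2_8, tolerance = 1e-6)
})

test_that("uncertainty propagation is exact for linear and product forms", {
  f_lin <- function(th) 2 * th[["a"]] - 3 * th[["b"]]
  out <- propagate_uncertainty(f_lin, c(a = 1, b = 2), c(a = 0.1, b = 0.2))
  expect_equal(out$sigma_f, sqrt(4 * 0.01 + 9 * 0.04), tolerance = 1e-6)
  f_prod <- function(th) th[["a"]] * th[["b"]]
  out2 <- propagate_uncertainty(f_prod, c(a = 2, b = 5), c(a = 0.2, b = 0.5))
  rel2 <- (0.2 / 2)^2 + (0.5 / 5)^2
  expect_equal(out2$sigma_f, 10 * sqrt(rel2), tolerance = 1e-4)
})

test_that("propagated efficiency uncertainty is on the printed scale", {
  # eta at c0 = 1 uM with the printed parameter uncertainties
  theta <- c(sigma_v2 = 146, tau_v = 1.19, G_r_kD = 2.28, tau_2 = 7.4,
             D_n = 8.1e-4, tau_n = 8.7)
  sigma <- c(sigma_v2 = 5, tau_v = 0.01, G_r_kD = 0.05, tau_2 = 0.3,
             D_n = 0.9e-4, tau_n = 0.9)
  f <- function(th) {
    env <- env_1uM()
    sw <- swimming_phenotype(th[["sigma_v2"]], th[["tau_v"]])
    kn <- kinase_phenotype(G_r = th[["G_r_kD"]] / env$k_D, tau_1 = 0,
                           tau_2 = th[["tau_2"]], D_n = th[["D_n"]],
                           tau_n = th[["tau_n"]])
    efficiency_eta(env, sw, kn, g = 0)
  }
  out <- propagate_uncertainty(f, theta, sigma)
  expect_gt(out$sigma_f, 5e-4)
  expect_lt(out$sigma_f, 6e-3)
})

test_that("FRET normalization is affine-invariant", {
  tt <- 0:99
  set.seed(12)
  fr <- time_series(tt, 0.5 + 0.1 * sin(tt / 5) + rnorm(100, 0, 0.01))
  a1 <- fret_to_activity(fr, 0.4, 0.7)
  expect_equal(a1$values, (fr$values - 0.4) / 0.3)
  fr2 <- time_series(tt, 3 * fr$values + 2)
  a2 <- fret_to_activity(fr2, 3 * 0.4 + 2, 3 * 0.7 + 2)
  expect_equal(a1$values, a2$values, tolerance = 1e-12)
  expect_equal(fret_to_activity(time_series(0:1, c(0.4, 0.7)), 0.4, 0.7)$values,
               c(0, 1))
  expect_error(fret_to_activity(fr, 0.5, 0.5), "exceed")
  anch <- fret_anchors(rep(0.35, 10), seq(0.8, 0.6, length.out = 20), dt = 0.5,
                       quarter_s = 2.5)
  expect_equal(anch$fret_min, 0.35)
  expect_equal(anch$fret_max, mean(seq(0.8, 0.6, length.out = 20)[1:5]))
})
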