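# Forward models: signal statistics, arrivals, response kernel, MWC gain,
# kinase simulation.

test_that("signal autocovariance follows the exponential form", {
  g <- g_per_um(0.4)  # 0.4 mm^-1
  expect_equal(signal_autocovariance(swim_median, g, 0), g^2 * 146)
  expect_equal(signal_autocovariance(swim_median, g, 0), 2.336e-5,
               tolerance = 1e-3)
  expect_equal(signal_autocovariance(swim_median, 0, 3.2), 0)
  expect_equal(signal_autocovariance(swim_median, g, 1.19),
               exp(-1) * signal_autocovariance(swim_median, g, 0))
  expect_equal(signal_autocovariance(swim_median, g, -2.5),
               signal_autocovariance(swim_median, g, 2.5))
  expect_error(signal_autocovariance(swim_median, g, NaN), "lag")
})

test_that("capture rate constant reproduces the diffusive-capture value", {
  kD <- capture_rate_constant(800, 0.06)
  expect_equal(kD, 1.2e5, tolerance = 0.05)
  expect_equal(capture_rate_constant(800, 0), 0)
  expect_error(capture_rate_constant(-1, 0.06))
  # background arrival rate at 0.1 uM
  env <- environment_spec(c0 = 0.1)
  expect_equal(env$r0, 1.2e4, tolerance = 0.05)
  expect_equal(env$r0, env$k_D * env$c0)
})

test_that("arrival sampling matches Poisson statistics and modes agree", {
  env <- environment_spec(c0 = 1)
  dt <- 1e-3
  n <- 1e4
  ct <- time_series(seq(0, by = dt, length.out = n), rep(1, n))
  # r0*dt ~ 116 >> 10
  po <- sample_arrivals(ct, env, "poisson_events", seed = 2)
  ga <- sample_arrivals(ct, env, "gaussian_rate", seed = 2)
  lam <- env$r0 * dt
  # mean within 3 SE
  expect_lt(abs(mean(po$values) - lam), 3 * sqrt(lam / n))
  expect_lt(abs(mean(ga$values) * dt - lam), 3 * sqrt(lam / n))
  # index of dispersion ~ 1 within 3 SE (var of sample variance ~ 2 lam^2/n)
  expect_lt(abs(var(po$values) / lam - 1), 3 * sqrt(2 / n) + 3 / sqrt(lam * n))
  # distributional agreement between modes
  ks <- suppressWarnings(stats::ks.test(po$values, ga$values * dt))
  expect_lt(unname(ks$statistic), 0.05)
  # determinism
  po2 <- sample_arrivals(ct, env, "poisson_events", seed = 2)
  expect_identical(po$values, po2$values)
  expect_error(sample_arrivals(time_series(c(0, 1), c(-1, 1)), env), "increasing|>= 0")
})

test_that("response kernel adapts perfectly and has the stated lobes", {
  kin <- kin_median(tau_1 = 0.5)
  G_r <- kin$G_r
  tt <- seq(0, 200, by = 1e-3)
  k <- response_kernel(kin, tt)
  expect_lt(abs(sum(k$smooth) * 1e-3 + k$impulse_weight), 1e-3 * G_r)
  expect_equal(response_kernel(kin, 1e-12)$smooth[1],
               G_r * (1 / 0.5 - 1 / 7.4), tolerance = 1e-6)
  k0 <- response_kernel(kin_median(tau_1 = 0), tt)
  expect_equal(k0$impulse_weight, kin_median()$G_r)
  expect_true(all(response_kernel(kin, c(-3, -0.1))$smooth == 0))
  expect_error(kinase_phenotype(G_r = 1, tau_1 = 8, tau_2 = 7.4,
                                D_n = 0, tau_n = 1), "tau_2")
})

test_that("step response peaks at G_r*dr and adapts back (analytic oracle)", {
  env <- environment_spec(c0 = 1)
  kin <- kin_median(tau_1 = 0)
  dt <- 0.1
  tt <- seq(0, 120, by = dt)
  dc <- 0.1
  conc <- ifelse(tt >= 40, 1 + dc, 1)
  a <- simulate_kinase(time_series(tt, conc), kin, env,
                       include_arrival_noise = FALSE,
                       include_internal_noise = FALSE)
  dr <- env$k_D * dc
  resp <- a$values - kin$a0
  # analytic: -dr * G_r * exp(-t/tau_2) after the step (tau_1 = 0)
  post <- tt >= 40
  expect_equal(min(resp), -dr * kin$G_r, tolerance = 0.02)
  expect_equal(resp[post][2:100],
               -dr * kin$G_r * exp(-(tt[post][2:100] - 40) / 7.4),
               tolerance = 0.03)
  # perfect adaptation: back to a0 to tolerance 1e-3
  expect_lt(abs(a$values[length(tt)] - kin$a0), 1e-3)
})

test_that("MWC gain has the stated limits and fitted-scale value", {
  expect_equal(mwc_gain(1, 3.5, 0.81)$G_r_kD, 1.934, tolerance = 1e-3)
  # linear-sensing limit c0 << K_i
  expect_equal(mwc_gain(1e-6, 3.5, 0.81)$G_r_kD, 3.5 / 0.81, tolerance = 1e-4)
  # log-sensing: G_r_kD ~ G_inf/c0
  expect_equal(mwc_gain(1e4, 3.5, 0.81)$G_r_kD * 1e4, 3.5, tolerance = 1e-3)
  cs <- 10^seq(-2, 2, length.out = 30)
  gk <- mwc_gain(cs, 3.5, 0.81)
  expect_true(all(diff(gk$G_r_kD) < 0))   # decreasing in c0
  expect_true(all(diff(gk$G) > 0))        # G increasing in c0
  expect_error(mwc_gain(0, 3.5, 0.81, k_D = kD_ref), "c0 = 0")
})

test_that("kinase simulation is flat without noise and has OU noise stats", {
  env <- environment_spec(c0 = 1)
  kin <- kin_median()
  n <- 1200
  ct <- time_series(seq_len(n) - 1, rep(1, n))
  a0trace <- simulate_kinase(ct, kin, env, include_arrival_noise = FALSE,
                             include_internal_noise = FALSE)
  expect_true(all(abs(a0trace$values - kin$a0) < 1e-12))
  # stationary variance Dn*tau_n = 7.047e-3 within 3 SE over 50 cells
  svar_target <- 8.1e-4 * 8.7
  vars <- vapply(1:50, function(i) {
    a <- simulate_kinase(ct, kin, env, include_arrival_noise = FALSE,
                         include_internal_noise = TRUE, seed = i)
    var(a$values)
  }, numeric(1))
  n_eff <- n / (2 * 8.7)
  se <- svar_target * sqrt(2 / n_eff) / sqrt(50)
  expect_lt(abs(mean(vars) - svar_target), 3 * se)
  # autocorrelation time of the noise ~ tau_n (pooled exponential fit)
  acs <- sapply(1:50, function(i) {
    a <- simulate_kinase(ct, kin, env, include_arrival_noise = FALSE,
                         include_internal_noise = TRUE, seed = 100 + i)
    stats::acf(a$values, lag.max = 25, plot = FALSE, type = "covariance",
               demean = TRUE)$acf[, 1, 1]
  })
  fit <- chemosense:::fit_exp_ls(1:20, rowMeans(acs)[2:21])
  expect_lt(abs(fit[["tau"]] - 8.7), 3 * 8.7 / sqrt(50 * n / (2 * 8.7)) * 3)
  # determinism and dt warning/error behavior
  a1 <- simulate_kinase(ct, kin, env, include_arrival_noise = FALSE, seed = 7)
  a2 <- simulate_kinase(ct, kin, env, include_arrival_noise = FALSE, seed = 7)
  expect_identical(a1$values, a2$values)
  expect_error(suppressWarnings(
    simulate_kinase(time_series(c(0, 1, 2), c(1, 1.2, 1)), kin, env)),
    "tau_2/20")
})

test_that("OU generator matches its stated correlation function", {
  # empirical correlation function vs D*tau*exp(-|dt|/tau) pointwise
  set.seed(5)
  D <- 8.1e-4; tau <- 8.7; dt <- 1; n <- 600; n_tr <- 200
  lags <- c(2, 5, 9, 17)
  emp <- matrix(0, n_tr, length(lags) + 1)
  for (i in seq_len(n_tr)) {
    x <- chemosense:::ou_path(n, dt, D, tau)
    ac <- stats::acf(x, lag.max = max(lags), plot = FALSE,
                     type = "covariance", demean = FALSE)$acf[, 1, 1]
    emp[i, ] <- ac[c(1, lags + 1)]
  }
  theo <- D * tau * exp(-c(0, lags) * dt / tau)
  se <- apply(emp, 2, sd) / sqrt(n_tr)
  expect_true(all(abs(colMeans(emp) - theo) < 3.5 * se))
})

test_that("Poisson and Gaussian arrival modes give matching kinase traces", {
  # feed both arrival streams through the same response filtering and compare
  # first and second moments (r0*dt >= 100)
  env <- environment_spec(c0 = 1)
  kin <- kinase_phenotype(G_r = 2.28 / env$k_D, tau_1 = 0, tau_2 = 0.5,
                          D_n = 0, tau_n = 1, a0 = 0.33)
  dt <- 1e-3; n <- 3e4
  ct <- time_series(seq(0, by = dt, length.out = n), rep(1, n))
  po <- sample_arrivals(ct, env, "poisson_events", seed = 3)
  ga <- sample_arrivals(ct, env, "gaussian_rate", seed = 4)
  make_activity <- function(r) {
    dr <- r - env$r0
    a <- kin$a0 - kin$G_r * (dr - chemosense:::exp_smooth(dr, dt, kin$tau_2, 0))
    a[-seq_len(10000)]   # discard the smoother transient
  }
  ap <- make_activity(po$values / dt)
  ag <- make_activity(ga$values)
  # coarse-grain to ~independent samples before comparing moments
  cg <- function(x) colMeans(matrix(x, nrow = 1000))
  mp <- cg(ap); mg <- cg(ag)
  se_mean <- sqrt(var(mp) / length(mp) + var(mg) / length(mg))
  expect_lt(abs(mean(mp) - mean(mg)), 3 * se_mean)
  expect_lt(abs(log(var(ap) / var(ag))), 3 * sqrt(2 / 20 + 2 / 20))
})
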