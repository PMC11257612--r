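# Causal-filter theory: SNRs, information rates, dual-solver agreement,
# asymptotic limits, efficiency, PSD decomposition, population variability.

test_that("arrival SNR matches its closed form and printed value", {
  env <- env_1uM(g = 0.05)
  gr <- gamma_r(env, swim_median)
  expect_equal(gr, 2 * env$r0 * env$g^2 * 146 * 1.19^3)
  expect_equal(gr, 0.15, tolerance = 0.01 / 0.15)
  expect_equal(gamma_r(env_1uM(0), swim_median), 0)
  expect_equal(gamma_r(env_1uM(0.4), swim_median), 9.4, tolerance = 0.05)
})

test_that("kinase SNR scales as stated", {
  env <- env_1uM(g = 0.05)
  kin <- kin_median()
  ga <- gamma_a(env, swim_median, kin)
  # ratio identity: gamma_r/gamma_a = 2 tau_v^2 D_n / (G_r^2 r0)
  expect_equal(gamma_r(env, swim_median) / ga,
               2 * 1.19^2 * 8.1e-4 / (kin$G_r^2 * env$r0))
  expect_equal(gamma_r(env, swim_median) / ga, 53, tolerance = 0.06)
  expect_equal(gamma_a(env_1uM(0), swim_median, kin), 0)
  kin2 <- kin_median(G_r_kD = 2 * 2.28)
  expect_equal(gamma_a(env, swim_median, kin2), 4 * ga)
  kin0 <- kinase_phenotype(G_r = kin$G_r, tau_2 = 7.4, D_n = 0, tau_n = 8.7)
  expect_identical(gamma_a(env, swim_median, kin0), Inf)
})

test_that("information rate from correlation follows the Gaussian identity", {
  expect_equal(info_rate_from_rho(0, 2), 0)
  expect_equal(info_rate_from_rho(0.5, 2), 0.5)
  expect_equal(info_rate_from_rho(1e-6, 1.19), 1e-6 / 1.19, tolerance = 1e-5)
  expect_equal(info_rate_from_rho(0.5, 2, units = "bits"), 0.5 / log(2))
  expect_error(info_rate_from_rho(1, 2), "infinite")
})

test_that("physical limit reproduces the small-signal form", {
  # the leading correction to the small-signal form is 2*sqrt(gamma_r), so the
  # ratio approaches 1 from below as the gradient vanishes
  env <- env_1uM()
  ratios <- vapply(c(1e-4, 1e-6), function(gr) {
    g_target <- sqrt(gr / (2 * env$r0 * 146 * 1.19^3)) * 1e3  # mm^-1
    sol <- solve_physical_limit_filter(env, swim_median, g = g_target)
    sol$info_rate / (gr / (4 * 1.19))
  }, numeric(1))
  expect_equal(ratios[1], 1 - 2 * sqrt(1e-4), tolerance = 1e-3)
  expect_equal(ratios[2], 1, tolerance = 0.01)
  expect_true(ratios[2] > ratios[1])
  # g = 0 gives no information
  sol0 <- solve_physical_limit_filter(env, swim_median, g = 0)
  expect_equal(sol0$rho2, 0)
  expect_equal(sol0$info_rate, 0)
})

test_that("Riccati and spectral factorization agree to 1e-6 on a 10x10 grid", {
  c0s <- 10^seq(-1, 1, length.out = 10)
  gs <- seq(0.04, 0.4, length.out = 10)
  worst_r <- 0; worst_a <- 0
  for (cc in c0s) for (g in gs) {
    env <- environment_spec(c0 = cc, g = g)
    kin <- kin_median()
    r1 <- solve_physical_limit_filter(env, swim_median)
    r2 <- solve_physical_limit_filter(env, swim_median, method = "spectral")
    a1 <- solve_kinase_filter(env, swim_median, kin)
    a2 <- solve_kinase_filter(env, swim_median, kin, method = "spectral")
    worst_r <- max(worst_r, abs(r1$posterior_var - r2$posterior_var) /
                              r1$posterior_var)
    worst_a <- max(worst_a, abs(a1$posterior_var - a2$posterior_var) /
                              a1$posterior_var)
  }
  expect_lt(worst_r, 1e-6)
  expect_lt(worst_a, 1e-6)
})

test_that("kinase filter limits: noiseless sensor and internal-noise-dominated", {
  env <- env_1uM(0.05)
  # gamma_a -> Inf (D_n -> 0): kinase rate -> physical limit within 1%
  kin_small <- kinase_phenotype(G_r = 2.28 / kD_ref, tau_2 = 7.4,
                                D_n = 8.1e-12, tau_n = 8.7)
  ir <- solve_physical_limit_filter(env, swim_median)
  ia <- solve_kinase_filter(env, swim_median, kin_small)
  expect_equal(ia$info_rate / ir$info_rate, 1, tolerance = 0.01)
  # D_n = 0 exactly: data-processing equality branch
  kin0 <- kinase_phenotype(G_r = 2.28 / kD_ref, tau_2 = 7.4, D_n = 0,
                           tau_n = 8.7)
  ia0 <- solve_kinase_filter(env, swim_median, kin0)
  expect_equal(ia0$info_rate, ir$info_rate)
  # gamma_a/gamma_r -> 0 with matched adaptation and noise time scales:
  # the rate approaches gamma_a/(4 tau_v) within 1%
  envs <- env_1uM(0.01)
  kin_big <- kinase_phenotype(G_r = 2.28 / kD_ref, tau_2 = 7.4, D_n = 8.1e-4 * 1e6,
                              tau_n = 7.4)
  ga <- gamma_a(envs, swim_median, kin_big)
  ia_big <- solve_kinase_filter(envs, swim_median, kin_big)
  expect_lt(ga / gamma_r(envs, swim_median), 1e-4)
  expect_equal(ia_big$info_rate / (ga / (4 * 1.19)), 1, tolerance = 0.01)
  # g = 0 gives no information
  expect_equal(solve_kinase_filter(env_1uM(0), swim_median, kin_median())$info_rate, 0)
})

test_that("both rates scale as g^2 in the shallow-gradient regime", {
  env <- env_1uM()
  kin <- kin_median()
  gs <- c(1e-4, 3e-4, 1e-3)  # mm^-1; saturation corrections O(sqrt(gamma_r))
  per_g2_r <- vapply(gs, function(g)
    solve_physical_limit_filter(env, swim_median, g = g)$info_rate / g^2,
    numeric(1))
  per_g2_a <- vapply(gs, function(g)
    solve_kinase_filter(env, swim_median, kin, g = g)$info_rate / g^2,
    numeric(1))
  expect_lt(diff(range(per_g2_r)) / mean(per_g2_r), 0.02)
  expect_lt(diff(range(per_g2_a)) / mean(per_g2_a), 0.02)
  # saturation: info per g^2 decreases as the gradient steepens
  sat <- vapply(c(0.1, 0.2, 0.4), function(g)
    solve_physical_limit_filter(env, swim_median, g = g)$info_rate / g^2,
    numeric(1))
  expect_true(all(diff(sat) < 0))
  expect_lt(sat[3], per_g2_r[1])
})

test_that("physical limit is monotone in r0 and tau_v and saturates in gamma_r", {
  g <- 0.1
  rates_r0 <- vapply(c(0.3, 1, 3, 10), function(cc)
    solve_physical_limit_filter(environment_spec(cc, g), swim_median)$info_rate,
    numeric(1))
  expect_true(all(diff(rates_r0) > 0))
  rates_tv <- vapply(c(0.6, 1.19, 2.4), function(tv)
    solve_physical_limit_filter(env_1uM(g),
                                swimming_phenotype(146, tv))$info_rate,
    numeric(1))
  expect_true(all(diff(rates_tv) > 0))
  # sub-linear growth of the rate with gamma_r at large gamma_r
  i1 <- solve_physical_limit_filter(env_1uM(0.4), swim_median)$info_rate
  i2 <- solve_physical_limit_filter(env_1uM(4), swim_median)$info_rate
  expect_lt(i2 / i1, 100^0.75)
})

test_that("data-processing inequality holds strictly with internal noise", {
  kin <- kin_median()
  for (cc in c(0.1, 1, 10)) for (g in c(0.05, 0.2, 0.4)) {
    env <- environment_spec(cc, g)
    ir <- solve_physical_limit_filter(env, swim_median)
    ia <- solve_kinase_filter(env, swim_median, kin)
    expect_lt(ia$info_rate, ir$info_rate)
  }
})

test_that("efficiency has a single interior peak near K_i and rises with g", {
  env <- env_1uM()
  # eta(c0) in the shallow limit using the MWC gain
  eta_of <- function(c0) {
    e <- environment_spec(c0, 0.05)
    kin <- kinase_phenotype(G_inf = 3.5, K_i = 0.81, tau_2 = 7.4,
                            D_n = 8.1e-4, tau_n = 8.7)
    efficiency_eta(e, swim_median, kin, g = 0)
  }
  opt <- stats::optimize(function(lc) -eta_of(exp(lc)), c(log(0.05), log(20)),
                         tol = 1e-4)
  c_peak <- exp(opt$minimum)
  expect_gt(c_peak, 0.81 / 2)
  expect_lt(c_peak, 0.81 * 2.5)
  # single interior maximum: eta increases below, decreases above
  cs <- 10^seq(-1.3, 1.3, length.out = 15)
  etas <- vapply(cs, eta_of, numeric(1))
  ipk <- which.max(etas)
  expect_true(ipk > 1 && ipk < length(cs))
  expect_true(all(diff(etas[1:ipk]) > 0))
  expect_true(all(diff(etas[ipk:length(etas)]) < 0))
  # eta rises with gradient steepness at c0 = 1 uM
  etag <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.4), function(g)
    efficiency_eta(env, swim_median, kin_median(), g = g), numeric(1))
  expect_true(all(diff(etag) > 0))
  # ideal-sensor limit
  kin_id <- kinase_phenotype(G_r = 2.28 / kD_ref, tau_2 = 7.4, D_n = 8.1e-14,
                             tau_n = 8.7)
  expect_equal(efficiency_eta(env, swim_median, kin_id, g = 0.1), 1,
               tolerance = 0.01)
})

test_that("noise PSD decomposition is normalized and internally dominated", {
  env <- env_1uM()
  kin <- kin_median()
  expect_error(noise_psd_components(env, kin, c(-1, 1)), "omega")
  # omega -> 0 limit of the internal-noise PSD
  low <- noise_psd_components(env, kin, 1e-9)
  expect_equal(low$internal, 2 * 8.1e-4 * 8.7^2, tolerance = 1e-6)
  # variance normalization: integral of the internal PSD = D_n tau_n
  iv <- stats::integrate(function(w)
    noise_psd_components(env, kin, w)$internal / pi, 0, Inf,
    rel.tol = 1e-9)$value
  expect_equal(iv, 8.1e-4 * 8.7, tolerance = 1e-6)
  # internal noise exceeds filtered arrival noise over the observable band
  f <- 10^seq(-3, log10(0.5), length.out = 50)
  tab <- noise_psd_components(env, kin, 2 * pi * f)
  expect_true(all(tab$internal > tab$arrival))
  expect_equal(tab$total, tab$internal + tab$arrival)
})

test_that("Berg-Purcell threshold check uses the strict 16/3 criterion", {
  rep1 <- berg_purcell_check(env_1uM(0.05), swim_median)
  expect_equal(rep1$threshold, 16 / 3)
  expect_false(rep1$passes)
  expect_equal(rep1$gamma_r, 0.15, tolerance = 0.01 / 0.15)
  rep2 <- berg_purcell_check(env_1uM(0.4), swim_median)
  expect_true(rep2$passes)
  expect_equal(rep2$gamma_r, 9.4, tolerance = 0.05)
  # exactly at threshold: not passing (strict inequality)
  env_b <- env_1uM(0.05)
  g_b <- sqrt((16 / 3) / (2 * env_b$r0 * 146 * 1.19^3))
  rep3 <- berg_purcell_check(env_b, swim_median, g = g_b * 1e3)
  expect_equal(rep3$gamma_r, 16 / 3, tolerance = 1e-12)
  expect_false(rep3$passes)
})

test_that("population efficiency percentiles propagate phenotype diversity", {
  env <- env_1uM()
  kin <- kin_median()
  # zero spread: all percentiles equal the median-cell eta
  p0 <- population_eta_percentiles(env, swim_median, kin, cv = c(G_r = 0),
                                   n_mc = 10, seed = 1)
  eta_med <- efficiency_eta(env, swim_median, kin, g = 0)
  expect_true(all(abs(p0$percentiles - eta_med) < 1e-12))
  # lognormal spreads: upper tail within an order of magnitude of the median
  cvv <- c(sigma_v2 = 0.3, tau_v = 0.2, G_r = 0.4, tau_2 = 0.2, D_n = 0.6,
           tau_n = 0.2)
  p1 <- population_eta_percentiles(env, swim_median, kin, cv = cvv,
                                   n_mc = 300, seed = 3)
  ratio <- p1$percentiles[["95%"]] / p1$percentiles[["50%"]]
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 12)
  # still far from the physical limit
  expect_lt(p1$percentiles[["95%"]], 0.5)
  # seeded reproducibility
  p2 <- population_eta_percentiles(env, swim_median, kin, cv = cvv,
                                   n_mc = 300, seed = 3)
  expect_identical(p1$percentiles, p2$percentiles)
})

test_that("exported optimal kernel integrates the observation sensibly", {
  env <- env_1uM(0.2)
  sol <- solve_physical_limit_filter(env, swim_median)
  k <- filter_kernel(sol, seq(0, 10, by = 0.1))
  expect_equal(nrow(k), 101)
  expect_true(all(is.finite(k$kernel)))
  # the kernel decays: tail far below peak magnitude
  expect_lt(max(abs(k$kernel[k$t > 8])), 0.05 * max(abs(k$kernel)))
})
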