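# Causal-filtering information theory: signal-to-noise ratios, steady-state
# posterior variances, behaviorally-relevant information rates, sensing
# efficiency, and the noise power-spectrum decomposition.

#' Arrival signal-to-noise ratio
#'
#' Dimensionless signal-to-noise ratio of molecule arrivals,
#' `gamma_r = 2 r0 g^2 sigma_v2 tau_v^3`. Values much below 1 put the
#' physical limit in its small-signal regime.
#'
#' @param env an [environment_spec()]
#' @param swim a [swimming_phenotype()]
#' @return dimensionless `gamma_r`
#' @export
gamma_r <- function(env, swim) {
  stopifnot(inherits(env, "environment_spec"),
            inherits(swim, "swimming_phenotype"))
  2 * env$r0 * env$g^2 * swim$sigma_v2 * swim$tau_v^3
}

#' Kinase-activity signal-to-noise ratio
#'
#' Dimensionless signal-to-noise ratio of kinase activity,
#' `gamma_a = (G_r^2 / D_n) r0^2 g^2 sigma_v2 tau_v`. An ideal noiseless
#' sensor corresponds to `gamma_a -> Inf`; `D_n = 0` therefore returns `Inf`.
#'
#' @inheritParams gamma_r
#' @param kin a [kinase_phenotype()]
#' @return dimensionless `gamma_a` (possibly `Inf`)
#' @export
gamma_a <- function(env, swim, kin) {
  stopifnot(inherits(kin, "kinase_phenotype"))
  G_r <- resolve_gain(kin, env)
  if (kin$D_n == 0) return(Inf)
  (G_r^2 / kin$D_n) * env$r0^2 * env$g^2 * swim$sigma_v2 * swim$tau_v
}

#' Information rate from estimator correlation
#'
#' For jointly Gaussian signal and observations the behaviorally-relevant
#' (transfer-entropy = predictive-information) rate depends only on the
#' squared correlation `rho2` between the signal and its optimal causal
#' estimate: the predictive information `I(tau) = -1/2 log(1 - rho2
#' exp(-2 tau / tau_v))` decays with forecast interval `tau`, and the rate is
#' its decay slope at `tau = 0`:
#' `Idot = (1/tau_v) rho2 / (1 - rho2)` nats/s. For `rho2 << 1` this reduces
#' to `rho2 / tau_v`.
#'
#' @param rho2 squared signal-estimate correlation, in `[0, 1)`
#' @param tau_v signal correlation time, s
#' @param units `"nats"` (default) or `"bits"`
#' @return information rate in the requested units per second
#' @export
info_rate_from_rho <- function(rho2, tau_v, units = c("nats", "bits")) {
  units <- match.arg(units)
  if (any(rho2 < 0) || any(rho2 >= 1))
    stop("`rho2` must lie in [0, 1); rho2 = 1 implies an infinite rate",
         call. = FALSE)
  rate <- (1 / tau_v) * rho2 / (1 - rho2)
  if (units == "bits") rate / log(2) else rate
}

new_filter_solution <- function(rho2, sig_s2, tau_v, method, channel,
                                ss = NULL) {
  structure(list(posterior_var = sig_s2 * (1 - rho2), rho2 = rho2,
                 sig_s2 = sig_s2, tau_v = tau_v,
                 info_rate = info_rate_from_rho(rho2, tau_v),
                 method = method, channel = channel, ss = ss),
            class = "filter_solution")
}

#' @export
print.filter_solution <- function(x, ...) {
  cat(sprintf("causal filter solution (%s, %s): rho2 = %.4g, info rate = %.4g nats/s\n",
              x$channel, x$method, x$rho2, x$info_rate))
  invisible(x)
}

#' Physical limit of behaviorally-relevant information
#'
#' Optimal causal estimation of the signal `s = g vx` from the Gaussian
#' approximation of molecule arrivals: the signal is an OU process with
#' variance `g^2 sigma_v2` and correlation time `tau_v`; the observation is
#' the relative arrival rate, i.e. the integrated signal plus white noise of
#' spectral density `1/r0`. The steady-state posterior variance comes from the
#' filter-form algebraic Riccati equation (`method = "riccati"`, default) or
#' from Wiener-Hopf spectral factorization (`method = "spectral"`, kept as an
#' independent oracle). In the small-signal regime the information rate
#' approaches `gamma_r / (4 tau_v)`.
#'
#' @inheritParams gamma_r
#' @param g optional gradient-steepness override, mm^-1
#' @param method `"riccati"` or `"spectral"`
#' @return a `filter_solution` with fields `posterior_var`, `rho2`,
#'   `info_rate` (nats/s), `method`, `channel`
#' @export
solve_physical_limit_filter <- function(env, swim, g = NULL,
                                        method = c("riccati", "spectral")) {
  method <- match.arg(method)
  stopifnot(inherits(env, "environment_spec"),
            inherits(swim, "swimming_phenotype"))
  gg <- if (is.null(g)) env$g else g_per_um(g)
  if (env$r0 <= 0) stop("`r0` must be > 0 for the physical limit", call. = FALSE)
  sig_s2 <- gg^2 * swim$sigma_v2
  if (sig_s2 == 0)
    return(new_filter_solution(0, 0, swim$tau_v, method, "arrivals"))
  if (method == "riccati") {
    ss <- ss_physical_limit(env$r0, sig_s2, swim$tau_v)
    sol <- solve_scaled_filter(ss, swim$tau_v, sig_s2)
    new_filter_solution(sol$rho2, sig_s2, swim$tau_v, method, "arrivals",
                        ss = c(ss, list(K = sol$K, P = sol$P)))
  } else {
    m <- wiener_model_physical(env$r0, sig_s2, swim$tau_v)
    sol <- wiener_posterior_var(m$H, m$G, sig_s2)
    new_filter_solution(sol$rho2, sig_s2, swim$tau_v, method, "arrivals")
  }
}

#' Information encoded in kinase activity
#'
#' Optimal causal estimation of the signal from kinase activity under the
#' linear-response model with perfect adaptation (`tau_1 = 0` branch),
#' Ornstein-Uhlenbeck internal noise, and filtered molecule-arrival noise.
#' The instantaneous kernel lobe makes the observation noise white and
#' correlated with the adaptation state's drive; the correlated-noise Riccati
#' form (or, for `method = "spectral"`, Wiener-Hopf factorization of the joint
#' rational spectra) handles this exactly. With `D_n = 0` the kinase channel
#' is an invertible filter of the arrivals and the solution coincides with the
#' physical limit (data-processing equality).
#'
#' @inheritParams solve_physical_limit_filter
#' @param kin a [kinase_phenotype()]
#' @return a `filter_solution` (`channel = "kinase"`)
#' @export
solve_kinase_filter <- function(env, swim, kin, g = NULL,
                                method = c("riccati", "spectral")) {
  method <- match.arg(method)
  stopifnot(inherits(kin, "kinase_phenotype"))
  if (kin$tau_1 > 0)
    stop("the kinase filter is solved on the tau_1 = 0 branch; ",
         "set `tau_1 = 0` (the fast lobe only slightly affects the rate)",
         call. = FALSE)
  gg <- if (is.null(g)) env$g else g_per_um(g)
  sig_s2 <- gg^2 * swim$sigma_v2
  if (sig_s2 == 0)
    return(new_filter_solution(0, 0, swim$tau_v, method, "kinase"))
  G_r <- resolve_gain(kin, env)
  if (kin$D_n == 0)
    return(solve_physical_limit_filter(env, swim, g = gg * 1e3, method = method))
  if (method == "riccati") {
    ss <- ss_kinase(env$r0, sig_s2, swim$tau_v, G_r, kin$tau_2, kin$D_n,
                    kin$tau_n)
    sol <- solve_scaled_filter(ss, swim$tau_v, sig_s2)
    new_filter_solution(sol$rho2, sig_s2, swim$tau_v, method, "kinase",
                        ss = c(ss, list(K = sol$K, P = sol$P)))
  } else {
    m <- wiener_model_kinase(env$r0, sig_s2, swim$tau_v, G_r, kin$tau_2,
                             kin$D_n, kin$tau_n)
    sol <- wiener_posterior_var(m$H, m$G, sig_s2)
    new_filter_solution(sol$rho2, sig_s2, swim$tau_v, method, "kinase")
  }
}

#' Sensing efficiency
#'
#' Ratio of the kinase information rate to the physical limit,
#' `eta = Idot_a / Idot_r`, always in `[0, 1]` (data-processing inequality).
#' `g = 0` is evaluated as the `g -> 0+` limit by computing both rates at
#' `g = 1e-4 mm^-1`, deep in the `g^2`-scaling regime (the leading saturation
#' correction is of order `sqrt(gamma_r)` ~ 1e-3 there) yet numerically safe.
#'
#' @inheritParams solve_kinase_filter
#' @param g gradient steepness, mm^-1; `g = 0` or `NULL` gives the shallow
#'   limit
#' @return dimensionless efficiency
#' @export
efficiency_eta <- function(env, swim, kin, g = NULL,
                           method = c("riccati", "spectral")) {
  method <- match.arg(method)
  gg_mm <- if (is.null(g)) env$g * 1e3 else g
  if (gg_mm == 0) gg_mm <- 1e-4
  ir <- solve_physical_limit_filter(env, swim, g = gg_mm, method = method)
  ia <- solve_kinase_filter(env, swim, kin, g = gg_mm, method = method)
  ia$info_rate / ir$info_rate
}

#' Power spectral density of kinase-activity noise components
#'
#' Decomposes the kinase-activity noise spectrum into (i) internal noise,
#' `2 D_n tau_n^2 / (1 + omega^2 tau_n^2)`, (ii) molecule-arrival noise
#' filtered through the response kernel, `r0 |Kr~(omega)|^2`, and (iii) their
#' sum. If internal noise dominates over the observable band, sensing is
#' internally limited.
#'
#' @param env an [environment_spec()]
#' @param kin a [kinase_phenotype()]
#' @param omega angular frequencies, rad/s (> 0)
#' @return data frame with columns `omega`, `internal`, `arrival`, `total`
#' @export
noise_psd_components <- function(env, kin, omega) {
  stopifnot(inherits(env, "environment_spec"), inherits(kin, "kinase_phenotype"))
  if (any(omega <= 0)) stop("`omega` must be > 0", call. = FALSE)
  G_r <- resolve_gain(kin, env)
  internal <- 2 * kin$D_n * kin$tau_n^2 / (1 + omega^2 * kin$tau_n^2)
  # |Kr~|^2 for the bilobed kernel; tau_1 = 0 gives G_r^2 w^2 t2^2/(1+w^2 t2^2)
  k1 <- if (kin$tau_1 > 0) 1 / (1 + 1i * omega * kin$tau_1) else 1
  k2 <- 1 / (1 + 1i * omega * kin$tau_2)
  Krw2 <- G_r^2 * Mod(k1 - k2)^2
  arrival <- env$r0 * Krw2
  data.frame(omega = omega, internal = internal, arrival = arrival,
             total = internal + arrival)
}

#' Berg-Purcell threshold check
#'
#' The classical single-run criterion for gradient detection demands that the
#' change in concentration over one run exceed its estimation uncertainty,
#' which translates to `gamma_r > 16/3`. Cells can climb gradients well below
#' this threshold because displacement accumulates inference over many runs.
#'
#' @inheritParams gamma_r
#' @param g optional gradient override, mm^-1
#' @return list with `gamma_r`, `threshold` (16/3), `passes` (strict)
#' @export
berg_purcell_check <- function(env, swim, g = NULL) {
  e <- env
  if (!is.null(g)) { e$g <- g_per_um(g) }
  gr <- gamma_r(e, swim)
  list(gamma_r = gr, threshold = 16 / 3, passes = gr > 16 / 3)
}

#' Population variability of sensing efficiency
#'
#' Monte-Carlo propagation of cell-to-cell phenotype diversity to the sensing
#' efficiency: each draw samples independent lognormal marginals (medians from
#' the supplied phenotypes, spreads from `cv`) for the swimming, response and
#' noise parameters -- assuming these are uncorrelated across cells -- and
#' computes `eta` in the shallow-gradient limit.
#'
#' @param env an [environment_spec()]
#' @param swim,kin median phenotypes
#' @param cv named numeric: per-parameter coefficients of variation for
#'   `sigma_v2`, `tau_v`, `G_r`, `tau_2`, `D_n`, `tau_n` (missing names get 0)
#' @param n_mc Monte-Carlo sample size
#' @param seed integer seed
#' @param g gradient steepness, mm^-1 (0 = shallow limit)
#' @param probs percentiles to report
#' @return list with `percentiles` (named vector), `eta_samples`,
#'   `n_resampled` (non-positive draws rejected and redrawn)
#' @export
population_eta_percentiles <- function(env, swim, kin, cv, n_mc = 500,
                                       seed = 1L, g = 0,
                                       probs = c(0.05, 0.5, 0.95)) {
  set.seed(seed)
  pars <- c("sigma_v2", "tau_v", "G_r", "tau_2", "D_n", "tau_n")
  cvv <- stats::setNames(rep(0, length(pars)), pars)
  cvv[names(cv)] <- cv
  med <- c(sigma_v2 = swim$sigma_v2, tau_v = swim$tau_v,
           G_r = resolve_gain(kin, env), tau_2 = kin$tau_2,
           D_n = kin$D_n, tau_n = kin$tau_n)
  n_resampled <- 0L
  draw <- function() {
    repeat {
      th <- med * exp(stats::rnorm(length(med), 0, sqrt(log(1 + cvv^2))))
      if (all(th > 0) && th["tau_2"] > 0) return(th)
      n_resampled <<- n_resampled + 1L
    }
  }
  eta <- vapply(seq_len(n_mc), function(i) {
    th <- draw()
    sw <- swimming_phenotype(th[["sigma_v2"]], th[["tau_v"]])
    kn <- kinase_phenotype(G_r = th[["G_r"]], tau_1 = 0, tau_2 = th[["tau_2"]],
                           D_n = th[["D_n"]], tau_n = th[["tau_n"]])
    efficiency_eta(env, sw, kn, g = g)
  }, numeric(1))
  list(percentiles = stats::quantile(eta, probs, names = TRUE),
       eta_samples = eta, n_resampled = n_resampled)
}

#' Optimal causal estimator kernel
#'
#' Impulse response of the optimal causal filter mapping the observation to
#' the signal estimate, sampled on a time grid: row 1 of
#' `expm((A - K C) t) K`, rescaled to physical units.
#'
#' @param sol a `filter_solution` produced with `method = "riccati"`
#' @param t_grid times, s (>= 0)
#' @return data frame with columns `t` and `kernel`
#' @export
filter_kernel <- function(sol, t_grid) {
  stopifnot(inherits(sol, "filter_solution"))
  if (is.null(sol$ss))
    stop("kernel export requires a Riccati solution", call. = FALSE)
  A <- sol$ss$A; C <- matrix(sol$ss$C, nrow = 1); K <- sol$ss$K
  Acl <- A - K %*% C
  sig_s <- sqrt(sol$sig_s2)
  k <- vapply(t_grid, function(tt) {
    (as.matrix(Matrix::expm(Acl * tt)) %*% K)[1, 1]
  }, numeric(1))
  # scaled obs y_scaled = y_phys / y_scale; shat_phys = sig_s * z1
  data.frame(t = t_grid, kernel = k * sig_s / sol$ss$y_scale)
}
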