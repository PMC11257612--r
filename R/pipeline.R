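# Orchestration: published parameter sets, figure-style comparison tables, and
# the end-to-end synthesize -> fit -> info-rates -> simulate -> compare
# pipeline with a machine-readable report.

#' Load a parameter set
#'
#' Reads a YAML parameter file (defaults to the bundled population-median
#' values measured at backgrounds 0.1, 1 and 10 uM).
#'
#' @param path YAML file; `NULL` loads the bundled `params_published.yaml`
#' @return the parsed list, of class `chemosense_params`
#' @export
load_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "params_published.yaml",
                        package = "chemosense")
  structure(yaml::read_yaml(path), class = "chemosense_params")
}

#' Phenotypes and environment at one measured background
#'
#' Assembles the ([environment_spec()], [swimming_phenotype()],
#' [kinase_phenotype()]) triple for a measured background from a parameter
#' set, using the per-background measured gain. `gain = "mwc"` substitutes the
#' MWC-model gain `G(c0)/r0` (the construction used for cross-background
#' curves).
#'
#' @param params a `chemosense_params` list (see [load_params()])
#' @param c0 background concentration, uM (must be listed in `params`)
#' @param g gradient steepness, mm^-1
#' @param gain `"measured"` or `"mwc"`
#' @return list with `env`, `swim`, `kin`, and `gain_sigma` (uncertainty of
#'   the measured gain in 1/k_D units, when available)
#' @export
published_phenotype <- function(params, c0, g = 0, gain = c("measured", "mwc")) {
  gain <- match.arg(gain)
  stopifnot(inherits(params, "chemosense_params"))
  bgs <- vapply(params$backgrounds, `[[`, numeric(1), "c0")
  i <- which(abs(bgs - c0) < 1e-9)
  if (!length(i)) stop("background ", c0, " uM not in the parameter set", call. = FALSE)
  bg <- params$backgrounds[[i]]
  env <- environment_spec(c0 = c0, g = g,
                          D_ligand = params$capture$D_ligand,
                          l_sensor = params$capture$l_sensor)
  kin_block <- params$kinase
  sw_block <- params$swim_kinematics
  swim <- swimming_phenotype(sigma_v2 = bg$sigma_v2, tau_v = bg$tau_v,
                             speed = sw_block$speed,
                             p_run = sw_block$mean_run /
                               (sw_block$mean_run + sw_block$mean_tumble),
                             mean_run = sw_block$mean_run,
                             mean_tumble = sw_block$mean_tumble,
                             persistence = sw_block$persistence,
                             d_rot = sw_block$d_rot)
  G_r <- if (gain == "measured") {
    bg$G_r_kD / env$k_D
  } else {
    mwc_gain(c0, params$mwc$G_inf, params$mwc$K_i, k_D = env$k_D)$G_r
  }
  kin <- kinase_phenotype(G_r = G_r, G_inf = params$mwc$G_inf,
                          K_i = params$mwc$K_i, tau_1 = kin_block$tau_1,
                          tau_2 = bg$tau_2, D_n = bg$D_n, tau_n = bg$tau_n,
                          a0 = kin_block$a0)
  list(env = env, swim = swim, kin = kin,
       gain_sigma = bg$G_r_kD_sigma)
}

#' Comparison tables of information rates and efficiency
#'
#' Computes the tables behind the standard comparison figures: information
#' rates per squared gradient steepness and the efficiency
#' `eta = Idot_a / Idot_r` versus background for several gradients, plus the
#' kinase-noise PSD decomposition at a reference background. Curves across
#' backgrounds use the MWC-model gain with the remaining parameters measured
#' at 1 uM (only the gain varies strongly with background); measured dots use
#' the per-background measured gains.
#'
#' @param params a `chemosense_params` list
#' @param g_mm gradients, mm^-1; 0 denotes the shallow limit
#' @param c0_grid backgrounds for the curves, uM
#' @param c0_ref reference background for the PSD table and the curve's
#'   non-gain parameters, uM
#' @param freq_hz frequencies for the PSD table, Hz
#' @param units `"nats"` or `"bits"`
#' @return list of data frames: `curves` (c0 x g grid with `I_r_per_g2`,
#'   `I_a_per_g2`, `eta`), `measured` (same at the measured backgrounds with
#'   measured gains), `psd`
#' @export
reproduce_comparison <- function(params = load_params(),
                                 g_mm = c(0, 0.1, 0.2, 0.3, 0.4),
                                 c0_grid = 10^seq(-1.5, 1.5, length.out = 31),
                                 c0_ref = 1,
                                 freq_hz = 10^seq(-3, log10(0.5), length.out = 40),
                                 units = c("nats", "bits")) {
  units <- match.arg(units)
  conv <- if (units == "bits") 1 / log(2) else 1
  ref <- published_phenotype(params, c0_ref, gain = "measured")
  rows <- list(); mrows <- list()
  for (g in g_mm) {
    g_eval <- if (g == 0) 1e-4 else g
    for (cc in c0_grid) {
      env <- environment_spec(c0 = cc, g = g_eval,
                              D_ligand = params$capture$D_ligand,
                              l_sensor = params$capture$l_sensor)
      kin <- kinase_phenotype(
        G_r = mwc_gain(cc, params$mwc$G_inf, params$mwc$K_i, k_D = env$k_D)$G_r,
        tau_1 = 0, tau_2 = ref$kin$tau_2, D_n = ref$kin$D_n,
        tau_n = ref$kin$tau_n, a0 = ref$kin$a0)
      ir <- solve_physical_limit_filter(env, ref$swim)
      ia <- solve_kinase_filter(env, ref$swim, kin)
      g_um <- env$g
      rows[[length(rows) + 1]] <-
        data.frame(c0 = cc, g_mm = g,
                   gamma_r = gamma_r(env, ref$swim),
                   gamma_a = gamma_a(env, ref$swim, kin),
                   I_r = ir$info_rate * conv, I_a = ia$info_rate * conv,
                   I_r_per_g2 = ir$info_rate * conv / g_um^2,
                   I_a_per_g2 = ia$info_rate * conv / g_um^2,
                   eta = ia$info_rate / ir$info_rate)
    }
    for (cc in vapply(params$backgrounds, `[[`, numeric(1), "c0")) {
      ph <- published_phenotype(params, cc, g = g_eval, gain = "measured")
      ir <- solve_physical_limit_filter(ph$env, ph$swim)
      ia <- solve_kinase_filter(ph$env, ph$swim, ph$kin)
      g_um <- ph$env$g
      mrows[[length(mrows) + 1]] <-
        data.frame(c0 = cc, g_mm = g,
                   gamma_r = gamma_r(ph$env, ph$swim),
                   gamma_a = gamma_a(ph$env, ph$swim, ph$kin),
                   I_r = ir$info_rate * conv, I_a = ia$info_rate * conv,
                   I_r_per_g2 = ir$info_rate * conv / g_um^2,
                   I_a_per_g2 = ia$info_rate * conv / g_um^2,
                   eta = ia$info_rate / ir$info_rate)
    }
  }
  psd <- noise_psd_components(ref$env, ref$kin, omega = 2 * pi * freq_hz)
  psd$freq_hz <- freq_hz
  list(curves = do.call(rbind, rows), measured = do.call(rbind, mrows),
       psd = psd, units = units)
}

#' Pipeline configuration
#'
#' @param backgrounds backgrounds to analyze, uM (must be in the parameter set)
#' @param gradients gradient steepnesses, mm^-1
#' @param seed master seed; stage seeds are derived deterministically
#' @param units information units
#' @param fit run the synthesize-and-refit stages
#' @param simulate run the chemotaxis simulations
#' @param sizes named list of dataset/simulation sizes (see defaults in the
#'   function body)
#' @param params_path optional YAML parameter file
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(backgrounds = c(0.1, 1, 10),
                            gradients = c(0.05, 0.1, 0.2, 0.3, 0.4),
                            seed = 1L, units = "nats", fit = TRUE,
                            simulate = TRUE, sizes = list(),
                            params_path = NULL) {
  if (!length(backgrounds)) stop("at least one background required", call. = FALSE)
  if (!length(gradients)) stop("at least one gradient required", call. = FALSE)
  defaults <- list(n_tracks = 500, track_s = 60, track_dt = 0.05,
                   n_step_cells = 30, n_noise_cells = 50, noise_s = 1200,
                   n_agents = 500, agent_T = 500, agent_dt = 0.01,
                   mcmc_steps = 2000)
  defaults[names(sizes)] <- sizes
  structure(list(backgrounds = backgrounds, gradients = gradients,
                 seed = as.integer(seed), units = units, fit = fit,
                 simulate = simulate, sizes = defaults,
                 params_path = params_path),
            class = "pipeline_config")
}

stage_seed <- function(seed, k) (as.integer(seed) * 101L + k * 7919L) %% 2000000000L

#' Recover swimming statistics from a synthetic track dataset
#'
#' Generates zero-gradient tracks at the population median and runs the full
#' estimation chain: tumble detection, median run-fraction binning,
#' duration-weighted velocity autocorrelation, and the exponential MAP/MCMC
#' fit. Standard errors of the recovered parameters come from a bootstrap over
#' the cells in the median bin, which absorbs both the cell-sampling
#' variability and the correlations between autocorrelation lags that the
#' per-fit Gaussian likelihood ignores.
#'
#' @param pop a [population_spec()] (swim phenotype must be calibrated)
#' @param env an [environment_spec()] with `g = 0`
#' @param n_tracks,duration_s,dt dataset size
#' @param seed integer seed
#' @param mcmc_steps MCMC steps for the fit
#' @param n_boot bootstrap replicates for the standard errors
#' @return list with `estimate` and `se` (named over `sigma_v2`, `tau_v`),
#'   `fit` (the `fit_result`), `V_table`, `bin`, `boot` (bootstrap draws), and
#'   `n_used`
#' @export
recover_swim_statistics <- function(pop, env, n_tracks = 500, duration_s = 60,
                                    dt = 0.05, seed = 1L, mcmc_steps = 1000,
                                    n_boot = 30) {
  pop$n_cells <- n_tracks
  tracks <- generate_track_dataset(pop, env, duration_s = duration_s, dt = dt,
                                   seed = seed)
  labeled <- lapply(tracks, detect_tumbles)
  bin <- prun_and_bin(labeled)
  V_table <- velocity_acf(bin$subset, max_lag_s = 10)
  fit <- fit_exponential_acf(V_table, fit_range = c(2 * dt, 10),
                             seed = stage_seed(seed, 2L),
                             n_steps = mcmc_steps)
  # bootstrap over cells in the bin (least-squares refits for speed)
  set.seed(stage_seed(seed, 3L))
  nb <- length(bin$subset)
  boot <- t(replicate(n_boot, {
    idx <- sample.int(nb, nb, replace = TRUE)
    Vb <- velocity_acf(bin$subset[idx], max_lag_s = 10)
    keep <- Vb$lag >= 2 * dt
    fb <- stats::optim(log(fit$map_estimate), function(p)
      sum(((Vb$V[keep] - exp(p[1]) * exp(-Vb$lag[keep] / exp(p[2]))) /
             Vb$se[keep])^2),
      control = list(reltol = 1e-10, maxit = 2000))
    exp(fb$par)
  }))
  colnames(boot) <- c("sigma_v2", "tau_v")
  list(estimate = fit$map_estimate, se = apply(boot, 2, stats::sd),
       fit = fit, V_table = V_table, bin = bin, boot = boot,
       n_used = nb)
}

#' Recover kinase response parameters from synthetic step responses
#'
#' @param pop a [population_spec()] with `kin`
#' @param env an [environment_spec()]
#' @param protocol a [step_protocol()]
#' @param seed integer seed
#' @param mcmc_steps MCMC steps per cell
#' @param noise correlated-noise model passed to [fit_response_kernel()];
#'   the default uses the population noise parameters and measurement noise of
#'   `pop` (in the full pipeline these come from the separate
#'   constant-background noise fits)
#' @return list with `fits` (per cell), `summary`
#'   (a [population_median_uncertainty()] table for `G_r_kD`, `tau_1`, `tau_2`)
#' @export
recover_response_parameters <- function(pop, env, protocol = step_protocol(),
                                        seed = 1L, mcmc_steps = 2000,
                                        noise = NULL) {
  if (is.null(noise))
    noise <- list(D_n = pop$kin$D_n, tau_n = pop$kin$tau_n,
                  meas_sd = pop$measurement_noise_sd)
  cells <- generate_step_response_dataset(pop, env, protocol, seed = seed)
  fits <- lapply(seq_along(cells), function(i) {
    avg <- average_step_response(cells[[i]])
    fit_response_kernel(avg, protocol, seed = stage_seed(seed, 100L + i),
                        n_steps = mcmc_steps, noise = noise)
  })
  list(fits = fits, summary = population_median_uncertainty(fits))
}

#' Recover internal-noise parameters from synthetic noise traces
#'
#' @param pop a [population_spec()] with `kin`
#' @param env an [environment_spec()]
#' @param duration_s,dt recording length and sampling
#' @param seed integer seed
#' @param mcmc_steps MCMC steps per cell
#' @return list with `fits` and `summary` (for `D_n`, `tau_n`)
#' @export
recover_noise_parameters <- function(pop, env, duration_s = 1200, dt = 1.0,
                                     seed = 1L, mcmc_steps = 2000) {
  cells <- generate_noise_dataset(pop, env, duration_s = duration_s, dt = dt,
                                  seed = seed)
  fits <- lapply(seq_along(cells), function(i) {
    fit_ou_noise(cells[[i]], dt = dt,
                 measurement_noise_sd = pop$measurement_noise_sd,
                 seed = stage_seed(seed, 200L + i), n_steps = mcmc_steps)
  })
  list(fits = fits, summary = population_median_uncertainty(fits))
}

#' Run the full analysis pipeline
#'
#' Executes synthesize -> fit -> info-rates -> simulate -> compare according
#' to the configuration and returns (optionally writes) a machine-readable
#' report: recovered parameters with uncertainties, `gamma_r`, `gamma_a`,
#' information rates and `eta` per condition, drift-speed ratios against the
#' square-root information relation, and a provenance block.
#'
#' @param config a [pipeline_config()]
#' @param out optional path for the JSON report
#' @return the report list, invisibly when `out` is given
#' @export
run_full_pipeline <- function(config = pipeline_config(), out = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  params <- load_params(config$params_path)
  sz <- config$sizes
  report <- list(provenance = list(
    seed = config$seed, units = config$units,
    version = as.character(utils::packageVersion("chemosense")),
    timestamp = "deterministic-output"))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[", name, "] ...")
    val <- tryCatch(expr, error = function(e)
      stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
    message("[", name, "] done (", round(proc.time()[["elapsed"]] - t0, 1), " s)")
    val
  }
  ref <- published_phenotype(params, 1, gain = "measured")

  if (config$fit) {
    swim_cal <- stage("calibrate", calibrate_swim_phenotype(
      sigma_v2 = ref$swim$sigma_v2, tau_v = ref$swim$tau_v,
      mean_run = ref$swim$mean_run, mean_tumble = ref$swim$mean_tumble,
      persistence = ref$swim$persistence))
    pop <- population_spec(swim_cal, ref$kin, cv = 0.2,
                           n_cells = sz$n_noise_cells)
    env0 <- environment_spec(c0 = 1, g = 0)
    sw <- stage("fit-swim", recover_swim_statistics(
      pop, env0, n_tracks = sz$n_tracks, duration_s = sz$track_s,
      dt = sz$track_dt, seed = stage_seed(config$seed, 1L),
      mcmc_steps = sz$mcmc_steps))
    pop_step <- pop; pop_step$n_cells <- sz$n_step_cells
    pop_step$kin$tau_1 <- 0.5
    resp <- stage("fit-response", recover_response_parameters(
      pop_step, env0, seed = stage_seed(config$seed, 3L),
      mcmc_steps = sz$mcmc_steps))
    noise <- stage("fit-noise", recover_noise_parameters(
      pop, env0, duration_s = sz$noise_s, seed = stage_seed(config$seed, 4L),
      mcmc_steps = sz$mcmc_steps))
    gains <- data.frame(
      c0 = vapply(params$backgrounds, `[[`, numeric(1), "c0"),
      G_r_kD = vapply(params$backgrounds, `[[`, numeric(1), "G_r_kD"),
      sigma = vapply(params$backgrounds, `[[`, numeric(1), "G_r_kD_sigma"))
    mwc <- fit_mwc(gains)
    report$fits <- list(
      swim = list(estimate = as.list(sw$estimate),
                  se = as.list(sw$se)),
      response = as.list(stats::setNames(resp$summary$median,
                                         resp$summary$parameter)),
      noise = as.list(stats::setNames(noise$summary$median,
                                      noise$summary$parameter)),
      mwc = list(G_inf = mwc$G_inf, K_i = mwc$K_i))
  }

  report$information <- stage("info-rates", {
    rows <- list()
    for (cc in config$backgrounds) for (g in config$gradients) {
      ph <- published_phenotype(params, cc, g = g, gain = "measured")
      ir <- solve_physical_limit_filter(ph$env, ph$swim)
      ia <- solve_kinase_filter(ph$env, ph$swim, ph$kin)
      conv <- if (config$units == "bits") 1 / log(2) else 1
      rows[[length(rows) + 1]] <- data.frame(
        c0 = cc, g_mm = g, gamma_r = gamma_r(ph$env, ph$swim),
        gamma_a = gamma_a(ph$env, ph$swim, ph$kin),
        I_r = ir$info_rate * conv, I_a = ia$info_rate * conv,
        eta = ia$info_rate / ir$info_rate)
    }
    do.call(rbind, rows)
  })
  report$comparison_tables <- stage("reproduce", {
    rc <- reproduce_comparison(params, g_mm = c(0, config$gradients),
                               units = config$units)
    list(eta_peak_shallow = max(rc$curves$eta[rc$curves$g_mm == 0]),
         eta_peak_c0 = rc$curves$c0[rc$curves$g_mm == 0][
           which.max(rc$curves$eta[rc$curves$g_mm == 0])],
         curves = rc$curves, measured = rc$measured)
  })

  if (config$simulate) {
    report$drift <- stage("simulate", {
      swim_cal <- if (config$fit) NULL else NULL
      ph <- published_phenotype(params, 1, gain = "measured")
      di <- list(); da <- list()
      for (k in seq_along(config$gradients)) {
        g <- config$gradients[k]
        env_g <- environment_spec(c0 = 1, g = g,
                                  D_ligand = params$capture$D_ligand,
                                  l_sensor = params$capture$l_sensor)
        cfg_i <- agent_config("ideal", ph$swim)
        cfg_a <- agent_config("ecoli", ph$swim, ph$kin)
        di[[k]] <- drift_speed(simulate_agents(
          cfg_i, env_g, n_agents = sz$n_agents, T = sz$agent_T,
          dt = sz$agent_dt, seed = stage_seed(config$seed, 300L + k),
          keep_traces = 0))
        da[[k]] <- drift_speed(simulate_agents(
          cfg_a, env_g, n_agents = sz$n_agents, T = sz$agent_T,
          dt = sz$agent_dt, seed = stage_seed(config$seed, 400L + k),
          keep_traces = 0))
      }
      info_drift_consistency(di, da)
    })
  }
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
    return(invisible(report))
  }
  report
}
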