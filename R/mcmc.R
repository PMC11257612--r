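# Affine-invariant ensemble MCMC (Goodman-Weare stretch moves) and the
# FitResult container shared by all estimation stages.
#
# Sampling is always done in log-parameter space with uniform priors over a
# bounded box (log-uniform priors on the natural scale), +/- `prior_halfwidth`
# decades around a moment-based initial guess.

#' Affine-invariant ensemble sampler
#'
#' Goodman-Weare stretch-move MCMC. Walkers are updated in two half-ensembles
#' so proposals always stretch toward the complementary half.
#'
#' @param log_post log-posterior function of a parameter vector
#' @param init center of the initial walker ball
#' @param n_walkers number of walkers (>= 2 * dimension)
#' @param n_steps total steps per walker; the first half is discarded as
#'   burn-in
#' @param seed integer seed
#' @param ball_sd relative scatter of the initial walker ball
#' @param a stretch parameter
#' @return list with `samples` (matrix, post-burn-in draws x parameters),
#'   `acceptance` (fraction), `n_walkers`, `n_steps`
#' @export
mcmc_ensemble <- function(log_post, init, n_walkers = 32, n_steps = 2000,
                          seed = 1L, ball_sd = 0.01, a = 2) {
  set.seed(seed)
  d <- length(init)
  if (n_walkers < 2 * d) n_walkers <- 2 * d
  if (n_walkers %% 2 == 1) n_walkers <- n_walkers + 1
  X <- matrix(rep(init, each = n_walkers), n_walkers, d) +
    matrix(stats::rnorm(n_walkers * d, 0, ball_sd), n_walkers, d) *
      (abs(matrix(rep(init, each = n_walkers), n_walkers, d)) + 1e-8)
  lp <- apply(X, 1, log_post)
  bad <- !is.finite(lp)
  if (any(bad)) {
    X[bad, ] <- matrix(rep(init, sum(bad)), ncol = d, byrow = TRUE)
    lp[bad] <- log_post(init)
  }
  if (!is.finite(lp[1]))
    stop("log-posterior is not finite at the initial point", call. = FALSE)
  halves <- list(seq_len(n_walkers / 2), n_walkers / 2 + seq_len(n_walkers / 2))
  keep <- floor(n_steps / 2)
  out <- matrix(NA_real_, keep * n_walkers, d)
  n_acc <- 0L; n_prop <- 0L; row <- 0L
  for (step in seq_len(n_steps)) {
    for (h in 1:2) {
      mine <- halves[[h]]; other <- halves[[3 - h]]
      z <- (stats::runif(length(mine)) * (sqrt(a) - 1 / sqrt(a)) + 1 / sqrt(a))^2
      partners <- other[sample.int(length(other), length(mine), replace = TRUE)]
      prop <- X[partners, , drop = FALSE] +
        z * (X[mine, , drop = FALSE] - X[partners, , drop = FALSE])
      lp_prop <- apply(prop, 1, log_post)
      log_ratio <- (d - 1) * log(z) + lp_prop - lp[mine]
      acc <- log(stats::runif(length(mine))) < log_ratio
      acc[!is.finite(lp_prop)] <- FALSE
      X[mine[acc], ] <- prop[acc, , drop = FALSE]
      lp[mine[acc]] <- lp_prop[acc]
      n_acc <- n_acc + sum(acc); n_prop <- n_prop + length(mine)
    }
    if (step > n_steps - keep) {
      out[row + seq_len(n_walkers), ] <- X
      row <- row + n_walkers
    }
  }
  best <- which.max(lp)
  list(samples = out, acceptance = n_acc / n_prop,
       n_walkers = n_walkers, n_steps = n_steps,
       best = X[best, ], best_lp = lp[best])
}

#' Robust scale estimate
#'
#' `1.4826 * mad(x)`: coincides with the standard deviation for Gaussian
#' samples, robust to outliers.
#'
#' @param x numeric vector
#' @return scale estimate
#' @export
robust_sd <- function(x) 1.4826 * stats::mad(x, constant = 1)

# MAP + MCMC fit in log-parameter space with a log-uniform box prior.
# `log_lik` takes the natural-scale parameter vector.
fit_map_mcmc <- function(log_lik, init, names, seed = 1L,
                         prior_halfwidth = 3, n_walkers = 32, n_steps = 2000) {
  lo <- log(init) - prior_halfwidth * log(10)
  hi <- log(init) + prior_halfwidth * log(10)
  log_post <- function(lp) {
    if (any(lp < lo) || any(lp > hi)) return(-Inf)
    ll <- log_lik(exp(lp))
    if (!is.finite(ll)) return(-Inf)
    ll
  }
  opt <- stats::optim(log(init), function(lp) -log_post(lp),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 4000))
  mc <- mcmc_ensemble(log_post, opt$par, n_walkers = n_walkers,
                      n_steps = n_steps, seed = seed)
  # polish the mode from the best posterior draw in case the first search
  # stalled on a ridge
  if (mc$best_lp > -opt$value) {
    opt2 <- stats::optim(mc$best, function(lp) -log_post(lp),
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-10, maxit = 4000))
    if (opt2$value < opt$value) opt <- opt2
  }
  samples <- exp(mc$samples)
  colnames(samples) <- names
  map <- stats::setNames(exp(opt$par), names)
  post_med <- stats::setNames(apply(samples, 2, stats::median), names)
  unc <- apply(samples, 2, robust_sd)
  # a posterior piling onto a prior bound marks an unidentified parameter
  edge_frac <- 10^0.3
  at_edge <- vapply(seq_along(map), function(j) {
    map[j] < exp(lo[j]) * 1.26 || map[j] > exp(hi[j]) / 1.26 ||
      mean(samples[, j] < exp(lo[j]) * edge_frac) > 0.25 ||
      mean(samples[, j] > exp(hi[j]) / edge_frac) > 0.25
  }, logical(1))
  structure(list(map_estimate = map, posterior_median = post_med,
                 samples = samples,
                 uncertainty = stats::setNames(unc, names),
                 diagnostics = list(acceptance = mc$acceptance,
                                    n_walkers = mc$n_walkers,
                                    n_steps = mc$n_steps,
                                    converged_acceptance =
                                      mc$acceptance >= 0.1 & mc$acceptance <= 0.7,
                                    at_prior_edge = stats::setNames(at_edge, names),
                                    neg_loglik = opt$value)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("MAP fit (", paste(names(x$map_estimate), collapse = ", "), ")\n", sep = "")
  for (nm in names(x$map_estimate))
    cat(sprintf("  %s = %.4g +/- %.2g%s\n", nm, x$map_estimate[[nm]],
                x$uncertainty[[nm]],
                if (isTRUE(x$diagnostics$at_prior_edge[[nm]])) " [at prior edge]" else ""))
  cat(sprintf("  MCMC acceptance %.2f (%d walkers x %d steps)\n",
              x$diagnostics$acceptance, x$diagnostics$n_walkers,
              x$diagnostics$n_steps))
  invisible(x)
}
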