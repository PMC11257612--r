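# Frequency-domain causal Wiener filtering by rational spectral factorization.
#
# Independent cross-check of the Riccati route. Stationary Gaussian processes
# are described by transfer functions from independent unit-intensity white
# noises w_j to the observation y and to the signal s. All rational functions
# are kept in zero-pole-gain form; the observation spectrum
# S_y(p) = sum_j H_j(p) H_j(-p) is factored as W(p) W(-p) with W minimum
# phase, the cross-spectrum is projected onto its causal part by partial
# fractions, and the mean squared error of the causal estimator follows from
# the residue formula for integrals of rational spectra.

zpk <- function(gain, zeros = complex(0), poles = complex(0)) {
  list(gain = as.complex(gain), zeros = as.complex(zeros),
       poles = as.complex(poles))
}

zpk_eval <- function(r, p) {
  v <- r$gain + 0 * p
  for (z in r$zeros) v <- v * (p - z)
  for (q in r$poles) v <- v / (p - q)
  v
}

zpk_mul <- function(a, b) {
  zpk(a$gain * b$gain, c(a$zeros, b$zeros), c(a$poles, b$poles))
}

# substitute p -> -p
zpk_flip <- function(r) {
  sgn <- (-1 + 0i)^(length(r$zeros) - length(r$poles))
  zpk(r$gain * sgn, -r$zeros, -r$poles)
}

zpk_inv <- function(r) zpk(1 / r$gain, r$poles, r$zeros)

# cancel matching zero/pole pairs (within tol relative to scale)
zpk_cancel <- function(r, tol = 1e-7) {
  zs <- r$zeros; ps <- r$poles
  scale <- max(1, abs(c(zs, ps)))
  keep_z <- rep(TRUE, length(zs)); keep_p <- rep(TRUE, length(ps))
  for (i in seq_along(zs)) {
    j <- which(keep_p & abs(ps - zs[i]) < tol * scale)
    if (length(j)) { keep_z[i] <- FALSE; keep_p[j[1]] <- FALSE }
  }
  zpk(r$gain, zs[keep_z], ps[keep_p])
}

# polynomial coefficients (ascending powers) from roots, times gain
poly_from_roots <- function(roots, gain = 1 + 0i) {
  cf <- as.complex(gain)
  for (r in roots) cf <- c(0i, cf) - c(r * cf, 0i)
  cf
}

poly_mul <- function(a, b) {
  out <- complex(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

poly_add <- function(a, b) {
  n <- max(length(a), length(b))
  c(a, complex(n - length(a))) + c(b, complex(n - length(b)))
}

poly_roots <- function(cf) {
  tol <- 1e-12 * max(abs(cf))
  while (length(cf) > 1 && abs(cf[length(cf)]) < tol) cf <- cf[-length(cf)]
  if (length(cf) <= 1) return(complex(0))
  polyroot(cf)
}

# Numerator/denominator coefficients of S_y(p) = sum_j H_j(p) H_j(-p) over the
# common denominator prod_j d_j(p) d_j(-p).
spectrum_coeffs <- function(H) {
  dens <- lapply(H, function(h) poly_from_roots(h$poles))
  dens_f <- lapply(H, function(h)
    poly_from_roots(-h$poles, (-1 + 0i)^length(h$poles)))
  den <- as.complex(1)
  for (j in seq_along(H)) den <- poly_mul(poly_mul(den, dens[[j]]), dens_f[[j]])
  num <- NULL
  for (j in seq_along(H)) {
    nj <- poly_from_roots(H[[j]]$zeros, H[[j]]$gain)
    njf <- poly_from_roots(-H[[j]]$zeros,
                           H[[j]]$gain * (-1 + 0i)^length(H[[j]]$zeros))
    term <- poly_mul(nj, njf)
    for (k in seq_along(H)) if (k != j)
      term <- poly_mul(poly_mul(term, dens[[k]]), dens_f[[k]])
    num <- if (is.null(num)) term else poly_add(num, term)
  }
  list(num = num, den = den)
}

# Roots of an even spectrum polynomial come in +/- mirror pairs; return the
# left-half-plane half. Imaginary-axis roots occur with even multiplicity
# (pure integrators); half of each coincident cluster is assigned to the
# stable factor.
lhp_half <- function(roots) {
  if (!length(roots)) return(complex(0))
  scale <- max(1, abs(roots))
  on_axis <- abs(Re(roots)) < 1e-7 * scale
  out <- roots[!on_axis & Re(roots) < 0]
  ax <- roots[on_axis]
  while (length(ax)) {
    cl <- abs(ax - ax[1]) < 1e-7 * scale | abs(ax + ax[1]) < 1e-7 * scale
    m <- sum(cl)
    if (m %% 2 != 0)
      stop("spectral factorization: unpaired imaginary-axis root", call. = FALSE)
    out <- c(out, rep(complex(real = 0, imaginary = Im(ax[1])), m / 2))
    ax <- ax[!cl]
  }
  out
}

# Minimum-phase spectral factor W of S_y. The gain is fixed by matching
# |W(i w*)|^2 to S_y(i w*) at a probe frequency.
spectral_factor <- function(H, probe = NULL) {
  sp <- spectrum_coeffs(H)
  zs <- lhp_half(poly_roots(sp$num))
  ps <- lhp_half(poly_roots(sp$den))
  W <- zpk(1, zs, ps)
  if (is.null(probe)) {
    cand <- abs(c(zs, ps))
    cand <- cand[cand > 0]
    probe <- if (length(cand)) stats::median(cand) else 1
  }
  p0 <- complex(real = 0, imaginary = probe)
  Sy <- Reduce(`+`, lapply(H, function(h) {
    v <- zpk_eval(h, p0); Re(v * Conj(v))
  }))
  B <- zpk_eval(W, p0)
  W$gain <- W$gain * sqrt(Sy / Re(B * Conj(B)))
  W
}

# Residues of a zpk rational with distinct poles.
zpk_residues <- function(r) {
  res <- complex(length(r$poles))
  for (k in seq_along(r$poles)) {
    pk <- r$poles[k]
    v <- r$gain
    for (z in r$zeros) v <- v * (pk - z)
    for (m in seq_along(r$poles)) if (m != k) v <- v / (pk - r$poles[m])
    res[k] <- v
  }
  res
}

# Steady-state mean squared error of the optimal causal estimator of the
# signal (transfer functions G from the shared white noises) from the
# observation (transfer functions H), and the corresponding squared
# correlation. The estimator variance is
#   (1/2pi) int |Phi_+(iw)|^2 dw,  Phi = S_sy / W(-p),
# computed exactly from the causal residues.
wiener_posterior_var <- function(H, G, sig_s2) {
  W <- spectral_factor(H)
  Winv_flip <- zpk_inv(zpk_flip(W))
  poles <- complex(0); res <- complex(0)
  for (j in seq_along(H)) {
    if (abs(G[[j]]$gain) == 0) next
    phi <- zpk_cancel(zpk_mul(zpk_mul(G[[j]], zpk_flip(H[[j]])), Winv_flip))
    rr <- zpk_residues(phi)
    keep <- Re(phi$poles) < -1e-9 * max(1, abs(phi$poles))
    poles <- c(poles, phi$poles[keep]); res <- c(res, rr[keep])
  }
  if (length(poles) > 1) {
    merged_p <- complex(0); merged_r <- complex(0)
    used <- rep(FALSE, length(poles))
    for (i in seq_along(poles)) {
      if (used[i]) next
      same <- !used & abs(poles - poles[i]) < 1e-9 * max(1, abs(poles[i]))
      merged_p <- c(merged_p, poles[i]); merged_r <- c(merged_r, sum(res[same]))
      used <- used | same
    }
    poles <- merged_p; res <- merged_r
  }
  est_var <- 0 + 0i
  for (j in seq_along(poles)) for (k in seq_along(poles))
    est_var <- est_var - res[j] * res[k] / (poles[j] + poles[k])
  est_var <- Re(est_var)
  rho2 <- min(max(est_var / sig_s2, 0), 1)
  list(posterior_var = sig_s2 * (1 - rho2), rho2 = rho2)
}

# Transfer-function models matching the state-space builders (unscaled).
# Physical limit: y = (r - r0)/r0 = x + xi/sqrt(r0), with s an OU process of
# variance sig_s2 and correlation time tau_v, x = int s dt.
wiener_model_physical <- function(r0, sig_s2, tau_v) {
  b <- sqrt(2 * sig_s2 / tau_v); al <- 1 / tau_v
  list(H = list(zpk(b, poles = c(0, -al)),
                zpk(1 / sqrt(r0))),
       G = list(zpk(b, poles = -al),
                zpk(0)))
}

# Kinase activity (tau_1 = 0): y = a - a0 = -G_r p/(p + 1/tau_2) u + n with
# u = r0 x + sqrt(r0) xi and n an OU process of variance D_n tau_n.
wiener_model_kinase <- function(r0, sig_s2, tau_v, G_r, tau_2, D_n, tau_n) {
  b <- sqrt(2 * sig_s2 / tau_v); al <- 1 / tau_v
  list(H = list(zpk(-G_r * r0 * b, poles = c(-1 / tau_2, -al)),
                zpk(-G_r * sqrt(r0), zeros = 0, poles = -1 / tau_2),
                zpk(sqrt(2 * D_n), poles = -1 / tau_n)),
       G = list(zpk(b, poles = -al),
                zpk(0),
                zpk(0)))
}
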