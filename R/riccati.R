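# Steady-state Kalman-Bucy (filter-form) algebraic Riccati solver.
#
#   A P + P A' + Q - (P C' + S) R^-1 (C P + S') = 0
#
# with scalar observation noise intensity R and process/observation noise
# cross-intensity S. Solved by the Hamiltonian invariant-subspace method
# (after shifting the correlated noise into an equivalent standard problem)
# and polished by Newton iterations, each a Lyapunov solve via Kronecker
# products -- cheap at the 2-4 states used here.

care_filter <- function(A, C, Q, R, S = NULL) {
  n <- nrow(A)
  C <- matrix(C, nrow = 1)
  if (is.null(S)) S <- rep(0, n)
  S <- matrix(S, ncol = 1)
  Ab <- A - S %*% C / R
  Qb <- Q - S %*% t(S) / R
  G <- t(C) %*% C / R
  H <- rbind(cbind(t(Ab), -G), cbind(-Qb, -Ab))
  e <- eigen(H)
  idx <- order(Re(e$values))[seq_len(n)]
  if (max(Re(e$values[idx])) >= 0)
    stop("Riccati solve failed: Hamiltonian has no stable invariant subspace ",
         "of dimension ", n, " (system not detectable/stabilizable)",
         call. = FALSE)
  U <- e$vectors[, idx, drop = FALSE]
  U1 <- U[seq_len(n), , drop = FALSE]
  rc <- rcond(rbind(Re(U1), Im(U1))[seq_len(n) + 0, , drop = FALSE])
  P <- tryCatch(Re(U[n + seq_len(n), , drop = FALSE] %*% solve(U1)),
                error = function(e)
                  stop("Riccati solve failed: stable subspace basis is ",
                       "numerically singular (rcond ~ ", signif(rc, 2), ")",
                       call. = FALSE))
  P <- (P + t(P)) / 2
  # Newton polish; skipped silently if the Lyapunov system is too
  # ill-conditioned (the Hamiltonian solution is then kept as-is)
  for (it in 1:40) {
    K <- (P %*% t(C) + S) / R
    Acl <- A - K %*% C
    res <- A %*% P + P %*% t(A) + Q - K %*% R %*% t(K)
    D <- tryCatch({
      M <- kronecker(diag(n), Acl) + kronecker(Acl, diag(n))
      matrix(solve(M, -as.vector(res)), n, n)
    }, error = function(e) NULL)
    if (is.null(D)) break
    P <- P + (D + t(D)) / 2
    if (max(abs(D)) <= 1e-15 * max(abs(P))) break
  }
  list(P = P, K = (P %*% t(C) + S) / R)
}

# Scaled state-space model for the physical-limit filter.
# States z = (s/sig_s, x/(sig_s*tau_v)) where x = int s dt and the observation
# is the relative arrival-rate deviation y = x + white noise of spectral
# density 1/r0, rescaled by 1/(sig_s*tau_v).
ss_physical_limit <- function(r0, sig_s2, tau_v) {
  list(A = matrix(c(-1 / tau_v, 0, 1 / tau_v, 0), 2, 2, byrow = TRUE),
       C = c(0, 1),
       Q = diag(c(2 / tau_v, 0)),
       R = 1 / (r0 * sig_s2 * tau_v^2),
       S = c(0, 0),
       y_scale = sqrt(sig_s2) * tau_v)   # y_phys = y_scale * y_scaled
}

# Scaled state-space model for the kinase filter (tau_1 = 0 branch).
# The kinase activity is a(t) = a0 - G_r (u - m) + n with u = r0 x + sqrt(r0) xi
# and dm = (u - m)/tau_2 dt. The integrator x enters the observation only
# through q = (m/r0 - x), so the filter states are z = (s/sig_s, q/(sig_s
# tau_v), n/sig_n) -- all stable. Observation y = (a - a0)/(G_r r0 sig_s tau_v)
# = q + (sig_n/(G_r r0 sig_s tau_v)) n - xi/(sqrt(r0) sig_s tau_v): white
# observation noise of intensity R correlated with the process noise driving q
# (cross-intensity -R/tau_2).
ss_kinase <- function(r0, sig_s2, tau_v, G_r, tau_2, D_n, tau_n) {
  # coincident time constants make the Hamiltonian defective; nudge
  if (abs(tau_n - tau_2) < 1e-9 * tau_2) tau_n <- tau_2 * (1 + 1e-6)
  if (abs(tau_n - tau_v) < 1e-9 * tau_v) tau_n <- tau_n * (1 + 1e-6)
  if (abs(tau_2 - tau_v) < 1e-9 * tau_v) tau_2 <- tau_2 * (1 + 1e-6)
  sig_s <- sqrt(sig_s2)
  sig_n <- sqrt(max(D_n, 0) * tau_n)
  Rr <- 1 / (r0 * sig_s2 * tau_v^2)
  A <- matrix(0, 3, 3)
  A[1, 1] <- -1 / tau_v
  A[2, 1] <- -1 / tau_v
  A[2, 2] <- -1 / tau_2
  A[3, 3] <- -1 / tau_n
  Q <- diag(c(2 / tau_v, Rr / tau_2^2, 2 / tau_n))
  if (D_n <= 0) Q[3, 3] <- 0
  C <- c(0, 1, sig_n / (G_r * r0 * sig_s * tau_v))
  S <- c(0, -Rr / tau_2, 0)
  list(A = A, C = C, Q = Q, R = Rr, S = S,
       y_scale = G_r * r0 * sig_s * tau_v)
}

# Solve a scaled model; rho^2 computed cancellation-free from the filter gain:
# the shat-row of the closed-loop dynamics is autonomous (A row 1 couples only
# to itself), so Var(shat)/sig_s2 = K1^2 R tau_v / 2 exactly.
solve_scaled_filter <- function(ss, tau_v, sig_s2) {
  sol <- care_filter(ss$A, ss$C, ss$Q, ss$R, ss$S)
  rho2 <- as.numeric(sol$K[1]^2 * ss$R * tau_v / 2)
  rho2 <- min(max(rho2, 0), 1)
  list(P = sol$P, K = sol$K, rho2 = rho2,
       posterior_var = sig_s2 * (1 - rho2))
}
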