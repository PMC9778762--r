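# Small fixtures and an R-level reference RK4 stepper used to cross-check
# the compiled integrator.

# pair parameters for very small systems (n may be < 3, below the
# tripartition minimum, so resolve via a padded gene and trim)
toy_pair_params <- function(bases, EcrH = 1e-18, beta_zero = TRUE,
                            params = mech_params()) {
  n <- length(bases)
  g <- gene_sequence(rep(bases, length.out = max(3L, n)))
  pp <- resolve_pair_params(g, params, EcrH)
  for (f in c("I1", "I2", "R1", "R2", "K1", "K2", "k12", "beta1", "beta2",
              "Ecr"))
    pp[[f]] <- pp[[f]][seq_len(n)]
  pp$n <- n
  if (beta_zero) {
    pp$beta1[] <- 0
    pp$beta2[] <- 0
  }
  pp
}

# one full RK4 step + bond update, built only on the exported R-level
# pure functions; independent of the compiled loop
rk4_step_r <- function(state, pp, cfg, t) {
  dt <- cfg$dt
  bump <- function(s, k, h) {
    s$phi1 <- state$phi1 + h * k$dphi1
    s$phi2 <- state$phi2 + h * k$dphi2
    s$v1 <- state$v1 + h * k$dv1
    s$v2 <- state$v2 + h * k$dv2
    s
  }
  k1 <- equations_rhs(t, state, pp, cfg)
  k2 <- equations_rhs(t + dt / 2, bump(state, k1, dt / 2), pp, cfg)
  k3 <- equations_rhs(t + dt / 2, bump(state, k2, dt / 2), pp, cfg)
  k4 <- equations_rhs(t + dt, bump(state, k3, dt), pp, cfg)
  state$phi1 <- state$phi1 + dt / 6 * (k1$dphi1 + 2 * k2$dphi1 + 2 * k3$dphi1 + k4$dphi1)
  state$phi2 <- state$phi2 + dt / 6 * (k1$dphi2 + 2 * k2$dphi2 + 2 * k3$dphi2 + k4$dphi2)
  state$v1 <- state$v1 + dt / 6 * (k1$dv1 + 2 * k2$dv1 + 2 * k3$dv1 + k4$dv1)
  state$v2 <- state$v2 + dt / 6 * (k1$dv2 + 2 * k2$dv2 + 2 * k3$dv2 + k4$dv2)
  state$delta <- update_bond_states(state, pp)
  state
}

# analytic small-angle eigenfrequencies of a single pair (2x2 generalized
# eigenproblem of the linearized coupling about (0, pi))
pair_eigenfrequencies <- function(pp) {
  S <- matrix(c(pp$k12[1] * pp$R1[1] * (pp$R1[1] + 2 * pp$R2[1]),
                -pp$k12[1] * pp$R1[1] * pp$R2[1],
                -pp$k12[1] * pp$R1[1] * pp$R2[1],
                pp$k12[1] * pp$R2[1] * (2 * pp$R1[1] + pp$R2[1])), 2L, 2L)
  M <- diag(c(pp$I1[1], pp$I2[1]))
  ev <- eigen(solve(M, S))
  list(omega = sqrt(ev$values), vectors = ev$vectors)
}

# 60-pair gene with the per-part A-T percentages of the studied gene
toy_gene_60 <- function(seed = 42L) {
  synthesize_gene(composition_spec(lengths = c(20L, 20L, 20L),
                                   at_pct = c(49.8, 57.1, 72.2),
                                   seed = seed))
}
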