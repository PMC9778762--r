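test_that("substitution scales only the targeted pair's k12 and Ecr", {
  pp <- toy_pair_params(c("A", "C", "G", "T", "A"), EcrH = 1e-22)
  sub <- apply_substitution(pp, 5L, kD = 1.05)
  expect_equal(sub$k12[5L], 1.05 * pp$k12[5L])
  expect_equal(sub$Ecr[5L], 1.05 * 1e-22)
  expect_equal(sub$k12[1:4], pp$k12[1:4])
  expect_equal(sub$Ecr[1:4], pp$Ecr[1:4])
  ident <- apply_substitution(pp, 2L, kD = 1)
  expect_equal(ident$k12, pp$k12)
  expect_equal(ident$Ecr, pp$Ecr)
  expect_error(apply_substitution(pp, 6L), "out of range")
  expect_error(apply_substitution(pp, 0L), "out of range")
})

test_that("pair potential vanishes at equilibrium and is non-negative", {
  pp <- toy_pair_params(c("A", "C", "G", "T"))
  expect_equal(pair_binding_energy(rep(0, 4), rep(pi, 4), pp), rep(0, 4))
  set.seed(1)
  for (k in 1:50) {
    v <- pair_binding_energy(stats::runif(4, -pi, pi),
                             stats::runif(4, 0, 2 * pi), pp)
    expect_true(all(v >= 0))
  }
  expect_error(pair_binding_energy(0, pi, pp, i = 9L), "out of range")
})

test_that("minus the potential gradient reproduces the coupling torques", {
  # central finite differences at 100 random angle pairs, both chains
  pp <- toy_pair_params("G")
  cfg <- sim_config(F0 = 0, T = 1e-13, dt = 1e-15, m = 10, EcrH = 1e-18)
  h <- 1e-6
  set.seed(42)
  for (k in 1:100) {
    p1 <- stats::runif(1, -pi, pi)
    p2 <- stats::runif(1, 0, 2 * pi)
    st <- list(phi1 = p1, phi2 = p2, v1 = 0, v2 = 0, delta = 1L)
    rhs <- equations_rhs(0, st, pp, cfg)
    torque1 <- rhs$dv1 * pp$I1  # only coupling acts (n = 1, F0 = 0, beta = 0)
    torque2 <- rhs$dv2 * pp$I2
    g1 <- (pair_binding_energy(p1 + h, p2, pp) -
             pair_binding_energy(p1 - h, p2, pp)) / (2 * h)
    g2 <- (pair_binding_energy(p1, p2 + h, pp) -
             pair_binding_energy(p1, p2 - h, pp)) / (2 * h)
    scale <- max(abs(torque1), abs(torque2), pp$k12 * pp$R1[1]^2 * 1e-6)
    expect_lt(abs(torque1 + g1) / scale, 1e-6)
    expect_lt(abs(torque2 + g2) / scale, 1e-6)
  }
})

test_that("small displacements see the linearized quadratic potential", {
  pp <- toy_pair_params("A")
  u <- 1e-3
  k_eff <- pp$k12 * pp$R1 * (pp$R1 + 2 * pp$R2)  # chain-1 diagonal stiffness
  v <- pair_binding_energy(u, pi, pp)
  expect_lt(abs(v - 0.5 * k_eff * u^2) / (0.5 * k_eff * u^2), 0.01)
})

test_that("equilibrium is stationary and torque-free cases are inert", {
  pp <- toy_pair_params(c("A", "C", "G"), beta_zero = FALSE)
  cfg0 <- sim_config(F0 = 0, T = 1e-13, dt = 1e-15, m = 10, EcrH = 1e-18)
  st <- equilibrium_state(3L)
  rhs <- equations_rhs(0, st, pp, cfg0)
  # zero up to the float representation of pi (sin(pi) ~ 1e-16) times the
  # stiffness-to-inertia scale of the accelerations
  accel_scale <- max(pp$k12 * (pp$R1 + pp$R2)^2 / pmin(pp$I1, pp$I2))
  expect_lt(max(abs(rhs$dv1)), 1e-12 * accel_scale)
  expect_lt(max(abs(rhs$dv2)), 1e-12 * accel_scale)
  expect_equal(rhs$dphi1, rep(0, 3))
  # integrated: stays at equilibrium to machine precision
  tr <- integrate_dynamics(config = cfg0, pp = pp)
  expect_lt(max(abs(tr$final$phi1)), 1e-14)
  expect_lt(max(abs(tr$final$phi2 - pi)), 1e-14)
  expect_true(all(tr$q == 0))
  # all torques off: zero acceleration at any angles
  ppz <- pp
  ppz$K1[] <- 0; ppz$K2[] <- 0; ppz$beta1[] <- 0; ppz$beta2[] <- 0
  stz <- list(phi1 = c(0.3, -1, 2), phi2 = c(1, 4, 0.2),
              v1 = rep(0, 3), v2 = rep(0, 3), delta = rep(0L, 3))
  rhz <- equations_rhs(0.5e-12, stz, ppz, cfg0)
  expect_equal(rhz$dv1, rep(0, 3))
  expect_equal(rhz$dv2, rep(0, 3))
})

test_that("bond automaton follows the strict break/restore rules with tie freeze", {
  pp <- toy_pair_params(c("A", "G"))
  st <- equilibrium_state(2L)
  st$phi1 <- c(0.3, 0.3)
  v <- pair_binding_energy(st$phi1, st$phi2, pp)
  # break: energy above critical
  pp$Ecr <- v * c(0.8, 0.8)
  expect_equal(update_bond_states(st, pp), c(0L, 0L))
  # restore: energy below critical, starting broken
  st$delta <- c(0L, 0L)
  pp$Ecr <- v * c(2, 2)
  expect_equal(update_bond_states(st, pp), c(1L, 1L))
  # exact tie leaves flags unchanged
  pp$Ecr <- v
  st$delta <- c(0L, 1L)
  expect_equal(update_bond_states(st, pp), c(0L, 1L))
})

test_that("energy is conserved without damping, forcing or bond events", {
  # uniform (poly-A) parameters so the per-base backbone constants are a
  # conservative field; 1e4 RK4 steps
  g <- gene_sequence(strrep("A", 10))
  pp <- resolve_pair_params(g, mech_params(), Inf)
  pp$beta1[] <- 0; pp$beta2[] <- 0
  init <- equilibrium_state(10L)
  init$phi1[3] <- 0.3
  init$phi2[5] <- pi - 0.2
  cfg <- sim_config(F0 = 0, T = 2e-11, dt = 2e-15, m = 100, EcrH = 1e-18)
  expect_equal(cfg$m * cfg$steps_per_sample, 10000)
  E0 <- system_energy(init, pp)
  tr <- integrate_dynamics(config = cfg, pp = pp, init = init)
  expect_true(all(tr$final$delta == 1L))  # no break events occurred
  expect_lt(abs(system_energy(tr$final, pp) - E0) / E0, 1e-6)
})

test_that("kD = 1 substitution reproduces the baseline bitwise", {
  g <- toy_gene_60()
  p <- mech_params(kD = 1)
  cfg0 <- sim_config(T = 3e-12, dt = 1e-14, m = 50, EcrH = 2e-25, kD = 1)
  cfgs <- sim_config(T = 3e-12, dt = 1e-14, m = 50, EcrH = 2e-25, kD = 1,
                     site = 7L)
  tr0 <- integrate_dynamics(g, p, cfg0)
  trs <- integrate_dynamics(g, p, cfgs)
  expect_identical(trs$q, tr0$q)
  expect_identical(trs$final, tr0$final)
})

test_that("trajectories are deterministic and dt-convergent", {
  g <- toy_gene_60()
  p <- mech_params()
  cfg <- sim_config(T = 3e-12, dt = 1e-14, m = 50, EcrH = 1e-18)
  tr1 <- integrate_dynamics(g, p, cfg)
  tr2 <- integrate_dynamics(g, p, cfg)
  expect_identical(tr1$final, tr2$final)
  # halving dt moves final angles by < 1e-4 relative on a 10-pair gene
  g10 <- gene_sequence(strrep("ACGTA", 2))
  cfga <- sim_config(T = 3e-12, dt = 1e-14, m = 50, EcrH = 1e-18)
  cfgb <- sim_config(T = 3e-12, dt = 5e-15, m = 50, EcrH = 1e-18)
  tra <- integrate_dynamics(g10, p, cfga)
  trb <- integrate_dynamics(g10, p, cfgb)
  denom <- max(abs(trb$final$phi1))
  expect_lt(max(abs(tra$final$phi1 - trb$final$phi1)) / denom, 1e-4)
})

test_that("small-angle eigenfrequencies match the 2x2 analytic oracle", {
  pp <- toy_pair_params("G")
  an <- pair_eigenfrequencies(pp)
  for (k in 1:2) {
    per <- 2 * pi / an$omega[k]
    init <- equilibrium_state(1L)
    eps <- 1e-4
    init$phi1 <- eps * an$vectors[1L, k]
    init$phi2 <- pi + eps * an$vectors[2L, k]
    cfg <- sim_config(F0 = 0, T = 10 * per, dt = per / 2000, m = 2000,
                      EcrH = 1e-18)
    tr <- integrate_dynamics(config = cfg, pp = pp, init = init,
                             keep_trajectory = TRUE)
    u <- if (k == 1) tr$phi1[, 1L] else tr$phi2[, 1L] - pi
    s <- sign(u)
    cross <- which(diff(s) != 0)
    tc <- tr$t[cross] - u[cross] * (tr$t[cross + 1L] - tr$t[cross]) /
      (u[cross + 1L] - u[cross])
    omega_meas <- pi / mean(diff(tc))
    expect_lt(abs(omega_meas - an$omega[k]) / an$omega[k], 0.01)
  }
})

test_that("compiled integrator matches the R reference stepper exactly", {
  pp <- toy_pair_params(c("A", "C", "G", "T", "A"), EcrH = 1e-24,
                        beta_zero = FALSE)
  cfg <- sim_config(T = 5e-14, dt = 1e-14, m = 5, EcrH = 1e-24)
  init <- equilibrium_state(5L)
  init$phi1[2] <- 0.2
  init$v2[4] <- 1e10
  st <- init
  t <- 0
  for (j in 1:5) {
    st <- rk4_step_r(st, pp, cfg, t)
    t <- t + cfg$dt
  }
  tr <- integrate_dynamics(config = cfg, pp = pp, init = init)
  expect_identical(st$phi1, tr$final$phi1)
  expect_identical(st$phi2, tr$final$phi2)
  expect_identical(st$v1, tr$final$v1)
  expect_identical(st$v2, tr$final$v2)
  expect_identical(st$delta, tr$final$delta)
})

test_that("the step-size guard rejects unstable steps", {
  g <- gene_sequence(strrep("G", 5))
  expect_error(
    integrate_dynamics(g, mech_params(),
                       sim_config(T = 1e-11, dt = 1e-12, m = 10, EcrH = 1e-18)),
    "stability guard")
})
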