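#' Simulation configuration
#'
#' Holds forcing, dissipation, integration and sampling settings for the
#' torsional dynamics. All quantities are SI: energies in J (N m), times in
#' s. The defaults follow the study conditions: forcing amplitude
#' `F0 = 0.526e-22` N m, angular frequency `omega = 0.4e12` 1/s, total time
#' `T = 3.0e-10` s, step `dt = 1e-14` s, `m = 1000` sample points.
#'
#' @param F0 external forcing torque amplitude (N m).
#' @param omega forcing angular frequency (1/s).
#' @param T total simulated time (s).
#' @param dt integration step (s).
#' @param m number of sample times `t_j = j T / m`, `j = 1..m` (t = 0 is
#'   not sampled). `T/(m dt)` must round to a positive integer number of
#'   steps per sample.
#' @param EcrH critical hydrogen-bond break energy (J).
#' @param kD deuterium strengthening factor.
#' @param site substitution site (pair index) or `NA` for the all-protium
#'   molecule.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(F0 = 0.526e-22, omega = 0.4e12, T = 3.0e-10,
                       dt = 1e-14, m = 1000L, EcrH = 0.581e-22,
                       kD = 1.05, site = NA_integer_) {
  stopifnot(dt > 0, m >= 1, T >= m * dt, EcrH > 0, kD >= 1, F0 >= 0,
            omega > 0)
  sps <- round(T / (m * dt))
  if (sps < 1) stop("T/(m*dt) must be at least 1 step per sample")
  structure(list(F0 = F0, omega = omega, T = T, dt = dt, m = as.integer(m),
                 steps_per_sample = as.integer(sps), EcrH = EcrH, kD = kD,
                 site = as.integer(site)), class = "sim_config")
}

#' Pair binding potential
#'
#' Potential energy of the transverse coupling of pair `i`, in J. The
#' potential is chosen so that minus its partial derivatives reproduce the
#' coupling torques of the equations of motion on both chains, and it is
#' normalized to zero at the equilibrium configuration `(phi1, phi2) =
#' (0, pi)`, which is its global minimum (so the value is always >= 0).
#' It is always evaluated with the full stiffness `k12[i]` regardless of
#' the bond flag, because a broken pair must still be tested for
#' restoration.
#'
#' @param phi1,phi2 chain-1 and chain-2 angles (rad) of pair `i` (scalars
#'   or vectors; with vectors the potential of every pair is returned).
#' @param pp a `pair_params` object.
#' @param i pair index, or `NULL` to evaluate all pairs.
#' @return numeric, binding energy in J, `>= 0`.
#' @export
pair_binding_energy <- function(phi1, phi2, pp, i = NULL) {
  if (!is.null(i)) {
    if (any(i < 1L | i > pp$n)) stop("pair index out of range")
    r1 <- pp$R1[i]; r2 <- pp$R2[i]; k <- pp$k12[i]
  } else {
    r1 <- pp$R1; r2 <- pp$R2; k <- pp$k12
  }
  k * ((r1 + r2)^2 + r1 * r2 -
         r1 * (r1 + r2) * cos(phi1) + r2 * (r1 + r2) * cos(phi2) +
         r1 * r2 * cos(phi1 - phi2))
}

# coupling torques (-dV/dphi) on both chains, vectorized over pairs
coupling_torques <- function(phi1, phi2, pp) {
  r1 <- pp$R1; r2 <- pp$R2; k <- pp$k12
  t1 <- k * (-r1 * (r1 + r2) * sin(phi1) + r1 * r2 * sin(phi1 - phi2))
  t2 <- k * (r2 * (r1 + r2) * sin(phi2) + r1 * r2 * sin(phi2 - phi1))
  list(t1 = t1, t2 = t2)
}

# backbone (sugar-phosphate) torque: discrete Laplacian, one-sided at ends
backbone_torque <- function(phi, K) {
  n <- length(phi)
  if (n == 1L) return(0)
  left <- c(0, K[-1L] * (phi[-n] - phi[-1L]))
  right <- c(K[-n] * (phi[-1L] - phi[-n]), 0)
  left + right
}

#' Right-hand side of the equations of motion
#'
#' Angular accelerations and velocities of the 2n-rotor system:
#' `I phi'' = backbone + delta * coupling + F0 cos(omega t) - beta phi'`,
#' with the coupling torque derived from [pair_binding_energy()] and gated
#' by the bond flag `delta` (a broken pair, `delta = 0`, loses only its
#' transverse coupling). Boundary pairs use one-sided backbone terms.
#'
#' @param t time (s).
#' @param state list with numeric vectors `phi1`, `phi2`, `v1`, `v2` and
#'   integer vector `delta`.
#' @param pp a `pair_params` object.
#' @param config a [sim_config()].
#' @return list of derivatives `dphi1`, `dphi2`, `dv1`, `dv2`.
#' @export
equations_rhs <- function(t, state, pp, config) {
  ct <- coupling_torques(state$phi1, state$phi2, pp)
  f <- config$F0 * cos(config$omega * t)
  a1 <- (backbone_torque(state$phi1, pp$K1) + state$delta * ct$t1 +
           f - pp$beta1 * state$v1) / pp$I1
  a2 <- (backbone_torque(state$phi2, pp$K2) + state$delta * ct$t2 +
           f - pp$beta2 * state$v2) / pp$I2
  list(dphi1 = state$v1, dphi2 = state$v2, dv1 = a1, dv2 = a2)
}

#' Update bond break/restore flags
#'
#' A bond breaks (`delta = 0`) when its binding energy exceeds the pair's
#' critical value, and a broken bond is restored (`delta = 1`) when the
#' energy falls below it. Equality leaves the flag unchanged (the rules are
#' strict inequalities).
#'
#' @param state list with `phi1`, `phi2`, `delta`.
#' @param pp a `pair_params` object.
#' @return integer vector, the new `delta`.
#' @export
update_bond_states <- function(state, pp) {
  v <- pair_binding_energy(state$phi1, state$phi2, pp)
  delta <- state$delta
  delta[v > pp$Ecr] <- 0L
  delta[v < pp$Ecr] <- 1L
  delta
}

#' Equilibrium initial state
#'
#' The rest configuration of the model: `phi1 = 0`, `phi2 = pi`, zero
#' angular velocities, all bonds intact.
#'
#' @param n number of pairs.
#' @return state list (`phi1`, `phi2`, `v1`, `v2`, `delta`).
#' @export
equilibrium_state <- function(n) {
  list(phi1 = rep(0, n), phi2 = rep(pi, n), v1 = rep(0, n), v2 = rep(0, n),
       delta = rep(1L, n))
}

# characteristic angular frequency used by the step-size guard
char_frequency <- function(pp) {
  max(sqrt((pmax(pp$K1, pp$K2) + pp$k12 * pmax(pp$R1, pp$R2) *
              (pp$R1 + pp$R2)) / pmin(pp$I1, pp$I2)))
}

#' Integrate the torsional dynamics
#'
#' Fixed-step classical RK4 integration of the 2n coupled equations of
#' motion from the equilibrium initial conditions (or a supplied initial
#' state), with the bond break/restore automaton applied once after each
#' full step. The trajectory is deterministic: there is no randomness
#' anywhere in the model.
#'
#' @param gene a [gene_sequence()], or `NULL` when `pp` is supplied.
#' @param params a [mech_params()], ignored when `pp` is supplied.
#' @param config a [sim_config()]; its `site`/`kD` entries apply the
#'   deuterium substitution when `pp` is built here.
#' @param pp optional pre-resolved `pair_params` (overrides `gene`/`params`).
#' @param init optional initial state list (defaults to equilibrium).
#' @param keep_trajectory if `TRUE`, sampled angles and bond flags are
#'   returned (memory grows as `m * n`); the broken-pair fraction `q_j` is
#'   always returned.
#' @return An object of class `dna_trajectory`: list with `t` (sample
#'   times), `q` (broken fraction at each sample), `final` (final state),
#'   `config`, `n`, and optionally matrices `phi1`, `phi2`, `delta`
#'   (`m x n`).
#' @export
integrate_dynamics <- function(gene = NULL, params = mech_params(),
                               config = sim_config(), pp = NULL,
                               init = NULL, keep_trajectory = FALSE) {
  if (is.null(pp)) {
    stopifnot(inherits(gene, "gene_sequence"))
    pp <- resolve_pair_params(gene, params, config$EcrH)
    if (!is.na(config$site)) pp <- apply_substitution(pp, config$site, config$kD)
  }
  wc <- char_frequency(pp)
  if (is.finite(wc) && config$dt > 0.5 / wc)
    stop(sprintf("dt = %.3g s exceeds the stability guard 0.5/omega_char = %.3g s",
                 config$dt, 0.5 / wc))
  if (is.null(init)) init <- equilibrium_state(pp$n)
  ecr <- pp$Ecr
  ecr[!is.finite(ecr)] <- .Machine$double.xmax  # Inf means "never breaks"
  res <- rk4_bond_automaton(
    pp$I1, pp$I2, pp$K1, pp$K2, pp$R1, pp$R2, pp$k12,
    pp$beta1, pp$beta2, ecr,
    init$phi1, init$phi2, init$v1, init$v2, as.integer(init$delta),
    config$F0, config$omega, config$dt,
    config$m, config$steps_per_sample, isTRUE(keep_trajectory))
  if (!is.null(res$error_step))
    stop(sprintf("non-finite state at step %d (pair %d)",
                 res$error_step, res$error_pair))
  out <- list(t = seq_len(config$m) * config$steps_per_sample * config$dt,
              q = res$q, final = res$final, config = config, n = pp$n,
              site = pp$site)
  if (keep_trajectory) {
    out$phi1 <- res$phi1; out$phi2 <- res$phi2; out$delta <- res$delta
  }
  structure(out, class = "dna_trajectory")
}

#' Total mechanical energy of a state
#'
#' Kinetic energy plus backbone torsion energy plus the pair binding
#' potential of intact pairs. With zero damping, zero forcing and no bond
#' events this is a conserved quantity of the dynamics (used by the
#' integrator's accuracy checks). The backbone term assumes per-segment
#' constants; with per-base constants it uses the mean of the two adjacent
#' bases' values.
#'
#' @param state state list (`phi1`, `phi2`, `v1`, `v2`, `delta`).
#' @param pp a `pair_params` object.
#' @return energy in J.
#' @export
system_energy <- function(state, pp) {
  kin <- sum(0.5 * pp$I1 * state$v1^2 + 0.5 * pp$I2 * state$v2^2)
  seg <- function(phi, K) {
    n <- length(phi)
    if (n < 2L) return(0)
    kseg <- (K[-n] + K[-1L]) / 2
    sum(0.5 * kseg * (phi[-1L] - phi[-n])^2)
  }
  pot <- seg(state$phi1, pp$K1) + seg(state$phi2, pp$K2) +
    sum(state$delta * pair_binding_energy(state$phi1, state$phi2, pp))
  kin + pot
}

#' @export
print.dna_trajectory <- function(x, ...) {
  cat("dna_trajectory:", x$n, "pairs,", length(x$t), "samples over",
      format(max(x$t), digits = 3), "s\n")
  cat("  mean broken fraction q:", format(mean(x$q), digits = 4),
      " (max", format(max(x$q), digits = 4), ")\n")
  if (!is.na(x$site)) cat("  deuterium substitution at pair", x$site, "\n")
  invisible(x)
}

#' @export
plot.dna_trajectory <- function(x, ...) {
  graphics::plot(x$t, x$q, type = "l", xlab = "time (s)",
                 ylab = "broken-pair fraction q", ...)
  invisible(x)
}
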