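#' Per-base mechanical parameter set
#'
#' Coefficients of the coarse-grained torsional model, one value per base
#' type on each strand: rotational inertia `I` (kg m^2), distance `R` from
#' the base's center of inertia to the sugar-phosphate backbone (m),
#' backbone torsion constant `K` (N m), transverse pair-coupling stiffness
#' `k12` (N/m, resolved per pair from the first-strand base), and damping
#' coefficient `beta` (J s). `kD` is the dimensionless deuterium
#' strengthening factor (a deuterium bond is ~5% stronger than a hydrogen
#' bond, so `kD = 1.05`).
#'
#' The shipped defaults are literature-typical values for Yakushevich-type
#' base rotors; they are a calibration input of the model, not measured
#' constants, and can be overridden entry by entry. `beta` defaults to
#' `I / 1e-10`, i.e. a viscous damping time of about 1e-10 s in water.
#'
#' @param I named numeric (A, T, G, C), rotational inertias in kg m^2.
#' @param R named numeric, backbone-to-base distances in m.
#' @param K named numeric, torsion constants in N m.
#' @param k12 named numeric, pair stiffness in N/m keyed by base; A and T
#'   carry the two-hydrogen-bond A-T value, G and C the three-bond G-C value.
#' @param beta named numeric, damping coefficients in J s.
#' @param kD deuterium strengthening factor, dimensionless, `>= 1`.
#' @return An object of class `mech_params`.
#' @examples
#' p <- mech_params()
#' p$K[["G"]]
#' @export
mech_params <- function(I = c(A = 7.61e-44, T = 4.86e-44, G = 8.22e-44, C = 4.11e-44),
                        R = c(A = 5.8e-10, T = 4.8e-10, G = 5.7e-10, C = 4.7e-10),
                        K = 0.7 * R^2,
                        k12 = c(A = 0.062, T = 0.062, G = 0.096, C = 0.096),
                        beta = I / 1e-10,
                        kD = 1.05) {
  req <- c("A", "T", "G", "C")
  for (nmv in list(I = I, R = R, K = K, k12 = k12, beta = beta)) {
    if (!all(req %in% names(nmv))) stop("parameter vectors need names A, T, G, C")
  }
  vals <- c(I[req], R[req], K[req], k12[req], beta[req], kD)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all mechanical parameters must be finite and strictly positive")
  if (kD < 1) stop("kD must be >= 1")
  structure(list(I = I[req], R = R[req], K = K[req], k12 = k12[req],
                 beta = beta[req], kD = kD), class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("mech_params (per-base coefficients):\n")
  m <- rbind(I = x$I, R = x$R, K = x$K, k12 = x$k12, beta = x$beta)
  print(signif(m, 4))
  cat("kD =", x$kD, "\n")
  invisible(x)
}

#' Resolve per-pair parameter arrays for a gene
#'
#' Expands the per-base-type coefficients into per-pair arrays of length n:
#' chain 1 carries the first-strand base of each pair, chain 2 its
#' complement. The pair stiffness `k12[i]` and critical energy `Ecr[i]`
#' are those of an unsubstituted (all-protium) molecule; apply a deuterium
#' substitution afterwards with [apply_substitution()].
#'
#' @param gene a [gene_sequence()].
#' @param params a [mech_params()].
#' @param EcrH critical break energy of a hydrogen-bonded pair, in J (N m).
#' @return An object of class `pair_params`: list of numeric vectors
#'   `I1, I2, R1, R2, K1, K2, k12, beta1, beta2, Ecr`, plus `n` and `site`
#'   (NA until a substitution is applied).
#' @export
resolve_pair_params <- function(gene, params, EcrH) {
  stopifnot(inherits(gene, "gene_sequence"), inherits(params, "mech_params"))
  if (!is.finite(EcrH) && !identical(EcrH, Inf)) stop("EcrH must be positive")
  if (EcrH <= 0) stop("EcrH must be positive")
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  b1 <- gene$bases
  b2 <- comp[b1]
  structure(list(
    I1 = unname(params$I[b1]), I2 = unname(params$I[b2]),
    R1 = unname(params$R[b1]), R2 = unname(params$R[b2]),
    K1 = unname(params$K[b1]), K2 = unname(params$K[b2]),
    k12 = unname(params$k12[b1]),
    beta1 = unname(params$beta[b1]), beta2 = unname(params$beta[b2]),
    Ecr = rep(EcrH, gene$n),
    n = gene$n, site = NA_integer_, kD = params$kD
  ), class = "pair_params")
}

#' Apply a single deuterium substitution
#'
#' Replacing one hydrogen bond of pair `site` with deuterium strengthens
#' that pair: its coupling stiffness and critical energy are both scaled by
#' `kD` (`k12_D = kD * k12_H`, `Ecr_D = kD * EcrH`). All other pairs are
#' untouched; the rule is the same for A-T (2 bonds) and G-C (3 bonds)
#' pairs.
#'
#' @param pp a `pair_params` object from [resolve_pair_params()].
#' @param site 1-based pair index.
#' @param kD strengthening factor; defaults to the factor stored in `pp`.
#' @return The modified `pair_params`.
#' @export
apply_substitution <- function(pp, site, kD = pp$kD) {
  stopifnot(inherits(pp, "pair_params"))
  site <- as.integer(site)
  if (length(site) != 1L || is.na(site) || site < 1L || site > pp$n)
    stop("substitution site out of range 1..", pp$n)
  pp$k12[site] <- kD * pp$k12[site]
  pp$Ecr[site] <- kD * pp$Ecr[site]
  pp$site <- site
  pp
}
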