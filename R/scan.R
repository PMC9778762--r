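#' Broken-pair fraction of a state
#'
#' The ratio `q` of the number of pairs with a broken bond to the total
#' number of pairs.
#'
#' @param state state list with integer vector `delta` (1 intact, 0 broken).
#' @return numeric in `[0, 1]`.
#' @export
broken_fraction <- function(state) {
  d <- state$delta
  sum(d == 0L) / length(d)
}

#' Open-state probability estimator
#'
#' The time-averaged broken-pair fraction over the m sample times:
#' `P = (1/m) * sum_j q_j`.
#'
#' @param traj a `dna_trajectory` from [integrate_dynamics()], or a numeric
#'   vector of `q_j` values.
#' @return numeric in `[0, 1]`.
#' @export
open_state_probability <- function(traj) {
  q <- if (inherits(traj, "dna_trajectory")) traj$q else as.numeric(traj)
  if (length(q) == 0L) stop("empty trajectory")
  mean(q)
}

#' Scan every single-site deuterium substitution
#'
#' For each critical energy, runs one baseline (all-protium) simulation and
#' one simulation per substitution site (each with `k12` and `Ecr` of that
#' site scaled by `kD`), estimating the open-state probability `P0` and
#' `P_i` from the time-averaged broken-pair fraction. Every trajectory is
#' re-simulated from scratch: bond events feed back on the motion through
#' the coupling gate, so probabilities cannot be re-thresholded from one
#' trajectory. The scan is deterministic and its result is independent of
#' the order in which (site, energy) cells are computed.
#'
#' @param gene a [gene_sequence()].
#' @param params a [mech_params()].
#' @param config a [sim_config()]; its `EcrH`/`site` fields are ignored in
#'   favour of the scanned grid.
#' @param energies numeric vector of critical energies `EcrH` in J,
#'   strictly positive and ascending.
#' @param sites integer vector of substitution sites to scan (default all).
#' @param progress print one line per energy.
#' @return An object of class `os_scan`: list with `energies`, `P0`
#'   (length `|energies|`), `P` (`n x |energies|` matrix over scanned
#'   sites, rownames = site indices), `sites`, `gene`, `config`.
#' @export
scan_substitutions <- function(gene, params = mech_params(),
                               config = sim_config(), energies,
                               sites = seq_len(gene$n), progress = FALSE) {
  stopifnot(inherits(gene, "gene_sequence"))
  energies <- as.numeric(energies)
  if (length(energies) == 0L || any(energies <= 0) || is.unsorted(energies))
    stop("energies must be strictly positive and sorted ascending")
  sites <- as.integer(sites)
  if (any(sites < 1L | sites > gene$n)) stop("scan site out of range")
  P0 <- numeric(length(energies))
  P <- matrix(NA_real_, nrow = length(sites), ncol = length(energies),
              dimnames = list(sites, signif(energies, 6)))
  for (e in seq_along(energies)) {
    base_pp <- resolve_pair_params(gene, params, energies[e])
    run <- function(pp, label) {
      tr <- tryCatch(
        integrate_dynamics(config = config, pp = pp),
        error = function(err) stop("integration failed for ", label,
                                   " at EcrH = ", energies[e], ": ",
                                   conditionMessage(err)))
      open_state_probability(tr)
    }
    P0[e] <- run(base_pp, "baseline")
    for (s in seq_along(sites)) {
      pp <- apply_substitution(base_pp, sites[s], params$kD)
      P[s, e] <- run(pp, paste0("site ", sites[s]))
    }
    if (progress)
      message(sprintf("EcrH %.4g J: P0 = %.3g, max Pi = %.3g",
                      energies[e], P0[e], max(P[, e])))
  }
  structure(list(energies = energies, P0 = P0, P = P, sites = sites,
                 gene = gene, config = config), class = "os_scan")
}

#' @export
print.os_scan <- function(x, ...) {
  cat("os_scan:", length(x$sites), "sites x", length(x$energies),
      "critical energies\n")
  df <- data.frame(EcrH = x$energies, P0 = x$P0,
                   Pimax = apply(x$P, 2, max), Pimin = apply(x$P, 2, min))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write scan results as delimited text
#'
#' Long format, one row per (site, energy) cell; site 0 is the baseline.
#'
#' @param scan an `os_scan`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path) {
  stopifnot(inherits(scan, "os_scan"))
  base <- data.frame(site = 0L, EcrH = scan$energies, P = scan$P0)
  cells <- expand.grid(site = scan$sites, EcrH = scan$energies,
                       KEEP.OUT.ATTRS = FALSE)
  cells$P <- as.vector(scan$P)
  out <- rbind(base, cells)
  utils::write.csv(out[order(out$site, out$EcrH), ], path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.os_scan <- function(x, scale = 1e-22, ...) {
  e <- x$energies / scale
  graphics::matplot(e, t(x$P), pch = 16, col = grDevices::grey(0.6),
                    xlab = "EcrH (1e-22 N m)", ylab = "open-state probability",
                    ...)
  graphics::lines(e, x$P0, col = "red", lwd = 2)
  graphics::legend("topright", legend = c("P_i (per site)", "P0 (baseline)"),
                   col = c(grDevices::grey(0.6), "red"),
                   pch = c(16, NA), lty = c(NA, 1), bty = "n")
  invisible(x)
}
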