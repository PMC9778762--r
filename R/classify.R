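#' "Maximum" range of the modified Basov-Jimack algorithm
#'
#' Selects the substitution sites whose open-state probability `P_i` clears
#' the branch-dependent high threshold. With `Pimax = max(P)` and
#' `Pimin = min(P)`, and provided `Pimax > P0 >= Pimin >= 0`:
#' \itemize{
#'   \item branch 1: if `Pimax - (Pimax - Pimin)/10 >= P0 + (Pimax - P0)/2`,
#'     the threshold is `Pimax - (Pimax - Pimin)/10`;
#'   \item branch 2: otherwise the threshold is `Pimax - (Pimax - P0)/4`.
#' }
#' Membership is `P_i >= threshold`. When `Pimax <= P0` or `P0 < Pimin`
#' the range is empty (`nmax = 0`), which is what the saturated
#' highest-energy rows show.
#'
#' @param P numeric vector of per-site open-state probabilities (>= 0).
#' @param P0 baseline open-state probability.
#' @return list with `threshold` (NA when the range is empty), `branch`
#'   (1, 2 or NA), `members` (integer indices into `P`), `nmax`.
#' @export
maximum_range_count <- function(P, P0) {
  if (length(P) == 0L) stop("empty probability vector")
  if (any(P < 0) || P0 < 0) stop("probabilities must be >= 0")
  Pimax <- max(P); Pimin <- min(P)
  if (!(Pimax > P0 && P0 >= Pimin)) {
    return(list(threshold = NA_real_, branch = NA_integer_,
                members = integer(0), nmax = 0L))
  }
  thr1 <- Pimax - (Pimax - Pimin) / 10
  if (thr1 >= P0 + (Pimax - P0) / 2) {
    threshold <- thr1; branch <- 1L
  } else {
    threshold <- Pimax - (Pimax - P0) / 4; branch <- 2L
  }
  members <- which(P >= threshold)
  list(threshold = threshold, branch = branch, members = members,
       nmax = length(members))
}

#' Closed-state (CSNB) sites, counted per part and pair class
#'
#' A substitution site is a closed state of nitrogenous bases (CSNB) when
#' its open-state probability is exactly zero: the pair never opened at any
#' sample time. The estimator is a mean of non-negative rationals, so it is
#' exactly 0 iff no break was ever sampled; no tolerance is involved.
#'
#' @param P numeric vector of per-site probabilities, one per gene pair.
#' @param gene a [gene_sequence()] with `n == length(P)`.
#' @return data frame with columns `part`, `class`, `csnb` (six rows:
#'   3 parts x 2 classes).
#' @export
csnb_count <- function(P, gene) {
  stopifnot(inherits(gene, "gene_sequence"))
  if (length(P) != gene$n) stop("length mismatch between P and gene")
  zero <- P == 0
  part <- part_of(gene, seq_len(gene$n))
  cls <- pair_class(gene)
  tab <- table(part[zero], cls[zero])
  out <- expand.grid(part = factor(c("I", "II", "III"),
                                   levels = c("I", "II", "III")),
                     class = factor(c("A-T", "G-C"), levels = c("A-T", "G-C")),
                     KEEP.OUT.ATTRS = FALSE)
  out$csnb <- mapply(function(p, cl) {
    if (p %in% rownames(tab) && cl %in% colnames(tab)) tab[p, cl] else 0L
  }, as.character(out$part), as.character(out$class))
  out$csnb <- as.integer(out$csnb)
  out[order(out$part, out$class), ]
}

#' Weighted CSNB correction ("new approach")
#'
#' Down-weights a part's raw CSNB count as gene-wide closure saturates:
#' `n_CSNB = nx * (1 - ngCSNB/ng)^2`, where `nx` is the part's raw count,
#' `ngCSNB` the whole-gene CSNB count at the same critical energy and `ng`
#' the gene size. Early closed states (small `ngCSNB`) keep nearly full
#' weight; once the whole gene is closed the weight vanishes, which removes
#' the cumulative saturation artifact from part-to-part comparisons.
#'
#' @param nx raw CSNB count in the part.
#' @param ngCSNB whole-gene CSNB count at the same energy.
#' @param ng number of pairs in the whole gene.
#' @param truncate if `TRUE`, truncate toward zero to an integer (the
#'   convention used for the reported per-part sums); the continuous value
#'   is the one used in correlation analyses.
#' @return numeric (or integer-valued) weighted count, `<= nx`.
#' @export
weighted_csnb <- function(nx, ngCSNB, ng, truncate = FALSE) {
  if (any(nx < 0) || any(ngCSNB < 0) || any(ng <= 0))
    stop("counts must be non-negative")
  if (any(ngCSNB > ng)) stop("ngCSNB cannot exceed ng")
  w <- nx * (1 - ngCSNB / ng)^2
  w[ngCSNB == 0] <- 0
  if (truncate) trunc(w) else w
}

#' Lower quantile range Q2-min to Q4-min
#'
#' Membership rule for the sub-CSNB regime (only meaningful while
#' `P0 > 0`): site `i` belongs when `P_i <= Pimin + (3/4) (P0 - Pimin)`.
#' Kept as a separate operation; the default classification does not use
#' it.
#'
#' @param P numeric vector of per-site probabilities.
#' @param P0 baseline probability, `>= Pimin`.
#' @param Pimin minimum of `P` (recomputed when `NULL`).
#' @return integer indices of member sites.
#' @export
minimum_q2q4_range <- function(P, P0, Pimin = NULL) {
  if (is.null(Pimin)) Pimin <- min(P)
  if (P0 < Pimin) stop("P0 must be >= Pimin")
  which(P <= Pimin + 0.75 * (P0 - Pimin))
}

#' Classify a substitution scan
#'
#' Applies [maximum_range_count()] and [csnb_count()] at every scanned
#' critical energy, and attaches the weighted-CSNB correction (continuous
#' and truncated) per part. Counts are split by part and by the A-T / G-C
#' class of the substituted pair.
#'
#' @param scan an `os_scan` covering all sites of its gene.
#' @param gene a [gene_sequence()]; defaults to the scan's gene.
#' @return An object of class `bj_classification`: list with `table` (data
#'   frame: `ecrh`, `part`, `class`, `nmax`, `csnb`, `csnb_weighted`,
#'   `csnb_weighted_trunc`), `gene_csnb` (per-energy whole-gene counts),
#'   `thresholds` (per-energy threshold/branch), `energies`.
#' @export
classify_scan <- function(scan, gene = scan$gene) {
  stopifnot(inherits(scan, "os_scan"))
  if (nrow(scan$P) != gene$n)
    stop("scan must cover every site of the gene")
  ng <- gene$n
  rows <- list(); thr <- list()
  gene_csnb <- integer(length(scan$energies))
  for (e in seq_along(scan$energies)) {
    P <- scan$P[, e]
    mx <- maximum_range_count(P, scan$P0[e])
    part <- part_of(gene, seq_len(ng))
    cls <- pair_class(gene)
    nmax_tab <- table(part[mx$members], cls[mx$members])
    cs <- csnb_count(P, gene)
    ngCSNB <- sum(cs$csnb)
    gene_csnb[e] <- ngCSNB
    part_tot <- stats::aggregate(csnb ~ part, cs, sum)
    cs$nmax <- mapply(function(p, cl) {
      if (p %in% rownames(nmax_tab) && cl %in% colnames(nmax_tab))
        nmax_tab[p, cl] else 0L
    }, as.character(cs$part), as.character(cs$class))
    cs$nmax <- as.integer(cs$nmax)
    pt <- part_tot$csnb[match(cs$part, part_tot$part)]
    # the weighting is applied to part totals; per-class rows carry the
    # same whole-gene damping factor
    cs$csnb_weighted <- weighted_csnb(cs$csnb, ngCSNB, ng)
    cs$csnb_weighted_trunc <- weighted_csnb(cs$csnb, ngCSNB, ng, truncate = TRUE)
    cs$part_csnb <- as.integer(pt)
    cs$part_csnb_weighted <- weighted_csnb(pt, ngCSNB, ng)
    cs$part_csnb_weighted_trunc <- weighted_csnb(pt, ngCSNB, ng, truncate = TRUE)
    cs$ecrh <- scan$energies[e]
    rows[[e]] <- cs[, c("ecrh", "part", "class", "nmax", "csnb",
                        "csnb_weighted", "csnb_weighted_trunc",
                        "part_csnb", "part_csnb_weighted",
                        "part_csnb_weighted_trunc")]
    thr[[e]] <- data.frame(ecrh = scan$energies[e], P0 = scan$P0[e],
                           Pimax = max(P), Pimin = min(P),
                           threshold = mx$threshold, branch = mx$branch,
                           nmax = mx$nmax)
  }
  part_sizes <- table(part_of(gene, seq_len(ng)))
  structure(list(table = do.call(rbind, rows),
                 thresholds = do.call(rbind, thr),
                 gene_csnb = gene_csnb, energies = scan$energies,
                 ng = ng,
                 part_sizes = stats::setNames(as.integer(part_sizes),
                                              names(part_sizes))),
            class = "bj_classification")
}

#' @export
print.bj_classification <- function(x, ...) {
  cat("bj_classification over", length(x$energies), "critical energies",
      "(gene of", x$ng, "pairs)\n")
  print(x$thresholds, row.names = FALSE)
  invisible(x)
}

#' @export
plot.bj_classification <- function(x, scale = 1e-22, ...) {
  tab <- x$table
  agg <- stats::aggregate(csnb ~ ecrh + part, tab, sum)
  sizes <- stats::aggregate(cbind(one = rep(1, nrow(tab))) ~ part, tab,
                            length)
  e <- sort(unique(agg$ecrh)) / scale
  graphics::matplot(e, sapply(levels(agg$part), function(p)
    agg$csnb[agg$part == p][order(agg$ecrh[agg$part == p])]),
    type = "b", pch = 1:3, lty = 1,
    xlab = "EcrH (1e-22 N m)", ylab = "CSNB count", ...)
  graphics::legend("topleft", legend = paste("part", levels(agg$part)),
                   pch = 1:3, lty = 1, col = 1:3, bty = "n")
  invisible(x)
}

#' Write a classification table as delimited text
#'
#' @param cls a `bj_classification`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_classification <- function(cls, path) {
  stopifnot(inherits(cls, "bj_classification"))
  utils::write.csv(cls$table, path, row.names = FALSE)
  invisible(path)
}
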