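#' Yates-corrected chi-squared test for a 2x2 table
#'
#' The shortcut form
#' `chi2 = N (|ad - bc| - N/2)^2 / (NA NB NS NF)` with the continuity
#' correction clamped at zero when `|ad - bc| < N/2` (otherwise the
#' correction would manufacture a positive statistic from a null table).
#' One degree of freedom.
#'
#' @param a,b,c,d the four cell counts (row-wise), or `a` may be a 2x2
#'   matrix.
#' @return An `htest` object with `statistic`, `parameter` (df) and
#'   `p.value`.
#' @export
yates_chi2 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2L, 2L)))
    b <- a[1L, 2L]; c <- a[2L, 1L]; d <- a[2L, 2L]; a <- a[1L, 1L]
  }
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("negative cell count")
  NA. <- a + b; NB <- c + d; NS <- a + c; NF <- b + d
  if (any(c(NA., NB, NS, NF) == 0)) stop("degenerate table: zero margin")
  N <- NA. + NB
  stat <- N * max(0, abs(a * d - b * c) - N / 2)^2 / (NA. * NB * NS * NF)
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = 1),
                 p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = "Chi-squared test with Yates continuity correction",
                 data.name = sprintf("2x2 table [%g %g; %g %g]", a, b, c, d)),
            class = "htest")
}

#' Pearson chi-squared for an r x 2 table with Bonferroni adjustment
#'
#' Plain Pearson statistic `sum (O - E)^2 / E` with expected counts from
#' the margins, `df = (r - 1)(c - 1)`, and the p-value multiplied by the
#' number of comparisons `k` (capped at 1). Intended for the 3x2 part-wise
#' count comparisons, where three pairwise contrasts share one family.
#'
#' @param grid integer matrix of counts (rows = groups, 2 columns).
#' @param comparisons Bonferroni family size `k` (default 1: no
#'   adjustment).
#' @return An `htest` with `statistic`, `parameter`, `p.value` and
#'   `adjusted.p.value`.
#' @export
chi2_rx2_bonferroni <- function(grid, comparisons = 1L) {
  grid <- as.matrix(grid)
  if (any(grid < 0)) stop("negative cell count")
  if (any(rowSums(grid) == 0) || any(colSums(grid) == 0))
    stop("degenerate table: zero margin")
  E <- outer(rowSums(grid), colSums(grid)) / sum(grid)
  stat <- sum((grid - E)^2 / E)
  df <- (nrow(grid) - 1L) * (ncol(grid) - 1L)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = c("X-squared" = stat),
                 parameter = c(df = df), p.value = p,
                 adjusted.p.value = min(1, p * comparisons),
                 method = sprintf(
                   "Pearson chi-squared (%d x %d) with Bonferroni k = %d",
                   nrow(grid), ncol(grid), comparisons),
                 data.name = "count grid"),
            class = "htest")
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-squared reference distribution on
#' `(number of groups - 1)` degrees of freedom. When every observation is
#' equal the tie-correction denominator vanishes; by convention the
#' statistic is then 0 (no evidence of any difference).
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return An `htest` with `statistic` (H), `parameter` (df), `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) == 0L))
    stop("need at least two non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df <- length(groups) - 1L
  if (length(unique(x)) == 1L) {
    return(structure(list(statistic = c("Kruskal-Wallis H" = 0),
                          parameter = c(df = df), p.value = 1,
                          method = "Kruskal-Wallis rank sum test",
                          data.name = "groups"),
                     class = "htest"))
  }
  kt <- stats::kruskal.test(x, g)
  structure(list(statistic = c("Kruskal-Wallis H" = unname(kt$statistic)),
                 parameter = c(df = df), p.value = kt$p.value,
                 method = "Kruskal-Wallis rank sum test",
                 data.name = "groups"),
            class = "htest")
}

# two-sided p for a rank correlation via the t approximation on n - 2 df
spearman_p_t <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
}

#' Spearman rank correlation, d^2 formula
#'
#' Mean ranks are assigned to ties and the classical formula
#' `rho = 1 - 6 sum(d^2) / (n (n^2 - 1))` is applied with
#' `d = rank(x) - rank(y)`. With ties this differs (slightly) from the
#' Pearson correlation of the ranks; both variants are exposed because the
#' reported coefficients require one each.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return An `htest` with `estimate` (rho), `statistic` (sum of d^2) and
#'   `p.value` (t approximation, n - 2 df).
#' @export
spearman_d2 <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  d <- rank(x) - rank(y)
  r <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))
  structure(list(estimate = c(rho = r),
                 statistic = c(S = sum(d^2)),
                 p.value = spearman_p_t(r, n),
                 method = "Spearman rank correlation (d^2 formula)",
                 data.name = "x and y"),
            class = "htest")
}

#' Spearman rank correlation as Pearson correlation of mean ranks
#'
#' Exact under heavy ties (it is the definition the tie-corrected Spearman
#' coefficient reduces to).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return An `htest` with `estimate` (rho) and `p.value` (t
#'   approximation, n - 2 df).
#' @export
spearman_rank_pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3L) stop("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite input")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    stop("constant input: rank variance is zero")
  r <- stats::cor(rx, ry)
  structure(list(estimate = c(rho = r),
                 p.value = spearman_p_t(r, n),
                 method = "Spearman rank correlation (Pearson on mean ranks)",
                 data.name = "x and y"),
            class = "htest")
}
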