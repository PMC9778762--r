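#' Load the packaged reference tables
#'
#' Machine-readable transcriptions of the published count tables for the
#' 980-pair interferon alpha 17 gene over the highest critical-energy
#' range (EcrH 0.581-0.589 x 1e-22 N m, step 0.001):
#' \itemize{
#'   \item `csnb`: per-energy, per-part closed-state (CSNB) counts split
#'     by the A-T / G-C class of the substituted pair, with the published
#'     baseline probability column `p0e5` (`P0 x 1e5`) carried as data;
#'   \item `composition`: per-part lengths, bounds and A-T / G-C
#'     percentages;
#'   \item `nmax`: per-energy, per-part "Maximum"-range counts with the
#'     `p0e5` and `pimaxe5` columns.
#' }
#' The tables are transcribed verbatim, including one internal
#' inconsistency of the source (the part-II CSNB column sums to 1365 while
#' the accompanying text quotes 1371); derived reports only pin values
#' that are internally consistent.
#'
#' @return list of data frames `csnb`, `composition`, `nmax`, of class
#'   `fixture_tables`.
#' @export
load_fixture_tables <- function() {
  rd <- function(f) {
    df <- utils::read.csv(system.file("extdata", f, package = "dnaos",
                                      mustWork = TRUE))
    if ("part" %in% names(df))
      df$part <- factor(df$part, levels = c("I", "II", "III"))
    df
  }
  structure(list(csnb = rd("table1_csnb.csv"),
                 composition = rd("table2_composition.csv"),
                 nmax = rd("table3_nmax.csv")),
            class = "fixture_tables")
}

#' Sum selected cells of a fixture count table
#'
#' @param table one of the count tables (`csnb` or `nmax`) from
#'   [load_fixture_tables()].
#' @param parts subset of `c("I", "II", "III")`.
#' @param classes subset of `c("A-T", "G-C")`.
#' @param energies numeric interval `c(lo, hi)` in the table's energy
#'   units (inclusive), or a vector of exact energies.
#' @return integer sum of the selected counts.
#' @export
part_class_sum <- function(table, parts = c("I", "II", "III"),
                           classes = c("A-T", "G-C"),
                           energies = range(table$ecrh)) {
  cols <- c("A-T" = grep("^at_", names(table), value = TRUE)[1L],
            "G-C" = grep("^gc_", names(table), value = TRUE)[1L])
  if (length(energies) == 2L)
    keep <- table$ecrh >= energies[1L] & table$ecrh <= energies[2L]
  else keep <- table$ecrh %in% energies
  keep <- keep & table$part %in% parts
  if (!any(keep)) stop("empty selection")
  sum(vapply(classes, function(cl) sum(table[keep, cols[[cl]]]),
             numeric(1)))
}

# per-energy whole-gene and per-part CSNB totals from the fixture
fixture_csnb_totals <- function(csnb) {
  tot <- csnb$at_csnb + csnb$gc_csnb
  e <- sort(unique(csnb$ecrh))
  list(energies = e,
       gene = vapply(e, function(x) sum(tot[csnb$ecrh == x]), numeric(1)),
       gene_gc = vapply(e, function(x) sum(csnb$gc_csnb[csnb$ecrh == x]),
                        numeric(1)),
       part = sapply(levels(csnb$part), function(p)
         vapply(e, function(x) sum(tot[csnb$ecrh == x & csnb$part == p]),
                numeric(1))))
}

#' Derived ratio report from the fixture tables
#'
#' Recomputes, from the packaged count tables alone, every part-to-part and
#' class-to-class ratio quoted alongside them: the "Maximum"-range (nmax)
#' ratios, the CSNB ratios at selected energies, the whole-gene A-T:G-C
#' pair ratio, and the weighted-CSNB part II : part III percentage of the
#' corrected counts. Values are returned at full precision together with a
#' copy rounded half-away-from-zero to the precision at which each is
#' conventionally quoted.
#'
#' @param fixtures a `fixture_tables` list (default: the packaged tables).
#' @return data frame with columns `label`, `value`, `rounded`, `digits`;
#'   a ratio with a zero denominator is flagged `NA` (undefined), never an
#'   error.
#' @export
ratio_report <- function(fixtures = load_fixture_tables()) {
  t1 <- fixtures$csnb; t3 <- fixtures$nmax
  full <- range(t1$ecrh)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  ct <- fixture_csnb_totals(t1)
  wII <- sum(weighted_csnb(ct$part[, "II"], ct$gene, 980, truncate = TRUE))
  wIII <- sum(weighted_csnb(ct$part[, "III"], ct$gene, 980, truncate = TRUE))
  sat <- max(t1$ecrh)
  rows <- list(
    list("nmax_partII_over_partI",
         safe_div(part_class_sum(t3, "II"), part_class_sum(t3, "I")), 2L),
    list("nmax_gc_over_at",
         safe_div(part_class_sum(t3, classes = "G-C"),
                  part_class_sum(t3, classes = "A-T")), 2L),
    list("nmax_gc_over_at_partI",
         safe_div(part_class_sum(t3, "I", "G-C"),
                  part_class_sum(t3, "I", "A-T")), 1L),
    list("nmax_gc_over_at_partII",
         safe_div(part_class_sum(t3, "II", "G-C"),
                  part_class_sum(t3, "II", "A-T")), 2L),
    list("nmax_gc_over_at_low",
         safe_div(part_class_sum(t3, classes = "G-C",
                                 energies = c(0.581, 0.585)),
                  part_class_sum(t3, classes = "A-T",
                                 energies = c(0.581, 0.585))), 2L),
    list("nmax_gc_over_at_high",
         safe_div(part_class_sum(t3, classes = "G-C",
                                 energies = c(0.586, full[2L])),
                  part_class_sum(t3, classes = "A-T",
                                 energies = c(0.586, full[2L]))), 2L),
    list("csnb_partI_over_partII_0.584",
         safe_div(part_class_sum(t1, "I", energies = 0.584),
                  part_class_sum(t1, "II", energies = 0.584)), 2L),
    list("csnb_partII_over_partIII_0.585",
         safe_div(part_class_sum(t1, "II", energies = 0.585),
                  part_class_sum(t1, "III", energies = 0.585)), 2L),
    list("csnb_partIII_over_partI_0.586",
         safe_div(part_class_sum(t1, "III", energies = 0.586),
                  part_class_sum(t1, "I", energies = 0.586)), 2L),
    list("csnb_partIII_over_partII_0.586",
         safe_div(part_class_sum(t1, "III", energies = 0.586),
                  part_class_sum(t1, "II", energies = 0.586)), 2L),
    list("at_over_gc_pairs",
         safe_div(part_class_sum(t1, classes = "A-T", energies = sat),
                  part_class_sum(t1, classes = "G-C", energies = sat)), 2L),
    list("weighted_csnb_partII_pct_of_partIII",
         100 * safe_div(wII, wIII), 1L),
    list("weighted_csnb_partII_sum", wII, 0L),
    list("weighted_csnb_partIII_sum", wIII, 0L),
    list("csnb_partIII_sum", part_class_sum(t1, "III"), 0L)
  )
  out <- data.frame(label = vapply(rows, `[[`, character(1), 1L),
                    value = vapply(rows, `[[`, numeric(1), 2L),
                    digits = vapply(rows, `[[`, integer(1), 3L))
  out$rounded <- round_half_away(out$value * 10^out$digits) / 10^out$digits
  out[, c("label", "value", "rounded", "digits")]
}

#' Correlation report from the fixture tables
#'
#' Assembles the three published correlation inputs and evaluates the
#' Spearman variant each calls for:
#' \itemize{
#'   \item `csnb_vs_at_ratio`: 15 (part A-T/G-C ratio, part CSNB count)
#'     pairs over EcrH 0.581-0.585, Pearson-on-ranks;
#'   \item `weighted_total_vs_gc`: 8 whole-gene pairs of continuous
#'     weighted CSNB (all classes vs G-C-only, both damped by the
#'     whole-gene factor) over 0.581-0.588, Pearson-on-ranks;
#'   \item `nmax_total_vs_gc`: 16 (total nmax, G-C nmax) pairs from parts
#'     I and II over 0.581-0.588, d^2 formula.
#' }
#'
#' @param fixtures a `fixture_tables` list.
#' @return data frame with `label`, `rho`, `p.value`, `n`.
#' @export
correlation_report <- function(fixtures = load_fixture_tables()) {
  t1 <- fixtures$csnb; t2 <- fixtures$composition; t3 <- fixtures$nmax
  ct <- fixture_csnb_totals(t1)

  e5 <- ct$energies[ct$energies <= 0.585]
  ratio <- t2$at_pct / t2$gc_pct
  x1 <- rep(ratio, times = length(e5))
  y1 <- unlist(lapply(e5, function(e) ct$part[match(e, ct$energies), ]))
  r1 <- spearman_rank_pearson(x1, y1)

  e8 <- ct$energies[ct$energies <= 0.588]
  i8 <- match(e8, ct$energies)
  x2 <- weighted_csnb(ct$gene[i8], ct$gene[i8], 980)
  y2 <- weighted_csnb(ct$gene_gc[i8], ct$gene[i8], 980)
  r2 <- spearman_rank_pearson(x2, y2)

  k3 <- t3$ecrh <= 0.588 & t3$part %in% c("I", "II")
  x3 <- t3$at_nmax[k3] + t3$gc_nmax[k3]
  y3 <- t3$gc_nmax[k3]
  r3 <- spearman_d2(x3, y3)

  data.frame(label = c("csnb_vs_at_ratio", "weighted_total_vs_gc",
                       "nmax_total_vs_gc"),
             rho = c(r1$estimate, r2$estimate, r3$estimate),
             p.value = c(r1$p.value, r2$p.value, r3$p.value),
             n = c(length(x1), length(x2), length(x3)))
}
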