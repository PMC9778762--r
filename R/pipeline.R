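#' Default pipeline configuration
#'
#' Nested list mirroring the YAML layout: `composition` (part lengths,
#' A-T counts, seed), `forcing` (`F0`, `omega`), `damping` (`beta`
#' multiplier on the per-base defaults), `integration` (`dt`, `T`),
#' `sampling` (`m`), `bond` (`EcrH` grid in J, `kD`). Defaults are the
#' study conditions at the published scale; end-to-end examples usually
#' shrink `composition$lengths` and the grid.
#'
#' @return nested list.
#' @export
default_config <- function() {
  list(
    composition = list(lengths = c(327L, 326L, 327L),
                       at_counts = c(163L, 186L, 236L), seed = 1L),
    forcing = list(F0 = 0.526e-22, omega = 0.4e12),
    damping = list(beta_scale = 1),
    integration = list(dt = 1e-14, T = 3.0e-10),
    sampling = list(m = 1000L),
    bond = list(EcrH = seq(0.581e-22, 0.589e-22, by = 0.001e-22), kD = 1.05)
  )
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config()
  known <- names(base)
  extra <- setdiff(names(config), known)
  if (length(extra) > 0L)
    stop("unknown config key: ", paste(extra, collapse = ", "))
  for (k in names(config)) {
    sub <- setdiff(names(config[[k]]), names(base[[k]]))
    if (length(sub) > 0L)
      stop("unknown config key: ", k, ".", paste(sub, collapse = ", "))
    base[[k]][names(config[[k]])] <- config[[k]]
  }
  base
}

#' Run the full analysis pipeline
#'
#' Synthesizes (or accepts) a gene, scans every single-site deuterium
#' substitution over the configured critical-energy grid, classifies the
#' scan with the modified Basov-Jimack algorithm, runs the part-wise
#' chi-squared comparisons on the resulting counts, and (optionally)
#' writes all tables under `out_dir`.
#'
#' @param config nested list (see [default_config()]) or path to a YAML
#'   file; unknown keys are an error.
#' @param gene optional [gene_sequence()]; by default one is synthesized
#'   from `config$composition`.
#' @param out_dir optional output directory; when given, `gene.fasta`,
#'   `scan.csv`, `classification.csv` and `stats.csv` are written there.
#' @param progress print per-energy progress lines.
#' @return list with `gene`, `scan` (`os_scan`), `classification`
#'   (`bj_classification`), `stats` (data frame of part-wise chi-squared
#'   results), `config`.
#' @export
run_pipeline <- function(config = default_config(), gene = NULL,
                         out_dir = NULL, progress = FALSE) {
  cfg <- read_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(gene))
    gene <- stage("gene", synthesize_gene(composition_spec(
      lengths = cfg$composition$lengths, at_counts = cfg$composition$at_counts,
      seed = cfg$composition$seed)))
  params <- stage("params", {
    p <- mech_params(kD = cfg$bond$kD)
    p$beta <- p$beta * cfg$damping$beta_scale
    p
  })
  scfg <- stage("config", sim_config(
    F0 = cfg$forcing$F0, omega = cfg$forcing$omega, T = cfg$integration$T,
    dt = cfg$integration$dt, m = cfg$sampling$m, EcrH = cfg$bond$EcrH[1L],
    kD = cfg$bond$kD))
  scan <- stage("scan", scan_substitutions(gene, params, scfg,
                                           energies = cfg$bond$EcrH,
                                           progress = progress))
  cls <- stage("classify", classify_scan(scan, gene))
  stats_tab <- stage("stats", part_comparison_stats(cls))
  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_gene_sequence(gene, file.path(out_dir, "gene.fasta"))
      write_scan(scan, file.path(out_dir, "scan.csv"))
      write_classification(cls, file.path(out_dir, "classification.csv"))
      utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                       row.names = FALSE)
    })
  }
  list(gene = gene, scan = scan, classification = cls, stats = stats_tab,
       config = cfg)
}

#' Part-wise chi-squared comparisons of classification counts
#'
#' For CSNB and "Maximum"-range counts summed over the scanned energy
#' grid, compares each pair of gene parts with the Yates-corrected 2x2
#' test (success = counted site, failure = remaining pair-energy cells of
#' the part) and all three parts with the 3x2 Pearson test, Bonferroni
#' family of 3.
#'
#' @param cls a `bj_classification`.
#' @return data frame with `measure`, `comparison`, `statistic`, `df`,
#'   `p.value`, `adjusted.p.value`.
#' @export
part_comparison_stats <- function(cls) {
  stopifnot(inherits(cls, "bj_classification"))
  tab <- cls$table
  ne <- length(cls$energies)
  exposure <- cls$part_sizes * ne
  rows <- list()
  for (measure in c("csnb", "nmax")) {
    tot <- stats::aggregate(stats::as.formula(paste(measure, "~ part")),
                            tab, sum)
    for (cmb in list(c("I", "II"), c("I", "III"), c("II", "III"))) {
      s1 <- tot[[measure]][tot$part == cmb[1L]]
      s2 <- tot[[measure]][tot$part == cmb[2L]]
      f1 <- exposure[[cmb[1L]]] - s1; f2 <- exposure[[cmb[2L]]] - s2
      ht <- tryCatch(yates_chi2(s1, f1, s2, f2), error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = measure, comparison = paste(cmb, collapse = " vs "),
        statistic = if (is.null(ht)) NA_real_ else unname(ht$statistic),
        df = 1L, p.value = if (is.null(ht)) NA_real_ else ht$p.value,
        adjusted.p.value = NA_real_)
    }
    grid <- cbind(tot[[measure]], exposure[as.character(tot$part)] -
                    tot[[measure]])
    ht3 <- tryCatch(chi2_rx2_bonferroni(grid, comparisons = 3L),
                    error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      measure = measure, comparison = "I vs II vs III",
      statistic = if (is.null(ht3)) NA_real_ else unname(ht3$statistic),
      df = 2L, p.value = if (is.null(ht3)) NA_real_ else ht3$p.value,
      adjusted.p.value = if (is.null(ht3)) NA_real_ else ht3$adjusted.p.value)
  }
  do.call(rbind, rows)
}
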