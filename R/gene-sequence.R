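#' Gene sequence with tripartition
#'
#' Constructs a `gene_sequence`: an ordered run of base pairs given by the
#' first-strand letters (5'->3'), together with three contiguous part
#' boundaries. A pair is written by its first-strand base, so `"A"` denotes
#' the pair A-T, `"C"` the pair C-G, and so on. For the 980-pair interferon
#' alpha 17 (IFNA17) case the canonical tripartition is 1-327 (part I),
#' 328-653 (part II), 654-980 (part III); for other lengths the same
#' long/short/long pattern is used (middle part absorbs the deficit).
#'
#' @param bases character vector of single letters, or a single string, in
#'   A/C/G/T (case-insensitive).
#' @param part_bounds optional 3x2 integer matrix of inclusive 1-based
#'   (start, end) rows for parts I-III; defaults to the generalized
#'   327/326/327 pattern.
#' @return An object of class `gene_sequence`: a list with `bases`
#'   (uppercase character vector), `n`, and `part_bounds`.
#' @examples
#' g <- gene_sequence("ACGT")
#' pair_symbols(g)
#' @export
gene_sequence <- function(bases, part_bounds = NULL) {
  if (length(bases) == 1L && nchar(bases[1L]) > 1L)
    bases <- strsplit(bases, "")[[1L]]
  bases <- toupper(as.character(bases))
  if (length(bases) == 0L) stop("empty sequence")
  bad <- setdiff(unique(bases), c("A", "C", "G", "T"))
  if (length(bad) > 0L)
    stop("invalid character in sequence: ", paste(bad, collapse = ", "))
  n <- length(bases)
  if (is.null(part_bounds)) part_bounds <- default_tripartition(n)
  part_bounds <- validate_part_bounds(part_bounds, n)
  structure(list(bases = bases, n = n, part_bounds = part_bounds),
            class = "gene_sequence")
}

#' Default three-part split of an n-pair gene
#'
#' Generalizes the 327/326/327 split used for the 980-pair gene: parts are
#' near-equal and contiguous, with the middle part taking the deficit when
#' n is not divisible by 3.
#'
#' @param n number of base pairs (>= 3).
#' @return 3x2 integer matrix of inclusive (start, end) bounds.
#' @export
default_tripartition <- function(n) {
  if (n < 3L) stop("need at least 3 pairs for a tripartition")
  a <- as.integer(ceiling(n / 3))
  b <- as.integer(floor(n / 3))
  rbind(c(1L, a), c(a + 1L, a + b), c(a + b + 1L, n))
}

validate_part_bounds <- function(pb, n) {
  pb <- matrix(as.integer(pb), nrow = 3L, ncol = 2L)
  if (pb[1L, 1L] != 1L || pb[3L, 2L] != n ||
      pb[2L, 1L] != pb[1L, 2L] + 1L || pb[3L, 1L] != pb[2L, 2L] + 1L ||
      any(pb[, 2L] < pb[, 1L]))
    stop("part bounds must be contiguous, ordered and cover 1..n")
  dimnames(pb) <- list(c("I", "II", "III"), c("start", "end"))
  pb
}

#' Read a gene sequence from FASTA or plain text
#'
#' The file gives the first strand 5'->3'; the complementary strand is
#' implied. A 980-letter input gets the canonical 1-327/328-653/654-980
#' tripartition.
#'
#' @param path file path.
#' @param format `"fasta"` (single record) or `"plain"` (letters, whitespace
#'   ignored).
#' @return A [gene_sequence()].
#' @export
read_gene_sequence <- function(path, format = c("fasta", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "fasta") {
    recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE)
    if (length(recs) == 0L) stop("empty sequence")
    bases <- as.character(recs[[1L]])
  } else {
    txt <- readLines(path, warn = FALSE)
    bases <- strsplit(gsub("[[:space:]]", "", paste(txt, collapse = "")), "")[[1L]]
  }
  gene_sequence(bases)
}

#' Write a gene sequence as single-record FASTA
#'
#' @param gene a [gene_sequence()].
#' @param path output file path.
#' @param name FASTA record name.
#' @return `path`, invisibly.
#' @export
write_gene_sequence <- function(gene, path, name = "gene") {
  stopifnot(inherits(gene, "gene_sequence"))
  seqinr::write.fasta(list(gene$bases), names = name, file.out = path)
  invisible(path)
}

#' Base-pair symbols of a gene
#'
#' @param gene a [gene_sequence()].
#' @return character vector like `"A-T"`, `"C-G"`, ordered along the gene.
#' @export
pair_symbols <- function(gene) {
  comp <- c(A = "T", T = "A", G = "C", C = "G")
  paste0(gene$bases, "-", comp[gene$bases])
}

#' Pair class (A-T vs G-C) of every site
#'
#' @param gene a [gene_sequence()].
#' @return factor with levels `"A-T"`, `"G-C"`.
#' @export
pair_class <- function(gene) {
  factor(ifelse(gene$bases %in% c("A", "T"), "A-T", "G-C"),
         levels = c("A-T", "G-C"))
}

#' Part label of a pair index
#'
#' @param gene a [gene_sequence()].
#' @param i 1-based pair index (vectorized).
#' @return factor with levels `"I"`, `"II"`, `"III"`.
#' @export
part_of <- function(gene, i) {
  stopifnot(inherits(gene, "gene_sequence"))
  i <- as.integer(i)
  if (any(i < 1L | i > gene$n)) stop("pair index out of range 1..", gene$n)
  pb <- gene$part_bounds
  lab <- cut(i, breaks = c(0L, pb[, "end"]), labels = c("I", "II", "III"))
  factor(as.character(lab), levels = c("I", "II", "III"))
}

#' Per-part A-T and G-C pair counts
#'
#' @param gene a [gene_sequence()].
#' @return data frame with columns `part`, `at`, `gc`, `length`.
#' @export
pair_counts <- function(gene) {
  part <- part_of(gene, seq_len(gene$n))
  cls <- pair_class(gene)
  tab <- table(part, cls)
  data.frame(part = factor(c("I", "II", "III"), levels = c("I", "II", "III")),
             at = as.integer(tab[, "A-T"]), gc = as.integer(tab[, "G-C"]),
             length = as.integer(rowSums(tab)))
}

#' Composition specification for synthetic genes
#'
#' Per-part lengths and exact A-T pair counts (or percentages). The default
#' emulates the composition of the studied 980-pair gene: part lengths
#' 327/326/327 with A-T counts 163/186/236 (A-T fractions 49.8/57.1/72.2%).
#'
#' @param lengths integer vector of the three part lengths.
#' @param at_counts integer vector of per-part A-T pair counts; exclusive
#'   with `at_pct`.
#' @param at_pct numeric per-part A-T percentages in `[0, 100]`, converted
#'   with round-half-away-from-zero to the nearest pair count.
#' @param seed integer seed for the pseudo-random base draw.
#' @return An object of class `composition_spec`.
#' @export
composition_spec <- function(lengths = c(327L, 326L, 327L),
                             at_counts = NULL, at_pct = NULL, seed = 1L) {
  lengths <- as.integer(lengths)
  stopifnot(length(lengths) == 3L, all(lengths >= 1L))
  if (is.null(at_counts)) {
    if (is.null(at_pct)) at_counts <- c(163L, 186L, 236L)
    else {
      stopifnot(all(at_pct >= 0), all(at_pct <= 100))
      at_counts <- as.integer(round_half_away(at_pct / 100 * lengths))
    }
  } else at_counts <- as.integer(at_counts)
  if (any(at_counts < 0L) || any(at_counts > lengths))
    stop("A-T count exceeds part length")
  structure(list(lengths = lengths, at_counts = at_counts,
                 seed = as.integer(seed)), class = "composition_spec")
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Synthesize a gene with exact per-part composition
#'
#' Each part gets exactly the requested number of A-T pairs; positions and
#' strand orientation (A-T vs T-A, G-C vs C-G) are drawn pseudo-randomly
#' from the seed in `spec`, so the same `spec` always yields the same
#' sequence.
#'
#' @param spec a [composition_spec()].
#' @return A [gene_sequence()].
#' @export
synthesize_gene <- function(spec) {
  stopifnot(inherits(spec, "composition_spec"))
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(spec$seed)
    on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
            else assign(".Random.seed", old, envir = globalenv()))
    unlist(lapply(seq_len(3L), function(p) {
      len <- spec$lengths[p]; nat <- spec$at_counts[p]
      cls <- character(len)
      cls[sample.int(len, nat)] <- "AT"
      cls[cls == ""] <- "GC"
      ifelse(cls == "AT", sample(c("A", "T"), len, replace = TRUE),
             sample(c("G", "C"), len, replace = TRUE))
    }))
  })
  n <- sum(spec$lengths)
  pb <- rbind(c(1L, spec$lengths[1L]),
              c(spec$lengths[1L] + 1L, spec$lengths[1L] + spec$lengths[2L]),
              c(spec$lengths[1L] + spec$lengths[2L] + 1L, n))
  gene_sequence(rng, part_bounds = pb)
}

#' @export
print.gene_sequence <- function(x, ...) {
  pc <- pair_counts(x)
  cat("gene_sequence:", x$n, "base pairs\n")
  cat("  parts:", paste(sprintf("%s %d-%d (%d A-T / %d G-C)",
                                pc$part, x$part_bounds[, 1], x$part_bounds[, 2],
                                pc$at, pc$gc), collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.gene_sequence <- function(object, ...) {
  pc <- pair_counts(object)
  pc$at_pct <- 100 * pc$at / pc$length
  pc
}
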