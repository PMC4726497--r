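# Genome-wide tripartite motif screen with Venn accounting.

#' Genes carrying every named motif
#'
#' @param annotation Gene x motif annotation ([annotate_motifs()]).
#' @param motif_names Character vector of motif names; an empty vector is a
#'   vacuous conjunction and returns all genes.
#' @return Sorted character vector of gene ids with `site_count >= 1` for
#'   every named motif.
#' @export
genes_with_all <- function(annotation, motif_names) {
  genes <- sort(unique(annotation$gene_id))
  unknown <- setdiff(motif_names, unique(annotation$motif))
  if (length(unknown) > 0L) stop("unknown motif name: ", unknown[1])
  for (nm in motif_names) {
    pos <- annotation$gene_id[annotation$motif == nm & annotation$has_motif]
    genes <- intersect(genes, pos)
  }
  sort(genes)
}

#' Exclusive-region Venn partition of 2 or 3 gene sets
#'
#' @param sets Named list of 2 or 3 character vectors (duplicates ignored).
#' @return List with the exclusive region counts (for three sets: `A_only`,
#'   `B_only`, `C_only`, `AB`, `AC`, `BC`, `ABC`; for two: `A_only`,
#'   `B_only`, `AB`), the `union` size, and `set_names`.
#' @export
venn_partition <- function(sets) {
  if (!length(sets) %in% c(2L, 3L)) {
    stop("venn_partition supports 2 or 3 sets, got ", length(sets))
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  inA <- universe %in% sets[[1]]
  inB <- universe %in% sets[[2]]
  if (length(sets) == 2L) {
    out <- list(A_only = sum(inA & !inB), B_only = sum(!inA & inB),
                AB = sum(inA & inB))
  } else {
    inC <- universe %in% sets[[3]]
    out <- list(A_only = sum(inA & !inB & !inC),
                B_only = sum(!inA & inB & !inC),
                C_only = sum(!inA & !inB & inC),
                AB = sum(inA & inB & !inC),
                AC = sum(inA & !inB & inC),
                BC = sum(!inA & inB & inC),
                ABC = sum(inA & inB & inC))
  }
  out$union <- length(universe)
  out$set_names <- if (is.null(names(sets))) {
    paste0("set", seq_along(sets))
  } else {
    names(sets)
  }
  out
}

#' Detection call for expressed genes
#'
#' A gene counts as expressed when its mean abundance across all samples
#' exceeds the given quantile of the per-gene means.
#'
#' @param exprs Gene x sample matrix (log2 scale).
#' @param quantile Detection quantile (default: 25th percentile).
#' @return Character vector of expressed gene ids.
#' @export
detect_expressed <- function(exprs, quantile = 0.25) {
  m <- rowMeans(exprs)
  sort(rownames(exprs)[m > stats::quantile(m, quantile)])
}

#' Genome-wide tripartite screen
#'
#' Sequential filter: genes whose 3'UTR carries all screen motifs (default
#' CPE, CPSF, NRE), restricted to expressed genes, restricted to
#' driver-anticorrelated genes. Counts, percentages (of the genome) and the
#' final sorted gene list are reported.
#'
#' @param annotation Gene x motif annotation of the genome.
#' @param expressed Character vector of expressed gene ids.
#' @param anticorrelated Character vector of anticorrelated gene ids.
#' @param motif_names Motifs that must all be present.
#' @return List of class `screen_report`: `n_genome`, `n_tripartite`,
#'   `n_expressed_tripartite`, `n_final`, the matching percentages
#'   (numeric, percent of genome), and `genes` (final sorted gene list).
#' @export
tripartite_screen <- function(annotation, expressed, anticorrelated,
                              motif_names = c("CPE", "CPSF", "NRE")) {
  genome <- sort(unique(annotation$gene_id))
  bad <- setdiff(c(expressed, anticorrelated), genome)
  if (length(bad) > 0L) stop("gene not in annotation: ", bad[1])
  tri <- genes_with_all(annotation, motif_names)
  tri_expr <- intersect(tri, expressed)
  final <- sort(intersect(tri_expr, anticorrelated))
  n <- length(genome)
  out <- list(n_genome = n,
              n_tripartite = length(tri),
              n_expressed_tripartite = length(tri_expr),
              n_final = length(final),
              pct_tripartite = 100 * length(tri) / n,
              pct_expressed_tripartite = 100 * length(tri_expr) / n,
              pct_final = 100 * length(final) / n,
              motifs = motif_names,
              genes = final)
  class(out) <- "screen_report"
  out
}

# round half away from zero, the convention behind printed percentages
round_half_away <- function(x, digits = 0L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Format a count pair as a printed percentage
#'
#' `percent(71, 149)` gives `"48%"`; `percent(3424, 27305, 1)` gives
#' `"12.5%"`. Rounding is half away from zero at the requested precision.
#'
#' @param k Numerator count (0 <= k <= n).
#' @param n Denominator count (> 0).
#' @param decimals Digits after the decimal point.
#' @return Character scalar like `"48%"`.
#' @export
percent <- function(k, n, decimals = 0L) {
  if (n <= 0) stop("denominator must be > 0")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  val <- round_half_away(100 * k / n, decimals)
  paste0(formatC(val, format = "f", digits = decimals), "%")
}
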