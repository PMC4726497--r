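# Motif enrichment by genome resampling: draw random gene sets of the same
# size from the annotated background, record how many carry the motif (and
# how many sites they carry), and compare the observed target set against
# that resampled null.

ann_motif_vectors <- function(annotation, motif) {
  sub <- annotation[annotation$motif == motif, , drop = FALSE]
  if (nrow(sub) == 0L) stop("motif '", motif, "' not in annotation")
  list(gene_id = sub$gene_id, has = sub$has_motif, sites = sub$site_count)
}

#' Resample the background to build a null for a motif
#'
#' Each resample draws `n` genes uniformly (without replacement by default)
#' from the annotated background and records the number carrying the motif
#' (`null_k`) and their total site count (`null_s`).
#'
#' @param annotation Gene x motif annotation ([annotate_motifs()]).
#' @param motif Motif name to resample.
#' @param n Genes per resample (the target-set size).
#' @param n_perm Number of resamples.
#' @param seed Seed for the resampling stream.
#' @param replace Sample genes with replacement (sensitivity analysis only).
#' @return List: integer vectors `null_k` and `null_s`, each of length
#'   `n_perm`.
#' @export
sample_null <- function(annotation, motif, n, n_perm = 1000L, seed = 1L,
                        replace = FALSE) {
  v <- ann_motif_vectors(annotation, motif)
  n_bg <- length(v$gene_id)
  if (n > n_bg && !replace) {
    stop("target size ", n, " exceeds background size ", n_bg)
  }
  if (n_perm < 1L) stop("n_perm must be >= 1")
  with_child_seed(seed, paste0("null/", motif), {
    null_k <- integer(n_perm)
    null_s <- integer(n_perm)
    has <- v$has
    sites <- v$sites
    for (i in seq_len(n_perm)) {
      idx <- sample.int(n_bg, n, replace = replace)
      null_k[i] <- sum(has[idx])
      null_s[i] <- sum(sites[idx])
    }
    list(null_k = null_k, null_s = null_s)
  })
}

#' Permutation enrichment test for one motif
#'
#' Tests whether a target gene set carries the motif more often than random
#' same-size gene sets drawn from the background. Two p-values are
#' reported: the empirical permutation p with add-one smoothing,
#' `p_empirical = (1 + #\{null >= observed\}) / (n_perm + 1)`, the headline
#' value; and `p_t`, a one-tailed t-style approximation that refers
#' `(observed - null_mean) / null_sd` to a t distribution with
#' `n_perm - 1` degrees of freedom.
#'
#' @param target Character vector of gene ids (must all be annotated).
#' @param annotation Gene x motif annotation ([annotate_motifs()]).
#' @param motif Motif name.
#' @param n_perm Number of resamples.
#' @param seed Seed for the resampling stream.
#' @param alpha Level for the `enriched` flag (on `p_empirical` of the
#'   chosen statistic).
#' @param statistic `"genes"` (number of target genes with >= 1 site, the
#'   default) or `"sites"` (total site count).
#' @param replace Resample with replacement.
#' @return One-row tibble: `motif`, `n_target`, `k_obs`, `s_obs`,
#'   `null_mean`, `null_sd`, `p_empirical`, `p_t`, `enriched`, plus the
#'   null draws as a list column `null`.
#' @export
enrichment_test <- function(target, annotation, motif, n_perm = 1000L,
                            seed = 1L, alpha = 0.05,
                            statistic = c("genes", "sites"),
                            replace = FALSE) {
  statistic <- match.arg(statistic)
  v <- ann_motif_vectors(annotation, motif)
  absent <- setdiff(target, v$gene_id)
  if (length(absent) > 0L) {
    stop("target gene absent from background: ", absent[1])
  }
  in_target <- v$gene_id %in% target
  k_obs <- sum(v$has[in_target])
  s_obs <- sum(v$sites[in_target])
  nul <- sample_null(annotation, motif, length(target), n_perm, seed,
                     replace = replace)
  draws <- if (statistic == "genes") nul$null_k else nul$null_s
  obs <- if (statistic == "genes") k_obs else s_obs
  null_mean <- mean(draws)
  null_sd <- stats::sd(draws)
  p_emp <- (1 + sum(draws >= obs)) / (n_perm + 1)
  p_t <- if (null_sd == 0) {
    if (obs > null_mean) 0 else 1
  } else {
    stats::pt((obs - null_mean) / null_sd, df = n_perm - 1,
              lower.tail = FALSE)
  }
  tibble::tibble(motif = motif, n_target = length(target),
                 k_obs = k_obs, s_obs = s_obs,
                 null_mean = null_mean, null_sd = null_sd,
                 p_empirical = p_emp, p_t = p_t,
                 enriched = p_emp < alpha,
                 null = list(nul))
}

#' Enrichment panel over a motif set
#'
#' Runs [enrichment_test()] for every motif, with per-motif seeds derived
#' from the master seed by motif name (so results do not depend on motif
#' order), and applies the minimum-count rule: motifs carried by fewer than
#' `min_genes` target genes are marked not considered (`considered =
#' FALSE`, `enriched = NA`) rather than tested for enrichment.
#'
#' @inheritParams enrichment_test
#' @param motifs A [motif_set()] or character vector of motif names present
#'   in the annotation.
#' @param min_genes Minimum number of motif-positive target genes for a
#'   motif to be considered.
#' @return Tibble with one row per motif: panel summary columns of
#'   [enrichment_test()] plus `considered`.
#' @export
motif_panel <- function(target, annotation, motifs = NULL, n_perm = 1000L,
                        seed = 1L, alpha = 0.05, min_genes = 10L,
                        statistic = c("genes", "sites"), replace = FALSE) {
  statistic <- match.arg(statistic)
  motif_names <- if (is.null(motifs)) {
    unique(annotation$motif)
  } else if (is.data.frame(motifs)) {
    unique(motifs$name)
  } else {
    as.character(motifs)
  }
  if (length(motif_names) == 0L) {
    out <- tibble::tibble(motif = character(), n_target = integer(),
                          k_obs = integer(), s_obs = integer(),
                          null_mean = double(), null_sd = double(),
                          p_empirical = double(), p_t = double(),
                          enriched = logical())
    out$considered <- logical()
    return(out)
  }
  rows <- lapply(motif_names, function(nm) {
    enrichment_test(target, annotation, nm, n_perm = n_perm, seed = seed,
                    alpha = alpha, statistic = statistic, replace = replace)
  })
  res <- dplyr::bind_rows(rows)
  res$null <- NULL
  apply_min_count_filter(res, min_genes = min_genes)
}

#' Mark motifs carried by too few target genes as not considered
#'
#' Mirrors the screening rule that a motif present in fewer than
#' `min_genes` of the target genes is excluded from enrichment
#' interpretation.
#'
#' @param results Panel tibble with columns `k_obs` and `enriched`.
#' @param min_genes Threshold on motif-positive target genes.
#' @return The tibble with a `considered` column; excluded motifs have
#'   `enriched = NA`.
#' @export
apply_min_count_filter <- function(results, min_genes = 10L) {
  results$considered <- results$k_obs >= min_genes
  results$enriched[!results$considered] <- NA
  results
}
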