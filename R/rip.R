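# RIP enrichment: transcripts enriched in the FLAG-CNOT7 IP relative to
# input and to the empty-vector control IP.

RIP_LIBS <- c("ip_flag", "ip_control", "input")

#' Counts-per-million normalization of RIP libraries
#'
#' @param counts Tibble with `gene_id`, `ip_flag`, `ip_control`, `input`
#'   (non-negative integer counts).
#' @return Tibble of the same shape with each library scaled to counts per
#'   million.
#' @export
rip_cpm <- function(counts) {
  stopifnot(all(c("gene_id", RIP_LIBS) %in% names(counts)))
  out <- counts
  for (lib in RIP_LIBS) {
    x <- counts[[lib]]
    if (any(x < 0)) stop("negative count in library ", lib)
    tot <- sum(x)
    if (tot == 0) stop("library ", lib, " has no positive counts")
    out[[lib]] <- x / tot * 1e6
  }
  out
}

#' Call RIP-enriched transcripts
#'
#' Fold-changes of the FLAG IP against input and against the control IP are
#' computed on depth-normalized counts with a pseudocount. Libraries are
#' first scaled to CPM and then rescaled to the mean library depth, so the
#' pseudocount acts on the raw-count scale and equal-depth libraries reduce
#' exactly to raw counts. A gene is enriched when both fold-changes reach
#' `theta`.
#'
#' @param counts Tibble with `gene_id`, `ip_flag`, `ip_control`, `input`.
#' @param theta Fold-change threshold (> 0), applied to both comparisons.
#' @param pseudocount Added to the depth-normalized counts before ratios.
#' @return Tibble: `gene_id`, `fc_input`, `fc_control`, `enriched`.
#' @export
call_rip_enriched <- function(counts, theta = 2, pseudocount = 0.5) {
  if (theta <= 0) stop("theta must be > 0")
  norm <- rip_cpm(counts)
  mean_depth <- mean(vapply(RIP_LIBS, function(l) sum(counts[[l]]), 0))
  scaled <- lapply(RIP_LIBS, function(l) norm[[l]] * mean_depth / 1e6)
  names(scaled) <- RIP_LIBS
  fc_input <- (scaled$ip_flag + pseudocount) / (scaled$input + pseudocount)
  fc_control <- (scaled$ip_flag + pseudocount) /
    (scaled$ip_control + pseudocount)
  tibble::tibble(gene_id = counts$gene_id,
                 fc_input = fc_input, fc_control = fc_control,
                 enriched = fc_input >= theta & fc_control >= theta)
}

#' Intersect RIP-enriched and anticorrelated gene sets
#'
#' The transcripts both bound by the deadenylase subunit (RIP-enriched) and
#' inversely regulated by it (anticorrelated): the pipeline's candidate
#' direct-target set.
#'
#' @param rip Output of [call_rip_enriched()].
#' @param de Output of [call_anticorrelated()].
#' @return Sorted character vector of gene ids.
#' @export
intersect_anticorrelated <- function(rip, de) {
  sort(intersect(rip$gene_id[rip$enriched], de$gene[de$anticorrelated]))
}
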