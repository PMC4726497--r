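# 3'UTR motif scanning: map degenerate RBP motif sites on mRNA sense strands.

#' Scan a set of 3'UTR sequences for motif sites
#'
#' Maps every occurrence of every pattern of every motif on the given
#' sequences (sense strand only). Overlapping occurrences are all reported.
#' Coordinates are 0-based, half-open. `N` bases match no pattern code.
#'
#' @param utrs A tibble with columns `gene_id` and `sequence` (RNA alphabet;
#'   T accepted and normalized to U), e.g. from [read_utr_fasta()] or
#'   [simulate_utrs()].
#' @param motifs A [motif_set()].
#' @return Tibble of sites: `gene_id`, `motif`, `start`, `end`, `matched`,
#'   sorted by gene, motif, start.
#' @export
scan_motifs <- function(utrs, motifs) {
  stopifnot(all(c("gene_id", "sequence") %in% names(utrs)))
  if (anyDuplicated(utrs$gene_id)) {
    stop("duplicate gene_id: ", utrs$gene_id[duplicated(utrs$gene_id)][1])
  }
  seqs <- normalize_rna(utrs$sequence)
  if (nrow(utrs) == 0L || nrow(motifs) == 0L) {
    return(tibble::tibble(gene_id = character(), motif = character(),
                          start = integer(), end = integer(),
                          matched = character()))
  }
  # Internal scan in DNA space so Biostrings IUPAC machinery applies.
  subject <- Biostrings::DNAStringSet(chartr("U", "T", seqs))
  names(subject) <- utrs$gene_id
  out <- vector("list", nrow(motifs))
  for (i in seq_len(nrow(motifs))) {
    pat <- chartr("U", "T", motifs$pattern[i])
    hits <- Biostrings::vmatchPattern(
      pat, subject, fixed = c(pattern = FALSE, subject = TRUE))
    starts <- Biostrings::startIndex(hits)
    len <- nchar(pat)
    rows <- lapply(seq_along(starts), function(j) {
      st <- starts[[j]]
      if (is.null(st) || length(st) == 0L) return(NULL)
      tibble::tibble(gene_id = utrs$gene_id[j], motif = motifs$name[i],
                     start = as.integer(st - 1L),
                     end = as.integer(st - 1L + len),
                     matched = substring(seqs[j], st, st + len - 1L))
    })
    out[[i]] <- dplyr::bind_rows(rows)
  }
  sites <- dplyr::bind_rows(out)
  if (nrow(sites) == 0L) {
    return(tibble::tibble(gene_id = character(), motif = character(),
                          start = integer(), end = integer(),
                          matched = character()))
  }
  # conservative: an N base never satisfies a pattern position
  sites <- sites[!grepl("N", sites$matched, fixed = TRUE), , drop = FALSE]
  dplyr::arrange(sites, .data$gene_id, .data$motif, .data$start)
}

#' Scan a single sequence for one motif
#'
#' @param sequence A single RNA (or DNA) string.
#' @param motif A `motif_set` (typically one motif) or a single IUPAC pattern.
#' @param gene_id Identifier used in the output.
#' @return Site tibble as in [scan_motifs()].
#' @export
scan_sequence <- function(sequence, motif, gene_id = "seq") {
  if (is.character(motif) && !inherits(motif, "motif_set")) {
    nm <- if (!is.null(names(motif))) names(motif) else
      rep("motif", length(motif))
    motif <- do.call(motif_set, stats::setNames(as.list(motif), nm))
  }
  scan_motifs(tibble::tibble(gene_id = gene_id, sequence = sequence), motif)
}

#' Summarize motif presence and site counts per gene
#'
#' Produces the complete gene-by-motif annotation: every (gene, motif) pair
#' is present, with `site_count = 0` where no site was found and
#' `has_motif = site_count >= 1`.
#'
#' @inheritParams scan_motifs
#' @return Tibble: `gene_id`, `motif`, `site_count`, `has_motif`.
#' @export
annotate_motifs <- function(utrs, motifs) {
  sites <- scan_motifs(utrs, motifs)
  grid <- tidyr::expand_grid(gene_id = utrs$gene_id,
                             motif = unique(motifs$name))
  counts <- dplyr::count(sites, .data$gene_id, .data$motif,
                         name = "site_count")
  ann <- dplyr::left_join(grid, counts, by = c("gene_id", "motif"))
  ann$site_count <- ifelse(is.na(ann$site_count), 0L,
                           as.integer(ann$site_count))
  ann$has_motif <- ann$site_count >= 1L
  dplyr::arrange(ann, .data$gene_id, .data$motif)
}

#' Read 3'UTR sequences from FASTA
#'
#' Record ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased and T is normalized to U.
#'
#' @param path FASTA file.
#' @return Tibble with `gene_id`, `sequence`.
#' @export
read_utr_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate gene id in FASTA: ", ids[duplicated(ids)][1])
  }
  seqs <- unname(as.character(ss))
  if (any(!nzchar(seqs))) {
    stop("empty FASTA record: ", ids[which(!nzchar(seqs))[1]])
  }
  tibble::tibble(gene_id = ids, sequence = normalize_rna(seqs))
}

#' Write 3'UTR sequences to FASTA
#'
#' @param utrs Tibble with `gene_id`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  ss <- Biostrings::BStringSet(utrs$sequence)
  names(ss) <- utrs$gene_id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
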