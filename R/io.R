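# Tabular I/O: TSV with '#' comment headers carrying reproducibility
# metadata, plain gene-list files, and the expression-matrix format.

#' @importFrom rlang .data
NULL

# FNV-1a style hash of a configuration, for output provenance headers.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  sprintf("%08x", h)
}

provenance_lines <- function(seed, hash) {
  c(sprintf("# cnotarget %s", as.character(utils::packageVersion("cnotarget"))),
    sprintf("# seed: %d", as.integer(seed)),
    sprintf("# config: %s", hash))
}

#' Write a tibble as TSV with a provenance header
#'
#' @param x Data frame.
#' @param path Output file.
#' @param seed,hash Seed and config hash recorded in `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path, seed = NA_integer_, hash = "") {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(seed)) writeLines(provenance_lines(seed, hash), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by the pipeline
#'
#' @param path File path; `#` lines are skipped.
#' @return A tibble.
#' @export
read_tsv_report <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Write / read an expression matrix with its sample-group companion
#'
#' The matrix file has a `gene_id` column then one column per sample; the
#' companion file maps sample id to group.
#'
#' @param exprs Gene x sample matrix.
#' @param groups Tibble `sample`, `group`.
#' @param path,groups_path Output files.
#' @param seed,hash Provenance metadata.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(exprs, groups, path, groups_path,
                                 seed = NA_integer_, hash = "") {
  df <- data.frame(gene_id = rownames(exprs), exprs, check.names = FALSE)
  write_tsv_report(df, path, seed, hash)
  write_tsv_report(groups, groups_path, seed, hash)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @return `read_expression_tsv()`: list with `exprs` (matrix) and `groups`
#'   (tibble).
#' @export
read_expression_tsv <- function(path, groups_path) {
  df <- read_tsv_report(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  list(exprs = m, groups = read_tsv_report(groups_path))
}

#' Write / read a plain gene-list file (one id per line)
#'
#' @param genes Character vector.
#' @param path File path.
#' @return `path` (write) or character vector (read).
#' @export
write_gene_list <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

#' @rdname write_gene_list
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Read a motif configuration file
#'
#' YAML-dialect config: each non-comment line is `name: pattern[, pattern]`.
#'
#' @param path Config file.
#' @return A [motif_set()].
#' @export
read_motif_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  defs <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("cannot parse motif config line: ", ln)
    pats <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    defs[[trimws(parts[1])]] <- pats[nzchar(pats)]
  }
  do.call(motif_set, defs)
}

#' Write a motif set as a config file
#'
#' @param motifs A [motif_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_motif_config <- function(motifs, path) {
  nm <- unique(motifs$name)
  lines <- vapply(nm, function(x) {
    paste0(x, ": ", paste(motifs$pattern[motifs$name == x],
                          collapse = ", "))
  }, "")
  writeLines(lines, path)
  invisible(path)
}
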