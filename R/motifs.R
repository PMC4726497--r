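# Degenerate RBP motif definitions and IUPAC handling.

IUPAC_RNA <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

#' Build a motif set
#'
#' A motif set maps motif names to one or more IUPAC-degenerate RNA patterns.
#' Patterns may be written with T or U (T is normalized to U) and must be at
#' least 4 nt long.
#'
#' @param ... Named arguments, each a character vector of IUPAC RNA patterns,
#'   e.g. `motif_set(CPE = c("UUUUUAU", "UUUUAAU"), CPSF = "AAUAAA")`.
#' @return A tibble with columns `name` and `pattern` (one row per pattern),
#'   of class `motif_set`.
#' @export
motif_set <- function(...) {
  defs <- list(...)
  if (length(defs) == 0L) {
    out <- tibble::tibble(name = character(), pattern = character())
    class(out) <- c("motif_set", class(out))
    return(out)
  }
  if (is.null(names(defs)) || any(!nzchar(names(defs)))) {
    stop("every motif must be named")
  }
  rows <- lapply(names(defs), function(nm) {
    pats <- chartr("T", "U", toupper(as.character(defs[[nm]])))
    for (p in pats) validate_iupac(p)
    tibble::tibble(name = nm, pattern = pats)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("motif_set", class(out))
  out
}

validate_iupac <- function(pattern) {
  if (nchar(pattern) < 4L) {
    stop("pattern '", pattern, "' is shorter than 4 nt")
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(IUPAC_RNA))
  if (length(bad) > 0L) {
    stop("invalid IUPAC RNA code '", chars[bad[1]], "' at position ",
         bad[1], " in pattern '", pattern, "'")
  }
  invisible(pattern)
}

#' Default RBP motif definitions
#'
#' Literature-standard consensi for the motifs interrogated in the 3'UTR
#' screen: the cytoplasmic polyadenylation element (CPE), the Pumilio binding
#' element (PUM), the Nanos response element (NRE), the cleavage and
#' polyadenylation stimulation factor element (CPSF, the canonical poly(A)
#' hexamer), and the permissive (AUUUA) and stringent (UUAUUUAUU) AU-rich
#' elements. All definitions are plain data and can be overridden by passing
#' a custom [motif_set()].
#'
#' @return A `motif_set` tibble.
#' @export
default_motifs <- function() {
  motif_set(
    CPE = c("UUUUUAU", "UUUUAAU"),
    PUM = "UGUAHAUA",
    NRE = "AUUGUA",
    CPSF = "AAUAAA",
    ARE_permissive = "AUUUA",
    ARE_stringent = "UUAUUUAUU"
  )
}

#' Expand an IUPAC pattern to its concrete sequences
#'
#' Enumerates every concrete RNA string (alphabet A/C/G/U) consistent with a
#' degenerate IUPAC pattern. `"UGUAHAUA"` expands to 3 concrete 8-mers
#' because H = A/C/U.
#'
#' @param pattern IUPAC RNA string (T accepted, normalized to U).
#' @param max_expansions Guard against combinatorial blow-up.
#' @return Character vector of concrete strings.
#' @export
expand_iupac <- function(pattern, max_expansions = 65536L) {
  pattern <- chartr("T", "U", toupper(pattern))
  validate_iupac(pattern)
  sets <- IUPAC_RNA[strsplit(pattern, "", fixed = TRUE)[[1]]]
  n_exp <- prod(lengths(sets))
  if (n_exp > max_expansions) {
    stop("pattern '", pattern, "' expands to ", n_exp, " concrete strings")
  }
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste0,
             collapse = ""))
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases, converts T to U, and rejects characters outside
#' \{A, C, G, U, N\}.
#'
#' @param x Character vector of sequences.
#' @return Normalized character vector.
#' @export
normalize_rna <- function(x) {
  out <- toupper(chartr("Tt", "UU", x))
  bad <- grepl("[^ACGUN]", out)
  if (any(bad)) {
    ch <- sub(".*?([^ACGUN]).*", "\\1", out[which(bad)[1]])
    stop("sequence contains character outside the RNA alphabet: '", ch, "'")
  }
  if (any(!nzchar(out))) stop("empty sequence after normalization")
  out
}
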