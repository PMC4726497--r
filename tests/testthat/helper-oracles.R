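# Independent oracles, deliberately written without reusing the package's
# scanning or survival machinery.

# IUPAC RNA ambiguity table, restated independently for oracle use.
ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U")
)

# Brute-force scan: test every start position of `sequence` against the
# per-position allowed-character sets of `pattern`. 0-based half-open
# output. An N in the sequence satisfies no pattern position.
oracle_scan <- function(sequence, pattern) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  allowed <- ORACLE_IUPAC[strsplit(pattern, "", fixed = TRUE)[[1]]]
  m <- length(allowed)
  L <- length(chars)
  if (L < m) return(integer())
  hits <- integer()
  for (s in 0:(L - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!chars[s + j] %in% allowed[[j]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# Vectorized variant for larger fixtures (same semantics as oracle_scan).
oracle_scan_fast <- function(sequence, pattern) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  allowed <- ORACLE_IUPAC[strsplit(pattern, "", fixed = TRUE)[[1]]]
  m <- length(allowed)
  L <- length(chars)
  if (L < m) return(integer())
  ok <- rep(TRUE, L - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & chars[j:(j + L - m)] %in% allowed[[j]]
  }
  which(ok) - 1L
}

random_rna <- function(n, len, probs = c(A = .25, C = .25, G = .25,
                                         U = .25)) {
  vapply(seq_len(n), function(i) {
    paste0(sample(names(probs), len, replace = TRUE, prob = probs),
           collapse = "")
  }, "")
}

# Mantel-Cox log-rank chi-square from the risk-table recursion, written
# directly from the observed-minus-expected definition.
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  stopifnot(all(group %in% 1:2))
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  o_minus_e^2 / v
}

# Direct annotation builder (no sequences): per-motif Bernoulli presence.
make_annotation <- function(n_genes, prevalence, seed = 1L) {
  withr::with_seed(seed, {
    ids <- sprintf("g%04d", seq_len(n_genes))
    rows <- lapply(names(prevalence), function(nm) {
      has <- runif(n_genes) < prevalence[[nm]]
      tibble::tibble(gene_id = ids, motif = nm,
                     site_count = ifelse(has, 1L +
                                           rpois(n_genes, 0.3), 0L),
                     has_motif = has)
    })
    dplyr::bind_rows(rows)
  })
}
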