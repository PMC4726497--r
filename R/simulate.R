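# Synthetic-data generators: every pipeline input with planted ground truth.

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. Defaults define
#' a desk-scale study: a 5,000-gene genome with 300 nt (sd 50) AU-rich
#' 3'UTRs, a two-perturbation expression design (control / knockdown /
#' overexpression, 6 arrays each) with 250 planted anticorrelated genes
#' shifted by 1.5 log2 units against 0.5 log2 units of noise, single-library
#' RIP counts (mean 100, NB dispersion 0.05) with 5% of genes planted at
#' 4-fold IP enrichment, and a 600-patient survival cohort whose hazard
#' decreases with the signature score (high score protective).
#'
#' @param seed Master seed; every generator is a pure function of
#'   (config, seed).
#' @param n_genes Number of genes in the synthetic genome.
#' @param utr_length_mean,utr_length_sd 3'UTR length distribution (nt).
#' @param base_composition Named probabilities over A, C, G, U (sum 1).
#' @param motif_prevalence Named fractions: per motif, the fraction of genes
#'   receiving at least one planted site.
#' @param n_planted_anticorr Genes planted as CNOT7-anticorrelated.
#' @param effect_size_delta Log2 shift: +delta in knockdown, -delta in
#'   overexpression for planted genes.
#' @param noise_sd Log2-scale Gaussian noise sd per sample.
#' @param n_per_group Samples per expression group (>= 2).
#' @param rip_mean Expected input-library count per gene.
#' @param rip_dispersion Negative-binomial dispersion
#'   (variance = mean + dispersion * mean^2).
#' @param rip_fold Planted IP fold-change for enriched genes.
#' @param rip_frac_enriched Fraction of genes planted as IP-enriched.
#' @param cohort_n Patients in the synthetic survival cohort.
#' @param hazard_beta Log-hazard per unit signature score (negative =
#'   high score protective). Scores from [score_patients()] are
#'   weight-normalized, so their spread shrinks roughly as 1/sqrt(G) for a
#'   G-gene signature; the default of -5 corresponds to about e^0.5 hazard
#'   per score standard deviation for a signature of ~100 genes.
#' @param baseline_hazard Baseline exponential event rate (per time unit).
#' @param censor_rate Fraction of patients with independent early censoring.
#' @param follow_up_max Administrative censoring horizon (time units).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 5000L,
                       utr_length_mean = 300,
                       utr_length_sd = 50,
                       base_composition = c(A = 0.3, C = 0.2, G = 0.2,
                                            U = 0.3),
                       motif_prevalence = c(CPE = 0.1, PUM = 0.1, NRE = 0.1,
                                            CPSF = 0.1, ARE_permissive = 0.1,
                                            ARE_stringent = 0.1),
                       n_planted_anticorr = 250L,
                       effect_size_delta = 1.5,
                       noise_sd = 0.5,
                       n_per_group = 6L,
                       rip_mean = 100,
                       rip_dispersion = 0.05,
                       rip_fold = 4,
                       rip_frac_enriched = 0.05,
                       cohort_n = 600L,
                       hazard_beta = -5,
                       baseline_hazard = 0.01,
                       censor_rate = 0.2,
                       follow_up_max = 120) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              utr_length_mean = utr_length_mean,
              utr_length_sd = utr_length_sd,
              base_composition = base_composition,
              motif_prevalence = motif_prevalence,
              n_planted_anticorr = as.integer(n_planted_anticorr),
              effect_size_delta = effect_size_delta, noise_sd = noise_sd,
              n_per_group = as.integer(n_per_group), rip_mean = rip_mean,
              rip_dispersion = rip_dispersion, rip_fold = rip_fold,
              rip_frac_enriched = rip_frac_enriched,
              cohort_n = as.integer(cohort_n), hazard_beta = hazard_beta,
              baseline_hazard = baseline_hazard, censor_rate = censor_rate,
              follow_up_max = follow_up_max)
  if (!setequal(names(cfg$base_composition), c("A", "C", "G", "U"))) {
    stop("base_composition must be named A, C, G, U")
  }
  if (abs(sum(cfg$base_composition) - 1) > 1e-9) {
    stop("base_composition must sum to 1")
  }
  fr <- c(cfg$motif_prevalence, cfg$rip_frac_enriched, cfg$censor_rate)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  cnt <- c(cfg$n_genes, cfg$n_planted_anticorr, cfg$n_per_group,
           cfg$cohort_n)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (cfg$noise_sd < 0 || cfg$utr_length_sd < 0) stop("sd must be >= 0")
  if (cfg$rip_dispersion < 0) stop("rip_dispersion must be >= 0")
  if (cfg$n_planted_anticorr > cfg$n_genes) {
    stop("n_planted_anticorr exceeds n_genes")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Evaluate code under a tag-derived child seed, restoring the caller's RNG.
# Child seeds depend on the tag, not on call order.
with_child_seed <- function(seed, tag, code) {
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147483563
  child <- as.integer((as.numeric(seed) * 48271 + h) %% 2147483563)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(child)
  force(code)
}

sim_gene_ids <- function(n) sprintf("gene%05d", seq_len(n))

#' Simulate 3'UTR sequences with planted motif sites
#'
#' Draws each gene's sequence from the configured base composition, then for
#' each motif plants one concrete site (uniform among the motif's patterns
#' and their concrete expansions) into a `motif_prevalence` fraction of
#' genes, at a position uniform among placements that do not overlap any
#' previously planted site in that gene. Chance (unplanted) occurrences
#' arise naturally and are expected.
#'
#' @param config A [sim_config()].
#' @param motifs A [motif_set()]; prevalences must be defined for every
#'   motif name.
#' @param extra_sites Optional named list, motif name -> character vector of
#'   gene ids that receive one guaranteed planted site in addition to the
#'   prevalence-based sampling. Used to plant correlated structure (e.g. a
#'   target program whose members carry the tripartite motifs).
#' @return List: `utrs` (tibble `gene_id`, `sequence`) and `truth` (tibble
#'   `gene_id`, `motif`, `start`, `end` of planted sites, 0-based half-open).
#' @export
simulate_utrs <- function(config, motifs = default_motifs(),
                          extra_sites = NULL) {
  stopifnot(inherits(config, "sim_config"))
  motif_names <- unique(motifs$name)
  missing_prev <- setdiff(motif_names, names(config$motif_prevalence))
  if (length(missing_prev) > 0L) {
    stop("no prevalence defined for motif: ", missing_prev[1])
  }
  with_child_seed(config$seed, "utrs", {
    n <- config$n_genes
    ids <- sim_gene_ids(n)
    lens <- pmax(1L, as.integer(round(
      stats::rnorm(n, config$utr_length_mean, config$utr_length_sd))))
    bases <- names(config$base_composition)
    draws <- sample(bases, sum(lens), replace = TRUE,
                    prob = config$base_composition)
    seq_chars <- split(draws, rep.int(seq_len(n), lens))
    occupied <- lapply(lens, function(L) logical(L))
    truth <- list()
    for (nm in motif_names) {
      prev <- config$motif_prevalence[[nm]]
      n_pick <- round(prev * n)
      picked <- if (n_pick == 0L) integer() else
        sample.int(n, n_pick)
      if (!is.null(extra_sites) && nm %in% names(extra_sites)) {
        picked <- union(picked, match(extra_sites[[nm]], ids))
        if (anyNA(picked)) stop("extra_sites gene not in genome")
      }
      picked <- sort(picked)
      if (length(picked) == 0L) next
      pats <- motifs$pattern[motifs$name == nm]
      for (g in picked) {
        pat <- if (length(pats) == 1L) pats else sample(pats, 1L)
        concrete <- expand_iupac(pat)
        site <- if (length(concrete) == 1L) concrete else
          sample(concrete, 1L)
        m <- nchar(site)
        L <- lens[g]
        if (m > L) {
          stop("motif ", nm, " (", m, " nt) is longer than the UTR of ",
               ids[g], " (", L, " nt)")
        }
        occ <- occupied[[g]]
        csum <- c(0, cumsum(occ))
        starts0 <- 0:(L - m)                       # candidate 0-based starts
        free <- (csum[starts0 + m + 1L] - csum[starts0 + 1L]) == 0
        if (!any(free)) {
          stop("cannot place motif ", nm, " in ", ids[g],
               ": no non-overlapping position available")
        }
        s0 <- if (sum(free) == 1L) starts0[free] else
          sample(starts0[free], 1L)
        seq_chars[[g]][(s0 + 1L):(s0 + m)] <-
          strsplit(site, "", fixed = TRUE)[[1]]
        occupied[[g]][(s0 + 1L):(s0 + m)] <- TRUE
        truth[[length(truth) + 1L]] <- list(gene_id = ids[g], motif = nm,
                                            start = s0, end = s0 + m)
      }
    }
    truth_tbl <- if (length(truth) == 0L) {
      tibble::tibble(gene_id = character(), motif = character(),
                     start = integer(), end = integer())
    } else {
      dplyr::bind_rows(lapply(truth, tibble::as_tibble))
    }
    truth_tbl$start <- as.integer(truth_tbl$start)
    truth_tbl$end <- as.integer(truth_tbl$end)
    list(utrs = tibble::tibble(
           gene_id = ids,
           sequence = unname(vapply(seq_chars, paste0, "", collapse = ""))),
         truth = dplyr::arrange(truth_tbl, .data$gene_id, .data$motif,
                                .data$start))
  })
}

#' Simulate the two-perturbation expression design
#'
#' Three groups (control, knockdown, overexpression) on the log2 scale.
#' Planted genes are shifted +delta in knockdown and -delta in
#' overexpression (inverse to the driver); all other genes have equal group
#' means. With `effect_size_delta = 0` no gene is planted.
#'
#' @param config A [sim_config()].
#' @param planted Optional character vector of gene ids to plant instead of
#'   sampling them (ignored when `effect_size_delta = 0`).
#' @return List: `exprs` (gene x sample numeric matrix), `groups` (tibble
#'   `sample`, `group`), `truth` (character vector of planted genes).
#' @export
simulate_expression <- function(config, planted = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_per_group < 2L) {
    stop("n_per_group must be >= 2 (t-test undefined otherwise)")
  }
  with_child_seed(config$seed, "expression", {
    n <- config$n_genes
    k <- config$n_per_group
    ids <- sim_gene_ids(n)
    samples <- c(sprintf("ctrl_%d", seq_len(k)), sprintf("kd_%d", seq_len(k)),
                 sprintf("oe_%d", seq_len(k)))
    groups <- tibble::tibble(
      sample = samples,
      group = rep(c("control", "knockdown", "overexpression"), each = k))
    truth <- if (config$effect_size_delta == 0) {
      character()
    } else if (!is.null(planted)) {
      stopifnot(all(planted %in% ids))
      sort(planted)
    } else if (config$n_planted_anticorr == 0L) {
      character()
    } else {
      sort(sample(ids, config$n_planted_anticorr))
    }
    baseline <- stats::rnorm(n, mean = 8, sd = 2)
    shift <- matrix(0, nrow = n, ncol = 3L * k)
    planted <- ids %in% truth
    shift[planted, (k + 1L):(2L * k)] <- config$effect_size_delta
    shift[planted, (2L * k + 1L):(3L * k)] <- -config$effect_size_delta
    noise <- matrix(stats::rnorm(n * 3L * k, 0, config$noise_sd),
                    nrow = n)
    exprs <- baseline + shift + noise
    dimnames(exprs) <- list(ids, samples)
    list(exprs = exprs, groups = groups, truth = truth)
  })
}

#' Simulate RIP count libraries
#'
#' Negative-binomial counts per gene for three libraries: the FLAG-CNOT7 IP
#' (`ip_flag`), the empty-vector control IP (`ip_control`) and the input
#' RNA (`input`). Planted genes have their `ip_flag` mean multiplied by
#' `rip_fold`. With `rip_fold = 1` no gene is planted. `rip_dispersion = 0`
#' gives the Poisson limit.
#'
#' @param config A [sim_config()].
#' @param planted Optional character vector of gene ids to plant instead of
#'   sampling them (ignored when `rip_fold = 1`).
#' @return List: `counts` (tibble `gene_id`, `ip_flag`, `ip_control`,
#'   `input`) and `truth` (character vector of planted genes).
#' @export
simulate_rip <- function(config, planted = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$rip_dispersion < 0) stop("rip_dispersion must be >= 0")
  if (config$rip_mean <= 0) stop("rip_mean must be > 0")
  with_child_seed(config$seed, "rip", {
    n <- config$n_genes
    ids <- sim_gene_ids(n)
    truth <- if (config$rip_fold == 1) {
      character()
    } else if (!is.null(planted)) {
      stopifnot(all(planted %in% ids))
      sort(planted)
    } else if (config$rip_frac_enriched == 0) {
      character()
    } else {
      sort(sample(ids, round(config$rip_frac_enriched * n)))
    }
    mu_ip <- rep(config$rip_mean, n)
    mu_ip[ids %in% truth] <- config$rip_mean * config$rip_fold
    draw <- function(mu) {
      if (config$rip_dispersion == 0) {
        stats::rpois(length(mu), mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$rip_dispersion)
      }
    }
    counts <- tibble::tibble(gene_id = ids,
                             ip_flag = draw(mu_ip),
                             ip_control = draw(rep(config$rip_mean, n)),
                             input = draw(rep(config$rip_mean, n)))
    list(counts = counts, truth = truth)
  })
}

#' Simulate a survival cohort driven by a gene signature
#'
#' Per-patient expression of the signature genes is standard normal; event
#' times are exponential with hazard
#' `baseline_hazard * exp(hazard_beta * score)` where `score` is the
#' patient's [score_patients()] value. A `censor_rate` fraction of patients
#' is censored at a uniform time before their event; all follow-up is
#' truncated (censored) at `follow_up_max`.
#'
#' @param signature A signature tibble (`gene`, `weight`), see
#'   [build_signature()].
#' @param config A [sim_config()].
#' @return List: `cohort` (tibble `patient`, `time`, `event`), `expression`
#'   (gene x patient matrix), `scores` (named numeric, the scores that
#'   drove the hazard).
#' @export
simulate_cohort <- function(signature, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(signature) == 0L) stop("signature must be non-empty")
  if (config$cohort_n < 2L) stop("cohort_n must be >= 2")
  with_child_seed(config$seed, "cohort", {
    n <- config$cohort_n
    patients <- sprintf("pt%04d", seq_len(n))
    expr <- matrix(stats::rnorm(nrow(signature) * n), nrow = nrow(signature),
                   dimnames = list(signature$gene, patients))
    scores <- score_patients(signature, expr)
    rate <- config$baseline_hazard * exp(config$hazard_beta * scores)
    t_event <- stats::rexp(n, rate = rate)
    censored <- stats::runif(n) < config$censor_rate
    time <- ifelse(censored, stats::runif(n, 0, t_event), t_event)
    event <- as.integer(!censored)
    over <- time > config$follow_up_max
    time[over] <- config$follow_up_max
    event[over] <- 0L
    list(cohort = tibble::tibble(patient = patients, time = time,
                                 event = event),
         expression = expr, scores = scores)
  })
}
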