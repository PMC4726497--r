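small_cfg <- function(...) {
  args <- list(n_genes = 50L, n_planted_anticorr = 10L,
               utr_length_mean = 120, utr_length_sd = 10, cohort_n = 100L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

test_that("generators are pure functions of the config seed", {
  cfg <- small_cfg(seed = 42L)
  a <- simulate_utrs(cfg)
  b <- simulate_utrs(cfg)
  expect_identical(a, b)
  expect_identical(simulate_expression(cfg), simulate_expression(cfg))
  expect_identical(simulate_rip(cfg), simulate_rip(cfg))
  sig <- tibble::tibble(gene = c("A", "B"), weight = c(1, 0.5))
  expect_identical(simulate_cohort(sig, cfg), simulate_cohort(sig, cfg))
  # different seeds diverge
  expect_false(identical(simulate_utrs(small_cfg(seed = 43L))$utrs, a$utrs))
  # byte-identical FASTA
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_utr_fasta(a$utrs, f1); write_utr_fasta(b$utrs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted motif truth is complete and positionally correct", {
  cfg <- sim_config(seed = 3L, n_genes = 50L, n_planted_anticorr = 5L,
                    utr_length_mean = 150, utr_length_sd = 0,
                    motif_prevalence = c(CPSF = 1.0))
  sim <- simulate_utrs(cfg, motif_set(CPSF = "AAUAAA"))
  # prevalence 1 -> every gene has a truth row
  expect_setequal(unique(sim$truth$gene_id), sim$utrs$gene_id)
  # every planted site is literally present at its recorded position
  for (i in seq_len(nrow(sim$truth))) {
    g <- sim$truth$gene_id[i]
    seq <- sim$utrs$sequence[sim$utrs$gene_id == g]
    expect_identical(substr(seq, sim$truth$start[i] + 1L,
                            sim$truth$end[i]), "AAUAAA")
  }
})

test_that("planted sites never overlap within a gene", {
  cfg <- sim_config(seed = 9L, n_genes = 30L, n_planted_anticorr = 5L,
                    utr_length_mean = 60, utr_length_sd = 0,
                    motif_prevalence = c(CPE = 1, CPSF = 1, NRE = 1))
  sim <- simulate_utrs(cfg, motif_set(CPE = "UUUUUAU", CPSF = "AAUAAA",
                                      NRE = "AUUGUA"))
  by_gene <- split(sim$truth, sim$truth$gene_id)
  for (tr in by_gene) {
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1L) {
      expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
    }
  }
})

test_that("scan presence matches prevalence plus the closed-form chance rate", {
  # 6-mer planted in half of 200 uniform-composition genes of length 200:
  # chance presence per unplanted window set is 1 - (1 - (1/4)^6)^(L-5)
  cfg <- sim_config(seed = 21L, n_genes = 200L, n_planted_anticorr = 20L,
                    utr_length_mean = 200, utr_length_sd = 0,
                    base_composition = c(A = .25, C = .25, G = .25,
                                         U = .25),
                    motif_prevalence = c(M6 = 0.5))
  sim <- simulate_utrs(cfg, motif_set(M6 = "AUCGAU"))
  ann <- annotate_motifs(sim$utrs, motif_set(M6 = "AUCGAU"))
  obs <- mean(ann$has_motif)
  q <- 1 - (1 - (1 / 4)^6)^(200 - 5)
  expected <- 0.5 + 0.5 * q
  se <- sqrt(expected * (1 - expected) / 200)
  expect_gte(obs, 0.5)
  expect_lt(abs(obs - expected), 3 * se + 1e-12)
})

test_that("planting errors name the offending gene", {
  cfg <- sim_config(seed = 1L, n_genes = 5L, n_planted_anticorr = 2L,
                    utr_length_mean = 4, utr_length_sd = 0,
                    motif_prevalence = c(CPSF = 1))
  expect_error(simulate_utrs(cfg, motif_set(CPSF = "AAUAAA")),
               "longer than the UTR of gene")
  cfg2 <- sim_config(seed = 1L, n_genes = 5L, n_planted_anticorr = 2L,
                     utr_length_mean = 9, utr_length_sd = 0,
                     motif_prevalence = c(A6 = 1, B6 = 1))
  expect_error(
    simulate_utrs(cfg2, motif_set(A6 = "AAAAGG", B6 = "CCCCGG")),
    "no non-overlapping position")
})

test_that("expression design plants inverse shifts with Gaussian noise", {
  # null case: no effect, no truth
  null_cfg <- small_cfg(seed = 5L, effect_size_delta = 0)
  sim0 <- simulate_expression(null_cfg)
  expect_length(sim0$truth, 0L)
  # noiseless limit: group difference is exactly delta
  cfg <- small_cfg(seed = 5L, noise_sd = 0, effect_size_delta = 1,
                   n_planted_anticorr = 1L)
  sim <- simulate_expression(cfg)
  g <- sim$truth
  kd <- sim$groups$sample[sim$groups$group == "knockdown"]
  ctrl <- sim$groups$sample[sim$groups$group == "control"]
  oe <- sim$groups$sample[sim$groups$group == "overexpression"]
  expect_equal(mean(sim$exprs[g, kd]) - mean(sim$exprs[g, ctrl]), 1.0)
  expect_equal(mean(sim$exprs[g, oe]) - mean(sim$exprs[g, ctrl]), -1.0)
  expect_error(simulate_expression(small_cfg(n_per_group = 1L)),
               "n_per_group")
})

test_that("planted genes carry the designed t-statistic magnitude", {
  # expected |t| approx delta / (sd * sqrt(2/n)) at delta=1.5, sd=0.5, n=4
  cfg <- sim_config(seed = 8L, n_genes = 2000L, n_planted_anticorr = 400L,
                    effect_size_delta = 1.5, noise_sd = 0.5,
                    n_per_group = 4L)
  sim <- simulate_expression(cfg)
  de <- call_anticorrelated(sim$exprs, sim$groups)
  t_planted <- de$t_kd[de$gene %in% sim$truth]
  target <- 1.5 / (0.5 * sqrt(2 / 4))
  # noncentral-t mean exceeds the noncentrality slightly; allow 3 SEs of
  # the simulated mean around the simulated expectation
  expect_lt(abs(mean(t_planted) - target),
            3 * stats::sd(t_planted) / sqrt(length(t_planted)) +
              0.2 * target)
})

test_that("RIP counts have planted fold-change with NB noise", {
  expect_length(simulate_rip(small_cfg(rip_fold = 1))$truth, 0L)
  expect_error(simulate_rip(small_cfg(rip_dispersion = -1)))
  # Poisson limit: dispersion 0, fold 4 -> ip/input ratio near 4
  cfg <- sim_config(seed = 13L, n_genes = 4000L, n_planted_anticorr = 200L,
                    rip_dispersion = 0,
                    rip_mean = 200, rip_fold = 4,
                    rip_frac_enriched = 0.25)
  sim <- simulate_rip(cfg)
  tr <- sim$counts$gene_id %in% sim$truth
  ratio <- sum(sim$counts$ip_flag[tr]) / sum(sim$counts$input[tr])
  n_tr <- sum(tr)
  se <- 4 * sqrt(1 / (200 * 4 * n_tr) + 1 / (200 * n_tr))
  expect_lt(abs(ratio - 4), 3 * se)
})

test_that("cohort hazard tracks the signature score", {
  sig <- tibble::tibble(gene = "G1", weight = 1)
  # beta = 0: score and event time uncorrelated
  cfg0 <- sim_config(seed = 17L, n_genes = 100L, n_planted_anticorr = 10L,
                     cohort_n = 2000L, hazard_beta = 0,
                     censor_rate = 0, follow_up_max = Inf)
  sim0 <- simulate_cohort(sig, cfg0)
  r <- cor(sim0$scores[sim0$cohort$patient], sim0$cohort$time,
           method = "spearman")
  expect_lt(abs(r), 3 / sqrt(2000))
  expect_true(all(sim0$cohort$event == 1L))
  # protective score: top-score half outlives bottom half on average
  wins <- 0L
  for (s in 1:60) {
    cfg <- sim_config(seed = 100L + s, n_genes = 100L,
                      n_planted_anticorr = 10L,
                      cohort_n = 200L, hazard_beta = -1,
                      censor_rate = 0, follow_up_max = Inf)
    sim <- simulate_cohort(sig, cfg)
    sc <- sim$scores[sim$cohort$patient]
    hi <- sim$cohort$time[sc > stats::median(sc)]
    lo <- sim$cohort$time[sc <= stats::median(sc)]
    wins <- wins + (stats::median(hi) >= stats::median(lo))
  }
  expect_gte(wins / 60, 0.9)
  expect_error(simulate_cohort(sig[0, ], small_cfg()), "non-empty")
  expect_error(simulate_cohort(sig, small_cfg(cohort_n = 1L)), "cohort_n")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(base_composition = c(A = .5, C = .5, G = 0,
                                               U = .1)), "sum to 1")
  expect_error(sim_config(motif_prevalence = c(CPE = 1.2)), "\\[0, 1\\]")
  expect_error(sim_config(n_genes = 10, n_planted_anticorr = 20),
               "exceeds")
  expect_error(sim_config(rip_dispersion = -0.1), "rip_dispersion")
})
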