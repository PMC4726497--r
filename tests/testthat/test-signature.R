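sig_matrix <- function() {
  withr::with_seed(61, {
    driver <- rnorm(12)
    m <- rbind(Cnot7 = driver,
               mirror = -driver + rnorm(12, sd = 1e-8),
               same = driver,
               noisy = rnorm(12),
               flat = rep(1, 12))
    colnames(m) <- sprintf("s%02d", 1:12)
    m
  })
}

test_that("signature weights are minus the driver correlation", {
  m <- sig_matrix()
  expect_warning(
    sig <- build_signature(c("same", "mirror", "noisy", "flat"), m,
                           "Cnot7"),
    "zero-variance")
  expect_equal(sig$weight[sig$gene == "same"], -1, tolerance = 1e-12)
  expect_equal(sig$weight[sig$gene == "mirror"], 1, tolerance = 1e-6)
  expect_false("flat" %in% sig$gene)
  expect_error(build_signature("noisy", m, "absent"), "driver")
  expect_error(build_signature("nope", m, "Cnot7"), "not in matrix")
})

test_that("planted anticorrelated genes receive positive weights", {
  sim <- simulate_expression(sim_config(seed = 71L, n_genes = 1000L,
                                        n_planted_anticorr = 100L))
  driver <- c(control = 0, knockdown = -1,
              overexpression = 1)[sim$groups$group]
  m <- rbind(sim$exprs, Cnot7 = driver)
  sig <- build_signature(sim$truth, m, "Cnot7")
  expect_gte(mean(sig$weight > 0), 0.99)
})

test_that("ortholog mapping reports coverage and collisions", {
  sig <- tibble::tibble(gene = c("Tob1", "Cpeb1", "Nanos1"),
                        weight = c(0.9, 0.5, -0.2))
  # empty map: nothing retained, coverage 0
  empty <- map_orthologs(sig, tibble::tibble(mouse = character(),
                                             human = character()))
  expect_identical(nrow(empty$signature), 0L)
  expect_identical(empty$coverage, 0)
  expect_identical(empty$n_unmapped, 3L)
  # identity-style mapping retains the weight
  m1 <- map_orthologs(sig, tibble::tibble(mouse = "Tob1", human = "TOB1"))
  expect_identical(m1$signature$gene, "TOB1")
  expect_identical(m1$signature$weight, 0.9)
  expect_equal(m1$coverage, 1 / 3)
  # collisions keep the larger-magnitude entry
  mc <- map_orthologs(sig, tibble::tibble(
    mouse = c("Tob1", "Cpeb1", "Nanos1"),
    human = c("TOB1", "TOB1", "NANOS1")))
  expect_identical(mc$collisions, "TOB1")
  expect_identical(mc$signature$weight[mc$signature$gene == "TOB1"], 0.9)
  expect_error(map_orthologs(sig, tibble::tibble(
    mouse = c("Tob1", "Tob1"), human = c("A", "B"))), "not a function")
  # 46-of-71 coverage prints as 65%
  expect_identical(percent(46, 71), "65%")
})

test_that("patient scores are normalized weighted z-sums", {
  withr::with_seed(81, {
    expr <- matrix(rnorm(5 * 30), nrow = 5,
                   dimnames = list(paste0("G", 1:5), paste0("p", 1:30)))
  })
  one <- tibble::tibble(gene = "G1", weight = 1)
  s1 <- score_patients(one, expr)
  z <- (expr["G1", ] - mean(expr["G1", ])) / sd(expr["G1", ])
  expect_equal(unname(s1), unname(z), tolerance = 1e-12)
  sig <- tibble::tibble(gene = paste0("G", 1:4),
                        weight = c(0.5, -0.25, 1, 0.25))
  s <- score_patients(sig, expr)
  # negating every weight negates every score
  neg <- sig; neg$weight <- -neg$weight
  expect_equal(score_patients(neg, expr), -s, tolerance = 1e-12)
  # permuting patients permutes scores identically
  perm <- sample(colnames(expr))
  expect_equal(score_patients(sig, expr[, perm]), s[perm],
               tolerance = 1e-12)
  # adding a constant to one gene's expression changes nothing
  shifted <- expr; shifted["G3", ] <- shifted["G3", ] + 7
  expect_equal(score_patients(sig, shifted), s, tolerance = 1e-12)
  # missing genes are dropped with renormalization, absent overlap errors
  expect_message(s_sub <- score_patients(
    tibble::tibble(gene = c("G1", "nope"), weight = c(1, 5)), expr),
    "missing")
  expect_equal(unname(s_sub), unname(z), tolerance = 1e-12)
  expect_error(score_patients(tibble::tibble(gene = "x", weight = 1),
                              expr), "no signature gene")
})

test_that("log-rank stratification matches the risk-table recursion", {
  # tiny worked set: all events, complete separation of the two halves
  cohort <- tibble::tibble(patient = paste0("p", 1:6),
                           time = c(1, 2, 3, 4, 5, 6),
                           event = rep(1L, 6))
  scores <- stats::setNames(c(1, 1, 1, -1, -1, -1), cohort$patient)
  strat <- stratify_logrank(scores, cohort)
  hand <- oracle_logrank(cohort$time, cohort$event,
                         ifelse(scores > 0, "high", "low"))
  expect_equal(strat$chisq, hand, tolerance = 1e-10)
  expect_equal(strat$p, stats::pchisq(hand, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  # identical survival in both groups: chi-square 0, p 1
  cohort2 <- tibble::tibble(patient = paste0("p", 1:8),
                            time = rep(c(2, 4, 6, 8), 2),
                            event = rep(1L, 8))
  scores2 <- stats::setNames(rep(c(1, -1), each = 4), cohort2$patient)
  strat2 <- stratify_logrank(scores2, cohort2)
  expect_lt(strat2$chisq, 1e-12)
  expect_equal(strat2$p, 1, tolerance = 1e-6)
  # swapping labels leaves the chi-square unchanged
  strat3 <- stratify_logrank(-scores, cohort)
  expect_equal(strat3$chisq, strat$chisq, tolerance = 1e-10)
})

test_that("log-rank agrees with the oracle on censored random cohorts", {
  withr::with_seed(91, {
    for (i in 1:10) {
      n <- 40L
      cohort <- tibble::tibble(patient = sprintf("p%02d", 1:n),
                               time = round(rexp(n, 0.1), 1) + 0.1,
                               event = rbinom(n, 1, 0.7))
      scores <- stats::setNames(rnorm(n), cohort$patient)
      strat <- stratify_logrank(scores, cohort)
      grp <- ifelse(scores[cohort$patient] <= median(scores), "low",
                    "high")
      hand <- oracle_logrank(cohort$time, cohort$event, grp)
      expect_equal(strat$chisq, hand, tolerance = 1e-10)
    }
  })
})

test_that("median split balances groups with ties to the low group", {
  cohort <- tibble::tibble(patient = paste0("p", 1:7),
                           time = 1:7, event = rep(1L, 7))
  scores <- stats::setNames(c(1, 2, 3, 4, 5, 6, 7), cohort$patient)
  strat <- stratify_logrank(scores, cohort)
  tab <- table(strat$group)
  expect_lte(abs(tab[["low"]] - tab[["high"]]), 1L)
  expect_identical(unname(strat$group["p4"]),
                   factor("low", levels = c("low", "high"))[1])
  expect_error(stratify_logrank(stats::setNames(rep(1, 7),
                                                cohort$patient), cohort),
               "fewer than 2")
})
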