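# End-to-end orchestration: simulate -> scan -> DE -> RIP -> enrichment ->
# tripartite screen -> signature -> survival.

#' Run the full target-discovery pipeline on synthetic data
#'
#' Generates a synthetic genome in which a single planted target program is
#' simultaneously anticorrelated with the driver, enriched in the IP
#' libraries, and carries the tripartite CPE/CPSF/NRE motifs (at
#' `program_motif_prevalence` per motif within the program), then runs
#' every analysis stage and aggregates the filter-chain accounting into a
#' run report.
#'
#' Stages, in order: motif scan and annotation; anticorrelated-transcript
#' calls from the knockdown/overexpression design; RIP enrichment calls and
#' intersection with the anticorrelated set; motif-panel permutation
#' enrichment of the intersection against the genome background; the
#' genome-wide tripartite screen; the inverse-correlation-weighted
#' signature, ortholog mapping, and median-split log-rank survival
#' stratification on a simulated cohort.
#'
#' @param config A [sim_config()]; its seed drives every stage.
#' @param out_dir Optional directory; when given, every stage artifact is
#'   written (TSV/FASTA/JSON with provenance headers).
#' @param motifs A [motif_set()].
#' @param alpha Per-contrast significance level for the DE calls.
#' @param rule,var_equal Passed to [call_anticorrelated()].
#' @param theta,pseudocount Passed to [call_rip_enriched()].
#' @param n_perm,enrich_alpha,min_genes Passed to [motif_panel()].
#' @param detect_quantile Passed to [detect_expressed()].
#' @param screen_motifs Motifs required jointly in the tripartite screen.
#' @param program_motif_prevalence Fraction of program genes receiving each
#'   screen motif.
#' @param ortholog_coverage Fraction of genome genes present in the
#'   synthetic mouse-to-human ortholog map.
#' @return List of class `cnotarget_run`: the stage outputs (`annotation`,
#'   `de`, `rip`, `intersection`, `panel`, `screen`, `signature`,
#'   `stratification`, ...) and `report`, a flat named list of the
#'   filter-chain counts and headline statistics.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         motifs = default_motifs(), alpha = 0.01,
                         rule = "any", var_equal = FALSE, theta = 2,
                         pseudocount = 0.5, n_perm = 1000L,
                         enrich_alpha = 0.05, min_genes = 10L,
                         detect_quantile = 0.25,
                         screen_motifs = c("CPE", "CPSF", "NRE"),
                         program_motif_prevalence = 0.8,
                         ortholog_coverage = 0.75) {
  hash <- config_hash(config)
  ids <- sim_gene_ids(config$n_genes)

  # one shared program: anticorrelated + IP-bound + tripartite
  program <- with_child_seed(config$seed, "program", {
    sort(sample(ids, config$n_planted_anticorr))
  })
  extra <- with_child_seed(config$seed, "program_motifs", {
    out <- lapply(screen_motifs, function(nm) {
      sort(sample(program, round(program_motif_prevalence *
                                   length(program))))
    })
    stats::setNames(out, screen_motifs)
  })

  sim_utr <- simulate_utrs(config, motifs, extra_sites = extra)
  annotation <- annotate_motifs(sim_utr$utrs, motifs)

  sim_expr <- simulate_expression(config, planted = program)
  de <- call_anticorrelated(sim_expr$exprs, sim_expr$groups, alpha = alpha,
                            rule = rule, var_equal = var_equal)
  anticorr <- de$gene[de$anticorrelated]

  sim_rip <- simulate_rip(config, planted = program)
  rip <- call_rip_enriched(sim_rip$counts, theta = theta,
                           pseudocount = pseudocount)
  intersection <- intersect_anticorrelated(rip, de)

  panel <- if (length(intersection) >= 2L) {
    motif_panel(intersection, annotation, motifs, n_perm = n_perm,
                seed = config$seed, alpha = enrich_alpha,
                min_genes = min_genes)
  } else {
    motif_panel(character(), annotation, motif_set())
  }

  tri <- genes_with_all(annotation, screen_motifs)
  tri_intersection <- sort(intersect(tri, intersection))
  venn <- venn_partition(lapply(
    stats::setNames(screen_motifs, screen_motifs), function(nm) {
      intersect(intersection,
                annotation$gene_id[annotation$motif == nm &
                                     annotation$has_motif])
    }))

  expressed <- detect_expressed(sim_expr$exprs, detect_quantile)
  screen <- tripartite_screen(annotation, expressed, anticorr,
                              screen_motifs)

  # signature from the bound, anticorrelated, tripartite transcripts;
  # in this design the driver's abundance is the perturbation itself
  driver <- rbind(sim_expr$exprs,
                  Cnot7 = c(control = 0, knockdown = -1,
                            overexpression = 1)[sim_expr$groups$group])
  sig_genes <- if (length(tri_intersection) >= 2L) tri_intersection else
    screen$genes
  ortho_map <- with_child_seed(config$seed, "orthologs", {
    covered <- sort(sample(ids, round(ortholog_coverage * length(ids))))
    tibble::tibble(mouse = covered, human = toupper(covered))
  })
  signature <- NULL; mapped <- NULL; strat <- NULL; cohort <- NULL
  if (length(sig_genes) >= 2L) {
    signature <- build_signature(sig_genes, driver, "Cnot7")
    mapped <- map_orthologs(signature, ortho_map)
    if (nrow(mapped$signature) >= 2L) {
      cohort <- simulate_cohort(mapped$signature, config)
      scores <- score_patients(mapped$signature, cohort$expression)
      strat <- stratify_logrank(scores, cohort$cohort)
    }
  }

  report <- list(
    seed = config$seed, config = hash,
    n_genes = config$n_genes,
    n_dysregulated = sum(de$dysregulated),
    n_anticorrelated = length(anticorr),
    n_rip_enriched = sum(rip$enriched),
    n_intersection = length(intersection),
    n_tripartite_intersection = length(tri_intersection),
    pct_tripartite_intersection = if (length(intersection) > 0)
      percent(length(tri_intersection), length(intersection)) else NA,
    n_genome_tripartite = screen$n_tripartite,
    pct_genome_tripartite = percent(screen$n_tripartite, config$n_genes, 1),
    n_expressed_tripartite = screen$n_expressed_tripartite,
    n_screen_final = screen$n_final,
    n_signature = if (is.null(signature)) 0L else nrow(signature),
    ortholog_coverage_pct = if (is.null(mapped)) NA else
      100 * mapped$coverage,
    logrank_chisq = if (is.null(strat)) NA else strat$chisq,
    logrank_p = if (is.null(strat)) NA else strat$p)

  run <- list(config = config, truth = list(program = program,
                                            utr = sim_utr$truth,
                                            expression = sim_expr$truth,
                                            rip = sim_rip$truth),
              utrs = sim_utr$utrs, annotation = annotation,
              expression = sim_expr, de = de, rip = rip,
              rip_counts = sim_rip$counts,
              intersection = intersection, panel = panel, venn = venn,
              screen = screen, signature = signature, mapped = mapped,
              cohort = cohort, stratification = strat, report = report)
  class(run) <- "cnotarget_run"

  if (!is.null(out_dir)) {
    write_run(run, out_dir, hash)
  }
  run
}

write_run <- function(run, out_dir, hash) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- run$config$seed
  p <- function(f) file.path(out_dir, f)
  write_utr_fasta(run$utrs, p("utrs.fasta"))
  write_tsv_report(run$annotation, p("annotation.tsv"), seed, hash)
  write_expression_tsv(run$expression$exprs, run$expression$groups,
                       p("expression.tsv"), p("sample_groups.tsv"),
                       seed, hash)
  write_tsv_report(run$rip_counts, p("rip_counts.tsv"), seed, hash)
  write_tsv_report(run$de, p("differential.tsv"), seed, hash)
  write_gene_list(run$de$gene[run$de$anticorrelated],
                  p("anticorrelated_genes.txt"))
  write_tsv_report(run$rip, p("rip_calls.tsv"), seed, hash)
  write_gene_list(run$intersection, p("intersection_genes.txt"))
  write_tsv_report(run$panel, p("enrichment_panel.tsv"), seed, hash)
  write_gene_list(run$screen$genes, p("screen_final_genes.txt"))
  if (!is.null(run$signature)) {
    write_tsv_report(run$signature, p("signature.tsv"), seed, hash)
  }
  if (!is.null(run$cohort)) {
    write_tsv_report(run$cohort$cohort, p("cohort.tsv"), seed, hash)
  }
  jsonlite::write_json(run$report, p("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}

#' @export
print.cnotarget_run <- function(x, ...) {
  r <- x$report
  cat("cnotarget run (seed ", r$seed, ", config ", r$config, ")\n",
      sep = "")
  cat("  genome genes:                 ", r$n_genes, "\n")
  cat("  dysregulated:                 ", r$n_dysregulated, "\n")
  cat("  anticorrelated:               ", r$n_anticorrelated, "\n")
  cat("  RIP-enriched:                 ", r$n_rip_enriched, "\n")
  cat("  RIP x anticorrelated:         ", r$n_intersection, "\n")
  cat("  tripartite among intersection:", r$n_tripartite_intersection,
      paste0("(", r$pct_tripartite_intersection, ")"), "\n")
  cat("  genome tripartite:            ", r$n_genome_tripartite,
      paste0("(", r$pct_genome_tripartite, ")"), "\n")
  cat("  screen final set:             ", r$n_screen_final, "\n")
  cat("  signature genes:              ", r$n_signature, "\n")
  if (!is.na(r$logrank_p)) {
    cat("  log-rank chi-square:          ",
        format(r$logrank_chisq, digits = 4),
        " (p = ", format(r$logrank_p, digits = 3), ")\n", sep = "")
  }
  invisible(x)
}
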