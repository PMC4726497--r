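---
title: "Methods: post-transcriptional target discovery for CNOT7"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-transcriptional target discovery for CNOT7}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnotarget)
```

## The problem

CNOT7 is a catalytic deadenylase subunit of the CCR4-NOT complex. It is
recruited to specific mRNAs through adaptors (TOB1, CPEB-family and other
sequence-specific RNA-binding proteins) that recognize elements in the
3'UTR, and it shortens their poly(A) tails, committing them to decay. A
transcript that is a direct CNOT7 target should therefore show three
signatures at once:

1. **Anticorrelation with the driver** — abundance rises when *Cnot7* is
   knocked down and falls when CNOT7 is overexpressed.
2. **Physical association** — enrichment in a FLAG-CNOT7
   immunoprecipitate relative to both input RNA and a control IP.
3. **cis-element content** — 3'UTR sites for the recruiting RBPs:
   the cytoplasmic polyadenylation element (CPE), the poly(A) signal
   region bound by CPSF, and the Nanos response element (NRE).

This package implements the full discovery pipeline around that logic:
degenerate-motif scanning, a resampling enrichment test against the
genome background, two-perturbation differential calls, RIP enrichment
calls, the genome-wide "tripartite" CPE/CPSF/NRE screen with Venn
accounting, and the downstream clinical read-out — an
inverse-correlation-weighted gene signature evaluated by median-split
Kaplan-Meier stratification of a survival cohort. Because the deposited
experimental data cannot be re-derived at desk scale, every input is
produced by a synthetic generator with planted, recorded ground truth,
and the package's claims are calibration and recovery properties on that
ground truth.

## Motif scanning

Motifs are IUPAC-degenerate RNA strings, one or more patterns per motif.
The shipped defaults are literature-standard consensi (CPE `UUUUUAU` /
`UUUUAAU`, PUM `UGUAHAUA`, NRE `AUUGUA`, CPSF `AAUAAA`, ARE permissive
`AUUUA`, ARE stringent `UUAUUUAUU`); they are plain data in
`default_motifs()` and fully overridable through `motif_set()` or a
config file, because no published consensus is canonical for every
family member.

Scanning conventions, chosen once and enforced by tests:

* sense strand only (3'UTRs are mRNA features); T on input is
  normalized to U;
* coordinates are 0-based, half-open;
* **all** overlapping occurrences are counted — with no documented
  exclusion rule, counting every match is the deterministic superset;
* `N` bases satisfy no pattern position (conservative: an unknown base
  never creates a site).

The scanner delegates string matching to Biostrings with
pattern-side-only ambiguity interpretation; the test suite holds it
bit-for-bit equal to an independent brute-force enumeration over every
start position, on 1,000 random 300-nt sequences across all six default
motifs.

## Resampling enrichment test

To ask whether a target gene set is enriched for a motif, the background
annotation (the full scanned gene universe — no GC or length matching,
matching the original design) is resampled: each of `n_perm` draws takes
the same number of genes uniformly **without replacement** (gene sets
are sets; with-replacement sampling is available as a sensitivity
analysis) and records how many carry the motif, and how many sites they
carry. Two p-values are reported:

* `p_empirical = (1 + #{null >= observed}) / (n_perm + 1)` — the
  standard smoothed permutation p, used as the headline value and for
  the `enriched` flag;
* `p_t` — a one-tailed t-style approximation referring
  `(observed - null mean) / null sd` to a t distribution with
  `n_perm - 1` degrees of freedom. Testing an observed value against a
  resampled null this way is statistically unusual, but it is part of
  the screening procedure this package reproduces, so both numbers are
  always reported side by side.

The statistic defaults to gene-with-motif counts (presence/absence is
what the downstream interpretation uses); total site counts are
available via `statistic = "sites"`. Motifs carried by fewer than
`min_genes = 10` target genes are marked *not considered* rather than
tested — a rare motif's enrichment p is meaningless at that count, and
the original screen applied the same rule. Per-motif null streams derive
their seeds from the master seed via a hash of the motif *name*, so
panel results are independent of motif order.

Known behavior worth stating plainly: the empirical p is calibrated
(slightly conservative) under random null targets, and at `alpha = 0.05`
each truly-null motif in a panel is flagged about 4–5% of the time. A
six-motif panel with three null motifs therefore shows at least one
false flag in roughly 1 run in 9. Whole-panel exactness at the 95% level
would require a family-wise flag rule (e.g. Bonferroni across motifs),
which the reproduced procedure does not use; the package reports
per-motif flags and leaves multiplicity control to the caller.

## Differential calls

Contrast orientation is fixed as *perturbation minus control*: a
driver-anticorrelated gene has `t_kd > 0` (up on knockdown) and
`t_oe < 0` (down on overexpression). A gene is *dysregulated* when
`min(p_kd, p_oe) < alpha` (default `alpha = 0.01`, raw p-values as in
the original analysis; Benjamini-Hochberg is available via `fdr =
TRUE`). The stricter both-contrasts rule is available as
`rule = "both"`; it is not the default because with 4–6 samples per
group its sensitivity collapses (both contrasts must clear the
threshold independently, roughly squaring the per-contrast power).

The per-contrast engine is a vectorized two-sample t. Welch
(Satterthwaite df) is the default, being the safer choice on real data
with unequal group variances. For the synthetic study the generator
draws every group at exactly equal variance, and there the pooled test
(`var_equal = TRUE`) is the exact one; the design calculation makes the
difference concrete at the hardest condition used in the acceptance
checks (shift 1.5, sd 0.5, n = 4 per group, per-contrast noncentrality
4.24): the pooled test has fixed df 6 and per-contrast power 0.69 at
p < 0.01, while Welch's estimated df (mean ≈ 5) drops that to 0.58 —
about nine points of sensitivity on the combined call. The acceptance
suite therefore runs the recovery property with the pooled option, and
the vignette records this as the package's recommendation whenever the
design is balanced with homogeneous noise.

## RIP enrichment

Each library (FLAG IP, control IP, input) is scaled to counts per
million; for fold-changes the CPM values are rescaled to the mean
library depth so that the pseudocount (default 0.5) acts on the
raw-count scale — with equal-depth libraries the fold-change is exactly
`(count + 0.5) / (count + 0.5)` arithmetic on raw counts. A transcript
is called enriched when the IP-vs-input and IP-vs-control fold-changes
both reach `theta = 2`. The original report states no numeric
criterion, so `theta` and the pseudocount are explicit arguments, and
no replicate-based dispersion test is attempted — the design has single
libraries, and inventing a variance model the data cannot support would
only manufacture false confidence.

## Tripartite screen and accounting

`genes_with_all()` takes the conjunction of per-motif presence;
`tripartite_screen()` chains genome → tripartite → expressed →
anticorrelated, with counts and genome percentages at each step. The
expression-detection rule (mean abundance above the 25th percentile of
per-gene means, configurable) is explicit because the original
detection call is unstated. Venn partitions are exact exclusive-region
counts for 2 or 3 sets. Percentages are formatted with
half-away-from-zero rounding at caller-chosen precision, reproducing
both the integer (`48%` from 71/149) and one-decimal (`12.5%` from
3424/27305) printed styles.

## Signature and survival

The signature weight of gene *g* is `-cor(x_g, x_driver)` (Pearson,
across all samples), so genes anticorrelated with the driver carry
positive weights and a high score means high expression of the
driver-repressed program. Patient scores are weight-normalized sums of
per-gene z-scores, `sum(w_g z_gp) / sum(|w_g|)`; z-standardization
makes scores invariant to per-gene location shifts, and missing
signature genes are dropped with renormalization — never imputed,
mirroring how a fixed external cohort is actually used (46 of 71 and
217 of 293 orthologs available in the original evaluation). Ortholog
mapping is a plain two-column table; unmapped genes are counted, and
collisions keep the larger-|weight| entry with a report. The cohort is
split at the median score with ties to the low group (deterministic),
and the halves are compared with the Mantel-Cox log-rank test
(survival::survdiff); the test suite pins the chi-square to an
independent risk-table recursion at 1e-10.

## The synthetic generator

`sim_config()` freezes the study conditions; every generator is a pure
function of (config, seed), with child seeds derived per component so
outputs are independent of call order.

* **UTRs** — lengths N(300, 50) nt (desk scale; real mouse 3'UTRs are
  several-fold longer, which only raises chance-hit rates), AU-rich
  base composition (A/U 0.30, C/G 0.20). Planted sites are concrete
  realizations of the motif pattern, placed uniformly among positions
  that do not overlap previously planted sites, so truth-table site
  counts stay interpretable. Chance occurrences arise naturally and are
  expected: scan-level tests compare against a brute-force oracle, not
  the truth table.
* **Expression** — log2 scale directly (effects additive), three groups
  of 6, planted genes shifted ±1.5 against N(0, 0.5) noise. Group size
  6 was fixed by a design power analysis: it gives the default pipeline
  >99% per-gene recovery so the joint RIP-and-expression property is
  limited by the RIP arm, while the acceptance checks separately probe
  the harder n = 4 condition.
* **RIP** — negative binomial with variance `mu + phi mu^2`,
  `mu = 100`, `phi = 0.05` (technical-scale overdispersion for
  single-library designs), planted 4-fold IP enrichment in 5% of
  genes; `phi = 0` gives the Poisson limit used in tests.
* **Cohort** — signature-gene expression standard normal; event times
  exponential with hazard `h0 exp(beta * score)`, `h0 = 0.01` per
  month, 120-month administrative horizon, 20% independent early
  censoring. Because scores are weight-normalized their spread is about
  `1/sqrt(G)`; the default `beta = -5` corresponds to ≈ e^0.5 hazard
  per score-sd for a signature of ~100 genes, i.e. high signature
  expression protective, the direction under study.

What the generator does **not** emulate: probe-level array artifacts,
read-level sequencing noise, gene-gene correlation outside the planted
program, length/GC confounding of motif content, and cohort covariates.
Passing tests demonstrate that the algorithms are correct and
calibrated on data matching their assumptions — not that the biological
thresholds transfer to any particular real data set.

Independent per-module sampling cannot express the central biological
premise — that one gene program is simultaneously anticorrelated,
IP-bound, and tripartite-motif-bearing — so the generators accept
explicit planted sets (`planted`, `extra_sites`) and `run_pipeline()`
plants one shared program (default 250 genes, each screen motif planted
in 80% of them, giving an intersection that is roughly half tripartite,
the regime of interest).

## Numerical choices and degenerate inputs

Add-one smoothing keeps permutation p-values off zero
(`p >= 1/(n_perm+1)`). A zero-sd null with an observed value equal to
the null gives `p_t = 1` (and 0 if the observed exceeds it). A t-test
on two zero-variance groups returns t = 0, p = 1 at equal means and
signed infinity, p = 0 otherwise. Double-zero counts give a RIP
fold-change of exactly 1. Median-split ties go to the low group.
Rounding is half away from zero. Errors name the offending gene, motif,
or character; nothing is silently dropped.

## Problem sizes

The shipped defaults (5,000 genes, 300-nt UTRs, 6 samples per group,
600 patients, 1,000 resamples) are the package's desk-scale study: the
full pipeline runs in well under a minute and the complete test suite,
including the property-based acceptance checks (100-seed panels,
50,000-resample limit checks, 1,000-replicate log-rank calibration), in
a few minutes on one CPU. All sizes scale through `sim_config()` and
the function arguments.

## Known limitations

* Motif consensi are configurable stand-ins, not a claim about the
  exact patterns used in any prior screen.
* The RIP rule is a fold-change heuristic; with replicated libraries a
  count-model test (e.g. edgeR-style) would be preferable.
* The signature scoring scheme is a transparent reconstruction of a
  black-box external evaluator (weighted z-sum with inverse-correlation
  weights); directions and qualitative behavior are reproducible,
  exact external scores are not.
* Raw p-values at `alpha = 0.01` reproduce the original rule; for real
  genome-scale use, enable the FDR option.
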