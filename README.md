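# cnotarget

Target discovery for the CCR4-NOT deadenylase subunit CNOT7, from 3'UTR
sequence to patient outcome.

CNOT7 shortens mRNA poly(A) tails and is recruited to transcripts by
RNA-binding proteins that recognize 3'UTR elements — the cytoplasmic
polyadenylation element (CPE), the CPSF-bound poly(A) signal, and the
Nanos response element (NRE). A direct CNOT7 target should therefore be
(i) *anticorrelated* with the driver across knockdown/overexpression
perturbations, (ii) *enriched* in a FLAG-CNOT7 RIP relative to input and
control IP, and (iii) a *carrier* of the tripartite CPE/CPSF/NRE motif
set. `cnotarget` implements that discovery pipeline for computational
biologists who want each stage as a tested, seedable R function:

* **Motif scanning** — IUPAC-degenerate RBP motifs mapped on 3'UTRs
  (sense strand, all overlapping sites, 0-based half-open coordinates).
* **Resampling enrichment** — for target set `T` and motif `m`, draw
  `n_perm` same-size gene sets from the genome background and report
  `p_emp = (1 + #{k_null >= k_obs}) / (n_perm + 1)` together with the
  one-tailed t-approximation `P(t_{n_perm-1} > (k_obs - mean(k_null)) / sd(k_null))`.
* **Anticorrelated transcripts** — per-gene contrasts (perturbation −
  control); anticorrelated ⇔ `min(p_kd, p_oe) < α` with `t_kd > 0`,
  `t_oe < 0`.
* **RIP enrichment** — depth-normalized fold-changes with pseudocount;
  enriched ⇔ `fc_input ≥ θ` and `fc_control ≥ θ`.
* **Tripartite screen** — genome → CPE∧CPSF∧NRE → expressed →
  anticorrelated, with Venn accounting and printed-style percentages.
* **Signature & survival** — weights `w_g = -cor(x_g, x_CNOT7)`, patient
  scores `Σ w_g z_gp / Σ |w_g|`, median split, Mantel-Cox log-rank.
* **Synthetic data** — every input generated with planted, recorded
  ground truth (`sim_config()`), so all of the above is testable.

## Worked example

```r
library(cnotarget)
run <- run_pipeline(sim_config(seed = 1))
print(run)
#> cnotarget run (seed 1, config 78b36522)
#>   genome genes:                  5000
#>   dysregulated:                  322
#>   anticorrelated:                252
#>   RIP-enriched:                  228
#>   RIP x anticorrelated:          221
#>   tripartite among intersection: 136 (62%)
#>   genome tripartite:             218 (4.4%)
#>   screen final set:              126
#>   signature genes:               136
#>   log-rank chi-square:          43.77 (p = 3.69e-11)
```

Reading the chain: of 5,000 genes, 322 respond to the perturbations and
252 do so inversely to *Cnot7* (the generator planted a 250-gene
program). 228 transcripts are RIP-enriched; 221 are both bound and
anticorrelated, and 136 of those (62%) carry all three 3'UTR motifs.
The genome-wide tripartite screen retains 126 genes after the
expression and anticorrelation filters. The 136 bound tripartite
transcripts, weighted by inverse driver correlation and mapped through
the synthetic ortholog table, stratify the simulated 600-patient cohort
at log-rank p ≈ 4e-11, with high signature expression protective — the
qualitative pattern the pipeline is designed to detect. The enrichment
panel on the 221-gene intersection flags CPE/CPSF/NRE
(p_emp = 1/1001 each) but neither ARE variant.

Individual stages are plain functions (`scan_motifs()`,
`annotate_motifs()`, `call_anticorrelated()`, `call_rip_enriched()`,
`motif_panel()`, `tripartite_screen()`, `build_signature()`,
`stratify_logrank()`), and a thin command-line wrapper with
per-stage subcommands ships in `inst/cli/pipeline.R`:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/pipeline.R", package="cnotarget"))') \
  all --seed 1 --out-dir results/run1
```

See `vignettes/target-discovery-methods.Rmd` for the model, parameter
and calibration details.

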