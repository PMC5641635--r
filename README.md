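# tmtcodon

Codon-utilization analysis of isobaric-tag (TMT) quantitative proteomics.

## The scientific problem

Enzymes that modify the anticodon loop of tRNA-Lys(UUU) — the tRNA decoding
the lysine codon **AAA** — are candidates for regulating translation
elongation and fidelity. If such an enzyme is knocked out in a tissue, do
proteins encoded by AAA-rich genes become selectively depleted?

A 10-plex TMT experiment (five control vs five knockout samples, pooled
1:1, MS3 reporter-ion quantification) can answer this proteome-wide. The
analysis requires a chain of steps that this package implements as a tested,
reproducible pipeline for anyone analyzing codon usage against quantitative
peptide evidence:

1. **PSM quality filtering** — drop PSMs with no MS3 spectrum, more than
   eight missing reporter channels, or summed reporter signal-to-noise
   below 100 (strict boundaries: exactly 8 missing / exactly 100 pass).
2. **Target-decoy FDR** — collapse PSMs to peptides by best score, control
   at 1% FDR with monotone q-values (estimated FDR = decoys/targets above a
   score threshold), then collapse to proteins (best-peptide score) at 1%.
3. **Parsimony protein inference** — greedy minimal set cover with
   deterministic tie-breaks; every peptide assigned to exactly one group.
4. **Quantification** — per-sample abundance of a peptide/protein is the
   sum of reporter S:N over its PSMs (missing values count 0, never
   imputed).
5. **Codon mapping** — each peptide is located in its protein, the matching
   codons are sliced from the in-frame CDS with translation validation, and
   counted over the fixed universe of the **61 sense codons**.
6. **Statistics** —
   * abundance-weighted per-sample codon totals, compared between groups by
     a pooled-variance Student's *t*-test (`weighted_codon_totals()`,
     `compare_codon_totals()`);
   * log2 fold changes with a >2-fold downregulation flag
     (`fold_changes()`, log2FC ≤ −1);
   * unweighted per-codon frequency enrichment of the downregulated peptide
     set vs all peptides, with a rank over the 61 codons and a
     codon-table heatmap layout (`codon_enrichment()`, `heatmap_layout()`);
   * a mixed-effects regression of peptide log2FC on percent AAA with a
     random intercept per protein (`regress_fc_on_aaa()`, via lme4).

Because such studies rarely deposit raw data, the package ships a
**synthetic-proteome generator** (`sim_config()`, `simulate_dataset()`)
emulating the 5-vs-5 design end to end — log-normal protein lengths,
Dirichlet per-protein codon usage, tryptic digestion (cut after K/R, not
before P, ≤2 missed cleavages, length 6–40), Poisson PSM counts,
multiplicative reporter noise, channel dropout, reversed-sequence decoys,
and an injectable protein-level effect `log2FC = −β · %AAA` with an exact
ground-truth table. Every pipeline stage is testable without any download.

## Worked example

```r
library(tmtcodon)

cfg <- pipeline_config(
  sim = sim_config(n_proteins = 150, effect_beta = 0.3, seed = 11))
res <- run_pipeline(cfg)   # add out_dir = "out/" to write all TSV/FASTA files
```

```
[simulate] seed=11 proteins=150
[process] 18798/21927 PSMs pass quality filters
[process] 9164 peptides / 150 proteins at 1%/1% FDR
[map] codon profiles for 9164 peptides
[analyze] 2811 peptides >2-fold down; Lys(AAA) delta rank 1
```

The injected deficit (β = 0.3 per %AAA) is recovered by the enrichment
ranking — AAA is the most enriched of the 61 codons among >2-fold
downregulated peptides:

```r
head(res$enrichment[order(res$enrichment$rank), ], 3)
#>    codon freq_total_percent freq_down_percent delta_percent rank
#> 1    AAA               1.93              3.65         1.719    1
#> 17   CAA               2.05              2.64         0.583    2
#> 18   CAC               1.53              1.87         0.341    3

res$comparison[res$comparison$codon == "AAA", ]
#>   codon mean_control mean_ko t_statistic   p_value
#> 1   AAA       809830  395851       83.33 4.797e-13
```

The abundance-weighted AAA totals are roughly halved in the knockout
channels (t > 0 means control above knockout). The peptide-level
mixed-model slope, by contrast, is attenuated toward zero at this scale
(`res$regression$p_value` ≈ 0.16 here) — within-protein %AAA variation is
compositional noise with no fold-change signal, so the random intercept
absorbs most of the between-protein effect; the rank statistic is the
sensitive detector at desk scale. See the methods vignette
(`vignettes/codon-utilization.Rmd`) for the analysis of this attenuation
and all other design decisions.

Ground truth for every simulation is in `res$truth`
(`protein_id, true_base_abundance, true_log2fc, f_AAA_percent`).

A command-line front end with `simulate`, `run-all`, `analyze` and
`validate` subcommands is installed at `inst/scripts/tmtcodon.R`; runs are
byte-identical under a fixed seed and configurable through a flat
`key: value` file (`read_pipeline_config()`).

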