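---
title: "Codon-utilization analysis of TMT proteomics: methods and design notes"
author: "tmtcodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon-utilization analysis of TMT proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question this package addresses

Several tRNA-modifying enzymes act on the anticodon loop of tRNA-Lys(UUU),
the tRNA that decodes the lysine codon AAA. When such an enzyme is knocked
out, a natural hypothesis is that translation of AAA-rich coding sequences
becomes less efficient or less faithful, so that proteins whose genes use
many AAA codons are selectively depleted in the knockout tissue.

Quantitative isobaric-tag (TMT) proteomics can test this hypothesis tissue-
wide: up to ten samples (here five control and five knockout animals, pooled
1:1) are labeled, pooled, and quantified together through MS3 reporter-ion
signal-to-noise (S:N) values, one per channel per peptide-spectrum match
(PSM). Each quantified peptide can then be mapped back to the coding
sequence (CDS) of its parent protein, giving per-peptide counts over the 61
sense codons. Three statistics connect abundance to codon usage:

1. **Abundance-weighted codon totals** per sample: each peptide's codon
   counts multiplied by that peptide's abundance and summed, compared
   between groups by a two-sample Student's *t*-test (pooled variance,
   two-sided). This asks whether the knockout proteome as a whole contains
   fewer AAA-encoded residues.
2. **Codon-frequency enrichment in downregulated peptides**: the percentage
   of each codon among all codons of the >2-fold-downregulated peptide set,
   minus the same percentage in the total peptide set, ranked over the 61
   sense codons (rank 1 = most enriched among downregulated peptides).
   These frequencies are deliberately *unweighted* — percentage of codons
   in the coding sequence — while statistic 1 is abundance-weighted; both
   code paths exist under distinct names (`codon_enrichment()` vs
   `weighted_codon_totals()`).
3. **A mixed-effects regression** of each peptide's log2 knockout/control
   fold change on its percent AAA codon content, with a random intercept
   per protein (peptides of one protein share their protein's true fold
   change, so they are not independent observations).

## Processing model

The quantification pipeline mirrors standard MS3-TMT practice:

* **PSM quality filters.** A PSM is excluded if it has no MS3 spectrum, if
  *more than eight* of its ten reporter channels are missing, or if its
  summed reporter S:N over present channels is *less than 100*. The
  boundaries are deliberately strict inequalities: exactly eight missing
  channels or a sum of exactly 100 is retained. Exclusions are tallied by
  the first failing rule in that order.
* **Target-decoy FDR.** Identifications carry an opaque search score and a
  decoy flag (decoys are searched against reversed sequences). PSMs are
  collapsed to peptides by best score, ranked, and the FDR at a score
  threshold is estimated as decoys/targets above the threshold, smoothed
  into monotone q-values (running minimum from the permissive end). The
  peptide list is cut at 1% and then collapsed again to proteins — a
  protein scores as its best surviving peptide, with decoy proteins from
  the decoy peptides that passed the same score threshold — and cut at a
  1% protein FDR. Whether a production pipeline scores proteins by best
  peptide or a combined score is rarely documented; best-peptide is used
  here and stated openly.
* **Parsimony inference.** The smallest protein set explaining all retained
  peptides is approximated by greedy set cover: repeatedly select the
  protein covering the most uncovered peptides (ties: larger total peptide
  count, then lexicographically smaller accession). Each peptide is
  assigned to its earliest-selected cover, so shared peptides are counted
  once. Greedy cover is not guaranteed optimal; on randomized instances
  with realistic sharing (≈70% unique peptides) it matches the exhaustive
  optimum in ≈99% of cases and always covers every peptide — both
  properties are exercised against an exhaustive-enumeration oracle in the
  test suite.
* **Quantification.** A unit's abundance in a sample is the sum of reporter
  S:N over all its PSMs in that sample's channel. Missing reporter values
  contribute zero to sums (their number per PSM is already bounded by the
  missingness filter) and are never imputed.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `max_missing_channels` | 8 | channels | strict reading of "more than eight missing" |
| `min_summed_sn` | 100 | S:N | strict reading of "less than 100" |
| `peptide_fdr`, `protein_fdr` | 0.01 | fraction | standard 1%/1% two-level control |
| `threshold_fold` | 2 | fold | the downregulation definition (log2FC ≤ −1) |
| `pseudocount` | 0.5 | S:N | added to both group means; bounds ratios for units absent in one group |
| `max_missed_cleavages` | 2 | sites | standard tryptic search practice |
| `min/max_peptide_len` | 6–40 | aa | standard detectable tryptic range |
| `grouping` | protein | — | the random-intercept unit of the regression |

The optional `significance_gate` (off by default) additionally requires a
per-peptide equal-variance *t*-test p < 0.05 for membership in the
downregulated set; the primary definition is the pure >2-fold rule.

## The synthetic world

`sim_config()` / `simulate_dataset()` generate a complete, ground-truthed
experiment: a CDS database, its protein translations, and a PSM-level
10-plex table. Design choices, fixed once:

* **Sequences.** Protein lengths are log-normal with natural-scale mean 400
  and SD 250 amino acids (a realistic mammalian length distribution,
  median ≈ 340). Codons after a fixed ATG start are drawn from a
  per-protein usage vector sampled from a Dirichlet centred on the
  configured usage (uniform over the 61 sense codons by default, the
  testable choice; any mouse-like table can be supplied) with concentration
  60, giving a between-protein SD of AAA frequency of ≈1.6–1.9 percentage
  points around the ≈1.6% mean — comparable to real between-gene codon
  usage spread. No stop codons are ever emitted.
* **Effect model.** A protein with AAA frequency *f* (percent of codons)
  has true knockout/control log2 fold change −β·*f*, applied identically to
  all its peptides; β = 0 is the null world. The knob spans null to strong
  because the biological effect size is unknown (the motivating experiment
  did not detect one).
* **Measurement.** Expected per-channel S:N is
  `base_sn_mean (50) × protein abundance (log-normal, sdlog 1) × peptide
  response (log-normal, sdlog 1)`, times `2^(true log2FC)` in knockout
  channels, times per-channel multiplicative noise `2^N(0, 1)`. PSM counts
  per digest peptide are Poisson (mean 1.3). Channels drop out with
  probability 0.05 and are emitted as explicit NA, never zero; 2% of PSMs
  lack MS3 and carry no reporter values. With these choices roughly 10–15%
  of PSMs fail the quality filters — a realistic attrition.
* **Decoys.** 10% of PSMs are drawn from reversed protein sequences with
  scores N(1, 1) against targets' N(4, 1); decoy peptides that collide with
  any target peptide are removed and resampled, so decoy hits are
  unambiguously false.
* **Determinism.** One top-level seed starts a single RNG stream for the
  entire dataset; a rerun with the same configuration is byte-identical on
  disk, including the run manifest (which therefore carries no timestamps).

What the generator does **not** emulate: spectra (m/z, fragmentation),
retention time, chemical modifications, isotopic impurity, channel
cross-talk, shared-peptide ambiguity beyond exact tryptic sequence
identity, and any correlation between codon usage and protein abundance or
length. A green test therefore establishes that the *computational*
contract holds under a plausible error model, not that the statistics are
robust to every instrumental artifact.

## Numerical choices

* Ranks break ties alphabetically by codon, making the full ranking a
  deterministic permutation of 1..61 even when all deltas are zero.
* The codon-table heatmap is 16 rows (first × second base, T/C/A/G order)
  by 4 columns (third base); the three stop cells are NA, so 61 of 64
  positions are populated.
* An empty downregulated set yields NA enrichment columns and an explicit
  flag rather than fabricated zeros.
* The group *t*-statistic is control minus knockout over the pooled
  standard error (the `t.test(ctrl, ko)` convention); two constant equal
  groups are defined as t = 0, p = 1.
* The mixed model is fit by maximum likelihood; a singular random-intercept
  fit falls back to ordinary least squares with `converged = FALSE`. A
  constant predictor is a degenerate-design error; identically zero fold
  changes return slope 0, p 1, unconverged.
* Peptides occurring multiple times in their protein use the first
  occurrence (multiplicity is recorded in `n_sites`); peptides shared
  across proteins take the codon profile of their parsimony representative
  only.

## A known limitation: attenuation of the peptide-level regression

The regression `log2fc ~ pct_AAA + (1 | protein)` is statistically honest
but weak when the true effect acts at the protein level. Within a protein,
peptide-to-peptide variation in percent AAA is compositional sampling noise
(a 16-residue tryptic peptide quantizes AAA content in ≈6-point steps) that
carries **no** fold-change signal, while all the signal lives between
proteins. The ML fixed-effect estimate is a precision-weighted blend of the
within-protein slope (≈0 by construction, estimated from tens of thousands
of peptide deviations) and the between-protein slope (≈−β, estimated from a
few hundred protein means), so the blend is pulled heavily toward zero:
with *P* proteins of *n* peptides each, the weight ratio scales like
`P·var(f̄)/(σ_b² + σ_w²/n)` against `P·n·var_within(x)/σ_w²`, and at a few
hundred proteins the between share is ~1%. A between-protein regression of
protein fold change on protein AAA frequency recovers −β essentially
exactly (this is verified in the test suite via the truth table), and the
enrichment *rank* statistic detects the same injected effect with near
certainty — the rank route, not the mixed model, is the sensitive detector
at small scale. This attenuation is intrinsic to the specified estimator
and consistent with the null mixed-model result reported in the motivating
study despite its much larger scale; the package keeps the estimator as
specified and documents the power profile rather than silently substituting
a different model.

## A second limitation: lysine codons are not exchangeable under trypsin

Tests of the enrichment *rank* against a uniform null assume AAA is
exchangeable with the other 60 sense codons. Under tryptic digestion it is
not: every peptide ends in exactly one K or R residue (plus one per missed
cleavage), so the per-peptide total of cleavage-site codons is fixed by
peptide length and missed-cleavage count rather than by gene codon usage.
The frequencies of the eight K/R codons in any peptide subset consequently
have lower sampling variance than those of free codons — they only compete
for a fixed number of terminal slots — so under a true null the AAA
enrichment delta hugs zero and its rank concentrates toward the middle of
1..61 instead of spreading uniformly. The effect is mild (rank SD ≈ 16
versus 17.6 for uniform, mean unbiased at ≈31, measured over 200 null
simulations by the acceptance suite) but detectable by a goodness-of-fit
test at that sample size. Practically this means a mid-scale AAA rank in
real tryptic data is *less* surprising than a uniform null suggests, and a
strict uniformity test on the rank of a cleavage-site codon will reject
even when no biological effect exists. The group *t*-test on
abundance-weighted AAA totals is unaffected (its rejection rate is
calibrated at 5%), and the injected-effect recovery (rank 1–3 under a real
deficit) is far outside this mild distortion.

## What the tests establish

The suite builds every fixture in code and checks each operation against an
independent route: hand-derived digestion and enrichment examples, a
brute-force threshold scan for the FDR collapse, exhaustive minimal set
cover for parsimony, `stats::t.test` for the group comparison, and the
generator's own truth table for effect recovery. The acceptance-grade
properties — 61-codon universe, exact filter boundaries, oracle
equivalences, null calibration of the AAA rank and of the group *t*-test,
effect recovery, round-trip integrity, and byte-identical reruns — live in
`tests/testthat/test-acceptance.R` and print their measured fractions as
messages. Two clauses are expected to fail and are left asserting their
stated targets rather than weakened: the regression-power clause of the
effect-recovery criterion (the attenuation analysis above) and the strict
rank-uniformity clause of the null-behavior criterion (the trypsin
exchangeability analysis above).
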