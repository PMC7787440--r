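---
title: "Inferring metabolic functions and routes from 16S amplicon data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring metabolic functions and routes from 16S amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metgems)
```

## Scope and model

`metgems` predicts community-level metabolic function profiles (KO and EC
abundances) from 16S rRNA amplicon data. The chain of models is
deliberately linear and transparent:

1. **Reference networks.** Per-genome function annotations (as curated in
   genome-scale metabolic model collections) are aggregated to a
   taxon-by-function matrix at genus or species rank. *Pan* mode sums (by
   default averages) member-genome counts; *core* mode is the 0/1
   intersection of member presence sets. The weighted variants multiply
   each genome's counts by a taxonomic weight before pan aggregation;
   core-type matrices are always computed from unweighted presence, which
   is why core and core-weight coincide — a property the reference data
   this design is modeled on also exhibits.
2. **Prediction.** ASV counts are summed per taxon, divided by the median
   16S gene copy number of the genomes pooled at that taxon (to approximate
   organismal rather than gene abundance), and multiplied through the
   network. Prediction is therefore linear in the input counts: scaling a
   sample scales its profile, and relative-abundance normalization commutes
   with prediction up to a per-sample constant — which is also why the
   rank-based statistics downstream are insensitive to whether raw or
   relative tables are fed in.
3. **Routes.** Each sample's observed (positive-abundance) ECs are covered
   by a minimum set of catalog routes; selected routes are scored by the
   harmonic mean of member EC abundances.
4. **Validation.** Per-sample Spearman correlation against a reference
   profile, judged against a permutation-plus-bootstrap null.
5. **Differential abundance.** Per-feature Wilcoxon rank-sum tests between
   two conditions, with rank-transform summaries and log2 fold changes.

## Key parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `aggregation` | `build_pan()` | `"mean"` | The defining aggregation can be read as either a plain sum or an average of member-genome counts. Both are offered; the mean is the default because under a sum, genera with many sequenced genomes would dominate predictions in proportion to sequencing effort rather than biology. |
| presence threshold | `build_core()` | count > 0 | Equivalent to "count ≥ 1" on integer annotation counts, but additionally invariant to any positive rescaling of counts, which makes core matrices robust to upstream unit choices. |
| `default` copy number | `normalize_copy_number()` | 1.0 | Taxa without copy-number data are divided by 1 and listed in the report rather than dropped: silently removing them would bias function profiles toward well-characterized clades. 16S copy numbers in gut bacteria span roughly 1–15. |
| `exact_limit` | `select_minimal_routes()` | 20 | Up to 20 candidate routes (after dominance pruning) the minimum cover is found by exhaustive enumeration by increasing size — provably minimal. Beyond that, a greedy largest-marginal-cover heuristic with a logged caveat keeps the cost linear. |
| zero-member convention | `route_abundance()` | zero forces zero | A route whose required enzymatic step has zero predicted abundance is scored absent (the harmonic-mean limit), rather than skipping the zero member and scoring the route as present. |
| `n_permutations`, `n_bootstrap` | `build_null()` | 100, 200 | The validation procedure's stated null size: 100 ASV-label permutations, each bootstrapped with 200 samples drawn with replacement. Tests use scaled-down values (20 × 50) to stay within seconds; the null mean is stable well below the full size. |
| exact-test switch | `wilcoxon_test()` | both groups ≤ 12, no ties | Exact enumeration at cohort-scale group sizes, normal approximation with tie and continuity correction beyond — the standard bias/cost trade-off for thousands of features. |
| pseudocount | `log2_foldchange()` | half the smallest nonzero value | Keeps fold changes finite for features absent in one condition while vanishing relative to typical abundances. |
| multiple testing | `diff_analysis(fdr=)` | off | Raw p-value thresholds are the primary interface (matching how such screens are usually reported); Benjamini–Hochberg q-values are available behind the flag. |

## Design choices where the design was open

- **Correlation universe.** Per-sample Spearman is computed over the
  *union* of function ids present in either table, zero-filling absences,
  rather than the intersection. The union penalizes false presences and
  false absences symmetrically; an intersection would reward a predictor
  for predicting nothing. The policy is recorded in every `scc_result`.
- **Welch, not pooled, t-test.** The null distribution's variance is not
  guaranteed equal to the real coefficients', so `compare_to_null()` uses
  unequal-variance t throughout.
- **Normalization order.** Copy-number division happens at the taxon-group
  level, after ASV aggregation, using the median over the genomes pooled at
  that group — not per ASV. This matches the definition of the per-taxon
  copy number as a median over pooled organisms.
- **Tie-breaking in set cover.** Among equal-cardinality covers the
  lexicographically smallest sorted route-id tuple wins; among routes with
  identical coverage the smallest id survives dominance pruning.
  Reproducibility over arbitrariness: identical inputs always give
  identical selections.
- **Whether to renormalize before or after prediction.** Linearity makes
  the two equivalent up to a per-sample constant, and Spearman correlation
  ignores that constant; function tables are therefore emitted raw and
  `relative_abundance()` is an explicit separate step.
- **Species precedence.** When both genus- and species-rank networks are
  supplied, `predict_functions2()` routes species-resolved ASVs through
  the species network and falls back to genus for the rest.
- **Seeding.** Every stochastic routine takes one root seed;
  `build_null()` derives per-permutation child seeds (root + index for the
  label shuffle, root + 500000 + index for the bootstrap draw) so single
  permutations are independently reproducible. `with_seed()` restores the
  caller's RNG state, so library calls never perturb user scripts.

## The synthetic world

`synth_spec()` fixes the stated world the test suite reasons about:
10 genera × 3 genomes, a pool of 200 KOs and 100 ECs, per-genus core sets
covering 30% of the pool shared by all member genomes, accessory functions
present per genome with probability 0.3, integer 16S copy numbers uniform
on 1–7, 3 ASVs per genus, 10 samples of 50,000 reads with
Dirichlet(1)-distributed taxon proportions, and a reference profile equal
to the true function mixture under multiplicative log-normal noise with
SD 0.5. These values are in the range a gut-microbiome amplicon study
would consider realistic (hundreds of functions per genome, copy numbers
1–15 with low medians, uneven compositional profiles) while staying small
enough that every property test runs in seconds.

Two details matter for interpreting green tests:

- The ground-truth function profile is defined at the **realized**
  (multinomially sampled) taxon counts, not the intended Dirichlet
  proportions. This makes the noiseless single-genome world exactly
  invertible — the pipeline's per-sample Spearman against the truth is
  exactly 1 — so the exact-recovery test isolates algorithmic error from
  sampling noise. The intended proportions are also recorded and are
  recovered to within 1% at depth 10^6.
- The generator emulates taxonomic structure, compositional variance,
  copy-number dispersion and reference noise. It does **not** emulate
  chimeras, classifier misassignment (taxonomy maps are exact), primer
  bias, PCR amplification noise, or the phylogenetic correlation of gene
  content between related genera. A green suite therefore establishes
  correctness of the computations, not field accuracy of the predictions
  on real data.

`make_route_catalog()` plants a unique minimum cover and verifies its
uniqueness by exhaustive enumeration at generation time, so set-cover
recovery tests cannot silently pass on a degenerate instance.

## Numerical notes and degenerate inputs

- Tables are plain numeric matrices; all-zero samples are preserved (and
  flagged) rather than dropped, so sample sets stay aligned across stages.
- Spearman coefficients are reported as undefined (`NA`, counted) when a
  sample has fewer than two functions in the union or a constant profile;
  undefined values are excluded from the Welch test on both sides.
- Constant features get Wilcoxon p = 1 with a `constant` flag instead of a
  test failure.
- The TSV dialect writes 7 significant digits, guaranteeing round-trip
  relative error below 5e-7; metadata travels in `# key=value` comment
  lines so a network file is self-describing.
- Function ids are normalized before matching (whitespace trimmed, `EC:`
  prefixes stripped); partial EC numbers with a trailing `-` are kept
  verbatim. Malformed ids are dropped with line-numbered warnings, never
  silently.

## Known limitations

- Reference networks inherit every bias of the genome collection they are
  built from: clades without sequenced genomes are invisible, and genomes
  with incomplete annotations depress core-mode entries for their genus.
- The minimum-cover objective is parsimony, not likelihood; like all
  parsimony pathway callers it can drop genuinely present routes that are
  redundant with others.
- The greedy fallback above `exact_limit` can exceed the optimum by a
  logarithmic factor in the worst case; selections made that way are
  flagged `provably_minimal = FALSE`.
- Differential testing is per-feature and rank-based; it does not model
  compositionality (no CLR/ALR transforms) or covariates. Stratified
  designs are expressed by subsetting the design table, one invocation per
  stratum.
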