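# metgems

Metabolic function and route inference for 16S rRNA amplicon communities.

## The problem

Shotgun metagenomics measures the functional gene content of a microbial
community directly, but remains expensive at cohort scale. 16S rRNA
amplicon sequencing is cheap, yet only yields taxonomic composition. This
package bridges the gap for human-gut-style communities: given an
ASV-by-sample count table and a taxonomy assignment for each ASV, it
predicts the community's metabolic function profile — KEGG Orthology (KO)
and Enzyme Commission (EC) abundances — from taxon-level reference matrices
built out of per-genome annotations, such as those attached to genome-scale
metabolic model (GEM) collections. On top of the function profiles it
reconstructs metabolic-route abundances, validates predictions against
reference (e.g. shotgun-derived) profiles, and runs rank-based differential
abundance between two conditions.

It is aimed at microbiome researchers who have amplicon data and want
function-level hypotheses without running a shotgun pipeline.

## The model

**Reference networks.** For each taxon group $TG_i$ (genus or species) and
function $f_j$, a taxon-by-function matrix is built from member genomes
$G_k$ under four modes:

- *pan*: $fq(TG_i, f_j) = \sum_{G_k \in TG_i} fq(G_k, f_j)$, divided by
  $|TG_i|$ under the default `mean` aggregation;
- *core*: $fq(TG_i, f_j) = 1$ iff $fq(G_k, f_j) > 0$ for **every** member
  genome, else 0 (the intersection of member presence sets);
- *pan-weight*: pan computed after replacing $fq(G_k, f_j)$ with
  $fq(w_k)\,fq(G_k, f_j)$ for per-genome taxonomic weights $w_k$;
- *core-weight*: core computed from unweighted presence (weights recorded
  in metadata only), so it coincides with core.

**Prediction.** An ASV table is aggregated to taxon groups
($fq(TG_i, s_j) = \sum_{ASV_k \in TG_i} fq(ASV_k, s_j)$), divided by the
median 16S rRNA gene copy number of the genomes pooled at each taxon, and
pushed through the network:

$$fq(f_i, s_j) = \sum_{TG_k} fq(TG_k, s_j)\; fq(TG_k, f_i).$$

**Routes.** Per sample, the minimum set of catalog routes covering all
observed ECs is selected (exact set cover up to a candidate limit, greedy
beyond it) and each selected route is scored by the harmonic mean of its
member EC abundances, with any zero member forcing the route to zero.

**Validation.** Per-sample Spearman correlation (SCC) against a reference
profile over the zero-filled union of function ids, compared by Welch
t-test with a null distribution built from ASV-label permutations plus
bootstrap resampling of samples.

**Differential abundance.** Within-sample rank transform, per-condition
geometric means of ranks, per-feature two-sided Wilcoxon rank-sum tests
(exact on small tie-free groups), log2 fold change of group mean relative
abundances with a half-minimum pseudocount, optional Benjamini–Hochberg
adjustment.

## Worked example

The package ships a synthetic-data generator with known ground truth, so a
complete analysis runs in seconds:

```r
library(metgems)

spec      <- synth_spec(seed = 1)          # 10 genera x 3 genomes, 200 KOs
genomes   <- make_genomes(spec)
community <- make_community(spec, genomes)

net_pan  <- build_pan(genomes$gems, rank = "genus", namespace = "KO")
net_core <- build_core(genomes$gems, rank = "genus", namespace = "KO")
print(net_core)
#> metgems_network: core / genus / KO - 10 taxa x 200 functions
cat("coverage:", coverage(net_pan), "(pan) vs", coverage(net_core), "(core)\n")
#> coverage: 200 (pan) vs 195 (core)

cn   <- data.frame(taxon = genomes$gems$meta$genus,
                   copy_number = genomes$gems$meta$copy_number_16s)
taxa <- normalize_copy_number(aggregate_asvs(community$asv,
                                             community$taxonomy), cn)
pred <- predict_functions(taxa, net_pan)
ref  <- make_reference_profile(community$truth, namespace = "KO")

real <- spearman_per_sample(pred, ref)
print(real)
#> scc_result: 10 sample(s), 200 functions in union; mean SCC = 0.5625

null <- build_null(community$asv, community$taxonomy, cn, net_pan, ref,
                   n_permutations = 20, n_bootstrap = 50, seed = 1)
print(null)
#> null_scc: 1000 coefficients from 20 permutation(s) x 50 bootstrap draw(s); mean = 0.3329

test <- compare_to_null(real, null)
cat(sprintf("Welch t = %.2f, p = %.3g\n", test$statistic, test$p.value))
#> Welch t = 9.94, p = 2.46e-06
```

Reading: the pan network covers all 200 simulated KOs while the core
network drops 5 that are not shared by every genome of some genus. With the
default reference noise (log-SD 0.5) the prediction agrees with the
reference at mean SCC 0.56 per sample, clearly above the label-shuffled
null (0.33): the prediction captures real taxon-to-function signal, not
shared compositional structure.

## Command line

Every stage is also a subcommand (see `inst/scripts/metgems`):

```sh
metgems simulate --out demo --seed 7
metgems build-db --gem-metadata demo/gem_metadata.tsv --mode core \
        --namespace EC --out demo/network.tsv
metgems predict  --asv-table demo/asv_table.tsv --taxonomy demo/taxonomy.tsv \
        --network demo/network.tsv --copy-number demo/copy_numbers.tsv \
        --relative --out demo/pred.tsv
metgems routes   --ec-table demo/pred.tsv --catalog demo/route_catalog.tsv \
        --out demo/routes.tsv
metgems diff     --table demo/pred.tsv --design demo/design.tsv \
        --out demo/diff.tsv
```

Each command writes a JSON provenance record (inputs, parameters, seed,
version) next to its output.

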