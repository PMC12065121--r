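# cladeforest

Tools for asking whether categorical **host-taxonomy and biogeographical
metadata carry phylogenetic signal** for a parasite tree — written for
systematists working on host–parasite systems (the motivating case is
proteocephalidean tapeworms in fishes, reptiles and amphibians) whose
trees resist reconciliation with hosts and geography one character at a
time.

The package implements two complementary analyses on a rooted, possibly
polytomous tree with a disjoint partition of its terminals into named
clades:

1. **Parsimony character optimization.** Each categorical attribute
   (host class `CatHC`, order `CatHO`, family `CatHF`, genus `CatHG`,
   species `CatHS`; habitat `CatE1`, aquatic-ecosystem type `CatE2`;
   zoogeographical region `CatL1`, continent `CatL2`, country/basin
   `CatL5`) is optimized on the tree by unit-cost parsimony
   (Fitch/Hartigan, exact for hard polytomies; missing `?` and
   inapplicable `NA` cells are full-alphabet wildcards). Deterministic
   ACCTRAN and DELTRAN reconstructions define *nonambiguous*
   transformations — branches where both flavours place the same
   (from, to) change — and each such transformation on a clade of ≥ 3
   terminals is classified as a **unique** synapomorphy (single origin,
   all bearers inside the clade), a **private** homoplasy (multiple
   origins, bearers still exclusive) or a **nonprivate** homoplasy.
   Branches with no nonambiguous change of any character can be
   collapsed, yielding the synapomorphy-supported cladogram.

2. **Random-forest clade prediction under a label-perturbation null.**
   The metadata table is curated (intermediate/paratenic-host rows
   dropped, missing data removed, clade labels attached) and one-hot
   encoded into a binary matrix X with one column per observed
   (feature, value) pair. For each perturbation level
   p ∈ {0, 0.01, …, 1}, each terminal's clade label is replaced with
   probability p by a uniform draw over the observed clade names; a
   100-tree random forest is trained on a random 75% of rows and scored
   on the remaining 25% (plain accuracy against the perturbed labels),
   ten replicates per level. Ordinary least squares of accuracy on
   perturbation level summarizes the degradation:

   accuracy ≈ β₀ + β₁·p,  reported with R² and the slope's p-value.

   If the metadata predict clades, β₁ < 0 with high R², accuracy at
   p = 0 is far above chance, and accuracy at p = 1 falls to 1/k for k
   clades. Normalized impurity importances, averaged per level, rank the
   value-level attributes driving the predictions.

A **synthetic-data generator** produces trees with planted monophyletic
clades and clade-correlated, hierarchically consistent metadata
(species ⊂ genus ⊂ family ⊂ order ⊂ class; country ⊂ continent) at a
tunable signal strength, so the whole pipeline is testable end to end
without any external data. A **tree-comparison** utility counts shared
and unique clades (exact terminal-set identity, rooted semantics)
between two trees on the same terminals.

## Worked example

Simulate a study-scale dataset (8 clades, 537 terminals, ~8%
intermediate/paratenic rows, signal 0.9), curate, encode, and run a
coarse perturbation sweep:

```r
library(cladeforest)

cfg <- synthetic_config(seed = 42)
sim <- make_tree_with_clades(cfg)
md  <- make_metadata(sim$partition, cfg)

labels <- label_terminals(sim$tree, sim$partition)
cur <- curate(md$metadata, labels = labels)
print(cur)
#> Curated metadata table: 494 rows x 10 features (4940 data points)
#>   dropped: 43 intermediate/paratenic rows, 0 rows with missing data, 0 unlabelled rows

enc <- one_hot(cur)          # 494 x 234 binary matrix for this seed
sw <- sweep_perturbation(enc, levels = seq(0, 1, by = 0.1),
                         replicates = 5, base_seed = 42)
print(sw)
#> Perturbation sweep: 11 levels x 5 replicates = 55 forest runs
#>   mean accuracy at p=0.00: 0.9903
#>   accuracy ~ level: slope -0.8966, R2 0.9800, p 1.08e-46

aggregate_importances(sw, level = 0, top_n = 5)
#>         column mean_importance
#> 1 CatL5=L5_001      0.02647321
#> 2 CatHS=HS_006      0.02269081
#> 3 CatE1=E1_001      0.02261446
#> 4 CatL5=L5_007      0.02226340
#> 5 CatL1=L1_008      0.02206935
```

Read: of 537 simulated terminals, 43 intermediate/paratenic records are
excluded, leaving 494 rows × 10 features. With strong planted signal the
forest places 99.0% of held-out terminals in their clade at zero
perturbation; accuracy decays essentially linearly (slope −0.90,
R² 0.98) to chance (1/8) at full perturbation, and the top-ranked
columns are clade-profile values (a country, a host species, a habitat…).
`plot_accuracy_sweep()` and `plot_importances()` draw the corresponding
figures; `render_report()` writes the full bundle (runs CSV, regression
JSON, figures) to a directory.

Character optimization works the same way from the tree side:

```r
cm  <- make_character_matrix(sim$tree, n_chars = 6, changes_per_char = 2,
                             seed = 1)
rec <- classify_transformations(sim$tree, cm$matrix)   # one row per change
head(rec[!rec$ambiguous & !is.na(rec$classification),
         c("character", "clade_size", "from", "to", "classification")])
collapsed <- collapse_unsupported(sim$tree, rec)       # polytomic cladogram
```

## Command line

A thin CLI mirrors the pipeline (`exec/cladeforest`, or call
`cladeforest::cf_cli()`):

```sh
cladeforest simulate --seed 1 --clades 8 --out sim/
cladeforest curate   --metadata sim/metadata.csv --clades sim/clades.json \
                     --tree sim/tree.nwk --out cur/
cladeforest predict  --metadata sim/metadata.csv --clades sim/clades.json \
                     --tree sim/tree.nwk --seed 1 --out out/
cladeforest compare-trees a.nwk b.nwk
```

Every run writes a `manifest.json` (config, input checksums, seed,
outputs) from which results replay bit-identically.

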