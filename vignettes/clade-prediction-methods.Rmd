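---
title: "Methods: parsimony optimization and random-forest clade prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parsimony optimization and random-forest clade prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladeforest)
```

## The problem

Host–parasite systems often show phylogenies that are hard to reconcile
with host taxonomy and biogeography one character at a time: individual
attributes such as host order or zoogeographical region map onto the
parasite tree with extensive homoplasy, and few branches are supported by
clean synapomorphies. `cladeforest` implements two complementary ways of
asking whether such metadata nevertheless carry phylogenetic signal:

1. **Character optimization** — classical parsimony mapping of each
   categorical attribute onto the tree, with every nonambiguous state
   change classified as a unique synapomorphy, a private homoplasy, or a
   nonprivate homoplasy, and branches lacking any nonambiguous change
   collapsed into polytomies.
2. **Multidimensional clade prediction** — a random-forest classifier
   trained on all attributes simultaneously (one-hot encoded) to predict
   clade membership, validated by an escalating label-perturbation null:
   if the metadata truly predict clades, accuracy must decay linearly as
   clade labels are progressively randomized, reaching chance at full
   perturbation.

The package is written for rooted, possibly polytomous trees (class
`phylo` from **ape**) whose terminals are sequenced parasite specimens,
together with a disjoint partition of terminals into named clades and a
categorical metadata table (host class/order/family/genus/species,
habitat, aquatic-ecosystem type, zoogeographical region, continent,
country/river basin).

## Parsimony engine

`fitch_score()` computes the minimum number of unordered state changes by
a unit-cost dynamic program (Sankoff recursion with 0/1 costs). For each
node $v$ and state $s$ the subtree cost is

$$ c_v(s) = \sum_{u \in \mathrm{children}(v)} \min_t\,
   \bigl(c_u(t) + [t \neq s]\bigr), $$

which for multifurcating nodes is equivalent to the Hartigan
generalization of Fitch optimization (the minimizing state set is the set
of states attaining maximal child coverage, with cost equal to the number
of children not covered). The score is $\min_s c_{\mathrm{root}}(s)$ and
is exact for hard polytomies; the test suite checks it against exhaustive
enumeration of all internal labelings on hundreds of random trees.

Missing (`?`) and inapplicable (`NA`, used for paratenic-host records)
cells are optimized as full-alphabet wildcards. Because a wildcard
terminal can always adopt its parent's state at zero cost, wildcards
never generate changes of their own — they only fail to constrain.

### ACCTRAN, DELTRAN and nonambiguity

`mpr_reconstructions()` returns two deterministic most-parsimonious
assignments obtained by top-down traceback through the cost vectors: the
root takes the first minimum-cost state in alphabet order; descending,
**DELTRAN** keeps the parent's state whenever it is among the child's
minimizers (delaying changes tipward), while **ACCTRAN** adopts a
non-parent minimizer whenever one exists (accelerating changes rootward).
Residual ties are broken by the declared alphabet order, so output is
fully reproducible. Any traceback through exact cost vectors realizes the
optimal score, so both flavours always imply exactly `fitch_score()`
changes — a property the tests assert on random trees.

A transformation on a branch is **nonambiguous** when both flavours agree
on its (from, to) pair. This is a design choice: "nonambiguous" could
also be defined over the full MPR set, but enumerating all MPRs is
exponential in the worst case and the two canonical flavours bracket the
placement freedom that matters here (root-ward versus tip-ward). We do
not guess beyond their agreement.

### Classification of transformations

For each nonambiguous transformation on a branch subtending at least
three terminals (smaller clades are recorded but left unclassified), the
derived state is classified as:

* **unique** — it originates exactly once on the tree (in both
  reconstructions) and every terminal exhibiting it lies inside the
  clade;
* **private** — it originates more than once, but all bearers are inside
  the clade;
* **nonprivate** — bearers occur outside the clade.

Origin counting needs a concrete reconstruction; we require a single
origin in *both* flavours before calling a state nonhomoplastic, the
conservative deterministic choice. `collapse_unsupported()` then removes
every internal branch that carries no nonambiguous change of any
character, which on weakly structured data produces the expected highly
polytomic cladogram.

## Metadata curation and encoding

`curate()` fixes an explicit order for an otherwise ambiguous cleaning
prescription: (1) drop intermediate/paratenic-host rows, (2) restrict to
the requested features, (3) drop feature columns above a missingness
threshold, (4) drop rows with any remaining missing cell, (5) drop rows
without a clade label, with a count report at every step. The column
threshold defaults to 1 (only fully-missing columns are removed) because
the design point of the analysis is to keep all ten features and lose the
minority of incompletely annotated terminals (~8% at study scale) rather
than sacrifice predictors. Synonym harmonization is an optional
user-supplied substitution map applied before anything else; hierarchical
consistency of the taxonomy is validated with warnings only, never
auto-corrected.

`one_hot()` expands each feature into one indicator column per observed
value (`CatHF=Pimelodidae` style), ordered by feature then first
observation. The encoder mapping is retained (and serializable as JSON)
so new rows can be encoded identically; `decode_one_hot()` inverts the
expansion exactly, and the tests assert losslessness and that the column
count equals the sum of per-feature cardinalities (446 columns for the
study's printed cardinalities over 494 rows).

## The perturbation experiment

`perturb_labels()` replaces each terminal's clade label, independently
with probability $p$, by a uniform draw over the observed clade names.
The draw **includes** the original label by default, so the effective
change probability is $p\,(k-1)/k$ and at $p = 1$ the expected fraction
of retained labels is $1/k$. An `exclusive` variant (always draw a
different label) is available; the inclusive default is the natural
reading of "assigning a terminal to a random label" and gives the cleaner
analytic null.

`run_replicate()` perturbs first, then draws a simple random
(unstratified) 75% training split, fits a 100-tree random forest
(**ranger**, single thread, impurity importance, all other
hyperparameters at the implementation's documented defaults, recorded in
the result), and scores plain accuracy on the held-out 25% *against the
perturbed labels*. Measuring against perturbed rather than original
labels is deliberate: the perturbation defines the (noisy) ground truth
of that run, and with a uniform inclusive draw it makes the full-
perturbation expectation exactly $1/k$ regardless of what the model
learned.

`sweep_perturbation()` runs the default grid of 101 levels
(0 to 1 in 0.01 steps) times 10 replicates = 1010 forest fits. Each run's
seed is a documented deterministic function of the base seed and the
run's (level, replicate) slot, all below $2^{31}$; identical inputs give
bit-identical sweeps. `fit_accuracy_regression()` fits ordinary least
squares of accuracy on level over all replicate points (fitting on level
means is an option; replicate points are the default because the
scatter of replicates is part of the reported evidence), returning slope,
intercept, $R^2$ and the slope's two-sided p-value. A constant-accuracy
degenerate input returns a flat fit (slope 0, $R^2$ 0) rather than a
numerically unstable one. `aggregate_importances()` averages normalized
impurity importances per level and ranks value-level columns.

## Synthetic data: what it emulates and what it does not

`synthetic_config()` defaults encode the study conditions: $k = 8$
clades over 537 terminals, 8% of rows flagged as intermediate/paratenic
(so curation retains ≈494 rows and 4940 data points), ten features with
cardinalities (5, 28, 63, 116, 170, 2, 3, 10, 7, 42), missingness 0, and
signal $s = 0.9$ — strong but imperfect clade-profile fidelity, the
regime a strongly structured empirical dataset occupies.

`make_tree_with_clades()` builds each clade by random sequential joins of
its terminals and then joins the clade roots, so every planted clade is
monophyletic by construction. `make_metadata()` gives each clade a
characteristic profile — one host-taxonomy chain (species through class),
habitat, ecosystem type, region, and one country/continent chain — and
each terminal copies the profile per feature *group* with probability
$s$, otherwise drawing from the global pool. Draws always follow the
declared hierarchy (a species implies its genus, family, order, class; a
country implies its continent; the zoogeographical region is drawn
independently of the continent, since faunal realms cut across
continents). Profiles are guaranteed distinct as combinations by giving
each clade its own host-order lineage and country; fully disjoint
per-feature profiles are optional and require every cardinality
$\geq k$.

What the generator does **not** model: branch-level host-switching
dynamics (profiles are clade-level, not a process along branches),
unbalanced or nested clade signal, correlated missingness, label noise in
the reference partition, and the oversampling biases of real collections.
Passing tests on synthetic data therefore demonstrate that the machinery
is correct and calibrated — chance-level accuracy at full perturbation,
near-perfect accuracy under perfect signal, monotone signal recovery —
not that any particular empirical dataset has signal.

`make_character_matrix()` plants a known number of state changes on
non-nested branches with distinct derived states ("clean" mode), making
the true minimum change count equal to the Fitch score; this is the test
harness for the optimization module.

## Numerical and design choices

* Clade identity is exact terminal-set equality on rooted trees; the
  root's full set and singleton terminals are never counted as clades,
  and no bipartition complementation is applied when comparing trees.
* All alphabet/tie-break orderings are lexicographic and documented, so
  every result is reproducible to the bit from one integer seed.
* The train/validation split uses `floor(0.75 n)` training rows; a clade
  absent from a training split is a warning, not an error (the forest
  predicts over seen classes only).
* Forest fits use one thread; parallelism would break bit-level seed
  reproducibility of importance vectors for no benefit at this problem
  size.
* The test suite works at deliberately chosen problem sizes: exhaustive
  parsimony checks on trees of up to 8 terminals and 4 states (where
  enumeration of all labelings is exact and fast), calibration and
  signal-recovery checks at the full study scale of ~494 encoded rows,
  and the complete 1010-fit sweep once.

## Known limitations

* "Nonambiguous" is defined by ACCTRAN/DELTRAN agreement, not the full
  MPR set; a transformation placed identically by both flavours but
  movable in some third MPR would still be called nonambiguous.
* `collapse_unsupported()` returns a cladogram (topology only); branch
  lengths and support annotations are not propagated through the
  collapse.
* The curation count report reproduces rule-based exclusions only;
  manual, judgement-based exclusions in an empirical dataset can make
  reported row counts differ from a strict replay of the rules.
* No weighted (Sankoff-cost) parsimony, no likelihood ancestral states,
  no optimization over tree sets: a single input tree is assumed.
* The forest protocol is fixed by design (100 trees, 75/25 split, ten
  replicates per level); there is deliberately no hyperparameter search
  and no alternative classifier.
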