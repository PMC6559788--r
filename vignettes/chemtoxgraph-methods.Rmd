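---
title: "Methods: similarity networks, toxicity overlap and enzyme dominance"
author: "chemtoxgraph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: similarity networks, toxicity overlap and enzyme dominance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemtoxgraph)
```

# Overview

`chemtoxgraph` builds a queryable property graph that connects food, drug and
endogenous compounds through three kinds of evidence relevant to gut microbial
metabolism: shared chemical substructure, shared side-effect (toxicity)
profiles, and shared metabolising enzymes, with each enzyme annotated by how
taxonomically concentrated it is across a microbial community. The intended
use is hypothesis generation: if a drug with a known microbiome-sensitive
fate sits next to a food compound in substructure space, and both connect to
the same microbial enzyme, that food compound is a candidate modulator or
alternative substrate.

This vignette explains each model, its assumptions, the tunable parameters,
the numerical conventions, and what the synthetic fixtures do and do not
establish.

# Substructure similarity network

Each compound carries an 881-bit binary substructure key (the PubChem-style
fingerprint layout: a base64 string over a 4-byte big-endian bit count
followed by MSB-first bit-packed data with zero padding). Similarity between
two compounds is the Tanimoto coefficient over set bits,

$$T(A,B) = \frac{|A \cap B|}{|A \cup B|},$$

which rewards shared substructures and ignores shared absences. Two all-zero
fingerprints are defined to have similarity 0: the 0/0 case carries no
substructure evidence, and calling featureless records identical would
manufacture spurious edges. Compounds lacking a fingerprint are dropped with
a warning rather than erroring, because real compound tables are incomplete.

Pairs below `min_similarity` (default **0.3**) are removed; surviving pairs
become weighted edges. Communities are found with Walktrap (random-walk
agglomeration, walk length **4**, the algorithm's canonical default), keeping
the partition at maximum modularity. Isolated nodes become singleton
communities, and community ids are renumbered by each community's
lexicographically smallest member so a given input always yields the same
labels regardless of library-internal ordering.

Within each community, an edge's Z-score is computed from that community's
own edge-score distribution, using the sample (n−1) standard deviation, and
an edge is *significant* when `z >= z_threshold` (default **1**). Two
conventions here were genuinely open and are package decisions:

* **One-sided threshold.** "At least one standard deviation away" could be
  read two-sided; we flag only the upper tail, because significance in a
  similarity network should reward unusually high overlap, and a two-sided
  rule would flag a community's *least* similar pairs as notable.
* **Degenerate communities.** Communities with fewer than two internal edges
  or zero spread yield no significant edges (the Z-score is undefined);
  inter-community edges stay in the graph but are never significant, since
  the significance statistic is defined only within a community.

# Toxicity similarity

Drug toxicity similarity follows the side-effect-profile approach: each drug
is its set of side-effect concept ids (taken as given; no ontology mapping is
performed), and a pair's similarity sums per-concept weights over the shared
concepts. Each concept's weight is the product of two terms:

* **Rarity**: `-ln(frequency)`, where frequency is the fraction of drugs
  listing the concept. The information-content form is our choice — the
  approach we follow defers the formula to its sources — and it has the
  properties that matter: a concept listed by every drug carries weight 0,
  and weight grows smoothly as a concept becomes rarer.
* **GSC redundancy weight**: concepts are clustered by the Tanimoto
  co-occurrence of their drug sets (UPGMA on distance 1 − co-occurrence,
  node heights at half the merge distance, so the tree is ultrametric), and
  Gerstein–Sonnhammer–Chothia weights are computed on that tree: edges are
  processed from the tips toward the root, and each edge's length is divided
  among its subtree's leaves in proportion to their accumulated weights
  (equally while all are zero). Before rescaling to mean 1, leaf weights sum
  exactly to the tree's total branch length, and a concept duplicated at
  distance zero has its weight split in half — the two properties that make
  GSC the standard cure for redundant, highly correlated items.

The pair score `sum of shared weights` is normalised cosine-style by the
geometric mean of the two drugs' self-scores, giving a bounded `[0, 1]` scale
with 1 exactly for identical weighted profiles and 0 for disjoint ones. The
source approach states no normalisation; a bounded scale is needed so that
"toxicity overlap at least x" queries mean the same thing for drugs with
short and long side-effect lists.

One caveat discovered during development and worth knowing: *adding* a
duplicate concept to the data (rather than duplicating a leaf on a fixed
tree) perturbs pair scores at second order, by about 1e-4 in our fixtures.
The duplicate leaf itself is down-weighted exactly as intended, but it also
doubles its cluster's size in UPGMA's size-weighted average linkage, which
shifts later merge heights slightly. We accept this as inherent to
average-linkage trees.

# Enzyme taxonomic dominance

For an enzyme with species-level carrier counts `n` summing to `N`, the
Simpson dominance is

$$D = \frac{\sum_s n_s (n_s - 1)}{N (N - 1)},$$

the probability that two individuals drawn without replacement belong to the
same species. The reported score is `ECs_D = 1 − D`: near 0 for functions
concentrated in one or few species (attractive intervention targets, fragile
community functions), near 1 for broadly distributed functions. `D` is
undefined for `N < 2`; such enzymes are reported as *not scoreable* rather
than silently assigned 0 or 1. Species with zero counts contribute nothing,
so padded tables are harmless.

Cohort classification labels an enzyme high-dominance when its score falls
below the cohort mean. The threshold is always recomputed from the input
cohort — it is a property of the dataset, not a constant — and the ±1 sd band
is reported alongside.

# Shared-enzyme probability model

To estimate the probability that two compounds are substrates of the same
enzyme, every pair is labelled `associated` (EC sets intersect) or
`non_associated`, and encoded by a symmetric feature vector: the pair's
Tanimoto similarity followed by the absolute difference of each
physiochemical descriptor (descriptors arrive precomputed in six groups:
geometry, functional groups, aromaticity, amino acid composition, polarity,
hydrophobicity; the package does not compute chemistry descriptors). Absolute
differences are our choice of pair encoding; they are order-invariant, which
a concatenation would not be.

The classifier is a radial-kernel support-vector machine with Platt-style
probability calibration (the binary task is the degenerate single case of a
one-vs-one decomposition). Features are standardised inside the model on
training data only; the kernel bandwidth uses the median heuristic on
pairwise feature distances; the majority class is down-sampled to at most
5:1 before fitting; and all stochastic steps are seed-controlled, so
retraining with the same seed reproduces identical predictions. Reported
probability-versus-similarity curves use out-of-fold predictions from
5-fold stratified cross-validation, with uniform similarity bins on
`[0, 1]`. Note that the *mean* predicted probability reflects class
prevalence; the label-permutation diagnostic is therefore run on a balanced
pair subset, where an uninformative model must sit near 0.5.

# Network validation analyses

* **Superclass agreement.** Per 0.05-wide similarity bin, among edges whose
  endpoints both carry a chemical-taxonomy superclass, the matched and
  unmatched counts are tallied. The matched *fraction* is reported alongside
  the matched:unmatched *ratio*, because the ratio is undefined in bins with
  no unmatched pairs.
* **Randomized reference.** The comparison network keeps the node set, node
  labels and edge count, and draws edges uniformly at random among node
  pairs without replacement; the original edge-score multiset is reassigned
  in random order. Degrees are deliberately not preserved — "same nodes,
  edges and labels" is the stated invariance — but a degree-preserving
  rewiring is available behind a flag for sensitivity analysis. The
  real-versus-random comparison is a two-sided Wilcoxon rank-sum test on the
  edge-level superclass-match indicators. (An alternative reading — testing
  the similarity *scores* of matched edges — is uninformative under this
  randomization, which preserves the score multiset by construction; the
  indicator reading tests the claim that connectivity carries chemical
  ontology.)
* **Structure–toxicity regression.** Ordinary least squares of toxicity
  similarity on substructure similarity over drug pairs present in both edge
  sets, reporting slope, Pearson r and the two-sided p-value.
* **Category self-similarity.** A two-sample Kolmogorov–Smirnov test between
  the within-category pairwise-similarity distributions of two compound
  categories.

# Property graph

Nodes are `Compound`, `Enzyme` and `Use`; relationships are
`SUBSTRUCTURE_SIMILARITY` and `TOXICITY_SIMILARITY` (Compound–Compound,
stored once in canonical min-id → max-id orientation and queried as
undirected), and `HAS_USE` and `METABOLIZED_BY` (directed Compound →
target). `ECs_D` is stored as an Enzyme node property — it is a per-enzyme
scalar, not an entity. Queries return rows ordered by score descending then
id ascending, so results are reproducible across runs and platforms. Export
formats are GraphML (typed attributes, one file) and a bulk-import CSV pair
following graph-database importer conventions (`:ID`, `:LABEL`,
`:START_ID`, `:END_ID`, `:TYPE` headers); both round trip through
`import_graph()`. Rows referencing unknown compounds are logged, skipped and
counted rather than failing the build.

The command-line wrapper (`inst/cli/chemtoxgraph.R`) is a thin layer over
these functions: `build` runs readers → network → toxicity → dominance →
graph and writes the export formats; `query
neighbors|dual|substrate-pool` answers the three query patterns; `export`
converts between formats. A key:value config file can supply thresholds and
seeds.

# Synthetic fixtures: what they emulate

All tests run on seeded synthetic data with the statistical structure each
stage assumes:

* compounds fall into `n_clusters` groups, each with a random template bit
  set covering `shared_bit_fraction` of the 881 positions; members flip bits
  independently at `bit_flip_noise`. Defaults (4 clusters,
  fraction 0.25, noise 0.02, 200 compounds) put within-cluster similarity
  near 0.85 and between-cluster similarity near 0.14 — clearly either side
  of the 0.3 edge threshold, which is the regime the pipeline assumes;
* superclasses align with clusters with probability 0.9, emulating chemical
  taxonomy tracking substructure;
* drugs draw side-effect concepts from a cluster-specific pool with
  probability `coupling` (default 0.8) and uniformly otherwise, so
  structure–toxicity coupling is tunable and `coupling = 0` is exact
  independence;
* each cluster owns an enzyme carried by members with probability
  `sqrt(enzyme_sharing)`, so a within-cluster pair shares it with
  probability `enzyme_sharing`, plus a small uniform background rate;
* species abundances per enzyme are Dirichlet-multinomial with concentration
  `evenness` (default 5, moderately uneven, 20 species, 1000 individuals);
  when a target `ECs_D` is requested, one dominant share is solved by root
  finding so the realised score lands within 0.02 of the target.

One global seed expands into per-stage child seeds through fixed counters,
so adding a stage never changes earlier stages' draws and a (spec, seed)
pair is byte-reproducible.

The fingerprints are statistical stand-ins, not valid molecules: passing
tests establishes that the algorithms behave as specified under planted
structure, not that real chemical space is this cleanly separable. In real
corpora, clusters overlap, superclass alignment is weaker, fingerprint bit
correlations are structural rather than independent, and side-effect data
carry reporting biases none of which the generator reproduces. The shipped
`steroid_fingerprints_synthetic.tsv` is likewise a constructed stand-in
(shared scaffold core, divergent decorations) used to exercise the
decode-and-compare path; its similarity values are properties of its
construction, not measurements of the real compounds its names allude to.

# Problem sizes and numerical conventions

The default test and acceptance runs use 1,000 compounds (4 clusters, ~125k
edges) for network and graph-query checks, 100 regression replicates at
1,000 pairs, 200 null replicates for the type-I-error check, and a few
hundred pairs for classifier fixtures — sizes chosen so the full suite
completes in a few minutes on a single core while leaving every statistical
check comfortably powered. Other conventions: UPGMA ties break
deterministically by clustering concepts in lexicographic order; Tanimoto
denominators of zero (both sets empty) return 0 everywhere they can arise
(fingerprints, concept co-occurrence); unordered pairs are stored once under
the lexicographically ordered key; and classification thresholds derived
from data (the ECs_D cohort mean, per-community Z statistics) are always
recomputed from the input at hand.

# Known limitations

* The rarity and normalisation formulas are principled substitutes where the
  sources leave the exact form unstated; rankings are stable under monotone
  reweighting but absolute toxicity-similarity values are convention-bound.
* Walktrap at maximum modularity inherits modularity's resolution limit;
  very small tight communities may be absorbed on real data.
* The shared-enzyme model predicts *whether* a pair shares any enzyme, not
  which enzyme acts — reaction-rule matching is out of scope.
* `ECs_D` treats "individuals carrying an enzyme" as given counts; it does
  not model gene copy number or read-depth noise in how those counts were
  produced.
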