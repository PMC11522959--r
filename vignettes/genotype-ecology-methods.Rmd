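---
title: "Methods: ontology-driven genotype-environment association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-driven genotype-environment association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yeastenv)
```

## The problem

Budding yeasts (subphylum Saccharomycotina) are isolated from an enormous
range of substrates — insect guts, flowers, decayed wood, soil, fermented
foods — but the isolation environment is recorded as free natural-language
text in species descriptions. That format blocks any high-throughput
analysis of genotype-environment association. `yeastenv` implements the two
halves of a solution:

1. **An environment ontology engine.** Isolation environments become classes
   in a strict single-parent hierarchy under six exclusive roots (animal,
   plant, environmental, fungal, industrial products, victuals). Each strain
   is an *instance* assigned to its most specific ("direct") class(es);
   membership in every ancestor class is derived by transitive closure, never
   stored. Secondary associations ("a beetle *on a flower*") are typed
   *relational* properties between the primary environment and another class;
   *modifier* properties annotate features such as decay or fermentation.
2. **A genotype-to-ecology pipeline.** Strains are labelled positive or
   negative for an environment through the ontology, and balanced consensus
   random forests over KEGG-ortholog (KO) presence/absence features identify
   the gene families whose presence predicts the environment, followed by
   per-KO Fisher exact tests and hypergeometric pathway over-representation.

## Membership semantics

For a class $c$, `members(ont, c)` returns every strain whose direct class is
$c$ or any descendant of $c$; counting is therefore *non-exclusive* up the
hierarchy (a strain on "pollen" is also a plant member). Relational
membership closes over the *target*: a relation pointing at "beetle" counts
as a relational connection to "animal". `order_distribution()` offers both
counting modes: a non-exclusive mode (closure plus, optionally, relational
connections), and an exclusive mode in which each strain is counted through
at most one of the supplied categories and the denominator is the number of
strains of that taxonomic order falling in any category.

Two semantics questions are left open by the source material and resolved
here as follows. First, a strain may carry several direct classes (a mixed
substrate); the validator accepts any set of resolvable ids and the closure
queries union over them. Second, relational membership counts *any* property
whose target lies in the queried subtree by default; a `property_id` filter
restricts it when a specific relation (for example only "is from plant on
animal") is wanted.

## Classification tasks

A `class_task()` names the positive strains: members of any include class,
plus relational members of any include relation, minus members of the
exclude terms. This makes label *redefinition* a first-class operation: the
plant task can be widened to strains carrying a "from plant" relational
value and narrowed by excluding decay-associated strains, and
`run_redefinition()` reports which strains flipped and the paired change in
mean AUC.

## The forest protocol

The model protocol mirrors the published analysis:

* **Prevalence filter.** KOs present in strictly fewer than 20% of strains
  are removed (`filter_low_prevalence()`, boundary kept at "below 20% is
  dropped", so exactly 20% survives).
* **Balancing.** The method behind the published "balanced data set" is not
  stated; we downsample the majority class at random without replacement,
  the simplest scheme consistent with the reported class sizes. Fresh
  balanced sets are drawn per iteration by default (`rebalance_each`),
  since the protocol describes "a different training and testing data set
  for each iteration"; a switch reuses one set when only split variation is
  wanted.
* **Splitting.** 20% of the balanced set is withheld for testing,
  stratified by label (otherwise a test AUC could be undefined). The test
  size is `round(0.2 n)`, allocated across classes by largest remainder.
* **Tuning.** A two-stage grid search on an internal 20% validation split:
  stage one over `mtry` in {sqrt(p), p/10, p/3} and `min_n` in {2, 5, 10}
  (the published text does not give the initial grid; these bracket the
  standard forest defaults), stage two at 0.75/1/1.25 times the stage-one
  winner, rounded, deduplicated and clamped to at least 1. The pair with
  maximum validation AUC over both stages wins, and tuning is done once per
  task, not per iteration.
* **Iterations.** 100 forests by default, iteration $i$ seeded
  `base_seed + i`; each stores test AUC, the true-positive rate at score
  threshold 0.5 (no threshold is stated alongside the published TPR; 0.5 is
  the natural probability cut), per-strain test predictions, and a per-KO
  permutation importance.
* **Consensus.** Per iteration the KOs are ranked by importance
  (descending, ties broken lexicographically by KO id so results are
  deterministic) and the top `top_k` marked; a KO is consensus-flagged when
  marked in at least `ceil(min_frac * n_iterations)` iterations. The
  published rule is top 1000 in 80% of 100 models; for smaller simulated
  studies `top_k` should scale with the feature count (about 5%).

### Permutation importance

Two modes are implemented. The default is ranger's built-in permutation
importance, computed on out-of-bag samples during training — the method the
published analysis itself used ("measured by permutation in the ranger
package") and the only mode whose cost is independent of the feature count
at prediction time. The alternative `"test"` mode (`permutation_importance()`)
permutes each feature column of the held-out fold and reports the mean AUC
drop against the unpermuted baseline; it matches the evaluation metric
exactly but costs one prediction pass per feature per repeat, which at 2000
features multiplies iteration time by roughly forty. Both modes agree on
which features carry signal in our simulations; the OOB mode is the default
because it is the method the original protocol names and its cost does not
grow with the feature count.

## Association statistics

Consensus KOs are re-analyzed with a Fisher exact test on the 2x2 table of
presence/absence against class membership. The reported odds ratio is the
unconditional cross-product $(ad)/(bc)$ — the quantity that pairs naturally
with the printed carrier percentages — reported as `Inf`/`0` with a
`degenerate` flag when an off-diagonal cell is zero (no continuity
correction, since the published values are raw). The two-sided p-value sums
hypergeometric probabilities of tables no more probable than the observed
one (the probability-mass convention; `stats::fisher.test` implements
exactly this rule and is used for the computation, while the test suite
checks it against a full enumeration oracle).

Pathway over-representation is one-sided (enrichment only): with $N$
universe KOs, $K$ in the pathway, $n$ selected and $k$ selected-in-pathway,
the p-value is the hypergeometric upper tail $P(X \ge k)$, BH-adjusted
across tested pathways. The universe is all KOs annotated in the analyzed
matrix (post-filter columns). Pathways whose label ends in "- yeast"
(hyphen, en-dash or em-dash, any surrounding whitespace) are removed first:
those KEGG maps are narrowly defined for one yeast order and under-annotated
elsewhere. Pathways with fewer than 3 in-universe KOs are skipped by
default (`min_pathway_size`), since one- or two-gene "pathways" produce
unstable, trivially extreme p-values.

## The synthetic-data generator

`simulate_study()` produces a complete, fully labelled study:

* a hierarchy of about 1200–2000 classes under six roots (depth 4, two to
  four children per node), with `is_from_<root>_on_<root>` relational
  properties and microbe/decay/fermentation modifiers;
* ~1000 strains, each on one leaf class, root mixture 0.31/0.34 on the
  animal- and plant-analogue roots (matching the published class sizes of
  339 and 366 over 1088 instances) with the remainder spread over the other
  four roots; cross-root relational assertions at rate 0.20;
* a configurable fraction (default 10%) of strains outside the target root
  that carry their positive signal *only* through a relational assertion,
  so the redefinition machinery has ground truth to recover;
* a KO matrix in which each non-planted KO gets one baseline prevalence
  drawn uniformly from [0.25, 0.95] (drawn once per KO, not per strain —
  presence/absence is a species-level trait) and planted KOs switch
  prevalence with the class label. The default planted effect is the
  published template: carrier rate 0.87 in the positive class versus 0.66
  outside. Planted KOs are concentrated in a dedicated 12-KO pathway.

Labels are computed through `build_labels()` on the generated ontology —
the simulation exercises the same closure machinery as real data, not a
shortcut.

What the generator does **not** emulate: phylogenetic correlation among
strains (the forests here, like the published ones, are phylogeny-naive, so
passing tests say nothing about confounding by shared ancestry), KO calling
error, within-species strain variation, or realistic pathway size and
overlap structure. Recovery results on synthetic data therefore demonstrate
the pipeline's correctness and statistical behaviour, not field performance
on real genomes.

## Validation problem sizes and numerical choices

The validation suite runs the full pipeline at the published class sizes
(339 positive / 747 negative, 2000 KOs, planted effect 0.87 vs 0.66, 25
iterations per master seed, `top_k = 100`, ten master seeds) with forests
of 200 trees, and a matching null study with no planted effect; 200 trees
keeps a ten-replicate validation affordable on a single CPU while leaving
consensus recovery and AUC essentially unchanged from the 500-tree default
(`pipeline_config()` retains 500). Under these conditions the planted KO is
consensus-flagged and its pathway ranks first in every replicate, the mean
test AUC clears 0.55 with tuned hyperparameters (a single informative
binary feature caps the achievable AUC near 0.60), the null AUC sits in
[0.45, 0.55], and the null Fisher false-positive rate at p < 0.05 is close
to 5%.

Other numerical conventions: ids are case-sensitive and
whitespace-trimmed; multi-values in the TSV dialect are `|`-separated with
relation triples encoded `property_id->target_class_id`; grid refinement
uses R's round-half-to-even; consensus and top-k ties break
lexicographically; OWL serialization is byte-stable so reruns diff cleanly.

## Limitations

* No OWL-DL reasoning: restriction, equivalence, and multiple-inheritance
  axioms are rejected or reported, never interpreted.
* One model per task; the hierarchy is not modelled jointly (a multi-label
  or structured model is future work, as the published discussion notes).
* The per-KO Fisher tests are marginal and uncorrected for relatedness;
  they are a re-analysis aid for consensus KOs, not a GWAS substitute.
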