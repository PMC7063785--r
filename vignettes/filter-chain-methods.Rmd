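---
title: "Filter-chain pathogenicity triage: model, parameters, and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-chain pathogenicity triage: model, parameters, and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treespp)
```

## The classification problem

A sequencing report on a patient typically surfaces thousands of
non-synonymous variants, most of them of uncertain clinical significance.
Standalone pathogenicity predictors (SIFT, PolyPhen, PROVEAN, and the larger
dbNSFP roster) disagree with each other often enough that manual review
remains the bottleneck. `treespp` implements a deliberately simple,
fully interpretable alternative: a *filter chain* — a degenerate decision
tree in which every node's neutral branch is terminal and the pathogenic
branch continues to the next node.

The chain consumes four binary variables, each coded 1 = pathogenic-leaning:

* **SPP** — the consensus of SIFT, PolyPhen and PROVEAN: 0 only when all
  three call the variant neutral, 1 when at least one calls it pathogenic.
* **ExAC** — rarity in the ExAC exome aggregate: 1 when the allele frequency
  is at or below `1e-4`, or when the variant is absent from the database.
* **NDamage** — the number of damage predictors (up to nine) calling the
  variant pathogenic: 1 when at least five do.
* **COMMON** — the same rarity rule over a 1000 Genomes-derived frequency.

A variant is classified by walking the levels in order; the first level
whose variable is 0 exits it as Neutral (final), and a variant whose
variables are all 1 is Pathogenic. The final label is therefore the
conjunction of the level variables — level *order* only affects the exit
level and the per-level error profile, not the final label. That identity
is the backbone of the test suite: every chain classification is checked
against the brute-force conjunction rule over all feature assignments.

## Discretization rules and their edge cases

Continuous and categorical annotations are reduced to binary flags by
`discretize_variants()`. The consequential choices:

* **Frequency boundary.** A frequency exactly equal to the threshold is
  assigned to the pathogenic side, matching the "less than" phrasing of the
  rare branch. At the default `1e-4` this affects a measure-zero set for
  continuous annotations and is covered by an explicit boundary test.
* **Missing frequencies are pathogenic-leaning.** A variant absent from the
  population databases cannot be called common; the imputation is recorded
  per variant in the `provenance` attribute, so downstream reports can
  quantify how much of a call set rests on imputed values. The cost of this
  convention is known: truly common variants in populations that are poorly
  represented in the reference databases will be misclassified pathogenic.
  That is also why tree induction here restricts the root to SPP and
  NDamage, keeping the frequency variables out of the first level.
* **Missing damage calls lower the NDamage count** rather than rescaling
  the cutoff; the rule is simpler and monotone (an added pathogenic call
  can never flip the flag 1 to 0).
* **Predictor-call encodings** follow dbNSFP conventions (SIFT `D`/`T`,
  PolyPhen `D`/`P`/`B` with "possibly damaging" counted pathogenic, PROVEAN
  `D`/`N`) and are configurable through the field map, since annotation
  pipelines differ. PolyPhen's middle category is debatable; counting it
  pathogenic is the conservative choice for a consensus whose job is to
  never miss a damaging call at the root.
* **Clinical-significance harmonization** treats numeric codes as
  authoritative (2/3 neutral, 4/5 pathogenic) with textual synonyms mapped
  to codes first. Multi-valued fields must be homogeneous; any mixture or
  unknown token is `unlabeled` and excluded from training — conservative
  label hygiene at the cost of set size.
* **Amino-acid class sets** for the biochemical features are the standard
  partitions (charged D/E/K/R/H; hydrophobic A/V/L/I/M/F/W/C), configurable
  in the registry.

## Greedy induction and the exhaustive oracle

`build_greedy()` grows the chain level by level: each remaining candidate is
appended provisionally, the accuracy of the provisional chain on the scoring
set is computed, and the maximizer is kept if it strictly improves on the
current chain. Scoring uses the whole training set by default (an optional
validation set can drive it instead); the trace additionally records each
candidate's accuracy restricted to the variants surviving the previous
levels, which is the quantity a per-level reading of the chain suggests.
Ties break lexicographically, and depth defaults to four.

`exhaustive_best()` is the oracle: it enumerates every root-restricted chain
up to the requested depth and ranks by exact correct-classification counts.
Because all full-depth chains over the same feature set classify
identically, final accuracy cannot rank the permutations; the ranking
therefore continues with prefix accuracies level by level (mirroring the
greedy builder's objective), then prefers shorter chains, then
lexicographic names. On data where each level strictly improves accuracy,
greedy and exhaustive agree; the suite checks both that agreement and the
general inequality (greedy never beats exhaustive).

## Evaluation protocol

`confusion()` uses the domain cell names (True/False Neutral,
False/True Pathogenic). `metrics()` reports accuracy and the
class-conditional rates — within true neutrals, the fraction predicted
neutral vs. pathogenic, and the analogous pair within true pathogenics; each
pair sums to 1. A second set of fields (`paper_formula_*`) reports
prediction-conditioned ratios (e.g. sensitivity = TN/(TN+FN)) that some
benchmark write-ups quote; the two normalizations disagree whenever classes
are imbalanced, so both are exposed and the class-conditional rates are
treated as primary. Zero-denominator ratios are `NA`, never 0.

* **Cross-validation** (`kfold_cv()`) splits each class separately into *k*
  seeded folds (sizes within one of each other) and tests on one neutral
  fold plus one pathogenic fold per iteration. With a builder classifier
  the chain is re-induced on the training folds each time; with a fixed
  topology only the evaluation varies.
* **Monte Carlo** (`monte_carlo()`) draws, per replicate, an unstratified
  30% subsample *without* replacement (a bootstrap mode is available behind
  `replace = TRUE`) from a set classified once with the fixed chain, and
  summarizes each metric by mean and standard deviation. The standard
  deviation uses the population formula (denominator *n*) by default,
  configurable to the sample formula.
* **Association and complementarity**: `phi_coefficient()` computes the
  2x2-table correlation of two binary variables (identical to the Pearson
  correlation of the indicators, which is how the tests cross-check it);
  `pairwise_distribution()` gives, per true class, the percentage of
  variants in each value combination of a feature pair — the off-diagonal
  cells are exactly the share of variants one feature rescues from the
  other's misclassification.
* **Per-level reports** (`level_report()`) classify with every prefix of
  the chain and report accuracy, false-pathogenic rate among true neutrals
  and false-neutral rate among true pathogenics, in percent. Along any
  chain the pathogenic set shrinks monotonically, so the false-pathogenic
  rate is non-increasing and the false-neutral rate non-decreasing with
  depth — a property the suite asserts on randomized datasets.

All seeded operations consume a single user-supplied seed and restore the
caller's RNG state (`local_rng()`).

## The synthetic-data generator

`generate_variants()` emulates a labeled, annotated call set: each variant's
class is drawn from the pathogenic prevalence, then every annotation is
drawn independently from a class-conditional distribution — per-predictor
pathogenic-call probabilities for the consensus and damage predictors, and
a two-part mixture for each population frequency (a probability of being
catalogued at all, and a log-uniform allele-frequency law when catalogued).
Missingness is controllable per field. Log-uniform frequency laws make the
binary feature rates exact analytic functions of the configuration, which
is what `expected_confusion()` exploits: under class-conditional
independence the probability of surviving the whole chain is the product of
the per-level feature rates, giving closed-form expected confusion rates
that the simulated pipeline must reproduce within Monte Carlo error. This
closed-form-vs-simulation agreement is the module's central oracle and runs
in the suite over randomized configurations at n = 200,000.

What the generator does *not* emulate: correlated annotations (real ExAC
and COMMON frequencies are strongly associated; an optional coupling
parameter links their catalogued status for sensitivity experiments, and
the analytic oracle refuses configurations where the coupling would break
the product form), realistic genomic positions or sequence context, and the
marginal distributions of any real clinical database. Passing tests on
synthetic data therefore demonstrate the correctness of the machinery — the
discretization contracts, the chain algebra, the induction procedure, the
evaluation estimators — not clinical performance on real call sets.

Two presets ship with the package:

* `clinvar_like` — class-conditional feature-1 rates
  (SPP .99/.60, ExAC .975/.45, NDamage .965/.55, COMMON .988/.60 for
  pathogenic/neutral) at pathogenic prevalence 0.573 and n = 31,389,
  giving expected per-class correct rates of 92.0% (pathogenic) and 91.1%
  (neutral). The rates were tuned once so that the proposed chain lands
  near the familiar ~90%-per-class operating point of published
  ClinVar-trained comparisons; it is a demonstration preset, not a
  reproduction of any external dataset.
* `ordered_separability` — strictly ordered marginal separabilities with
  every level strictly improving chain accuracy (balanced classes,
  n = 20,000), constructed so that greedy induction provably recovers the
  planted SPP-ExAC-NDamage-COMMON chain; the decision margins are at least
  about one accuracy point, an order of magnitude above sampling noise at
  that n, so recovery is stable across seeds.

Preset parameters are solved, not hand-set: consensus-predictor
probabilities invert the at-least-one rule, damage-predictor probabilities
invert the binomial tail at the cutoff, and frequency mixtures are solved in
log space so the `1e-4` threshold induces the target rates exactly.

## Problem sizes and numerical choices

The test suite exercises exhaustive oracles at small scale (all topologies
up to five features against the conjunction rule; the full 20x20 amino-acid
table), stochastic checks at moderate scale (planted-chain recovery across
20 seeds at n = 20,000; closed-form-vs-simulation agreement for 10 random
configurations at n = 200,000; 1,000-replicate Monte Carlo runs), all with
fixed seeds. Accuracy comparisons inside the builder and the exhaustive
oracle use integer correct-counts, so ties are exact rather than
floating-point artifacts. Statistical agreement tests use three-standard-
error bands (binomial errors for rates, replicate standard errors for
resampling means).

## Known limitations

* The chain is strictly binary with no scores; there is no ranking within
  the pathogenic set and no AUROC-style evaluation.
* Branching trees are out of scope: every neutral branch terminates by
  construction.
* The package consumes annotations; it does not run annotation pipelines or
  recompute predictor scores, and multi-allelic splitting is the only
  variant normalization performed.
* Real-data performance depends on annotation completeness: the
  missing-frequency convention biases toward pathogenic calls in
  under-sequenced populations, which is precisely why frequency variables
  are kept away from the root.
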