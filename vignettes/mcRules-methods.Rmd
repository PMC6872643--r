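---
title: "Monte Carlo feature selection and rule-based phylum classification: methods"
author: "mcRules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo feature selection and rule-based phylum classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcRules)
```

## The problem

Gut bacterial strains can be described by functional-annotation count
profiles: for each strain, how many annotated genes it carries per feature
from antibiotic-resistance databases (ARDB, CARD), a virulence-factor
database (VFDB) and KEGG pathway categories. The question mcRules addresses
is *interpretable* multi-class classification: which few annotation features
separate the major phyla (in the motivating data, Actinobacteria,
Bacteroidetes and Firmicutes, with censuses of roughly 235/447/796 after
dropping phyla with fewer than 100 strains), and what explicit threshold
rules on those features assign a strain to its phylum?

The workflow has four stages, each exposed as package functions and chained
by `runPipeline()`:

1. **Feature ranking** by Monte Carlo feature selection (MCFS).
2. **Incremental feature selection (IFS)**: scan nested top-$k$ subsets and
   pick the $k$ maximizing cross-validated multi-class MCC.
3. **Rule learning**: a RIPPER-family ordered rule list on the optimum
   subset.
4. **Validation**: compare the selected subset against random same-size
   subsets.

## Monte Carlo feature selection

`rankFeatures()` grows $t \times m$ information-gain decision trees: $m$
random feature subsets ("projections") of size $d$, each combined with $t$
stratified train/test splits. Each feature $g$ accumulates the relative
importance score

$$
\mathrm{RI}_g \;=\; \sum_{\tau = 1}^{t\,m} (\mathrm{wAcc}_\tau)^u
\sum_{n_g(\tau)} \mathrm{IG}\big(n_g(\tau)\big)\,
\Big(\frac{\text{no. in } n_g(\tau)}{\text{no. in } \tau}\Big)^{v},
$$

summing over every node $n_g(\tau)$ split on $g$: the node's information
gain, weighted by the fraction of the tree's training samples reaching the
node (exponent $v$) and by the tree's weighted accuracy on its held-out
split (exponent $u$). Both exponents default to 1. Features are ranked by
decreasing RI; only features with RI strictly greater than zero — features
that carried split information in at least one tree — are retained for the
downstream scan.

Choices that the score leaves open, fixed as follows:

* **Entropy/IG**: Shannon entropy with log base 2; information gain is the
  plain entropy reduction. Splits are binary, thresholds at midpoints
  between consecutive distinct observed values, "$\le$ goes left".
* **wAcc** is the unweighted mean of per-class recalls on the tree's test
  split (classes absent from the split are skipped), so rare classes weigh
  as much as common ones — the same reason multi-class MCC is the key
  selection measurement below.
* **Trees are not pruned**; stopping is purity, zero best gain, a minimum
  leaf size (default 2) and an optional depth cap. Tie-breaks (lowest
  feature index, then lowest threshold) make every tree deterministic.
* **"Bootstrap" splits** are stratified subsampling *without* replacement at
  `trainFraction` (default 0.66), the customary MCFS choice; a
  with-replacement mode sits behind `replace = TRUE`.
* **Defaults** `m = 2000`, `t = 5`, and `d = max(ceil(sqrt(p)),
  ceil(0.05 p))` are of the magnitude the MCFS literature uses and are fully
  config-exposed; the original description counts "$s$ bootstrap sets" but
  "$t \times m$ trees" — we follow the tree count and treat $s \equiv t$.

The C++ tree builder has a counting-bucket path for small integer counts
(the annotation-table case) and a generic sort path for arbitrary numeric
features; both produce identical splits.

## Incremental feature selection

`runIFS()` evaluates the rule learner on the top-$k$ columns for $k = 1,
\dots, k_\max$ (step 1) under stratified 10-fold cross-validation. The fold
assignment is a pure function of the labels and the seed and is **shared
across all $k$**, so the per-$k$ curve is not blurred by fold resampling
noise. The optimum is the $k$ maximizing multi-class MCC; exact ties resolve
to the smallest $k$ (parsimony — consistent with preferring compact,
reportable subsets). `kMax` defaults to the RI > 0 retained count.

## Rule learning

`learnRuleSet()` induces an ordered list of conjunctive threshold rules in
the RIPPER/JRip tradition; mcRules implements the learner itself and matches
that family's semantics rather than any particular binary:

* Classes are processed smallest-first (ties by name); the largest class
  becomes the default "others" class and gets no rules.
* Per class, sequential covering: split the remaining data 2:1 (stratified)
  into grow and prune sets; grow a rule by greedily adding the
  `feature >= t` / `feature <= t` condition maximizing FOIL information
  gain over observed thresholds; prune it by deleting trailing conditions
  while the metric $(p - n)/(p + n)$ on the prune set does not decrease
  (shortest rule among equals); accept unless it newly covers fewer than
  `minCovered = 2` positives, errs on more than half of its held-out
  coverage, or pushes the class's description length more than 64 bits above
  the best seen. Covered samples are removed and the loop repeats.
* **Description length** is our own formulation of the usual MDL
  bookkeeping: per-rule theory bits
  $\tfrac12(\log_2(k{+}1) + k\,\log_2(n_{\text{cand}}{+}1))$ over the
  candidate-condition alphabet, plus binomial-coded exceptions (false
  positives among covered rows, false negatives among uncovered rows). It is
  monotone in both rule complexity and errors, which is all the 64-bit
  surplus stop needs; no attempt is made to replicate another
  implementation's bit-level accounting.
* **Optimization passes** (default 2) revisit each rule with a replacement
  (regrown from scratch) and a revision (extended, then re-pruned) variant,
  keeping whichever minimizes the class's total description length, then mop
  up uncovered positives. Rules that no longer newly cover `minCovered`
  positives are dropped.

Prediction is first-match in rule order with the default class as fallback.
Rule sets serialize to JSON and to a human-readable text form
(`(feature >= 1) and (feature <= 0) => Class`, final line
`others => Class`); `parseRuleText()` reads that form back, including the
spaced `"> ="` spelling printed rule tables sometimes use, so published
rule tables can be loaded and applied directly.

## Performance measurement

`performanceReport()` derives from the confusion matrix: per-class accuracy
(= recall), precision and one-vs-rest binary MCC; overall accuracy; and the
multi-class (K-category) Matthews correlation

$$
R_K = \frac{N\,\mathrm{tr}(C) - \sum_k r_k c_k}
{\sqrt{(N^2 - \sum_k r_k^2)(N^2 - \sum_k c_k^2)}},
$$

which is the package's key measurement because the class censuses are
strongly imbalanced. Degenerate ratios (0/0 precision, zero MCC
denominator) are defined as 0 so cross-validation folds always produce a
finite report; for $K = 2$ the statistic coincides with the classical
binary MCC (verified exhaustively in the tests).

## The synthetic-data generator

No deposited strain table ships with the package, so `generateTable()`
produces tables with the statistical shape the workflow assumes, plus known
ground truth. The default spec is study-shaped: censuses 235/447/796,
993 features carrying ARDB/CARD/KEGG/VFDB-proportioned name prefixes
(342/259/243/149), background sparsity `noiseRate = 0.05` with geometric
nonzero counts (`1 + Geom(0.5)`), no label noise, and 25 planted
single-condition rules — 12 "subtype indicators" for the smallest class, 13
for the middle one, largest class as default. Each non-default sample is
assigned one subtype of its class (a balanced shuffled partition, so every
planted feature carries comparable signal) and gets that rule's features
raised to their thresholds; all other planted columns stay 0. Labels
therefore agree exactly with the generating rule set before label noise,
which is applied last so that two specs differing only in `labelNoise`
share the identical values matrix.

This construction makes all planted features *jointly* necessary: a
classifier needs every subtype indicator to recover a class completely, so
the IFS curve keeps rising until roughly the planted count and the optimum
lands near it — the regime in which feature selection is actually
interesting. What the generator deliberately does **not** model:
phylogenetic correlation between strains, correlated background features,
database-specific count distributions, or signal spread over correlated
feature groups. Passing recovery tests on these tables therefore
demonstrates the machinery (ranking finds threshold signal, the rule
learner reconstructs threshold rules, the significance test separates
signal from chance) — not that real annotation tables are this easy.

Generator guards: planted thresholds must be $\ge 1$ (otherwise the default
class would be unreachable), a feature may drive only one rule (rules out
contradictory generating rules), and generated labels are re-checked
against the ground-truth rule set — any mismatch aborts generation.

## Numerical and degenerate-input choices

* Strict `> 1e-12` improvement for split/condition tie-breaking, so scan
  order (lowest feature, `>=` before `<=`, lowest threshold) decides ties
  deterministically.
* `filterMinClassSize()` reads "at least `minN`" (default 100) and errors
  if fewer than two classes survive.
* Stratified folds require every class to hold at least `cvFolds` samples;
  MCFS splits require two samples per class.
* The empirical p-value of `randomSubsetTest()` uses the add-one rule
  $(1 + \#\{\text{null} \ge \text{top}\})/(n_{\text{random}} + 1)$, so it
  is never exactly zero; ties count against the top subset.
* All randomness flows from explicit integer seeds; `withSeed()` restores
  the caller's RNG state, and the pipeline derives one sub-seed per stage
  from the global seed by hashing the stage name (`deriveSeed()`), keeping
  every derived seed below $2^{31}$.

## Problem sizes used by the shipped checks

The package's own test suite and the `scripts/acceptance.R` summary run on
generated tables at sizes chosen to exercise the full workflow at desk
scale: the study-shaped 1478-strain, 993-feature table with a reduced
ensemble (`m = 300`, `t = 3`, about 900 trees), IFS scans to $k = 80$, and
100 random subsets in the significance test; smaller tables (tens of
samples, tens of features) drive the exhaustive-oracle and property checks.
These are the package's default demonstration sizes, not statements about
what the method needs; for real analyses the MCFS defaults (`m = 2000`,
`t = 5`) and `nRandom = 1000` are recommended.

## Known limitations

* The rule learner matches RIPPER *semantics*; exact rule-for-rule equality
  with other implementations is out of scope (different MDL accounting and
  split randomness legitimately change learned lists on hard data).
* The IFS loop supports only the package's own rule learner, by design.
* Features are numeric counts; nominal conditions and missing values are
  unsupported.
* The random-subset test is purely empirical; no analytic null is provided.
* Sampling-pool choice for the null (all features vs RI > 0 retained) is
  exposed as `pool = c("all", "retained")`, defaulting to all features,
  since a "randomly produced subset" with no stated restriction most
  naturally means the full feature space.
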