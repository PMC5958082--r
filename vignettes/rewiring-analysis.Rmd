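---
title: "Methods: transcriptional rewiring across treatment phenotypes"
author: "rewiremir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transcriptional rewiring across treatment phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rewiremir)
```

This vignette is the package's own account of the models and procedures
it implements, the choices made where a design was genuinely open, and
what the synthetic-data validation does and does not establish.

## Study design and data model

The pipeline analyses log2-scale expression matrices (features ×
samples; RMA-style array summaries or any comparable log2 quantity) for
mRNA and miRNA, with each sample assigned one of four phenotypes: HC
(healthy control), ADU (active disease, untreated), ADT (active disease
on therapy) and ID (inactive disease on therapy). HC is always the
reference; the three patient phenotypes define the three contrasts.
Probe sets mapping to one gene are collapsed by the arithmetic mean of
their log2 values within each sample (`collapse_features()`); the
probe-to-gene map is a required user input, since no annotation release
is bundled.

Readers reject rather than coerce malformed input (missing cells,
ragged rows, duplicate identifiers), and every writer round-trips
losslessly with its reader. Expression values are assumed to be log2
already; `linear_input = TRUE` applies `log2()` and treats non-positive
intensities as an error rather than guessing an offset.

## Differential expression and the rank-based q-value

Each feature is tested case-vs-HC with a two-sample t-test. The package
defaults to Welch's unequal-variance form because group variances in
clinical cohorts are rarely equal and Welch costs essentially nothing
when they are; `equal_var = TRUE` gives the pooled Student form for
users who want the classical test. A feature whose two groups both have
zero variance carries no evidence; it gets `t = 0`, `p = 1` and a
warning rather than an error, so a single degenerate row cannot abort a
run.

Multiple testing uses the rank-based q-value
\[ q_i = \frac{N\,p_i}{R_i}, \]
with \(N\) the number of features tested in that contrast and \(R_i\)
the ascending rank of \(p_i\). Two refinements make this well behaved:

* **Ties** share the maximum rank of their group, so equal p-values get
  equal q-values.
* **Monotonization** (on by default) replaces each raw value by the
  minimum raw value at its rank or any larger rank (the step-up rule),
  after which the q-values are exactly the Benjamini–Hochberg adjusted
  p-values — the test suite asserts equality with `p.adjust(method =
  "BH")` to 1e-12. The literal, unmonotonized formula remains available
  (`monotonize = FALSE`) because the raw ratio is occasionally wanted
  for comparison; it is clipped to 1 but can be non-monotone in p.

Each contrast is corrected independently with its own \(N\), so DEG
counts are per-comparison quantities. Significance is `q <= 0.05`
(inclusive). Direction is the sign of `log2fc = mean(case) −
mean(control)`; an exact zero — a measure-zero event on real data — is
assigned `U` by convention and logged.

```{r qvalue-example}
compute_qvalues(c(0.01, 0.02, 0.03, 0.04, 0.05))
```

## Overlap statistics

Overlap significance between two DEG lists is the exact upper tail
\(P(X \ge k)\) of the hypergeometric distribution, computed by direct
summation of the mass function. The universe defaults to the number of
features tested in the differential-expression step — the same \(N\) as
in the q-value — because that is the population both lists were drawn
from; it is overridable (`universe_override`) since overlap p-values
are extremely sensitive to the universe, and published overlap
p-values generally cannot be reproduced without knowing it. Unique
fractions are reported in both directions of each pair because summary
sentences in the literature alternate between denominators.

## Direction-pattern clustering

All genes significant in at least one patient phenotype (the union
DEGs) are assigned a 3-letter pattern over (ADU, ADT, ID) from the
*signs of their fold changes*, whether or not the gene is significant
in each individual phenotype — a full trajectory label requires all
three letters, and requiring per-phenotype significance would leave
most union genes unlabelled. The 8 patterns partition into three
groups: same-direction (`UUU`, `DDD`), sign flip at ID (`UUD`, `DDU`;
late response to therapy) and sign flip at ADT or other (`UDD`, `DUU`,
`UDU`, `DUD`; early response).

Within `UUU`/`DDD`, genes whose absolute log2 fold change in ID is
*strictly* smaller than in ADU form the attenuation sub-clusters
`UUu`/`DDd` — expression drifting back toward the healthy level, the
natural candidates for therapy-relevant genes. The comparison uses
absolute log2 fold changes (equivalently linear fold-change magnitude,
since log2 is monotone) and is strict so that a gene with identical
effects is not called attenuated. Enrichment downstream keys clusters
by sub-pattern, so `UUu` and the unattenuated `UUU` remainder are
tested separately.

## Regulator enrichment

For each (cluster, target set) pair the package runs a one-sided
(greater) Fisher exact test on the 2×2 table \([[k, m-k], [K-k,
N-m-K+k]]\); the p-value is the exact hypergeometric upper tail. The
background universe is all genes tested on the array after collapsing —
the most defensible background when target sets are defined over the
whole transcriptome — with an override available. Target-set members
absent from the universe are dropped (and logged) before testing.
Deliberately, *no multiple-testing correction* is applied at this
stage and the threshold is an uncorrected `p < 0.01` (strict
inequality): this screen exists to nominate regulators for network
construction, and its calibration is instead verified empirically on
decoy sets (below).

## miRNA consistency and qPCR validation

A miRNA that regulates a cluster should move opposite to it. For each
phenotype the opposition flag compares the sign of the miRNA's fold
change to the cluster letter; `all_opposite` needs all three,
`treated_opposite` needs ADT and ID only (the signature of a
therapy-induced regulator), everything else is `inconsistent`. A zero
miRNA fold change never counts as opposite.

qPCR fold changes use the ΔΔCt model with exponent 2 (amplification
efficiency ≈ 100% is assumed; efficiency correction is out of scope):
per-sample \( \Delta Ct = Ct_{target} - Ct_{reference}\), group means,
\( \Delta\Delta Ct = \overline{\Delta Ct}_{case} -
\overline{\Delta Ct}_{HC}\), fold change \(2^{-\Delta\Delta Ct}\).
Group-averaging per-sample ΔCt (rather than differencing group-average
Ct values) is equivalent for balanced designs and more robust
otherwise. Cross-platform "similar expression change" is
operationalized as sign agreement between the array log2 fold change
and \(\log_2\) of the qPCR fold change; no magnitude criterion is
imposed because none is standard.

## Co-regulatory networks

Per cluster, enriched regulators are joined to their in-cluster target
genes; miRNAs of one functional family (shared seed / target
repertoire, encoded in the GMT description field as `family=<id>`) are
collapsed to the member with the smallest enrichment p (ties:
lexicographically first). Protein–protein interaction edges are
restricted to pairs inside the cluster's gene set, keeping networks
cluster-scoped; `expand_ppi = TRUE` retains boundary edges and their
outside endpoints for users who want first neighbors. Gene nodes with
neither a regulator edge nor a PPI edge are omitted, and a regulator
whose target set misses the cluster entirely is dropped with a warning
rather than violating the every-regulator-has-targets invariant.
Networks are validated structurally on construction (typed edges only
between permitted node types, no loops or duplicates) and exported as
SIF (tab-delimited, so identifiers may contain spaces) or GraphML with
`node_type`/`edge_type` attributes; both round-trip through
`read_network()` with identical node and edge multisets.

## The synthetic-data generator

`sim_config()` defines the simulated study; its defaults are the
conditions under which the package validates itself:

* **Cohort**: 43 HC, 35 ADU, 26 ADT and 14 ID samples — a realistic
  cross-sectional treatment-response cohort, deliberately unbalanced
  the way clinical collections are.
* **Scale and noise**: 4000 genes, 400 miRNAs, baseline 8 log2 units,
  additive Gaussian noise with SD 0.8 on the log2 scale — the standard
  noise model for RMA-type summaries; no published variance estimates
  exist for the motivating cohorts, so this is a convention, chosen
  once.
* **Effects**: 40% of genes perturbed, with the within-DEG pattern mix
  following the census structure reported for treated-JIA neutrophils
  (same-direction clusters ≈ 45% each, late-flip a few percent,
  early-flip below 1%). Effect magnitude is 1.5 log2 units in ADU/ADT;
  same-direction patterns get an attenuated 0.75 in ID so that
  `UUu`/`DDd` sub-clusters exist in truth.
* **Regulators**: 5 planted miRNAs (carrying the letter-wise opposite
  direction triple of their planted cluster) and 5 planted TFs, each
  with a 50-gene target set drawn 80% from the planted cluster, plus
  20 uniform decoy sets per kind.
* **qPCR**: an 8 + 8 ADT/HC validation cohort, Ct noise SD 0.2, with a
  zero-effect reference feature; planting an effect on the reference is
  rejected as a contract violation.

Planted nulls are exactly zero-effect so that false-discovery
calibration is interpretable. Seeds are explicit in the config, all
randomness is scoped locally (the caller's RNG stream is untouched),
and identical configs give byte-identical outputs.

What the generator does *not* emulate: batch effects, probe-level
artifacts, correlated noise between genes, mechanistic
miRNA-knockdown kinetics (anti-correlated miRNAs are planted at the
phenotype-mean level only), and dropout. Passing tests therefore
demonstrate that the statistical machinery recovers planted structure
under idealized array-like noise — not that it is robust to every
failure mode of real arrays.

## Validation strategy and problem sizes

The test suite checks each operation against an independent route:
`stats::t.test` row by row, `p.adjust(method = "BH")`,
`stats::fisher.test` and brute-force enumeration of all draws on small
universes, per-element membership tabulation for Venn regions, and
closed forms for ΔΔCt. Calibration and power use planted-truth
simulation at deliberately modest sizes, chosen to keep the default
suite fast while leaving Monte-Carlo error well inside the asserted
margins:

* null FDR: 200 all-null datasets of 1000 features, n = 10/group;
* pattern recovery: exactness at zero noise, and 20 seeds at noise 0.5,
  |Δ| = 1.5, n = 20/group against a ≥ 90% bound (the expected
  per-letter error there is ~\(\Phi(-1.5/0.158) \approx 10^{-21}\), so
  the bound is loose by construction);
* enrichment: 1000 decoy sets against the discrete null's attainable
  level, and 100 seeds of 5 planted regulators at bias 0.8 — the power
  run uses a pattern mix concentrated on four well-populated clusters,
  because a regulator planted into a near-empty cluster (e.g. a 0.15%
  pattern in a 2000-gene simulation) has no targets to be enriched in,
  which would measure the generator's sparsity, not the test's power.

`scripts/acceptance.R` re-runs the same measurements from scratch under
a caller-supplied seed and writes them as JSON, alongside worked
set-arithmetic examples computed from published per-phenotype list
sizes (439/1976/112 genes, 8/83/14 miRNAs and their printed overlaps),
which exercise the overlap/census code paths at the printed precision.

## Known limitations

* The q-value formula is BH in disguise only after monotonization;
  literal mode can rank features differently near ties and is kept for
  comparability, not recommended for inference.
* Overlap p-values depend strongly on the universe size; without the
  original universe, published overlap p-values can only be matched in
  form, not value.
* Enrichment results inherit the target-set database: counts of
  enriched regulators are database-version-dependent and not
  comparable across annotation releases.
* The screen at uncorrected p < 0.01 trades specificity for sensitivity
  by design; downstream networks should be read as hypotheses.
* Sub-cluster attenuation compares ID to ADU only; a gene rising in ADT
  and falling back by ID is not specially flagged.
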