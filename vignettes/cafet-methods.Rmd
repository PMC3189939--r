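---
title: "Sample-axis pathway enrichment: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-axis pathway enrichment: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafet)
```

## The two axes of enrichment

Given a probe-by-sample intensity matrix, a two-group partition of the
samples and a collection of functional gene sets, there are two natural
2×2-table questions:

* **Gene axis (FGA).** Are differentially expressed genes
  over-represented in the set? Counts: `N_T` genes on the (filtered) array,
  `N_F` of them in the set, `N_G` in the query list, `N_C` in both.
* **Sample axis (CAFET).** Are samples that *carry the set's signature*
  over-represented in Group 1? A sample carries the signature when at least
  one member gene is dysregulated in it. Counts: `S_T` samples, `S_G` in
  Group 1, `S_FP` carrying the signature, `S_FC` carrying it and in Group 1.

Both use the same kernel, the inclusive one-sided hypergeometric upper tail
`P(X >= observed)` — the one-sided Fisher exact p-value — implemented in log
space with `lchoose()` because the binomial coefficients at cohort scale
(e.g. `C(138, 90)`) overflow naive factorials. The tail is *inclusive*: at
the boundary where every Group 1 sample is covered, it collapses to a single
term rather than zero.

The gene-axis test is powerful when many members shift coherently; its power
collapses when each case sample dysregulates a *different* single member,
because no gene then changes enough on average to enter the query list. The
sample-axis union `S_FP` is designed exactly for that regime: one member per
sample suffices. Statistical power follows the number of observations on the
tested axis, so the sample-axis test wants large cohorts and tolerates small
pathways, and is *not* appropriate for small sample sizes.

## Dysregulation flags

The per-(gene, sample) dysregulation event is defined on the **linear**
scale against a robust per-probe baseline:

* baseline = the probe's median across all samples (default), or
  optionally its mean across Group 2 samples;
* a sample is flagged **up** when any probe of the gene exceeds
  `up_fold = 2.5` × baseline (strict inequality);
* flagged **down** when any probe falls below `down_fold = 0.5` × baseline.

The thresholds are deliberately asymmetric: additive background intensity
compresses fold changes downward, so an equally strict down threshold would
flag almost nothing. Both are exposed as parameters. The any-probe union is
used at two levels: across probes of one gene, and across member genes of a
pathway. A probe whose baseline is zero can never flag down and flags up for
any positive value; such probes are reported and the caller may wish to
filter them out beforehand.

The median baseline is group-agnostic and is the canonical mode; the
Group 2-mean baseline is kept as an option because it is sometimes
convenient to express coverage "relative to controls", at the cost of tying
the flags to the grouping. Note an important geometric consequence of the
median baseline: a single gene up-flagged in a *majority* of samples is
impossible (its median moves with it), so coverage above 50 % necessarily
arises as a union across members — which is precisely the object the group
test evaluates.

## Multiple testing and eligibility

Benjamini–Hochberg step-up is applied with `m` equal to the number of tests
actually performed in the batch:

* group-level: only *eligible* sets — at least `min_contributing_genes = 5`
  members with one or more flagged samples — enter the adjustment;
  ineligible sets keep their p-value with `fdr = NA`;
* gene-level: within the supplied gene list, separately per direction
  (up and down are independent batches and are reported as separate panels);
* differential expression: across all tested probes.

Filtered-out items never inflate `m`. The adjustment itself delegates to
`stats::p.adjust(method = "BH")`; the test suite checks it against an
independently hand-coded step-up.

## Differential expression and clustering

The probe-level test is a Welch (unequal-variance) two-sample *t*-test on
`log2(intensity + 1)`; the fold-change gate is the ratio of the *linear*
group means (strictly greater than `fold_threshold = 2.5`), and a probe is
called DE only when both the BH-adjusted p (`< 0.05`) and the fold gate
pass. A gene is DE when at least one of its probes is, with the passing
probe's sign giving the direction; a gene with probes passing in both
directions appears in both lists, which we consider the honest reading of
the any-probe rule. Degenerate probes (zero variance in both groups) get
`p = 1` at equal means and `p = 0` (flagged) at unequal means, keeping the
decision rule continuous on toy fixtures. Welch on log intensities was
chosen as the robust default for two-group microarray comparisons; no
moderated-variance (eBayes-style) shrinkage is attempted.

Samples are clustered with average linkage (UPGMA) on Euclidean distances
between sample columns of the probe-filtered, log2-transformed matrix — the
transform is always an explicit step, never implicit. The two primary groups
are the two subtrees below the root. Which one is "Group 1" is a labeling
choice, so the cut takes an optional anchor (a sample id, or a class label
with a label map) and otherwise names the smaller subtree Group 1 with a
lexicographic tie-break — deterministic and caller-controllable. An optional
top-k-variance probe selection is available but off by default, since the
full filtered matrix is the canonical input.

## Signature scores

For validating a signature on an independent cohort, each gene's probes are
averaged on the log2 scale and the gene row is standardized across samples
(z-score with the `n − 1` standard deviation; "standardization" admits both
conventions and the sample-sd one is fixed here). The score of a sample is
the sum of z-values over up-genes minus the sum over down-genes. Zero
variance genes contribute zero; absent genes are dropped with a warning
rather than imputed. Scores are invariant to positive rescaling of any
gene's raw intensities and sum to zero across samples whenever no gene hit
the zero-variance rule.

## The synthetic cohort generator

`generate_cohort()` emulates just the marginal structure the method's
decision rules depend on: positive, right-skewed intensities with a
well-defined per-probe median. Cells are drawn i.i.d. as
`2^Normal(mean = 8, sd = 0.5)` (log-normal), with 1000 single-probe genes
and 100 samples split 50/50 by default, and a 20-gene pathway planted at
4-fold. Two planted regimes mirror the method's motivating contrast:

* **concentrated** — every planted gene is scaled in every Group 1 sample
  (both axes should detect it);
* **distributed** — each Group 1 sample scales exactly *one* planted gene,
  assigned round-robin (the strongest form of the single-member argument:
  the sample axis should detect it, the gene axis should not).

The collection bundles the planted set with decoy sets of matched size drawn
from non-planted genes (20 by default; the null-calibration studies use
100). The generator does **not** emulate inter-gene correlation, batch or
probe-level artifacts, or array normalization differences — so passing tests
demonstrate the statistical contrast under the assumed marginals, not
robustness to real-array systematics. All draws run under `withr::with_seed`,
so cohorts are bit-reproducible and the caller's RNG stream is untouched.

At these defaults the distributed regime flags each case sample through its
own planted gene with high probability (the 4-fold scaling must beat the
2.5-fold threshold against log-normal noise), giving `S_FC` near the Group 1
size while decoys stay at background coverage; and because only two or three
case samples share any one planted gene, group-mean fold changes stay far
below the DE gate.

## Numerical and interface choices

* Tail computation: log-space sum with a max-shift (log-sum-exp), clamped to
  `[0, 1]`; validated against exact `choose()` ratios over every valid query
  with population ≤ 25 and against full draw enumeration on small cases.
* Result tables are tibbles ordered by ascending p with lexicographic id
  tie-breaks, so written outputs are byte-deterministic.
* Genes are matched by exact, case-sensitive symbol; no alias resolution.
  Probe-to-gene mapping must be supplied (inline `gene` column or a
  two-column map); nothing is guessed from probe names.
* Gene-set inputs: standard GMT; the NCBI gene2go dialect (rows whose
  qualifier contains `NOT` are negated annotations and are excluded; no
  ontology-graph propagation is applied); and a deliberately flat
  `pathway_id TAB gene` KEGG dialect, keeping the package self-contained
  rather than parsing KGML.
* Intensities must arrive linear-scale and non-negative; the probe filter
  keeps probes whose maximum is `>=` the threshold (default 100).

## Problem sizes used in the test suite

The statistical property checks run at sizes chosen to make the contrasts
decisive yet quick on one CPU: the two-regime contrast uses 50 seeds per
regime at generator defaults, null calibration pools 20 seeds × 100 decoy
sets, the exhaustive tail sweep covers all populations up to 25, and the BH
property loop draws 1000 random vectors. The published-count checks are
closed-form and instantaneous.

## Known limitations

* The sample-axis test needs sizable cohorts; with few samples the
  hypergeometric support is too coarse for meaningful tails.
* Flags are marginal per gene: correlated dysregulation inside a pathway is
  treated the same as independent coverage, which makes decoy unions built
  from correlated genes anti-conservative in ways the i.i.d. generator
  cannot reveal.
* The discreteness of the hypergeometric makes the null conservative
  (p-values super-uniform); calibration checks assert conservativeness, not
  exact uniformity.
* Direction batches are independent; no combined up/down group test is
  offered.
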