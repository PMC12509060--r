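---
title: "Dissecting genotype-by-environment effects on gene regulatory networks"
author: "gxenet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting genotype-by-environment effects on gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxenet)
```

## The scientific question

Two inbred genotypes (coded 0 = Bd21, 1 = Bd3-1) are grown under two
watering treatments (0 = control, 1 = drought), with deep biological
replication (around 48 RNA-seq libraries per genotype-by-treatment
combination, called a *library type*). The interesting biology is not only
which genes change expression, but whether the *relationships between
genes* — coexpression modules and directed regulatory interactions — are
themselves reshaped by genotype (G), environment (E), or their interaction
(G×E). `gxenet` implements that analysis end to end:

1. **Per-gene level.** RLE (median-of-ratios) normalization, the
   `log2(count + 1)` transform, expression and replicate-variance filters,
   and per-gene linear models with genotype, treatment and interaction
   terms, each FDR-controlled within its coefficient family.
2. **Module level.** An unsigned weighted coexpression network per library
   type (soft power 5), topological overlap, adaptive dynamic branch cut
   into modules, eigengenes, and an exact multi-set intersection test of
   module-membership preservation across library types. Connected groups
   of mutually overlapping modules ("cliques") are classified as
   conserved, genotype-specific, environment-specific or G×E-specific.
3. **Edge level.** Within a module, a directed acyclic graph is estimated
   by interventional greedy sparsest-permutation search with stability
   selection; every retained regulator→target edge is then tested for
   G/E/G×E effects on its slope and intercept with the regression
   $$y = \gamma_0 + \gamma_g g + \gamma_e e + \gamma_{ge} ge +
     \sum_i (\beta_{0,i} + \beta_{g,i} g + \beta_{e,i} e +
     \beta_{ge,i} ge)\, x_i.$$
4. **Allele level.** For genes with diagnostic variants, allele-resolved
   counts from F1 hybrids and parents separate *cis* from *trans*
   regulatory divergence, including environment-dependent variants.

Because the full design is a 2×2 factorial, the condition codes $(g, e)$
enter every model the same way, so a planted simulation effect, a DGE
coefficient and an edge-modifier coefficient all live in the same
coordinates.

## The synthetic-data generator

No public data are required: `makeScenario()` + `simulateCounts()` build
count matrices with planted, known structure, and every claim the package
makes about itself is tested against that ground truth.

The generative model is a **log2-scale linear Gaussian structural equation
model with a negative-binomial observation layer**. Gene $j$ in sample $s$
with condition $(g, e)$ has latent log2 expression

$$x_{js} = b_{0j} + b_{gj} g + b_{ej} e + b_{gej} ge +
  \sum_{p \in pa(j)} w_{pj}(g, e)\,(x_{ps} - \mu_{ps}) +
  \sigma_{j}(g,e)\, \varepsilon_{js},$$

with edge weights $w_{pj}(g,e) = w_0 + w_g g + w_e e + w_{ge} ge$ — the
same coordinates as the edge regression above. Parent contributions are
centered at the parent's condition mean $\mu_{ps}$: this is an equivalent
reparameterization of the intercepts that keeps every gene's mean at its
planted baseline. (Propagating uncentered parent values, with baselines
around 7 log2 units and weights near ±1, drives regulated genes to
physically impossible expression levels — all-zero or astronomically
large counts.) Counts are negative-binomial around $2^x$ times a
log-normal per-sample size factor.

Key defaults, chosen once for realism at this replication depth:

| parameter | default | meaning |
|---|---|---|
| `nbDispersion` | 0.05 | moderate biological overdispersion (log2-scale measurement sd ≈ 0.33 at high expression) |
| `libSizeCv` | 0.2 | per-sample depth variation |
| `baselineLog2` | 7 | typical gene at ~128 counts |
| `defaultSigma` | 0.5 | residual sd of a structural equation |
| driver sd | 1 (`blocks`) / 1.5 (`gxe`) | module drivers are high-variance genes; smaller modules need a stronger shared factor for a comparable topological-overlap signature |
| residual noise | — | not stated by any replicate-variance figure we reproduce; a calibration choice |

Module "absence" in a condition is planted by silencing the module
driver's variance there (sd 0.02), not by deleting genes — absent modules
dissolve into background exactly as a deactivated regulatory program
would. Allele-resolved simulations place the planted effect on the
coefficient that defines it: *cis* adds $\delta A$, *trans* $\delta AG$,
*cis×E* $\delta AT$, *trans×E* $\delta AGT$; allele-indistinguishable
background genes (three per informative gene in the `ase` scenario) are
also emitted because size factors estimated from structured genes alone
are badly biased — mirroring the real protocol, where all genes enter the
normalization step.

What the generator does **not** emulate: read-level artifacts (mapping
bias, UMI saturation, 3′ bias), isoforms, batch structure, and
non-Gaussian regulatory nonlinearity. Passing tests therefore demonstrate
correctness of the estimators under the package's own model class, not
performance guarantees on any particular real data set.

## Normalization and per-gene models

Size factors are the median, over genes positive in every sample, of the
count-to-geometric-mean ratio; they equal DESeq2's
`estimateSizeFactorsForMatrix` to numerical precision (cross-checked in
the tests). Note that median-of-ratios assumes most genes are unchanged:
in simulations where a majority of genes co-vary (a single dominant
module) or where all differential genes move in one direction, the
factors absorb part of the signal. The benchmark scenarios plant balanced
effects for exactly this reason.

Differential expression uses per-gene ordinary least squares on
`log2(normalized + 1)` rather than a count GLM: at ~48 replicates per cell
the Gaussian approximation is excellent (type-I error at 0.05 lands in
[0.035, 0.065] on NB-simulated nulls), and the downstream stages consume
only signs, significance calls and classes. A per-gene negative-binomial
GLM backend (`method = "nb"`) is available. FDR control is applied within
each coefficient family — 0.05 for main effects, 0.1 for the interaction —
never pooled across families. G×E response classes (up/down in both
genotypes with different strength, single-genotype responses, opposite)
are assigned from per-genotype stratified treatment contrasts at FDR 0.05;
when neither stratified contrast is individually significant (rare, since
the interaction already is), the gene is attributed to the genotype with
the larger absolute fold change.

## Modules and the adaptive branch cut

The network is unsigned (`|cor|^5`); the topological overlap of genes
$i, j$ is $(\sum_u a_{iu}a_{uj} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$.
TOMs of the other three library types are rescaled to the reference
library type (Bd21d) by solving $q_{0.95}(\text{target})^p =
q_{0.95}(\text{reference})$ for $p$ and raising off-diagonal entries to
that power — a one-parameter monotone quantile match (full quantile
mapping would also be defensible; one quantile keeps the transform
rank-preserving and parametric).

Modules come from average-linkage clustering of $1 - \mathrm{TOM}$
followed by an adaptive dynamic branch cut with no PAM re-assignment
stage. The criterion, stated exactly:

* merges above `cutHeight` never bind modules;
* a branch below the cut is **split** when both halves hold at least
  `minClusterSize` genes and each is separated from their join by at
  least `minGap`;
* a branch is a **module** when it holds at least `minClusterSize` genes
  and the gap between its top merge and the height at which it joins its
  surroundings is at least `minGap`;
* a branch failing the gap test is descended into, so a handful of
  stragglers attaching just below the cut cannot mask a tight module
  underneath; the dendrogram root itself is never module-eligible
  (after rescaling, the noise floor can fall below the fixed cut height,
  and an eligible root would swallow the whole gene universe);
* genes in no qualifying branch get module id 0; modules whose eigengene
  dissimilarity $1 - r$ is below `mergeHeight` = 0.25 are merged
  iteratively.

`deepSplit` 0–4 maps to `minGap` = 0.05, 0.035, 0.025, 0.015, 0.010 on the
$1-\mathrm{TOM}$ scale: laxer gaps produce more, smaller modules. The two
presets are *moderate* (cutHeight 0.99, minClusterSize 30, deepSplit 2)
and *conservative* (cutHeight 0.984, minClusterSize 15, deepSplit 3). The
named dynamic-cut algorithm is specified by its parameters, not its
internals, so this implementation is validated by planted-partition
recovery (adjusted Rand index ≥ 0.9 on four 50-gene blocks at 48 samples)
and by null behaviour (≥ 90% of pure-noise genes unassigned), not by
output identity with any other package. Gene input order never changes
the result (genes are sorted before clustering; ties therefore break
lexicographically), and eigengenes are unit-norm first right singular
vectors oriented along the module's mean standardized expression, with a
deterministic fallback (first gene's profile) when the mean degenerates.

## Module preservation and cliques

The probability that $m$ independent uniformly drawn sets of the observed
sizes share at least the observed number of elements is computed exactly
by iterated hypergeometric mixing in log space; at $m = 2$ it reduces to
the hypergeometric upper tail (machine precision), and at $m \le 5$ it
matches a $10^5$-draw Monte-Carlo oracle. Pairs of modules from different
library types are linked when the moderate-preset overlap has
$P < 10^{-12}$ *and* the corresponding conservative-preset pair — matched
by best Jaccard similarity, since no cross-preset correspondence is
canonical — passes the same cutoff. Cliques are connected components of
that graph; single modules with no significant partner are singleton
cliques. Patterns count each library type once: all four = conserved, two
sharing genotype = genotype-specific, two sharing treatment =
environment-specific, and one or three (or two sharing neither factor) =
G×E-specific. The test universe is the variance-filtered gene set that
entered module detection, not the whole genome.

## Causal structure within modules

The search estimates a DAG over one module's genes from observational
samples (the module's source library type) plus "interventional" groups
(the other library types, assuming most regulatory structure is shared;
with fully shared mechanisms all samples may be pooled as observational).
A permutation $\pi$ is scored by the edge count of its minimal I-MAP —
edge $i \to j$ present when $i \not\perp j$ given $j$'s other
predecessors, by partial-correlation Fisher-z tests at `alpha` — plus the
number of implied intervention targets, detected by invariance tests
(mean-shift t and variance-shift F on the residuals of $j$ given its
permutation parents, Bonferroni over the two, at `alphaInv`). Depth-first
search over covered-edge transpositions accepts score-non-increasing
moves; the returned graph is always acyclic, and with d-separation oracle
CI answers the search attains the true edge count on random DAGs of up to
five nodes (checked against exhaustive permutation enumeration).

`alpha` defaults to 0.05: with half-subsamples of ~96 samples and the
negative-binomial measurement noise attenuating partial correlations, a
stricter level loses true edges faster than it removes false ones;
stability selection supplies the error control that a single
tight-threshold fit would.

**Stability selection.** 100 subsamples of half the samples, drawn
without replacement *within* each library type so interventional groups
survive; per directed edge, the selection frequency; per gene pair, the
skeleton frequency (sum of both directions — an edge whose orientation is
not identifiable alternates direction across subsamples and must not be
penalized for it). Pairs at or above the retention threshold are kept and
oriented in the dominant direction when it carries ≥ 2/3 of the pair's
frequency mass, otherwise flagged ambiguous (both directions reported).
Two retention rules are implemented:

* `retention = "fixed"` (default): majority vote, threshold 0.5 — the
  classical stability-selection regime, and the calibrated choice for
  module-sized node sets, where the alternative rule below retains only
  one or two edges regardless of how many are real;
* `retention = "quantile"`: threshold at the 0.95 (0.97 for conserved
  modules above 70 genes) empirical quantile of the positive skeleton
  frequencies — much sparser, appropriate when the candidate-edge pool is
  large and only a visualization-ready core is wanted.

The 70%-of-observational-samples size gate is enforced against the
per-subsample sample count (the count each fit actually sees), so every
subsample fit is well posed. Quantitative traits join a module as one
extra node via `attachTraitNode()` and are treated identically.

## Edge-level G×E tests

The full interaction regression (above) is fitted by OLS on
log2-normalized expression; with multiple inferred regulators the
multivariate form is used and the $R^2 > 0.5$ filter applies to the joint
fit. Per-coefficient t-tests are reported at 0.05 *uncorrected*, matching
the exploratory character of the edge level; BH-adjusted q-values per
module are available to users and clearly labelled as an extra. The
stratified slope in condition $(g,e)$ equals
$\beta_0 + \beta_g g + \beta_e e + \beta_{ge} ge$ from the pooled fit as
an algebraic identity (the design is saturated in condition), which the
tests verify to machine precision.

Pattern flags are non-exclusive; the primary label takes the first match
of: **GXE_SLOPE** ($\beta_{ge}$ significant) → **STRENGTH_CHANGE** (slope
significant with the same sign in all four library types while some slope
modifier is significant — a conserved-direction interaction whose
strength shifts) → **ENV_SLOPE**/**GENO_SLOPE** (by smaller P when both)
→ **INTERCEPT_CHANGE** (a $\gamma$ modifier) → **CONSERVED** (nothing
modified; when both genes are individually G×E this is the transmission
pattern). Placing STRENGTH_CHANGE above the single-factor slope flags is
deliberate: an edge present everywhere with a shifted slope is a
different biological object from an edge that exists only under drought,
even though both have $\beta_e$ significant.

Standardizing target and regulator before the fit
(`cilpStandardized()`) turns the slope-modifier tests into tests of
correlation differences between conditions, invariant to measurement
scale. The transmission enrichment asks whether G×E targets have a higher
fraction of G×E parents than non-G×E targets (Welch t-test on the
per-target fractions; a degenerate comparison with constant fractions in
both groups is reported as perfectly separated or indistinguishable).
This per-target-fraction construction is one reasonable reading of an
informally described statistic, and is documented as such.

## Allele-specific expression

With alleles $A$ (0 = Bd21, 1 = Bd3-1), treatment $T$ and generation $G$
(0 = F1, 1 = parents), the full model
$\log_2 q = \beta_0 + \beta_T T + \beta_A A + \beta_G G + \beta_{AG} AG +
\beta_{TG} TG + \beta_{AT} TA + \beta_{AGT} ATG$ is saturated in the
eight observable cells; $\beta_A$ tests cis, $\beta_{AG}$ trans,
$\beta_{AT}$ cis-by-environment and $\beta_{AGT}$ trans-by-environment
regulation, at $P < 0.1$ uncorrected. Per-condition "half models"
($q \sim A * G$ within one treatment) flag cis/trans per condition;
interaction-with-environment modes are only testable in the full model.
Genes qualify as allele-informative when, in every parental sample, the
own-accession allele exceeds one count and the opposing allele holds less
than 20% of the sample's total. OLS on log2-normalized abundances is used
for the same reasons as in the DGE stage; allele columns of a sample
share the sample's size factor, and size factors are estimated from
allele-summed gene totals.

Classification accuracy is defined over planted-effect genes: the
assigned primary mode (most significant allele term) must equal the
planted architecture; separately, null genes' per-coefficient flag rates
are compared with the nominal 10%. At the validation conditions (10
replicates per stratum, residual sd 0.3, effect 1 log2 unit) accuracy
exceeds 90%.

## Problem sizes and numerical choices

The validation suite runs module recovery on 4×50-gene blocks over 10
seeds, clique classification on the four-module G×E scenario over 10
seeds, causal recovery on 8-node DAGs with 100-subsample stability
selection over 20 seeds, edge-model calibration over 2000 null fits, and
ASE classification on a 100-gene panel — sizes chosen to give the
binomial margins the assertions need while keeping a complete run on one
CPU in minutes. Degenerate inputs are handled conservatively: singular
conditioning covariances count as dependence (sparsity-seeking searches
must not reward singularity), zero-variance genes are rejected or dropped
with warnings, and a directed cycle among unambiguously oriented retained
edges (not observed in practice) is demoted to ambiguous, weakest edge
first.

## Known limitations

* The branch-cut gap thresholds live on the $1-\mathrm{TOM}$ scale and
  were calibrated at ~48 samples per library type and soft power 5; very
  different replication or power choices shift the noise floor and may
  need custom `deepSplit`/`cutHeight`.
* Partial-correlation CI tests inherit the linear-Gaussian assumption of
  the log2 scale; saturating or switch-like regulation will be missed or
  distorted, and measurement noise attenuates deep conditioning sets.
* The paper-scale quantile retention rule and the majority-vote default
  answer different questions (visualization-ready sparse core vs
  best-effort skeleton recovery); users comparing against published
  module graphs should select the rule accordingly.
* Multiple-testing behaviour at the edge and ASE levels is intentionally
  uncorrected, matching exploratory practice; treat the labels as
  hypotheses, not discoveries.
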