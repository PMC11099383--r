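---
title: "Scoring cancer-rewired GPCR signaling axes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cancer-rewired GPCR signaling axes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcraxes)
```

## The problem

G-protein-coupled receptors respond to extracellular ligands — peptides,
neurotransmitters, metabolites — and cancers frequently dysregulate the
receptor together with the upstream supply of its ligand. For peptide
ligands the precursor transcript is directly measurable; for small-molecule
ligands it is not, so the expression of the ligand's biosynthetic enzymes
stands in as a proxy. This package treats the **axis** — a receptor paired
with a ligand precursor or a rate-limiting biosynthetic enzyme — as the unit
of analysis and asks four questions: are the two partners co-differentially
regulated across cancer subtypes; do transcript-level pathway changes agree
with metabolite-level changes; does joint high (or low) expression of both
partners stratify patient survival better than either gene alone; and are
drugs targeting these receptors growth-inhibitory in pooled viability
screens.

## The axis network

The network has three component classes and three edge types:
ligand→receptor edges carry an action mode (agonist/antagonist/mixed/
unknown), enzyme→ligand edges a reaction direction (LR/RL/UN), and derived
receptor–enzyme edges a functional-interaction confidence score. Enzyme
candidates are pruned by a composite annotation filter: keep an enzyme if
any of its cellular-component terms matches a keep list (e.g. plasma
membrane, axon terminus — an OR across terms, since requiring all terms
would discard essentially everything), and drop it if any class/domain/name
annotation contains an exclusion keyword (kinase, channel, transporter,
cytochrome) as a case-insensitive substring — the exclusion lists are
plain-language class names spanning several annotation vocabularies, so
substring matching is the robust reading. Among a pathway's enzymes, the
one with the most literature evidence for rate limitation (a
"rate limiting OR bottleneck" query count) is designated rate-limiting;
ties break to the lexicographically smallest symbol so the choice is
deterministic. Receptor–enzyme edges require a mediating ligand on both
sides and a confidence score of at least 150 — "minimum" is read
inclusively, as the lowest admitted value. Raising the cutoff can only
remove edges (tested as a monotonicity property).

## Differential expression

The pipeline's contract is the DE table (`gene`, `lfc`, `pvalue`, `padj`),
and the primary route is importing tables computed by any engine. The
built-in stage is deliberately simple and documented as such:
median-of-ratios size factors (reference genes = nonzero in all samples),
`log2(normalized + 1)` with a fixed pseudocount of 1, a Welch two-sample
test per gene (computed vectorised across genes and verified against
`t.test` in the unit tests), and Benjamini–Hochberg adjustment per
contrast over all genes tested. Genes with all-zero counts are reported
missing and excluded from the adjustment. Significance is strict on both
printed thresholds: `|lfc| > 1` and `padj < 0.01`, so a gene at exactly
LFC 1 is not called. Dispersion shrinkage, LFC shrinkage and batch
correction are intentionally out of scope — the axis-level computations
downstream, not the DE engine, are what this package contributes.

## Co-differential regulation

Each axis × subtype receives an integer score: ±2 when both partners exceed
the fold-change cut in the same direction and both are significant, ±1 when
both exceed it and exactly one is significant, 0 otherwise. The case where
both partners pass the fold-change cut but neither is significant is not
covered by the two stated positive classes, so it falls to 0. A pair is
*affected* when its score is nonzero in at least 25% of subtypes —
inclusive boundary, counting nonzero scores of either sign. Affected pairs
are clustered by Ward linkage on Euclidean distances between score rows
(the `ward.D2` criterion; verified against a brute-force Lance–Williams
agglomeration on small instances).

Receptor-level summaries: *ligand-wise similarity* is the mean pairwise
Euclidean distance between the receptor's partner score vectors across
subtypes (0 for single-partner receptors); *tissue-wise similarity* is the
analogous metric across tissues, obtained by averaging the receptor's
pair-by-subtype score matrix column-wise within each tissue and measuring
mean pairwise distance between the per-tissue profiles. The tissue of a
subtype defaults to the label prefix before the first underscore and can be
overridden with an explicit mapping. The up/down balance is the mean over
partners of (count of +2 entries − count of −2 entries).

Expression correlation of an axis is judged against a background of 1000
random gene pairs, drawn uniformly without replacement from the matrix's
genes (excluding tested pairs), one shared background per subtype — a
per-pair redraw is statistically equivalent and only costlier. The pair's
r is located within the background distribution by a two-sided t-score
using the background standard deviation (`df = n_background − 1`). A
one-sample test of the background *mean* against r was considered and
rejected: with 1000 background pairs the standard error of the mean is
~0.005, every tested pair gets a vanishing p, and the FDR filter loses all
discriminating power. With the distribution-based score, the combined call
(`q < 0.05` and `|r| > 0.25`) recovers a planted r = 0.8 pair among 99
nulls at n = 50 samples while calling ≤ 5% of nulls (a property test run
over 20 seeds).

Mutation association: within each subtype, a cancer gene's mutation
frequency is the fraction of samples carrying ≥ 1 mutation (a sample counts
once regardless of multiplicity); the top 5 genes per subtype are retained
with rank-boundary ties included, and each retained gene is scored by the
mean count of |score| = 2 pairs over its subtypes. The mutation table lists
only mutated samples, so cohort sizes default to the distinct samples
observed per subtype and can be supplied explicitly.

## Pathway abundance and concordance

`PAS = (I − D)/S`, where I and D count members with positive and negative
LFC and `S = I + D`, or 1 when no member is directionally regulated (the
guard keeps the empty pathway at 0). An LFC of exactly 0 counts toward
neither direction; all members with nonzero LFC are used rather than only
significant ones — PAS is a sign-balance statistic and magnitude gating is
left to the enrichment score it is compared with. The concordance code is
+1 when the (externally computed) enrichment score and the metabolite PAS
are both positive, −1 when both negative, 0 otherwise; ES significance
(`padj < 0.01`) is reported alongside but does not gate the sign.
Enrichment scores are consumed, never computed: gene-set enrichment is an
external standard step, and the synthetic generator emits ES tables
directly.

## Survival screening

Stratification is always at the median, with ties assigned to "low" — the
deterministic and conservative choice for the high-expression group — and
"low" as the Cox reference so hazard ratios compare high vs low expression.
The combined stratification intersects the two median splits: both-high vs
both-low, with mixed patients excluded from the comparison (the two extreme
groups are the only ones defined by the procedure). An axis passes the
screen when (a) its combined-stratification HR differs at least two-fold
from *both* single-gene HRs (ratio < 0.5 or > 2), (b) its log-rank p is
below both single-gene log-rank p-values, and (c) `logrank_p_axis < 0.05`;
BH-adjusted q-values are computed within a cohort across tested axes, per
the FDR < 0.1 reporting threshold. Cox fits use Efron tie handling; for a
two-group covariate the Cox score test and the log-rank test agree
asymptotically, which the tests assert at 10% relative tolerance.

The combinatorial stage forms a per-patient linear predictor from the
univariate Cox coefficients and the high/low indicators
(`beta_r * high_r + beta_p * high_p`). Indicators are the default because
the coefficients themselves were derived from median stratifications; a
continuous-expression mode is available behind a flag. The predictor is
median-split — so that a second-round log-rank p is defined — and evaluated
with a second Cox fit. A model is selected when its HR is at least two-fold
that of both individual models (in either direction, mirroring the axis
screen), with a significant log-rank p below both individual p-values.
Across selected models, ordinary least squares regresses the combined
coefficient on the two individual coefficients.

One caveat is intentional and surfaced rather than hidden: the convention
"HR > 1 means high expression correlates with high survival" that
accompanies some displays of this analysis conflicts with standard
high-vs-low Cox output, where HR > 1 means the high-expression group dies
faster. This package always computes standard high-vs-low hazard ratios;
any relabeling is left to presentation code.

## Drug-activity calling

Sarle's sample-adjusted bimodality coefficient
`b = (g1² + 1) / (g2 + 3(n−1)²/((n−2)(n−3)))` uses the bias-corrected
sample skewness (G1) and excess kurtosis (G2); it tends to 1/3 for a
normal distribution, 5/9 for a uniform, and 1 for a balanced two-point
mixture, and is invariant to affine transforms. The formula is not printed
in the methods it reproduces; Sarle's coefficient is the one used by the
pooled-screen resource the analysis draws on, and the package's calibration
tests pin its benchmark values. A drug is active when its
replicate-replicate Pearson correlation of per-cell-line LFC profiles
exceeds 0.2 *and* its bimodality coefficient exceeds 0.35 — both strict,
as printed. The correlation is interpreted as the replicate-reproducibility
metric (the screen's own quality statistic); the alternative reading
(predicted-vs-observed correlation in xenograft models) would require a
prediction model that is out of scope. Drugs with fewer than 4 scored cell
lines get a missing call. Top inhibitors are the k most negative LFCs per
cell line (ties by drug id), aggregated per tissue by mechanism of action
and by target, with target counts optionally normalized by the tissue's
top-k cell-line–drug pair count.

## The synthetic-data generators

Every pipeline input can be generated with planted structure from a single
seeded configuration; each generator draws from its own stream (seed +
fixed offset) and emits a truth table, so identical configs give
byte-identical files.

* **Counts**: negative-binomial with per-gene means log-uniform over
  `2^[3, 10]` and variance `mu + phi mu²`, dispersion `phi = 0.05` — the
  moderate-dispersion regime typical of bulk tumor RNA-seq at this depth.
  The reference study conditions are 2000 genes, 8 subtypes (two per
  tissue), 50 tumor vs 50 normal samples; planted axis genes shift their
  tumor mean by `2^lfc` with |lfc| = 2, half up and half down.
* **Survival**: exponential event times (proportional hazards hold
  exactly, giving Cox a clean oracle) with per-patient hazard
  `baseline × axis_multiplier^(both-high) × individual_multiplier^(high)`
  per planted axis, using the same median splits the screen applies.
  Censoring is independent exponential with its rate calibrated by
  root-finding so the expected censored fraction matches the configured
  30%. The default is a pure interaction (`individual_multiplier = 1`).
  Two properties of this construction matter when designing recovery
  experiments. First, a margin inherits part of an interaction: with a
  pure both-high multiplier m, the single-gene stratification sees a
  hazard mixture worth roughly sqrt(m), so the screen's two-fold HR
  criterion cannot distinguish a planted m = 3 axis from its own margins;
  planting mild individual effects (1.2, the level the recovery analysis
  is specified at) moves the combined-vs-individual ratio clearly past 2.
  Second, stacking many interaction axes in one cohort creates frailty
  (log-hazard sd ≈ 1.4 for ten ×3 axes) that attenuates every estimated
  HR toward 1; recovery cohorts therefore carry one synergistic axis each.
* **Drug panel**: active drugs draw per-cell-line LFCs from a balanced
  two-component mixture (separation 3) with replicate noise sd 0.1;
  inactive drugs have no reproducible cell-line-specific response (their
  between-line signal, sd 0.02, is negligible next to replicate noise), so
  they fail the correlation criterion — which is exactly what that
  reproducibility metric is for. A separation of 0 collapses actives to
  unimodal profiles that mostly fail the bimodality threshold.
* **Pathways**: alternating planted directions; concordant pathways (70%
  by default) have gene, metabolite and ES signs agreeing, discordant ones
  get an opposed ES sign, so their expected concordance codes are ±1 and 0
  by construction.

What the generators deliberately do **not** emulate: batch structure, tumor
purity, subtype sample-size imbalance, gene–gene correlation beyond the
planted axes, non-proportional hazards, and dose–response structure in the
drug panel. Passing recovery tests therefore demonstrates correctness of
the computations under clean planted structure, not robustness to the
messiness of real cohorts.

## Problem sizes and numerical choices

The test suite and the acceptance script run scaled study sizes chosen to
exercise every code path with stable statistics: DE recovery on 2000 genes
× 50 vs 50 samples; co-DE matrices over 4–8 subtypes; survival recovery on
twenty n = 400 cohorts; 50-seed combinatorial dominance runs at n = 300;
drug recovery on 60 × 100 panels over 20 seeds. Numerical details fixed
once and tested: pseudocount 1; BH via the standard step-up with
monotonicity (matches a reference implementation to 1e−12); Ward heights
from `ward.D2`; Cox ties by Efron; rate-limiting and top-k ties broken
lexicographically; all thresholds strict exactly where their printed
inequalities are strict.

## Limitations

The DE stage is a stand-in, not a negative-binomial model — import DESeq2
or edgeR tables for production use. The background-correlation test treats
background pairs as exchangeable with the tested pair under the null,
which is approximate when tested genes have atypical variance. The
combined stratification discards mixed patients, trading power for
interpretability of the two extreme groups. Mutation association is purely
count-based and makes no attempt at driver inference. The pipeline assumes
one expression unit per cohort and does not model inter-cohort batch
effects.
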