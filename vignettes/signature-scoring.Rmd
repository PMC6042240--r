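---
title: "Control-standardized signature scoring: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Control-standardized signature scoring: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrosig)
```

## The problem

Skin biopsies from patients with systemic sclerosis (SSc, scleroderma)
show coordinated transcriptional programs — adipogenic/PPAR-γ signaling,
profibrotic TGF-β signaling, and the activity of corepressors such as
NCoR that sit between them. A practical way to place a single biopsy on
such an axis is a *single-sample pathway score*: take a predefined gene
signature, standardize each gene against healthy controls, weight by the
direction in which the pathway moves the gene, and sum. `fibrosig`
implements that score together with the surrounding analysis: signature
gene filtering, hierarchical stratification of biopsies, anchor-gene
coexpression modules, and correlation of scores with one another and
with clinical severity (the modified Rodnan skin score, MRSS, 0–51).

## The score

For a signature of $n$ genes with direction weights $k_i \in \{+1,-1\}$
(+1 for pathway-induced genes, −1 for suppressed genes), the raw score
of sample $s$ is

$$\mathrm{score}(s) \;=\; \sum_{i=1}^{n} k_i \,
\frac{x_{is} - \overline{x}_{i,\mathrm{ctr}}}{\mathrm{SD}_{i,\mathrm{ctr}}},$$

where $\overline{x}_{i,\mathrm{ctr}}$ and $\mathrm{SD}_{i,\mathrm{ctr}}$
are the mean and sample standard deviation (divisor $n-1$) of gene $i$
over *control* samples only. Scores are then normalized to the mean of
the controls: the mean raw score of the control group is subtracted from
every sample, so controls are centred at zero. We implement the
normalization as a subtraction (not a division): it keeps the score an
affine function of the per-gene z-scores and makes the control mean
exactly zero; `compute_signature_score(..., normalize = "none")`
disables it.

Consequences we test for: the score is invariant to any per-gene affine
rescaling of the input applied to all samples (the reference absorbs
it); flipping every $k$ negates every score; raising a $k=+1$ gene in
one sample strictly raises only that sample's score. Genes with zero
control SD have an undefined z-score and are dropped and reported,
never imputed.

## Filtering signature genes

Candidate signature genes pass a two-part filter: coefficient of
variation (CV = sample SD / |mean|) above 0.5 *and*
Benjamini–Hochberg-adjusted case-vs-control differential-expression FDR
below 0.05, adjusted over exactly the tested signature genes. Three
choices here were genuinely open and are package decisions:

* **The differential test.** We default to a two-sided Welch two-sample
  t-test on the input scale — the standard microarray-era choice — with
  a Wilcoxon rank-sum alternative behind the `test` argument.
* **The CV population.** CV is computed across *all* samples (cases and
  controls pooled), the common variance-filter convention; computing it
  on controls only would be a different, defensible filter, and the
  threshold arguments make the behavior explicit either way.
* **Degenerate genes.** A gene with zero overall mean has no defined CV
  and is dropped with a recorded reason; a gene constant within both
  groups is assigned p = 1 (it carries no evidence) so BH still runs
  over the full tested set.

Because expression scales are assay-specific and the package never
guesses them, input values are taken as-is; the `scale_note` field on
the matrix records the user's declaration (e.g. whether intensities are
log2).

## Stratification

Samples are clustered hierarchically on a gene panel (typically the
filtered signature) after per-gene z-scoring. The default geometry —
distance = 1 − Pearson correlation between sample profiles, average
linkage — is the prevailing transcriptome-heatmap convention; Euclidean
distance is available, and matters: a mean shift that moves *all* panel
genes in the same direction is mathematically invisible to
profile-correlation distance, so panels of uniformly oriented genes
should be clustered with `distance = "euclidean"`. The tree is cut at a
fixed requested number of clusters (default 3) rather than by a height
rule, and labels are renumbered by decreasing cluster size with ties
broken by the smallest member sample id, making the labelling fully
deterministic. When every panel gene is constant (all samples identical
over the panel) an all-zero distance matrix is used so the cut is still
deterministic rather than an error.

Cluster–diagnosis association uses the Pearson chi-square test without
continuity correction on the clusters × groups table, with
$(r-1)(c-1)$ degrees of freedom; expected counts below 5 trigger a
warning but do not block the test, matching how the statistic is used on
modest biopsy cohorts.

## Coexpression modules

`derive_module()` correlates every gene with an anchor gene by Spearman
rank correlation (average ranks for ties) and keeps genes with
$r$ strictly above the threshold on the *positive* side only (no
absolute value). When more genes qualify than `max_candidates`
(default 400), the pool is truncated to the highest-r genes with ties
broken by gene id ascending — a deterministic rule standing in for an
unstated candidate-pool cap. The module is the intersection of the
candidates with the union of the selected GMT gene sets (e.g. lipid
metabolism pathways); the anchor is never its own module member.

## Associations and clinical summaries

Score–score and score–MRSS associations default to Pearson correlation
with a two-sided t-approximation p-value (`method = "spearman"` is a
flag); pairs with a missing covariate are dropped and counted, and
fewer than 3 complete pairs is an error. Two-group score comparisons
(diffuse vs limited subtype, early vs late duration) use the two-sided
Wilcoxon–Mann–Whitney test, the conventional distribution-free choice
for pathway scores. Cohort summaries report category counts with
percentages to one decimal (missing values as their own category, so
percentages sum to 100) and mean ± SD for continuous fields. The small
clinical formulas are provided verbatim: HOMA-IR = glucose × insulin /
400, and the leptin/adiponectin ratio, defined only for positive
adiponectin.

## The synthetic cohort generator

Every stage is exercised end-to-end on synthetic data with planted
structure; `simulate_cohort()` is first-class, tested code, not a test
fixture. The model is a Gaussian latent-factor design — the simplest
structure that realizes all the headline correlations simultaneously
and admits exact expected values:

* Each sample draws latent axis values from a multivariate normal with
  a configurable correlation matrix; case samples additionally receive
  a mean shift per axis.
* Each non-background gene is `loading × axis + N(0, noise_sd)`;
  background genes are pure noise.
* MRSS exists for cases only:
  `max(floor, intercept + slope × anchor-axis + N(0, mrss_noise_sd))`.

Defaults define the emulated study conditions: 22 controls + 70 cases;
blocks of 43 (anchor), 30, 30 and 400 background genes; planted axis
correlations +0.9 (anchor–pparg) and −0.8 (anchor–tgfb); case shift −1
on the anchor axis; loading 1; noise SD 1; MRSS slope −5, intercept 15,
noise SD 5, floor 0. Two defaults were not dictated by those conditions
and are package choices:

* **corr(pparg, tgfb) = −0.72**, the product of the two anchor
  correlations, i.e. the partner axes are conditionally independent
  given the anchor. Something must be chosen — leaving that entry at 0
  makes the matrix non-positive-semidefinite — and the product is the
  weakest assumption consistent with the planted pair.
* **MRSS intercept 15** places case severity in a clinically plausible
  mid-range of the 0–51 scale given slope −5 and noise SD 5.

Case subtype labels are drawn at diffuse:limited:overlap = 30:5:1 and
duration at early:late = 1:2, the composition of a typical deeply
phenotyped SSc cohort. Signatures are emitted with all k = +1 by
default; `flip_fraction` flips a stated fraction of genes to k = −1
with negated loadings so the direction-weight machinery is exercised.

One behavior of this design is worth knowing: the latent axis is shared
by all genes of a block, so per-gene differential-expression statistics
are strongly correlated, and the *realized* case–control shift varies
between simulated cohorts with SD ≈ `sqrt(1/22 + 1/70)`. Under the
default shift of −1 the CV+FDR filter therefore keeps anywhere from all
43 anchor genes down to none depending on the draw — a faithful
reflection of how signature filters behave on cohorts with correlated
genes, not a defect.

What the generator does **not** emulate: microarray probe-level noise,
batch effects, platform-specific intensity distributions, missing
values, or gene–gene correlation beyond the block structure. Passing
tests therefore certify the *statistical machinery* — recovery of
planted correlations, calibration of the filter under the null, exact
agreement with closed forms and brute-force oracles — not performance
on any particular real platform.

## Validation design and problem sizes

The test battery checks, among others:

* vectorized scores against an independent double-loop oracle on 200
  random small problems (≤ 10 genes × 10 samples, relative tolerance
  1e−10), and the exact-zero control mean;
* per-gene affine invariance at tolerance 1e−8;
* recovery of the planted score–score correlations over 50 simulated
  cohorts (22 + 70 samples, noise SD 0.5): mean Pearson r within ±0.05
  of +0.9 / −0.8 with the correct sign in every cohort. This check runs
  with the case-group shift set to 0: a mean shift on one axis adds
  between-group variance not shared with the partner axes and biases
  the pooled-sample Pearson estimate away from the planted latent
  value, so switching it off isolates the quantity the check measures;
* the negative score–MRSS association in at least 48 of 50 cohorts
  under the default shift;
* the null calibration of the FDR filter (mean kept fraction ≤ 0.05
  over 100 null cohorts of 200 genes);
* the chi-square statistic against its closed form on [[10,0],[0,10]]
  (exactly 20) and against brute-force Σ(O−E)²/E on 100 random tables;
* exact recovery of two 10-SD-separated sample populations at k = 2;
* the printed cohort percentages (83.3% diffuse, 33.3% early) from
  their integer counts.

Problem sizes (50–100 cohorts of ~500 genes × 92 samples) were chosen
so the full battery completes in well under a minute on a laptop while
keeping Monte-Carlo error far below every asserted tolerance.

## Known limitations

* Missing expression values are a hard error; the score has no
  principled missing-data rule and we prefer failure to silent
  imputation.
* The filter's t-test assumes approximate normality per gene on the
  supplied scale; use `test = "wilcoxon"` for heavy-tailed data.
* Correlation-distance clustering cannot see uniform mean shifts (see
  above); the distance is a parameter precisely because no single
  choice suits every panel.
* The package takes signature direction labels as given in the input
  file and takes no stance on their provenance.
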