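---
title: "Classifying phenolic antioxidants by stepwise discriminant analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying phenolic antioxidants by stepwise discriminant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpphqsar)
```

## The problem and the model

DPPH radical scavenging is the workhorse assay for antioxidant
discovery: a compound's IC50/EC50 in µM summarizes how well it quenches
the stable DPPH radical, computed per assay read as
$(A_0 - A)/A_0 \times 100\%$ from the absorbances without and with the
antioxidant (`dpph_scavenging()`). Potencies above 300 µM are not worth
pursuing, so the pipeline dichotomizes at that cut point
(`assign_activity_class()`): class 1 ("positive") at ≤ 300 µM, class 2
otherwise. A potency of exactly 300 µM is classed positive, because the
exclusion is stated for compounds *beyond* the threshold. Compounds
curated as inactive without a usable potency can be flagged `inactive`
and are classed negative; this mirrors how negative sets are typically
assembled from database records.

The classifier is two-group linear discriminant analysis in its Fisher
classification-function form. With pooled within-group covariance
$S$ and class means $m_g$, each class gets the affine score

$$ f_g(x) = x^\top S^{-1} m_g - \tfrac12 m_g^\top S^{-1} m_g + \log \pi_g , $$

and a sample is assigned to the class with the larger score. Under
multivariate normality with a shared covariance this is the Bayes rule,
and the softmax of the two scores is the class posterior — but the rule
itself only needs mean separation to be useful, which is why it
tolerates the heterogeneous data (potencies pooled across many
laboratories) that would violate the assumptions of a regression on
IC50 itself. Ties (margin exactly 0) go to the positive class: in a
screening setting the costlier error is discarding an active compound.

## The descriptor panel

Descriptors are 2D RDKit descriptors, computed through a bundled Python
helper (`inst/python/rdkit_descriptors.py`); the interpreter is located
via `options(dpphqsar.python = ...)`, `DPPHQSAR_PYTHON`, or the PATH.
The panel is *pinned* in `inst/extdata/descriptor_catalog.csv` — 200
names with a five-way category code (DF drug-likeness/fingerprint
density, P physicochemical, T topological, C constitutional, E
electronic). Pinning matters because descriptor backends drift across
versions; the catalog, not the backend's current default list, defines
the contract, and `compute_descriptors()` validates every name against
the backend before computing. The shipped panel is the backend's 2D
descriptor list minus the eight `BCUT2D_*` descriptors (undefined for
some structures) and the two `Ipc` variants (numerically overflow-prone
for large molecules). Category codes for the 87 descriptors that appear
in the published screening table follow that table; the remaining names
are assigned by naming convention (`fr_*` fragment counts →
constitutional, `*_VSA` surface partitions → physicochemical, EState
descriptors → topological, partial-charge extremes → electronic,
fingerprint densities and `qed` → DF). Those residual assignments only
affect reporting granularity, never the statistics.

Two cleaning rules precede modeling:

* **Semi-constant exclusion** (`filter_semiconstant()`): a descriptor
  whose modal value covers strictly more than 80% of samples is dropped.
  The inequality is strict — a column at exactly the threshold is kept —
  and only the maximal frequency matters, so ties between modal values
  are irrelevant. The threshold is a fraction in (0, 1], default 0.80.
* **Missing cells**: a descriptor that fails for one compound leaves an
  `NA` cell; columns with missing cells are median-imputed (with a
  warning) rather than dropped, preserving sample count. Wholesale
  structure failures drop the compound, with a warning naming it.

## Screening and selection

`ttest_screen()` applies a per-descriptor two-sample *t*-test, signed as
mean(positive) − mean(negative). The pooled-variance (Student) form is
the default and the Welch form is a flag, since the screening convention
this pipeline follows reports the classical pooled statistic. Raw
*p* < 0.05 decides retention — deliberately no multiple-testing
correction, matching the screening protocol; `adjust` exposes
`p.adjust` methods for users who want it. Columns with zero within-class
variance in both classes have no defined *t* and are flagged
`degenerate`, never retained.

`stepwise_select()` then runs stepwise discriminant analysis on the
retained pool. The criterion is Wilks' lambda
$\Lambda = \det(W)/\det(T)$, computed from Cholesky log-determinants for
numerical stability. With $p$ descriptors in the model, a candidate's
partial F-to-enter is $(n - 2 - p)(\Lambda_p/\Lambda_{p+1} - 1)$ (one
numerator degree of freedom for two groups), which reduces to the
squared pooled *t* for the first entry; F-to-remove is the same quantity
seen from the reduced model. Defaults F-to-enter 3.84 and F-to-remove
2.71 are the conventional stepwise defaults (the 5% and 10% χ²₁ points);
the entry threshold must exceed the removal threshold or the procedure
could cycle, and this is enforced. Ties on Λ break lexicographically so
runs are deterministic. A condition-number guard (default 10¹⁰) skips
candidates that would make the within-scatter numerically singular —
screened pools genuinely contain exact duplicates (e.g. two carboxylate
counts that agree on every compound), and skipping them with a message
is more informative than a failed inversion deep inside the search.

The trace records every action with one step index. A final model
reached "in 20 steps" therefore means entries *plus* removals — e.g. 18
entries and 2 removals for a 16-descriptor final model whose first two
entrants were later removed, which is exactly the arithmetic of the
published model this package freezes. Whether a selection at study scale
should also be capped at 20 actions is a protocol choice; `max_steps`
defaults to 100 and is set explicitly in every experiment below.

`fit_fisher()` fits the classification functions on any descriptor set
(typically `trace$selected`). Priors default to equal — appropriate when
the class frequencies in the training set reflect curation effort, not
prevalence — with class-proportional priors available. Changing priors
shifts only the constants, by the log-prior-ratio.

## Validation suite

`back_substitution()` classifies the training samples themselves;
`jackknife_loocv()` refits on every size-$N-1$ subset and classifies the
held-out sample, exactly $N$ refits. By default folds refit only the
coefficients over the fixed descriptor set; `reselect = TRUE` re-runs
the stepwise search inside every fold. The cheap default is the
conventional reading of "re-establish the discriminant function on the
remaining samples", and the expensive variant is exposed because the
protocols this implements do not settle the question. A fold may leave a
class with a single sample; the pooled covariance then rests on the
other class, which is why the fit accepts one-sample classes during
cross-validation only.

From a 2×2 confusion table the suite derives: per-class error
discriminant proportion (misclassified / actual, as a percentage; the
classical acceptability bars are 10% and 20%), Cohen's kappa
$(P_0 - P_e)/(1 - P_e)$ with chance agreement from both marginals,
sensitivity, specificity, Youden index, and McNemar's test. The McNemar
implementation is the *exact* two-sided binomial form,
$\min(1,\, 2\,P(X \le \min(b,c)))$ with $X \sim \mathrm{Bin}(b+c, 1/2)$
on the discordant counts — chosen because the reference results this
package reproduces (p = 0.250 for discordants 3/0, p = 0.375 for 4/1)
are exactly the exact-test values, not the χ² approximation.

`heatmap_matrix()` draws a seeded 10 + 10 sample panel, restricts to the
model's descriptors and z-scores each descriptor *over the displayed
subset* (mean 0, SD 1 across the 20 samples); `autoplot()` renders the
classic green-to-red diverging tile map. Standardizing over the subset
rather than the full matrix makes the panel self-contained, at the cost
of panel-dependent color scales — a display choice, not an inferential
one.

## The synthetic generator

`generate_two_class()` emulates the curated study design so every stage
is testable without any external data: defaults of 99 positive and 105
negative samples and 200 descriptors, of which 16 informative columns
are unit-variance Gaussians with a class-mean gap of 1.5 pooled SDs and
184 are pure noise. Optional features stress individual stages:
within-class equicorrelation through a shared per-sample factor,
semi-constant columns planted as 85% exact zeros (modal frequency above
0.8 by construction), bit-exact duplicates of informative columns (to
exercise the collinearity guard), and Poisson-count columns emulating
integer fragment descriptors. Everything is reproducible from the spec's
single seed.

What the generator does *not* emulate: the heavy mutual correlation of
real descriptor panels (molecular weight, atom counts and surface areas
move together), non-Gaussian marginals beyond the optional Poisson mode,
and any relation between descriptor identity and effect. Consequences
follow for what passing tests show. On independent synthetic noise, an
uncapped stepwise run with F-to-enter 3.84 keeps admitting noise columns
(among ~170 independent candidates, the best chance F exceeds 3.84
essentially always), whereas on real, correlated panels the search
starves after the informative structure is absorbed. The study-scale
recovery experiment therefore runs the full protocol — semi-constant
filter, t-screen, then stepwise *capped at 20 actions*, the reference
protocol's own stopping point — and under those conditions it recovers
the planted 16-descriptor structure with few noise admissions. Synthetic
results demonstrate the machinery is correct, not that any particular
real-data model is right.

A fixed 25-compound toy set (`toy_phenol_set()`: classic phenolic
antioxidants plus non-phenolic decoys, with invented potencies on both
sides of 300 µM) stands in for curated structure lists in examples and
IO tests; it is labelled synthetic and carries no experimental meaning.

## Numerical and design choices

* Wilks' lambda via Cholesky log-determinants; a non-positive-definite
  scatter raises a singularity error naming the offending subset.
* Model files are key-value text with 17 significant digits, so
  write/read round trips are bit-exact; the published 16-descriptor
  model ships as such a file with its printed coefficients.
* The published model's backend version is unrecorded; screening with it
  under any known backend version warns once per session, and every
  screening result carries the backend version in an attribute. Scores
  evaluated under a drifted backend shift visibly (the README example
  shows classic antioxidants scoring negative under a current backend) —
  an inherent limitation of frozen descriptor-space coefficients, which
  the package surfaces rather than hides.
* Problem sizes in the test suite are chosen to exercise the study scale
  once (204 × 200 with 20 seeds for the recovery experiment, ~1.5 s per
  seed) and small instances everywhere else; oracle checks use direct
  enumeration, textbook formulas, `stats::manova` and `MASS::lda` as
  independent references.

## Known limitations

The applicability domain is phenolic chemistry and DPPH activity;
nothing here validates extrapolation to other scaffolds or other
antioxidant assays. Two-group linear discriminant analysis with a shared
covariance cannot express class-specific covariance (no quadratic
boundaries), and the pipeline offers no applicability-domain scoring,
y-scrambling, or external test-set protocol — only the validation suite
described above. Reproducing the published model's coefficients from
scratch would require the original curated structures and the matching
descriptor-backend version, neither of which is available; the package
therefore freezes the published coefficients and treats full-scale
re-derivation as out of reach.
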