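---
title: "Methods: integrative mining of placental methylome and transcriptome in growth restriction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative mining of placental methylome and transcriptome in growth restriction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The analysis problem

Intrauterine growth restriction (IUGR) is a failure of the fetus to reach
its growth potential, usually rooted in placental insufficiency. Placental
case-control studies measure two omics layers on the same samples — CpG
methylation (beta values in $[0,1]$ from methylation arrays) and normalized
gene-expression intensities — together with clinical phenotypes: group
membership, gestational age, and birth-weight and head-circumference
Z-scores. `placmine` implements a reusable, fully testable version of a
data-mining workflow over such a cohort:

1. **Differential screen** of each omics layer independently;
2. **Cross-omics integration** at the gene level;
3. **Literature mining** of the significant genes from a per-gene abstract
   corpus (tf-idf, latent semantic analysis, k-means);
4. **Phenotype prediction** with SMOTE-balanced, grid-search-tuned support
   vector machines, summarized by permutation feature importance and a
   feature-trait network.

Because the real cohort data are controlled-access, the package ships a
synthetic-data generator that reproduces the study's design — an 8 control
/ 28 case cohort with the published phenotype moments — with known planted
truth, so every stage has measurable operating characteristics.

## Differential screen

Per feature, two-group comparison of cases against controls:

* **Levene gate.** Levene's variance-homogeneity test in its original
  mean-centered form (absolute deviations from the group mean, one-way
  ANOVA F on the deviations). A feature is only eligible when the gate
  does *not* reject at $\alpha = 0.05$. The median-centered Brown-Forsythe
  variant is exposed as an option (`levene_center = "median"`) but the
  mean-centered form is the default, matching the test the workflow names.
* **Pooled Student t-test**, two-sided, $df = n_a + n_b - 2$. The pooled
  (rather than Welch) form is coherent here precisely because the Levene
  gate precedes it.
* **Benjamini-Hochberg q-values** computed across all tested features
  *within* each omics layer (the layers are processed independently;
  joint adjustment across layers is possible by concatenating tables but
  is not the default).
* **Significance** requires both conditions: Levene $p \ge 0.05$ *and*
  $q < 0.05$. Fold-change (ratio of group means) and the mean difference
  are reported for every feature.

Features containing missing values are excluded and logged rather than
imputed. Degenerate features (zero pooled variance with unequal means)
are flagged and never declared significant.

The gate has a consequence worth stating plainly: under homogeneous
variances it still rejects about 5-7% of features at these group sizes
(its small-sample size is slightly above the nominal level), so the
screen's recall of genuinely shifted features is capped near 0.94 no
matter how large the shift. The acceptance suite measures exactly this.

Cohort description tables use Fisher's exact test (two-sided by the
point-probability-sum convention — the convention under which the
published cohort's resuscitation and NICU p-values, 0.03 and 0.003, are
reproduced; tail-doubling does not reproduce them) and the Wilcoxon
rank-sum test (exact for combined $n \le 20$ without ties). The Fisher
implementation enumerates the hypergeometric support directly, which
keeps exhaustive oracle sweeps fast; it agrees with `stats::fisher.test`
to $10^{-9}$ on random tables.

As a confounder check, the screen can be re-run on the high-gestational-age
subset (controls plus cases at $\ge 37$ weeks) and compared with the full
cohort by Kendall's tau-b on the per-feature t-statistics
(`kendall_concordance()`). t-statistics were chosen as the comparison
scale (the workflow's own choice is not recorded anywhere; p-values or
signed log-p give the same qualitative answer and the column is an
argument). Note that concordance values published for the real cohort
(τ ≈ 0.4-0.45) are properties of that data and are not reproduction
targets for synthetic cohorts.

Unsupervised structure is shown by complete-linkage hierarchical
clustering of samples on Euclidean distances over row-standardized
significant features, with a two-cluster cut reported.

## Cross-omics integration

A gene counts as altered in both layers when at least one of its CpGs and
at least one of its transcripts pass the screen. Per gene the
significant/total counts per layer, majority direction labels
(hypo-/hypermethylated, under-/overexpressed) and the Pearson correlation
across all samples between the mean significant-CpG beta and the mean
significant-transcript intensity are reported ($p < 0.05$ two-sided marks
a significant methylation-expression correlation).

## Literature mining

Abstracts are lowercased; punctuation and digits stripped; tokens of three
characters or fewer dropped; stop words removed (a standard English list
is built in, any list can be supplied); the remainder Porter-stemmed. The
package carries its own implementation of the original Porter (1980)
algorithm, verified against the algorithm's published step examples.
Stop-word removal precedes stemming, and n-grams are built on the
filtered token stream — two orderings the method's description leaves
open; both choices are the common ones.

Each gene's abstracts concatenate into one *gene summary*. The vocabulary
is all unigrams, bigrams and trigrams over the summaries. With $|D|$ gene
summaries, the matrix entry for term $i$ in gene $j$ is

$$M_{i,j} = \mathrm{tf}_{i,j} \times \mathrm{idf}_i,\qquad
\mathrm{idf}_i = \log_2\frac{|D|}{|\{d : t_i \in d\}|},$$

where $\mathrm{tf}_{i,j}$ is the count of term $i$ in summary $j$ divided
by the total number of terms (all n-gram orders pooled — one shared
denominator) in that summary. A term present in every summary has
$\mathrm{idf} = 0$ and can never surface in any cluster summary. Columns
are then length-normalized (L2 by default; L1 and none are options).
Terms appearing in fewer than two summaries are pruned before the SVD
(configurable, `min_df`): they are pure noise for between-gene similarity
and dominate the vocabulary at trigram order.

Latent semantic analysis is the truncated SVD of $M$; the retained
variance is $\sum_{i \le k} d_i^2 / \|M\|_F^2$ and gene $j$'s embedding is
the $j$-th row of $V_k D_k$. Requesting more components than the rank
retains all variance with a warning. Gene clustering is Lloyd's k-means
with k-means++ seeding and ten restarts in LSA space (Euclidean distance;
after L2 column normalization the Euclidean and cosine orderings
essentially coincide); an emptied cluster is re-seeded from the farthest
point, and the whole procedure is deterministic given its seed. Cluster
summaries back-project each cluster's mean latent coordinate through the
term loadings ($U_k \bar v$) and keep the `top_m` terms with positive
weight, ready for word-cloud rendering. At paper scale the method's
defaults were 1,000 components and 24 clusters; for synthetic corpora
both are configuration knobs with desk-scale defaults (50 components
capped at rank, 4 clusters).

## Phenotype prediction

Four traits are modeled from the significant features: case/control group
(classification, accuracy), and three regression traits measured by
Pearson correlation on the test set — the premature-birth score
($39 - \text{gestational age}$ in weeks, $> 2$ pre-term, $\le -3$
post-term), the birth-weight Z-score and the head-circumference Z-score.
Growth Z-scores may be supplied directly or derived from a user-provided
growth-curve reference table (GA-by-sex means and SDs, linearly
interpolated in GA); no reference values are embedded in the package.

The sample set is split once (shared across traits, seed-controlled) by
stratified sampling at a 2/3 : 1/3 ratio preserving the case-control
ratio. Feature columns are standardized with training-set statistics.
The training set is then balanced by SMOTE: synthetic minority samples
$x + \lambda (x_{nn} - x)$, $\lambda \sim U(0,1)$, with $x_{nn}$ among
the $k = 5$ nearest minority neighbors (lowered with a warning when the
minority is smaller). For the continuous traits the same interpolation is
applied within the minority *group* and the target value interpolates
with the same $\lambda$ (a SMOTER-style reading — the original technique
is defined for class labels, and this extension is flagged to users as an
interpretation). Test samples never pass through augmentation, and the
augmented set is used only for fitting — deleting the test set before
training changes nothing about the model.

Hyperparameters are chosen by k-fold (default 5) cross-validated grid
search on the augmented training set, folds stratified for
classification; the winning point (first in grid order on ties) is refit
on the full training set. The margin solver behind each fit is
`e1071::svm` (libsvm) — an exchangeable component behind the package's
grid loop, fold assignment, scoring and refit. Classification exposes
sigmoid-calibrated class probabilities. The default grids are linear and
RBF kernels, $C \in \{0.1, 1, 10, 100\}$, $\gamma \in \{0.5, 1, 2\}/p$,
and for regression $\varepsilon \in \{0.01, 0.1, 0.5\}$: the traits live
on the Z-score scale, so tubes much wider than 0.5 would swallow the
within-group signal entirely, and calibration showed $\varepsilon = 0.01$
is frequently optimal. During calibration we also evaluated scoring CV
folds on real (non-synthetic) samples only; it *reduced* test performance
at these sample sizes (too few real points per fold to rank grid points
reliably) and was discarded.

Permutation importance of each feature is the mean drop in the test
metric over `n_repeats = 20` shufflings of that feature's test column
(drawn in canonical sample order, so the result is invariant to row
order). Negative means are floored at zero and scaled to percent of the
maximum. The feature-trait network links every feature at $\ge 10\%$
importance to the corresponding trait, labels features reaching
$\ge 80\%$ for any trait, and exports SIF/GraphML plus a supplementary
table at $\ge 50\%$.

## The synthetic study

`simulate_omics_cohort()` emulates the study design, not array chemistry:

* **Cohort**: 8 controls / 28 cases. Gestational age: controls
  $N(38.7, 0.7^2)$ weeks; cases a two-component mixture (severe early and
  mild near-term sub-groups, component SDs 2.0 and 1.0 weeks, separation
  solved so the pooled moments are $34.0 \pm 3.9$) — the structure that
  makes hierarchical clustering split the cases into two
  gestational-age-separated sub-clusters.
* **Methylation**: per-CpG logit-normal with feature-specific baselines
  and residual SD 0.5 on the logit scale, so betas are bounded by
  construction and effects compose additively on the logit scale. Planted
  CpGs (default 200 of 2,000) shift the case mean by $\pm 0.4$ beta
  units, 75% of them downward (global hypomethylation bias). Planted
  baselines sit symmetric about 0.5 (hypermethylated features run
  0.3 → 0.7 and vice versa) so the planted shift leaves the beta-scale
  variance unchanged between groups; a mean shift that also changed
  variance would be removed by the Levene gate, which is a real
  phenomenon on beta-scale data but would make recall unmeasurable as a
  property of the test stack. This is the main idealization of the
  generator and is stated as such: on real arrays, strongly shifted CpGs
  near the scale boundary *do* fail the gate.
* **Expression**: normalized log2 intensities, $N(8, 1.5^2)$ baselines,
  residual SD 0.5; planted transcripts (default 120 of 2,000) shift by
  $\pm 1.5$ log2 units with near-balanced direction.
* **Gene structure**: features map to 200 genes blockwise. Methylation
  planting covers the leading genes, expression planting overlaps the
  tail of that block (6 dual-layer genes by default) and extends into
  fresh genes, so meth-only, expr-only and dual-layer genes all exist.
  Dual-layer genes share a per-sample latent factor added to their CpG
  logits and subtracted from their transcript intensities
  (SD 0.35), planting the negative methylation-expression correlation.
* **Trait signal**: the leading 40 planted CpGs and the trailing 40
  planted transcripts (outside the dual-layer genes, so the coupling
  noise does not mask them) are shifted oppositely in the two
  gestational-age components ($\pm 0.3$ logit/log2 units, severe
  component more extreme). Birth-weight and head-circumference Z-scores
  are linear in the within-group-standardized severity projection of the
  trait CpGs plus Gaussian noise, calibrated so the features explain
  $R^2 \approx 0.6$ of the within-group trait variance, with group
  moments fixed to the cohort description ($-0.07 \pm 0.89$ vs
  $-2.02 \pm 0.75$ for birth weight; $0.22 \pm 0.49$ vs $-1.30 \pm 0.86$
  for head circumference).
* **Corpus**: each of the 200 genes draws one of 4 latent topics;
  abstracts (8-15 per gene, 40-80 tokens) mix the gene's topic pool with
  a shared background pool at 70:30. Tokens are surface variants
  (plural/-ed/-ing) of pseudo-stems constructed to stem consistently, and
  abstracts are salted with stop words, short words and punctuation so
  the preprocessing stages are genuinely exercised. No real English is
  used, which keeps topic recovery measurable and independent of any
  shipped vocabulary.

What the generator does *not* emulate — probe chemistry, detection
p-values, batch effects, cell-composition heterogeneity, realistic
correlation structure among null features, real abstract language —
bounds what green tests mean: they certify the pipeline's statistical
machinery and its operating characteristics under the declared model, not
performance on real placental arrays.

### Problem sizes and calibrated operating points

Default synthetic scale is 2,000 features per layer, 36 samples, 200
genes — large enough for stable operating characteristics, small enough
that the full test suite and the acceptance script run in minutes on one
CPU. Monte-Carlo calibration (200 replicates for the screen, 20-50 seeded
replicates for the model stage, run before the test thresholds were
frozen) fixed the defaults above and established:

* screen recall of planted features ≈ 0.94 (bounded by the Levene gate's
  realized size), observed FDR ≈ 0.04;
* case-control test accuracy 1.0 with a wide probability gap;
* regression traits reach Pearson $p < 0.01$ on the 12-sample test set in
  ≳90% of seeds;
* 4-topic corpus recovery at ARI > 0.9 with k-means at $k = 4$.

## Numerical and degenerate-input conventions

* Both groups constant in the Levene test → $p = 1$ (no evidence of
  variance difference); within-group-constant but different spreads →
  $p = 0$.
* Zero pooled variance with equal means → $t = 0, p = 1$; with unequal
  means → degenerate flag, excluded from inference.
* Fisher tables with an empty margin → $p = 1$; point-probability
  comparisons use a $10^{-7}$ relative tolerance.
* Correlation of a constant vector is undefined and reported as a
  failure flag, never coerced to a number.
* k-means ties in assignment break to the lowest cluster index;
  grid-search ties keep the first grid point — both for determinism.
* All randomness flows from one master seed through stage-specific
  sub-seeds (`derive_seed`), and every output file is byte-reproducible
  given the seed.

## Known limitations

* The Levene gate bounds screen recall below 1 by construction; the
  package reports this honestly rather than tuning around it.
* Feature selection uses the whole cohort and *precedes* the train/test
  split, as in the workflow this package implements. A consequence,
  measurable on synthetic data: features that pass the screen by chance
  carry genuine test-set signal (they were chosen for their association
  in these very samples) and can receive permutation importances as high
  as truly planted features — and, being rarer, even higher, since the
  importance of 80 redundant signal carriers dilutes. Importance
  contrasts between planted and null features are therefore only
  interpretable against nulls drawn independently of the screen, which is
  how the test suite frames them. On real data this means the network's
  importance ranking inherits the screen's selection noise.
* SMOTER-style target interpolation for continuous traits is an
  interpretation, flagged as such.
* The synthetic corpus's pseudo-language cannot test stemmer behavior on
  real biomedical morphology beyond the injected variants.
* At 36 samples the test set holds 12 samples; Pearson $p < 0.01$ then
  requires $|r| > 0.7$, so single-seed regression metrics are noisy —
  multi-seed summaries are the meaningful quantity.
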