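---
title: "Methods and design choices in mirpanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in mirpanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mirpanel` implements a complete biomarker-discovery workflow for bulk
miRNA-seq case-control studies: detection filtering and reads-per-million
(RPM) normalization, a non-parametric differential screen, logistic
classification with ROC analysis, Monte-Carlo cross-validated PLS-DA panel
evaluation, clustering exports, and miRNA target-set enrichment. This
vignette records the statistical model behind each stage, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical choices that a maintainer would
otherwise have to reverse-engineer from the code.

## 1. The data model and the synthetic generator

The pipeline assumes a features × subjects matrix of non-negative integer
read counts for a two-group cohort. The generator (`sim_counts()`)
produces such matrices from an explicit `sim_design()`:

* Each feature has a baseline log2 expression drawn uniformly from
  `baseline_log_mean_range` (default 4–12, i.e. roughly 16–4,000 RPM).
* Within-group biological variation is Gaussian on the log2 scale with
  standard deviation `log_sd` (default 1, a two-fold SD — typical for
  between-subject variation in biofluid small-RNA data). Count data from
  this model are log-normal, hence right-skewed and non-normal on the raw
  scale, which is why the screen is rank-based.
* An *informative* feature is shifted by `d * log_sd` log2 units in the
  case group, so `d` is exactly the standardized effect size (Cohen's d)
  on the expression scale. The default effect vector has 14 entries with
  magnitudes 0.83–0.97, ten positive and four negative, matching the
  published panel the package is modelled on. Group sizes default to 24
  cases and 21 controls with 246 features.
* Expression is scaled to a per-subject library size drawn uniformly from
  `library_size_range` (default 2–4 million reads) and rounded to integer
  counts. The scaling uses the *expected* total, so counts of different
  features stay independent; dividing counts by the recorded true library
  size recovers the expression scale exactly.

**Dropout.** The detection filter ("present in at least half the
samples") only has work to do if some features genuinely hover below 50%
detection. Uniform per-cell dropout at rate 0.2 cannot produce that — a
feature zeroed independently at 20% per cell is detected in ≥ 23 of 45
samples with near certainty — so `dropout_rate` is implemented as the
*mean* of per-feature zeroing probabilities drawn from Beta(2r, 2(1−r)).
Most features then drop out rarely while a tail of features falls below
the detection threshold (about 30 of 246 under the defaults). Informative
features are exempt from dropout: the generator's contract is that the
sample Cohen's d of an informative feature is an unbiased estimate of the
configured `d`, and zero-inflation would attenuate it. This also reflects
the modelled study, whose panel miRNAs were all robustly detected.

**Compositional effects, deliberately retained.** RPM normalization
divides by the realized column total, which couples features: shifting 14
of 246 features upward in cases slightly deflates every case RPM value.
Under the defaults this attenuates the RPM-scale effect size by about
0.05 SD (measured at n = 500/group) — a real property of
relative-abundance sequencing data, not a bug. The generator's
unbiasedness contract therefore lives on the expression scale (counts
normalized by the *true* library size); the analysis scale inherits the
small compositional shift, exactly as a real cohort would.

**Behavior scores.** `sim_behavior()` attaches age, sex, an ADOS-like
severity score (cases only, mean 10.6, SD 4.1) and four Vineland-style
adaptive-behavior scores with the study's group moments (composite:
controls 105.3 ± 12.7, cases 70.7 ± 10.2). Coupling between miRNAs and
behavior is mediated by one latent severity per subject, *derived* from
the realized informative-feature noise (the direction-aligned mean of
standardized deviations). Each score is
`m_g + s_g(−c·severity + √(1−c²)·ε)` with coupling `c` (default 0.5).
Consequences: features remain conditionally independent given the group
(the generator injects no correlation structure, since the modelled study
reports none); up-regulated informative miRNAs correlate negatively with
behavior scores and down-regulated ones positively, reproducing the
published sign pattern; with a single informative feature and `c = 1` the
within-group Spearman correlation is exactly −1; and with `c = 0` scores
are independent of expression. Pooled across groups, the default coupling
yields composite-score correlations around ±0.4–0.5 for informative
features, the magnitude range the modelled study reports.

**Targets and gene sets.** `sim_target_db()` emulates a target-prediction
export: `k × targets_per_mirna` scored interactions (defaults 14 × 555 =
7,770, matching the published ≈ 7,764) over distinct genes chosen so that
10% of them are hit by two miRNAs (≈ 7,000 distinct targets). Scores are
uniform on 50–100, the confidence range of the emulated database.
`sim_gene_set()` draws a candidate list of exact size `set_size` (default
740) whose membership odds for high-confidence targets versus
non-targets equal `enrichment_factor`, so the downstream Fisher odds
ratio estimates that factor; `enrichment_factor = 1` gives a calibrated
null.

**What a green test does and does not establish.** The generator matches
the modelled study in group sizes, effect-size spectrum, score moments,
non-normality, library-size variation, and detection structure. It does
*not* emulate inter-miRNA correlation blocks, batch or extraction
effects, age/sex confounding, or sequencing-depth-dependent dispersion.
Passing tests establish that the pipeline machinery is correct and that
the published performance figures are attainable under a faithful
independent-feature world — not that the biological findings replicate.
One consequence worth stating plainly: the published per-miRNA effect
sizes were estimated on the same cohort that selected them, so they are
optimistic for fresh data; under honest resampling at those population
effect sizes the joint p < 0.05 / q < 0.15 screen recovers about 6–8 of
the 14 informative features, not all 14. The cross-validated AUC of that
smaller recovered panel nevertheless meets the published 0.92.

## 2. Normalization, filtering, and scales

`rpm_normalize()` scales each subject column to 10^6 (the denominator is
the total of the supplied matrix, i.e. miRNA-mapped reads).
`detection_filter()` keeps features with count > 0 in at least
⌈n/2⌉ samples, pooling groups; "at least half" rounds *up* for odd n,
since rounding down would retain features present in less than half.
"Detected" means a single read — no abundance threshold, because the
modelled protocol states none.

All mean/SD statistics (Z-difference, Cohen's d, logistic and PLS-DA
predictors) use `log2(RPM + 1)`; the pseudocount keeps zeros finite. The
rank-based statistics (Mann-Whitney, Spearman) are invariant to this
monotone transform, so the choice only affects parametric summaries.

## 3. The differential screen

* **Mann-Whitney U** counts pairs with `x > y` plus half the ties, so
  `U/(n1·n2)` is the single-feature ROC AUC (a cross-module identity the
  tests assert to 1e-9). The two-sided p-value uses the normal
  approximation with tie-corrected variance and a 0.5 continuity
  correction; for `n1 + n2 ≤ 12` all C(N, n1) label assignments are
  enumerated and p is the exact probability of a U at least as far from
  n1·n2/2 as observed. Exactness at the default cohort size (C(45,24) ≈
  10^12 assignments) is infeasible and unnecessary.
* **Benjamini-Hochberg** q-values use the step-up rule
  q(i) = min over j ≥ i of m·p(j)/j, capped at 1 (via `stats::p.adjust`,
  verified against a hand step-up in the tests).
* **Effect sizes**: `z_diff` divides the mean difference by the *control*
  SD (a control-referenced Z score); `d` divides by the pooled SD with
  the usual (n−1)-weighted pooling. Zero SDs yield flagged `NA`s, never a
  silent 0.
* **Spearman** correlations are Pearson correlations of midranks over
  pairwise-complete pairs, with a t-approximation p-value on n−2 df.
  Correlations are computed across *all* subjects pooled (a flagged
  choice: the modelled study correlates panel miRNAs with scores spanning
  both groups; within-group correlation is available by subsetting).
* **Selection** requires both p < 0.05 and BH q < 0.15 (strict
  inequalities, per the modelled study's joint statement). The panel is
  returned ordered by p.

Two-sided p-values are used throughout. Under the global null the screen
is calibrated: simulated type-I error at p < 0.05 is 0.05 ± 0.01 and the
p distribution passes a Kolmogorov-Smirnov uniformity check at α = 0.01.

## 4. Logistic classification and ROC

`fit_logistic()` maximizes the Bernoulli likelihood by Newton/IRLS with
step-halving, converging when the relative change in (penalized)
log-likelihood drops below 1e-10 (max 100 iterations). Predictors are
z-scored internally and the coefficients (and their covariance) mapped
back to the original scale; Wald statistics (b/se)² against χ²(1) are
scale-invariant.

With 14 predictors and 45 subjects, perfect separation is near-certain,
and the unpenalized MLE then diverges. The default ridge penalty of 1e-6
on the slopes (never the intercept) yields finite estimates while leaving
non-separable fits numerically unchanged (the tests compare against
`glm` at ridge 0 to 1e-6). With `ridge = 0` on separable data the best
iterate is returned with `converged = FALSE` and an explicit separation
warning. Saturated 2×2 problems reproduce the closed-form log-odds
solution.

`classify()` assigns class 1 when the predicted probability is `>=` the
cutoff (default 0.5) — ties go to the positive class, documented.
`roc_curve()` sweeps every distinct score (plus ±∞ endpoints) and
integrates by the trapezoidal rule, so tied scores contribute half and
the area equals the pair-counting estimate. PPV/NPV are intentionally not
reported: with pre-selected group sizes the prevalence is designed, not
estimated.

## 5. PLS-DA and Monte-Carlo cross-validation

`fit_plsda()` is PLS1 by NIPALS on column-standardized predictors and the
centered 0/1 class code: weights w ∝ X'y, scores t = Xw, deflation of X
and y per component; coefficients are W(P'W)⁻¹q. Score vectors are
orthogonal (asserted to 1e-8); at full rank the fitted values equal
multivariate least squares (asserted to 1e-6); variance explained per
component is t't·p'p over the total standardized X sum of squares,
verified against a projection oracle. Constant columns are scaled by 1
and carry no weight; rank exhaustion reduces the component count with a
warning.

`mccv()` interprets the modelled study's "balanced subsampling" as
class-stratified proportional sampling — `round(2/3·24)` cases and
`round(2/3·21)` controls per training set — because exactly class-equal
thirds do not exist at these sizes (`equal_classes = TRUE` switches to
class-equal draws). Per iteration, the full-panel fit ranks features by
|standardized coefficient|; each panel size k refits the top k with
`min(3, k)` components (three components matching the 3-axis
visualization convention) and predicts the held-out third. The continuous
PLS prediction clipped to [0, 1] serves as the class probability — the
natural reading of a least-squares discriminant used as a classifier.

Reported: the mean of per-iteration held-out AUCs per panel size with a
95% t-interval (the modelled study's "average ROC-AUC"; the pooled AUC of
averaged probabilities is also computed since the original tool's
aggregation is unstated); per-subject probabilities averaged over the
iterations in which the subject was held out, classified at 0.5 into a
confusion table with the misclassified subject list; and the aggregate
importance ranking, summing |b| over iterations — absolute values,
because signed coefficients of anticorrelated features would cancel.
No monotonicity of the AUC-versus-panel-size curve is asserted; at these
sample sizes it is noisy by nature.

Seeding: the master seed spawns one independent substream per iteration,
so results are invariant to the order of `panel_sizes` and reproducible
bit-for-bit. A held-out fold that misses a class (impossible under
stratification, possible with extreme designs) is redrawn and logged.

## 6. Clustering and component exports

`zscore_rows()` standardizes each feature to mean 0, sample (n−1) SD 1 —
the (n−1) convention is stated because the modelled figure caption is
silent on it. Constant rows are dropped with a warning and recorded.
`cluster_features()` is UPGMA (average linkage) on Euclidean distances
via `stats::hclust`, with its deterministic merge order; `merge_table()`
and `dendro_newick()` export the agglomeration. Only features are
clustered (subject-axis clustering is out of scope). `plsda_scores()`
exports per-subject component coordinates and cumulative variance
explained; on the default synthetic panel three components explain
roughly half to two-thirds of the panel variance, bracketing the
published 55% (recorded, not asserted — the value is cohort-specific).

## 7. Target-set enrichment

`top_fraction_filter()` keeps the top `ceiling(fraction · n)` rows per
miRNA (default 20%); ceiling makes "top 20%" inclusive and never empty,
and boundary ties break by score descending then gene id ascending, so
the kept set is deterministic and exactly Σ⌈0.2·n_i⌉ rows.
`fisher_enrichment()` forms the 2×2 table over an explicit gene universe
N — a required, echoed parameter (default 20,000 protein-coding genes)
because the modelled analysis never states its universe and the odds
ratio is undefined without one. It reports the sample odds ratio ad/bc
(Haldane 0.5 correction only when a cell is zero, flagged), a Wald 95% CI
on the log scale, the two-sided exact p by hypergeometric summation of
tables no more probable than the observed one (matching `fisher.test` to
1e-10 and full enumeration for N ≤ 200), and fold enrichment
(a/(a+b))/((a+c)/N), which approaches the odds ratio for rare sets.

## 8. Pipeline orchestration

`run_pipeline()` executes simulate/load → normalize+filter → screen →
classify → cross-validate → cluster → enrich, writing headered TSVs
(metadata as CSV), JSON summaries, a truth record for simulated data, and
a `manifest.json` with per-stage inputs, outputs, parameters, seed and
wall time. Logging goes to standard error; results only to files. A
missing seed is generated and logged, never silently defaulted; under a
fixed seed all outputs except the manifest's wall times are byte-stable.
An empty post-screen panel skips classification and cross-validation with
an explicit manifest notice. `read_run_config()` parses a flat
`key: value` configuration.

## 9. Known limitations

* Independent features are a favorable case for panel classifiers;
  correlated real panels carry less joint information than their marginal
  effect sizes suggest.
* The published per-feature effect sizes are discovery-cohort estimates;
  as noted in §1, fresh-data screens recover smaller panels, and
  cross-validated specificity in the synthetic world averages a few
  points below the published 87.5%.
* The Wald CI for the odds ratio is asymptotic; for very small cells the
  Haldane-corrected estimate is biased and flagged rather than replaced
  by a conditional-MLE estimate.
* The exact Mann-Whitney mode is limited to n1 + n2 ≤ 12 by design;
  beyond that the continuity-corrected approximation is accurate to the
  third decimal at the cohort sizes involved.
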