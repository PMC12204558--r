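---
title: "Methods: leakage-safe cross-validated prediction of spontaneous preterm birth from paired maternal blood transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leakage-safe cross-validated prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Spontaneous preterm birth (sPTB, delivery before 37 weeks after spontaneous
onset of labour) has motivated repeated attempts to find predictive gene
expression biomarkers in maternal whole blood. A typical discovery design
profiles each pregnant subject at two gestational-age windows — T1 (17–23
weeks) and T2 (28–33 weeks) — on a log2 RMA microarray scale, and asks
whether the T1 level, the T2 level, or the within-subject trajectory
dT = T2 − T1 of any gene predicts the outcome. Such datasets combine a small
subject count (order 10^2) with a large gene count (order 10^3–10^4), a
regime in which two methodological failure modes dominate:

* **data leakage** — computing differential expression (or any other
  outcome-informed screen) on the *full* dataset before splitting off a test
  set, so the test partition has already informed feature selection; and
* **overfitting** — flexible models memorizing noise in small training sets,
  visible as a large training/held-out performance gap that only an external
  cohort or a permuted-label control reliably exposes.

`sptbcv` implements the full discovery pipeline for this design — filtering,
repeated-measures moderated differential expression, stepwise feature
selection, five model families, repeated stratified cross-validation with
external validation — *together with* the two probes that make the failure
modes observable: a leakage-prone execution mode and a subject-level
label-permutation control. A synthetic cohort generator with known ground
truth makes every stage testable without any data download.

# The synthetic cohort generator

`simulate_cohort()` draws, per gene, a baseline mean
μ_g ~ U(3, 12) and residual SD σ_g ~ U(0.2, 1.2) (log2 units), with
designated fractions of near-constant (σ < 0.001, 2%), hyper-variable
(σ > 3, 2%) and lowly expressed (baseline below the conventional floor of 5,
5%) genes so that the filtering stage has realistic work to do. Each subject
contributes one T1 and one T2 sample; the paired residuals are bivariate
normal with within-subject correlation ρ (default 0.5), realized as a shared
subject effect: z_t = √ρ·u + √(1−ρ)·e_t. Defaults emulate the structure of
the discovery cohort this design is modelled on: 49 cases / 114 controls,
5,000 genes (scaled down from array scale for desk runtime).

Planted signals (`signal_spec()`) shift case samples additively at T1, at
T2, or — for a differential trajectory — at T2 only, the simplest
realization of a trajectory difference. Effects may be given in absolute
log2 units or as a multiple of the gene's own σ_g. Signals are planted only
in well-expressed regular genes (baseline > 6): a "biomarker" sitting below
the expression floor would be deleted by the pipeline's own low-expression
filter before testing, which is a statement about the filter, not about
recovery. Effect sizes that would push a mean log2 intensity below zero
raise an error; values are never clamped.

`simulate_external_cohort()` reuses the same gene universe, gene parameters
and ground truth but draws new subjects (default 34 cases / 64 controls,
i.e. 98 subjects / 196 samples) and offsets every gene's baseline by an
independent N(0, shift_sd²) location term — a batch/population effect
emulating an external site. The location shift may push lowly expressed
genes toward the floor; it is exempt from the negativity guard.
`permute_labels()` scrambles outcomes at the *subject* level (both samples
of a subject keep one common label), preserving class counts — the unit of
prediction is the subject, so a sample-level scramble would be incoherent.

One root seed drives derived, named child streams (gene parameters, noise,
permutations, fold draws), so e.g. changing the gene count does not perturb
the label permutation.

What the generator does **not** emulate: probe-level effects and
normalization artifacts, gene–gene correlation (genes are independent given
the subject effect), heavy-tailed intensity distributions, and
outcome-dependent covariate structure. Passing tests therefore demonstrate
the *mechanics* of the pipeline and the *direction and rough magnitude* of
leakage/overfitting effects, not their exact size on any real cohort.

# Filtering and differential expression

`filter_genes()` keeps a gene when its SD over all supplied samples lies in
[0.001, 3] and at most 35 samples fall below the expression floor of 5
(`max_low_fraction` offers the 35/240-equivalent fractional rule for resized
folds). Both criteria use all supplied samples — in leakage-safe execution
that is the training fold only, never the full study. Since both timepoints
live in one matrix, a surviving gene automatically has measurements at both
timepoints.

The testing model per gene is a four-cell means model (outcome × timepoint)
fitted by GLS under compound symmetry: each subject's two samples share
correlation ρ̂. Because every subject contributes exactly one sample to each
of its two cells, the GLS cell-mean estimates coincide with ordinary cell
means; the correlation enters the contrast variances — e.g. the trajectory
contrast (case.T2 − case.T1) − (control.T2 − control.T1) has sampling
variance 2(1−ρ)σ²(1/n₁ + 1/n₀), the same value one gets by treating the
per-subject dT as the observation (the paired-difference oracle used in the
tests) — and the residual sum of squares, computed through the 2×2 inverse
correlation block.

The consensus ρ̂ (`estimate_consensus_correlation()`) is the tanh of the
10%-trimmed mean of atanh-transformed per-gene residual correlations,
clipped to [0, 0.99]. This is a deliberate, light-weight alternative to a
REML-based consensus; its contract is parameter recovery (within ±0.05 of
the generating ρ at 120 subjects × 5,000 genes), which the test suite and
the acceptance script verify, and on simulated data it tracks the REML-style
estimate closely (cross-checked in a test).

Residual variances are moderated by an empirical-Bayes scaled
inverse-chi-square prior fitted by method of moments on log variances
(digamma/trigamma matching; the trigamma inverse is a Newton solve).
Posterior variances are (d₀s₀² + d·s²_g)/(d₀ + d) and moderated t statistics
carry d₀ + d degrees of freedom. Underdispersed variance ensembles drive d₀
to infinity (capped at 10⁶, with s₀² = mean(s²)); a non-finite moment
solution disables moderation (d₀ = 0) with a warning.

Five contrasts are tested (case vs control at T1; at T2; T2 vs T1 within
each class; the trajectory contrast), with two-sided t p-values and
Benjamini–Hochberg adjustment. Two points the interface makes explicit:

* The selection rule is stated in the source protocol as a "family-wise
  error rate" threshold but the named procedure is Benjamini–Hochberg, which
  controls the FDR; the named procedure is implemented.
* Whether BH pools the five contrasts into one family is not specified
  anywhere; the default corrects per contrast across genes, with
  `adjust = "pooled"` available.

`select_de_genes()` keeps genes significant in ≥ 1 contrast. The default
criterion is the BH-adjusted p-value at 0.05. The unadjusted-p criterion
(`criterion = "p"`) exists for the null-calibration and leakage experiments:
under a global null the FDR-controlled rule correctly returns an *empty*
set, every iteration degenerates to a no-skill classifier, and the leakage
mechanism has nothing to act on. The lenient screen mirrors the common
discovery practice of carrying forward nominally significant genes and is
what gives the leakage probe a realistic feature pool (~500–800 genes at
5,000 null genes).

# Feature construction and stepwise additive selection

Each selected gene expands to three per-subject base features (T1, T2,
dT = T2 − T1) plus three within-gene interaction candidates (T1·T2, T1·dT,
T2·dT). Pairwise products are generated within genes only: at thousands of
base features, cross-gene pairs would produce millions of candidates with no
protocol statement requiring them. Admitted interaction terms are capped (5
by default).

The stepwise additive selector (`sas_select()`) starts from an empty
logistic model whose AUROC is defined as 0.5, so the first admission
requires a nested-CV AUROC of at least 0.515. Each iteration scores every
remaining candidate by stratified 5-fold nested cross-validation: an
unregularized logistic regression on current features + candidate, fitted
on inner-training rows with inner-training standardization, scored by
validation AUROC, averaged over folds. The best candidate (ties: higher
score, then lexicographic feature id, for determinism) is admitted iff its
score beats the current model's recorded score by ε = 0.015. After a
failed iteration the inner folds are re-drawn — otherwise re-running the
unchanged model could never produce a different outcome and the patience
rule would be vacuous — and selection stops after 3 consecutive failures,
at 30 features, or on pool exhaustion.

At array scale the candidate pool is first screened once — on the supplied
(training) rows only — to the `max_candidates` features with the strongest
single-feature AUROC (default `Inf`, i.e. off; the canned experiments use
40). This is a runtime device that leaves the greedy search itself
unchanged; because the screen itself conditions on the training labels, it
*strengthens* the very selection-bias phenomenon the package studies, and
the null property (the selector admits a small, typically nonzero, number of
noise features) is asserted in the tests with the screen active.

# Model families

Five families sit behind one train/predict contract (`train_model()` /
`predict_scores()`); all except the scale-invariant random forest consume
features standardized with training-row statistics, and constant columns are
dropped with a warning.

* **LR** — unregularized maximum-likelihood logistic regression (iteration
  cap 10,000).
* **LR_reg** — ridge logistic regression; penalty strength tuned by nested
  stratified 5-fold validation AUROC along a glmnet path.
* **LR_ELN** — elastic net; (mixing, strength) tuned likewise over a small
  mixing grid (0.2/0.5/0.8 by default).
* **RF** — random forest; a small grid over mtry and node size (300 trees)
  tuned by nested stratified 5-fold AUROC. Grids are deliberately explicit
  and modest; no grid values are prescribed by the source protocol.
* **MLP** — a two-hidden-layer perceptron written on base-R matrix algebra:
  dense → batch-norm → leaky ReLU (slope 0.01) → dropout, twice, then a
  sigmoid output; binary cross-entropy loss, minibatch Adam with decoupled
  L2 weight decay. Hyperparameters (layer widths 16–256, dropout 0–0.5,
  learning rate 10⁻⁴–10⁻², weight decay 10⁻⁶–10⁻³, batch size 16/32/64) are
  searched by successive halving with reduction factor 4 under an epoch cap
  of 250, scoring by stratified k-fold validation AUROC with lower loss as
  tie-break. The shipped search budget is 20 configurations
  (`paper_scale = TRUE` restores the full-scale 500); the canned experiments
  use 6 with 3 tuning folds, which is ample to exhibit every property the
  package asserts about the family.

`internal_selection_report()` exposes the elastic net's nonzero coefficients
(ranked by |coefficient|) and the random forest's impurity importances. A
forest feature counts as "selected" when its share of total importance
exceeds the uniform share 1/p — an explicit operationalization, since no
selection rule for forests is stated in the source protocol.

# Orchestration, leakage modes and the permutation control

`make_folds()` builds repeated stratified subject-level partitions; the
default 2 × 5 plan yields ten outer iterations (the protocol's "ten folds"
and "2 times five-fold" descriptions conflict; repeated 5-fold matches the
stability-table semantics, and `repeats = 1, k = 10` covers the other
reading). Its printed per-fold sizes are internally inconsistent with both
readings; the stratified integer arithmetic here (test folds of 9–10 cases
and 22–23 controls at 49/114) is used instead.

`run_pipeline()` executes, per outer iteration: filter → consensus
correlation → DE → gene selection → feature construction → stepwise
selection → model training, then scores each family on the training
partition, the held-out partition and the external cohort. In **safe** mode
every stage up to training sees only the training partition. In **prone**
mode, filtering, DE and gene selection run once on *all* subjects before the
loop (optionally the stepwise selection too, `prone_scope = "de_and_sas"`);
everything downstream is unchanged, so the two modes differ only in which
rows inform preprocessing — precisely the leakage being studied. LR, LR_reg
and the MLP consume the stepwise-selected features; the elastic net and
random forest, which select internally, consume the post-DE base feature
space directly. Iterations with zero selected genes or features score as a
constant no-skill classifier (AUROC 0.5) rather than aborting, so null
experiments complete. `leakage_audit()` verifies the safe-mode purity
claim mechanically: grossly perturbing held-out subjects must leave every DE
statistic bit-identical.

Two findings from this package's own null experiments shaped the probe
design, and both are worth knowing when interpreting results:

* **Forward selection masks an upstream leak.** With DE computed on all
  subjects but stepwise selection still confined to training rows, the
  selector re-ranks the leaked gene pool by *training* association, and
  under a global null its choices (and the downstream LR's held-out AUROC,
  ~0.47 in both modes) are nearly unchanged. The inflation appears in the
  families that consume the leak-selected space *directly*: the elastic
  net's internal-test AUROC rises from ~0.56 (safe) to ~0.76 (prone) on
  otherwise identical null cohorts. The leakage experiment
  (`experiment_null_leakage()`) therefore reports the elastic-net contrast
  as its inflation measure, alongside the stepwise LR's external AUROC as
  the null calibration.
* **The permutation control needs a feature space large enough to
  memorize.** Under permuted labels the stepwise selector admits only a
  handful of features, from which no model can memorize 130 subjects. The
  overfitting-signature experiment (`experiment_overfit_signature()`)
  therefore routes the flexible families (RF, MLP) onto the post-DE feature
  space, capped at 99 base features ranked by smallest DE p-value — a
  feature-to-subject regime (p ≈ 100, n ≈ 130) in which both families reach
  training AUROC ≈ 1.0 while held-out AUROC stays at chance. The
  default-routing control remains available via
  `run_pipeline(permute = TRUE)`.

# Evaluation

`auroc()` is the Mann–Whitney pair-counting statistic (ties half),
exactly equal to brute-force pair enumeration and invariant under monotone
score transforms. `confusion_metrics()` derives the
sensitivity/specificity/PPV/NPV/FPR/FNR panel at a score cutoff of 0.5 (the
protocol states no threshold; 0.5 on the probability scale is the neutral
default and is configurable). Zero-denominator ratios are reported as `NA`
and excluded-with-count from aggregation, never silently replaced.
`aggregate_folds()` reports cross-fold means with normal-approximation 95%
intervals (mean ± 1.96·SD/√n_folds; the source tables do not state their CI
construction, so the method is labelled in the output; raw bounds are kept
and a [0,1]-clipped copy provided for display). `stability_summary()`
reproduces the times-selected / average-rank accounting used to compare
selection methods across outer iterations, and `selection_overlap()` the
three-way overlap.

# Numerical and scale choices

* Inner logistic fits in the selector use a dedicated IRLS routine
  (iteration cap 15, linear predictor clamped at ±30): quasi-separation is
  tolerated because only the AUROC *ranking* of candidates matters, not
  coefficient precision. The batch scorer is asserted equal to the
  per-candidate reference implementation to 10⁻¹².
* Batch-norm uses ε = 10⁻⁵ and momentum 0.1; minibatches of size 1 are
  skipped (batch statistics undefined); dropout is inverted.
* The canned experiments run a 1 × 5 fold plan per simulated cohort (the
  pipeline default stays 2 × 5): with 20 cohorts this gives 100 paired fold
  measurements per quantity. Elastic-net mixing is fixed at 0.5 there
  (strength still tuned); the MLP search budget is 6 with 3 tuning folds.
  These are the problem sizes at which all reported quantities are computed.
* All stochastic components consume named child streams of one root seed;
  identical (inputs, config, seed) yield bit-identical reports (timestamps
  aside).

# Known limitations

* The consensus-correlation estimator is a trimmed Fisher-z consensus, not
  REML; its recovery contract is verified on the generator, not proven for
  arbitrary missingness patterns (the package requires complete pairs, as
  the design does).
* BH families, the forest "selected" rule, the classification threshold and
  the CI method are explicit choices where the source protocol is silent;
  each is configurable and labelled in output.
* Synthetic nulls demonstrate mechanism, not clinical effect sizes; nothing
  here should be read as a performance claim about any real cohort.
* Interaction candidates are within-gene products only; the cap of five
  admitted interactions is enforced at admission time.
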