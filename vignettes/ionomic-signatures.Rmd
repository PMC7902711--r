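---
title: "Ionomic signatures of nutrient deficiency: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ionomic signatures of nutrient deficiency: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The ionome — the full mineral-element composition of a tissue — is tightly
regulated but highly plastic: depriving a plant of a single nutrient reshapes
the concentrations of many other elements through shared transporters and
metabolic coupling (Fe starvation de-represses IRT1, which also imports
Ni/Cu/Zn/Co; sulfate transporters carry molybdate and selenate; Na partially
substitutes for K). `ionosig` implements the complete analysis chain used to
exploit this plasticity diagnostically in hydroponic deprivation trials on
rapeseed and wheat: derived nutrient metrics, nonparametric screening,
multiclass PLS-DA classification of deficiency from a 20-element profile, and
the extraction of per-deficiency "ionomic signatures" from variable
importances. A seeded synthetic-data generator reproduces the statistical
structure of such a trial so that every stage is testable without any
external dataset.

## Derived nutrient metrics

**Elemental quantity.** For tissue $i$ at harvest day $D$,
$Q_{iD} = E_{iD} \times DW_{iD}$, with $E$ the concentration (ppm = µg g⁻¹
dry weight) and $DW$ the tissue dry weight (g); $Q$ is in µg. Whole-plant
quantity sums $Q$ over the species' full tissue set (roots, old/young leaf
blades, and for rapeseed old/young petioles); `whole_plant_quantity()`
refuses partial tissue sets rather than silently under-summing.

**Net uptake.** Between an initial harvest and the post-deprivation harvest,
$NU = \sum_i Q_i^{D_{22}} - \sum_i Q_i^{D_0}$ estimated over *all*
subtractive combinations of replicates: each later-harvest replicate minus
each earlier-harvest replicate. With 5 + 5 replicates this gives exactly 25
combinations; the combination mean equals the difference of group means
exactly, so the enumeration adds no bias — it only supplies the dispersion
used for the reported SE (SD of the combinations / √25). That SE is
anti-conservative, since combinations sharing a replicate are correlated; it
is reported in the same spirit as a mean ± SE for n = 25 and should not be
fed into formal inference. The full Cartesian product is used deterministically
(no random subsampling): with 5 × 5 replicates it is exactly the 25
combinations the design implies.

**Relative metrics.** Deprivation effects are expressed as ratios to
control: ratio of class means (not mean of per-replicate ratios, which is
unstable when control replicates are small), with a two-sample Wilcoxon
rank-sum p-value attached. The relative root nutrient content
RRNC = Q(roots)/Q(whole plant) is a unit-free fraction in [0, 1] used as a
proxy for root-to-shoot translocation.

**Relative expression.** qPCR fold changes use the ΔΔCt method:
$\Delta Ct = Ct_{target} - Ct_{ref}$,
$\Delta\Delta Ct = \Delta Ct_{sample} - \Delta Ct_{control}$, expression
$= 2^{-\Delta\Delta Ct}$. When two reference genes are supplied their Ct
values are combined by arithmetic mean before the subtraction — the natural
multi-reference extension of the single-reference formula.

**Display heatmaps.** Class × element ratio matrices are displayed with
cells masked (blank) when the control-vs-deprivation Wilcoxon test is
non-significant, and surviving ratios clipped to [0.2, 5] for a stable
diverging color scale. Masking level defaults to α = 0.05 for concentration
and uptake matrices and α = 0.01 for RRNC. Which rank test produces the mask
is an open choice; the two-sample Wilcoxon control-vs-treatment comparison is
used because the mask is a per-cell two-group contrast. Masking and clipping
are a display layer only: stored ratios are never altered.

## Nonparametric tests

All rank machinery is implemented in the package from first principles
(mid-ranks with tie corrections); base R's `wilcox.test`/`kruskal.test`
appear only as independent oracles in the test suite.

* `kruskal_wallis()` — H with tie correction, χ² reference with k − 1 df.
  All-identical data return H = 0, p = 1 rather than an error.
* `wilcoxon_rank_sum()` — exact two-sided p by complete enumeration of all
  $\binom{n_a+n_b}{n_a}$ rank labelings when the pooled sample is tie-free
  and no larger than 12 (so the trial's 5-vs-5 contrasts always take the
  exact path when tie-free); otherwise a normal approximation with tie and
  continuity corrections. The threshold 12 trades enumeration cost against
  approximation error; at n = 6 + 6 the two paths agree to well within 0.05.
* `dunn_posthoc()` — pairwise z statistics on pooled ranks after a global
  Kruskal-Wallis test. P-values are Holm-adjusted by default: the adjustment
  method is not dictated by the analysis itself, and Holm is uniformly safe;
  `adjust = "none"` recovers unadjusted comparisons.
* `compact_letters()` — insert-and-absorb letter display; two groups share a
  letter iff their comparison is non-significant.

## The PLS-DA engine

Predictors are raw concentrations (ppm), autoscaled to mean 0/SD 1 because
the panel spans five orders of magnitude (N at tens of g kg⁻¹, Se at tens of
ng g⁻¹). The response is the one-hot class indicator matrix, used as-is
(no scaling); because X is centered, centering Y or not provably yields the
same weights, scores and loadings. NIPALS extracts components with weight
tolerance 1e-10 and a 500-iteration cap; on the rare non-convergent component
(the iteration can cycle between near-degenerate eigendirections) the weight
restarts from the dominant eigenvector of X'YY'X, which is the fixed point
the iteration targets. Scores of successive components are orthogonal by
deflation; at full rank the fitted responses coincide with the least-squares
projection of Y onto the column space of X — both properties are enforced in
the test suite against independent oracles, and the fit is cross-checked
against an established PLS implementation to 1e-6.

**Class prediction.** Test samples are projected through the rotation
$R = W(P'W)^{-1}$ and assigned to the nearest training-class centroid in
score space under the Mahalanobis metric, using the pooled within-class
covariance of training scores (ridge-regularized with ε = 1e-8 · trace/A if
singular). Distance ties break to the lexicographically smallest label,
deterministically. Euclidean (`centroid`) and max-response (`max`) metrics
are provided as alternatives; score-space Mahalanobis is the default because
component selection is itself driven by score-space classification error.

**Component selection.** The number of latent components A is chosen by
repeated stratified k-fold cross-validation (default 5-fold × 50 repeats)
minimizing the classification error rate (CER); ties go to the smallest A.
Within each fold the training part is re-autoscaled and a single model with
the largest candidate A is fitted — components are nested, so one fit serves
every truncation. The candidate grid runs to min(n − 1, p): with 20 classes
the discriminative subspace is ~18-dimensional and a tighter cap would
cripple the classifier. With 4 replicates per class in an 80% training set
and 5 folds, fold sizes per class differ by at most one (stratification at
class level; exact balance is impossible).

**VIP.** Global importance of predictor j:
$$VIP_j = \sqrt{p \; \frac{\sum_a SS_a \, (w_{ja}/\|w_a\|)^2}{\sum_a SS_a}},
\qquad SS_a = \sum_k q_{ak}^2 \, t_a't_a,$$
with the identity $\frac{1}{p}\sum_j VIP_j^2 = 1$ holding algebraically for
every fit. The per-deficiency variant restricts $SS_a$ to one response
column ($SS_a^{(k)} = q_{ak}^2 t_a't_a$), giving each class its own
importance profile; this class-restricted form is an interpretation (no
canonical per-class VIP exists), chosen because it reduces exactly to the
global VIP when summed appropriately and preserves the per-column
normalization.

## The evaluation protocol

For one species × tissue stratum at a time (ionomes are strongly tissue- and
species-specific, so strata are never pooled):

1. Split 80/20 into training and test, stratified by class ("keeping the
   class proportions in balance"), 10 times by default.
2. Per split: select A by CV on the training set, fit, and predict the test
   set under four truncation methods —
   **A** all elements; **B** all except each sample's deprived element;
   **C** macronutrients only; **D** the deprived element only.
3. Collect confusion matrices; report accuracy, per-class sensitivity
   (fraction of a deficiency's individuals recovered) and specificity
   (fraction of non-members not attributed to it), averaged arithmetically
   over splits.
4. Compare methods by Kruskal-Wallis + Dunn over the per-split accuracy
   vectors, summarized as compact letters.

Truncation reuses the single method-A model: neutralized predictors are set
to the training mean (exactly 0 after autoscaling), so the model sees "no
information" in them while keeping its dimensionality. This reading is
chosen because the protocol fits one final model and predicts four test-set
variants with it; a retrain-per-method mode (`retrain_per_method = TRUE`) is
provided for comparison. Two edge conventions follow from the definitions:
under B control samples have no deprived element and are left untouched;
under D they are fully neutralized and thus predicted from the grand mean.
Both are interpretations and are documented here rather than hidden.

## Signatures

Per-class VIPs from a model fitted on the *full* stratum (not any single
split — the full-data model gives the most stable importances) are graded at
the conventional thresholds: 0 below 1, then 1 / 1.5 / 2, boundaries
inclusive. Elements at grade ≥ 1 constitute the class's ionomic signature;
classes whose signature set is empty are explicitly reported as having no
specific signature. Signatures are clustered by HCPC: PCA of the VIP matrix
(centered, unscaled) followed by Ward linkage on the retained component
scores. All components are retained by default, making the rotation lossless
so the tree equals Ward.D2 on the raw rows; `n_pcs` and a `min_grade` filter
(clustering only signature-worthy cells) are exposed. Ward.D2 (squared
distances inside the criterion) is used; the classical variant differs only
in height scaling for this use.

## The synthetic generator

The generator emulates the structure the analysis assumes, not any real
dataset:

* **Design** — 20 elements (6 macro, 8 micro, 4 beneficial, plus V and Al
  which are measured but never deprived), 2 control harvests + 18 single
  deprivation classes, 5 replicates, two species with their tissue sets.
* **Effects** — multiplicative fold changes on per-element baselines.
  The deprived element keeps a residual fold of 0.05 (trace contamination
  of water and salts makes true zeros unphysical, and log transforms stay
  finite). Documented crosstalks are encoded as folds of 1.5–3 (the core
  set: −Fe → Ni/Cu/Zn/Co; −Na → root Fe/Cu/Zn/Si; −K → Na; −S → Mo/Se/Cl);
  an extended set with further documented interactions is available via
  `default_effects(crosstalks = "extended")`. All remaining elements carry a
  species-wide bias (0.85 in rapeseed, 1.15 in wheat), reflecting the
  observed overall direction of ionome change in each species.
* **Noise** — log-normal on concentrations (ionome measurements are positive
  and heteroscedastic; no error model is dictated by the data, so the
  multiplicative form is the natural choice), default σ = 0.15 (~15% CV,
  typical of ICP-MS on biological replicates); dry weights analogous with
  σ = 0.08. σ is exposed because within-class variance is a free parameter
  of the emulation.
* **Harvest-day structure** — harvests are discrete class labels (no growth
  model). Control folds are identically 1; the D10 control harvest instead
  carries a developmental-stage multiplier (1.3 on all elements): younger
  plants are more concentrated, and the ionome is known to be growth-stage
  specific. This keeps the two control harvests distinguishable — without
  it they would be statistically identical, which no real trial exhibits.
* **Dry weight** — unaffected by treatment by default (deprivations are
  analyzed before growth effects appear); the one documented exception
  (B deprivation reducing rapeseed root mass) is available as an optional
  template (`b_root_dw = TRUE`).
* **Separability knob** — `strength` scales all log fold changes; method-A
  accuracy rises monotonically with it on average, which the test suite
  checks across seeds.

What the generator does **not** emulate: the rich element-element covariance
of real ionomes (beyond the explicit templates), absolute concentrations
beyond order of magnitude, growth dynamics, transporter kinetics, or
measurement artifacts (drift, detection limits). Passing tests therefore
demonstrate that the pipeline's machinery is correct and calibrated — not
that real deficiencies are classifiable at any particular accuracy; on real
data method B in particular benefits from covariance structure this
generator only sketches.

## Numerical and scale choices

* NIPALS: tol 1e-10, 500 iterations, eigenvector restart on non-convergence.
* Mahalanobis: pooled within-class score covariance, ridge ε = 1e-8·trace/A.
* Exact/approximate Wilcoxon switch at pooled n = 12; continuity correction
  in the approximation.
* Tie-breaks: class prediction → lexicographically smallest label; CV
  component selection → smallest A.
* Degenerate inputs: constant predictors are dropped and recorded by
  `autoscale()`; all-identical samples give H = 0/p = 1; empty confusion
  rows give NA sensitivity (undefined, not zero).
* Test and acceptance problem sizes: the suite exercises the full 20-class
  design with 3 repetitions × 5-fold × 5-repeat CV and 3–5 seeds, and a
  trimmed 7-class/2-tissue design for the faster structural checks; these
  sizes give stable Monte-Carlo estimates while keeping the suite quick.
  The defaults of `run_protocol()` (10 repetitions, 5 × 50 CV) match the
  full published protocol and remain the recommendation for real analyses.

## Known limitations

* The NU standard error treats the 25 subtractive combinations as a sample;
  it is descriptive, not inferential.
* Per-class VIP is one of several defensible definitions; signatures should
  be read as rankings, not calibrated effect sizes.
* Method B/D semantics for control samples are conventions (see above).
* Cross-dataset prediction (training on one trial, predicting another with a
  shared element subset) is supported generically through model
  serialization plus mean-neutralization of missing predictors, but no
  external dataset ships with the package.
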