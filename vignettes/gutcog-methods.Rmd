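---
title: "Methods: models, parameters and design choices in gutcog"
author: "gutcog authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in gutcog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutcog)
```

# Scope and scientific setting

gutcog packages the statistical machinery of a gut-brain-axis case-control
study: an elderly cohort split into dementia cases and matched controls,
serum acylated (AG) and unacylated (UAG) ghrelin, cognitive instruments
(MMSE, MoCA, GADL, HADS), and a 16S-derived species-level OTU table for a
subset of subjects. The package starts downstream of sequencing: read QC,
OTU picking and taxonomy assignment are out of scope; the entry point is a
species count table plus a clinical table.

Because raw cohorts of this kind are rarely deposited, the package treats
its synthetic-cohort generator as a first-class module: every analysis
stage is validated against data with planted, known structure.

# The synthetic cohort generator

`generate_cohort()` draws, per subject:

* **Latent factor block.** Two independent standard-normal factors; each
  indicator is `loading × factor + residual`, with residual sd
  `sqrt(1 − loading²)` so indicators have unit variance and fitted
  standardized loadings are directly comparable to the planted ones. The
  binary outcome arises from a latent logistic threshold on
  `e₁f₁ + e₂f₂`. Group membership (case/control) is tied to this outcome
  by ranking subjects on the latent linear predictor plus logistic noise
  and labelling the top `n_case` as cases: group sizes stay exact (40 +
  40 by default) while the factor-outcome association is preserved.
* **Hormones.** AG is lognormal, calibrated so the control mean is
  0.58 ng/mL (sdlog 0.45), with the case group shifted by
  `ag_effect_size` standard deviations on the log scale; the default
  0.631 is the effect size of the cohort's power calculation, giving the
  two-sample design 80% power at n = 40/group. UAG (mean 0.02 ng/mL) and
  insulin carry no group effect, mirroring the null findings they stand
  for.
* **Cognitive scores.** Normal draws with group-specific means chosen at
  clinically typical magnitudes (e.g. MMSE 28.5 vs 19.5), truncated to
  the instrument ranges (MMSE/MoCA 0–30). Truncation, not resampling:
  boundary mass is acceptable for score-like variables.
* **Microbiome.** The compositional generator is logistic-normal /
  multinomial — exactly the model under which SparCC's basis correlation
  is the recoverable target. Log-basis abundances are multivariate normal
  with unit variances and a correlation matrix carrying a handful of
  planted pairs (positive-definiteness is checked and a violation names
  the planted pairs); softmax closes each sample to proportions;
  multinomial sampling at `sequencing_depth` (default 295,684 reads, a
  typical MiSeq per-sample yield at this cohort's scale) produces counts.
  Baseline mean log-abundances are N(0, 1.5²) draws, giving the skewed
  rank-abundance profile of real stool communities; differential taxa add
  case-specific log-fold-changes (defaults span −1.9 to +2.2 across five
  species).

A fixed seed makes the cohort byte-identical across runs (base R
Mersenne-Twister; all internal seeds derive from the config seed).

What the generator does **not** emulate: phylogenetic structure,
zero-inflation beyond what the logistic-normal induces, sequencing error,
batch effects, covariance between the factor block and the microbiome
block, and age-matching structure. Passing recovery tests on these
cohorts therefore shows the estimators are correct under their own
generative assumptions — not that any real cohort satisfies those
assumptions. At the study's microbiome scale (9 + 9 samples) the default
planted fold-changes frequently do not reach beta-diversity significance;
this is a faithful property of small-n designs, not a defect.

# Clinical statistics

The AAGR is implemented verbatim as `6 + log10(AG/UAG) − age/10`, with
base-10 log and the additive constant 6. Group comparisons default to
Welch's t (robust to variance heterogeneity; the pooled-variance Student
test and Wilcoxon rank-sum are exposed too, since the cohort literature
uses both). The rank test is exact — full permutation distribution — when
both groups have ≤ 8 untied observations; beyond that the normal
approximation is used. All tests are two-sided at α = 0.05.

Power for the two-sample design uses the noncentral t directly:
df = 2n − 2, noncentrality d√(n/2), and *both* rejection tails, so d = 0
returns exactly α. (The common one-tail approximation returns α/2 at the
null; away from the null the two agree to ~10⁻⁴.)

# Diversity and its decomposition

"Simpson diversity" is implemented as Gini-Simpson (1 − Σp²), the variant
most alpha-diversity toolkits report; Pielou is undefined (NA) when
richness is 1 and is excluded pairwise from group tests. Bray-Curtis and
the alpha indices delegate to vegan.

PERMANOVA is the one-way distance-based pseudo-F with free label
permutations. When the number of distinct group assignments (the
multinomial coefficient) is ≤ 10,000 the p-value is computed by complete
enumeration and is exact; otherwise 999 seeded permutations with the
(count + 1)/(n + 1) estimator. The same dual path drives the Mantel test
(exhaustive for n ≤ 7). PCoA reports negative eigenvalues unchanged — no
Lingoes/Cailliez correction — and axis proportions relative to the sum of
positive eigenvalues.

SIMPER uses the pairwise definition: species i contributes
`mean over between-group pairs of |xᵢ − yᵢ| / Σⱼ(xⱼ + yⱼ)`, which sums
across species to the mean between-group Bray-Curtis exactly (an identity
the tests verify to 10⁻⁹). Percentages are reported as percent of total
dissimilarity plus a cumulative column. Published SIMPER tables sometimes
print per-species percentages that sum past 100; no standard definition
reproduces such numbers, so this package commits to the percent-of-total
convention and documents it.

Top-15 core-microbiota ranking uses the overall (not per-group) mean
relative abundance, with lexicographic tie-breaks for determinism. Both
filtration boundaries are strict inequalities ("more than 10", "> 1%").

# SparCC and the co-occurrence networks

SparCC works from log-ratio variances t(i,j) = var log(xᵢ/xⱼ), which are
invariant to the compositional closure, and solves for basis variances
under the sparsity assumption that average basis correlations vanish.
The implementation follows the classic scheme: fractions estimated with a
unit pseudocount ((count+1)/(total+D) point estimate on the first pass,
Dirichlet(count+1) resamples on the remaining passes), basis variances
from the linear system, correlations clipped to [−1, 1], and iterative
exclusion of the single strongest pair above |r| = 0.1 (up to 10 rounds)
so that strong true correlations do not bias the basis solution. Twenty
passes are aggregated by the elementwise median. Resampling draws are
made in sorted sample-label order, which makes the estimate invariant to
the column order of the input.

A sampling caveat worth stating precisely: with D = 30 taxa there are 435
pairs, and each correlation estimate carries ≈ 1/√n sampling noise. At
n = 200 that is ≈ 0.07 per pair, so the *maximum* absolute null
correlation concentrates near 3 sd ≈ 0.21 — for any consistent
estimator, not just SparCC. Null behaviour should therefore be judged by
the bulk of the distribution (mean |r| ≈ 0.05, 95th percentile < 0.15),
not its extreme order statistic.

Networks keep taxa with total abundance strictly > 10 and edges with
|r| ≥ 0.3; the paper trail behind that toolkit-typical threshold is thin,
so it is an exposed config value, not a constant. Louvain runs on
|weight|-weighted graphs (a signed-modularity treatment is out of scope)
with resolution 1.0 and a fixed seed for determinism. A community's
maximum-degree node represents it only if that node ranks in the global
top 20 by degree — communities of low-degree taxa go unlabelled, matching
how such networks are reported. Keystone screening differences normalized
degree centralities (degree/(n−1), each on its own network; absent taxa
count 0) as control − case, and flags outliers with Tukey fences at
1.5 × IQR — the rule is a pluggable function argument.

# Association screens

Mantel correlates the lower-triangle vectors of the species Bray-Curtis
matrix and the Euclidean distance matrix of z-scored clinical variables
(standardization is a documented choice: the clinical variables span
incommensurate scales). The p-value is one-sided (greater), the vegan
convention. Both r and r² are reported, since r² alone loses the sign.
No multiple-testing correction is applied to the many species × clinical
screens — mirroring field practice — but a Benjamini-Hochberg column is
emitted alongside for the reader.

The OLS screen keeps (species, clinical) pairs with R² strictly > 0.55
and p < 0.05. ROC analysis uses the Mann-Whitney AUC (ties count ½),
which equals the trapezoidal area under the empirical curve, and applies
the fixed decision cutoffs — 0.65 for clinical features, 0.70 for
microbial features — as strict inequalities when asked for sensitivity
and specificity at a cutoff.

# The MLP classifier

The architecture is deliberately small: one hidden layer of 16 ReLU
units, sigmoid output, binary cross-entropy, full-batch ADAM (lr 0.01,
β₁ 0.9, β₂ 0.999), at most 500 epochs with early stopping (patience 25)
on validation loss, keeping the best-validation weights. All of it is
exposed in the call signature. Splits are stratified 60/20/20 after
shuffling; scaling statistics come from the training split only and are
applied unchanged to validation and test, so test metrics never touch
training information. Feature contributions are permutation importances:
mean test-accuracy drop over 50 column permutations, floored at zero and
normalized to sum to 100% — a model-agnostic artifact with the same shape
as additive-attribution outputs, not the same algorithm. On 100%-accurate
fixtures many permutations leave accuracy unchanged, so contributions
concentrate on the features whose destruction actually breaks the
classifier.

# The two-latent-variable structural model

The measurement model loads each indicator on exactly one of two factors;
the binary dementia indicator enters the same covariance structure with a
"loading" row (b₁, b₂) — its regression on both factors. With factor
variances fixed at 1 and the factor correlation φ free, the implied
covariance is Σ(θ) = ΛΦΛ' + Θ. Parameters minimise the ML discrepancy
F = log|Σ| + tr(SΣ⁻¹) − log|S| − m by BFGS with three jittered starts
(flat regions and local minima are real risks at small n); residual
variances are log-parameterised and φ tanh-parameterised to stay in
bounds. Non-convergence is flagged on the returned object, never hidden.

Treating the binary outcome as numeric 0/1 under ML is an explicit
approximation (the categorical treatment would use weighted least squares
on polychoric/polyserial moments, out of scope here). Its observable
consequence is attenuation of the structural coefficients toward zero;
recovery tests therefore check signs and significance patterns, not the
magnitudes of b₁, b₂. Loadings are unaffected and are recovered within
±0.10 at n = 2000.

Fit statistics: χ² = (n−1)F at the optimum; df = m(m+1)/2 − the free
parameter count; GFI = 1 − tr[(Σ⁻¹S − I)²]/tr[(Σ⁻¹S)²]; CFI against the
independence baseline, clamped to [0, 1]. Factor-sign indeterminacy is
resolved by making the first indicator loading of each latent positive.
Factor scores use the regression method, ΦΛ'Σ⁻¹(z − mean), over all
observed model variables; over the fitting sample they are mean-zero by
construction. Indicator pruning refits after dropping the weakest
indicator (Wald p ≥ 0.05 or |standardized loading| < 0.2, weakest first
by Wald z) and halts, with a warning, before any latent would fall below
two indicators.

Two identifiability notes. First, when all loadings are truly zero the
individual loadings are not identified: a unit loading with zero residual
variance reproduces an identity covariance exactly as well as a zero
loading, and ML can return any point on that ridge. The identified null
quantity is the implied covariance between distinct observed variables,
which the tests check instead. Second, the package's fixed two-factor
surface (≥ 2 indicators per latent plus the outcome) never reaches df = 0,
so saturated-model checks are expressed as "fit indices match a
brute-force discrepancy evaluation at the returned parameters".

# Pipeline orchestration

`run_pipeline()` executes the stages in dependency order, records a
failed stage's error and skips its dependents, and writes every section
as TSV/JSON plus a manifest carrying an md5 hash of the analytic config
(output paths excluded) — a directory holding a different hash is refused
unless forced. Identical config + seed reproduces identical outputs. The
AG subgroup analysis strata are "> 1 ng/mL" vs "≤ 1 ng/mL": the boundary
value goes to the low stratum, a documented resolution of the open
boundary, and undersized strata skip the comparison with a warning. The
package's interface is its functions plus this config layer; no shell
entry point is provided because its users drive analyses from R.

# Validation problem sizes

The suite validates at sizes chosen to make the statistics sharp but the
run cheap: null calibrations over 200 replicates (rejection rates within
5% ± 3%), SparCC recovery at 30 taxa × 200 samples × 5×10⁴ reads,
factor-model recovery at n = 2000 and the study-scale lv2-pattern check
over 20 seeds at n = 80, SIMPER identities over 100 random tables, and
exhaustive-enumeration equivalence at 3 + 3 (PERMANOVA) and n = 4
(Mantel). `scripts/acceptance.R` re-runs the same computations from
scratch under a caller-supplied seed.

# Known limitations

* SparCC edge significance (bootstrap p-values) is not implemented; edge
  selection is by magnitude only.
* The structural model fits one fixed topology (two latents, simple
  structure, one binary outcome) — it is not a general SEM engine.
* PERMANOVA is one-way only; no strata or multi-factor designs.
* The MLP is full-batch and single-output; it is sized for cohort-scale
  tabular data, not larger feature spaces.
* Synthetic cohorts make no attempt to reproduce any particular study's
  printed tables — they emulate magnitudes, not data.
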