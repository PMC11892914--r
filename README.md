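# gutcog

Analysis toolkit for gut-brain-axis cohort studies that relate the fecal
microbiome, circulating acylated ghrelin and cognitive status in older
adults. It implements, as one tested R pipeline, the mixed-method analysis
typically applied to a dementia case-control cohort with a 16S microbiome
subset:

- **Ghrelin indices and clinical comparisons.** The acylated/unacylated
  ghrelin ratio and the age-adjusted ghrelin ratio,
  `AAGR = 6 + log10(AG/UAG) − age/10` (AG, UAG in ng/mL, age in years),
  with Welch/Student t and exact Wilcoxon rank-sum comparisons, and the
  two-sided noncentral-t power calculation for a two-sample design
  (d = 0.631 at n = 40/group gives 80% power).
- **OTU processing.** Species-table filtering (total count strictly > 10),
  per-sample relative abundance, the abundance-vs-incidence summary of the
  top-15 core microbiota (incidence = share of a group's samples with
  abundance strictly > 1%), and the natural-log Firmicutes/Bacteroidetes
  ratio.
- **Diversity.** Richness, Shannon, Gini-Simpson and Pielou alpha indices;
  Bray-Curtis dissimilarity `BC(x,y) = Σ|xᵢ−yᵢ| / Σ(xᵢ+yᵢ)`; PCoA
  ordination; one-way PERMANOVA with exact enumeration for small designs;
  and a SIMPER decomposition whose per-species contributions sum exactly
  to the mean between-group dissimilarity.
- **Co-occurrence networks.** SparCC basis-correlation inference for
  compositional counts (log-ratio variances, iterative exclusion of
  strongly correlated pairs, median over 20 Dirichlet-resampled passes),
  signed networks at |r| ≥ 0.3 over taxa with total abundance > 10,
  Louvain communities, representative species per community (top-20 rule),
  and keystone detection by differencing normalized degree centralities
  between the control and case networks with Tukey-fence outlier flagging.
- **Association screens.** Mantel tests between the Bray-Curtis matrix and
  Euclidean distances on z-scored clinical variables (exact for n ≤ 7),
  per-species OLS screens retained at R² > 0.55 and p < 0.05, and
  empirical ROC/AUC with the study's decision cutoffs (0.65 clinical,
  0.70 microbial).
- **Classifier.** A multilayer perceptron (ReLU hidden layer, sigmoid
  head) trained with ADAM on binary cross-entropy, stratified 60/20/20
  train/validation/test splits with train-only scaling, early stopping on
  validation loss, and permutation-based feature contributions normalized
  to 100%.
- **Two-latent-variable structural model.** A confirmatory two-factor
  model in which lv1 and lv2 carry opposite-signed effects on the binary
  dementia indicator: maximum-likelihood covariance fit, χ²/df, GFI and
  CFI, Wald-based indicator pruning, regression-method factor scores, and
  Wilcoxon comparison of scores between groups.
- **Synthetic cohorts.** Because cohort data of this kind are rarely
  deposited, a first-class generator produces clinical tables with
  group-shifted lognormal hormones, instrument-bounded cognitive scores,
  logistic-normal/multinomial OTU counts with planted basis correlations
  and differential taxa, and a planted two-factor structure — with the
  ground truth returned for recovery testing.

## Worked example

```r
library(gutcog)

cohort <- generate_cohort(cohort_config(seed = 42))
cohort
#> Synthetic cohort: 80 subjects ( 40 control / 40 dementia ), 18 microbiome samples, 53 taxa

idx  <- ghrelin_indices(cohort$clinical$AG, cohort$clinical$UAG,
                        cohort$clinical$age)
ctrl <- cohort$clinical$group == "control"
compare_groups(idx$aagr[ctrl], idx$aagr[!ctrl])
#> welch_t: statistic = -1.559, p = 0.123 (n = 40 vs 40)

filt <- filter_by_total(cohort$otu, 10)
bc   <- bray_curtis_matrix(filt)
permanova(bc, filt$sample_group, n_perm = 999, seed = 42)
#> PERMANOVA: pseudo-F = 1.095, R2 = 0.064, p = 0.336 (sampled, 999 permutations)

head(simper(relative_abundance(filt), filt$sample_group), 3)
#> SIMPER decomposition; mean between-group Bray-Curtis = 0.3584
#>                 species contribution percent cumulative_percent ...
#> 1    Clostridium_leptum      0.11756  32.803              32.80
#> 2 Bacteroides_eggerthii      0.04385  12.236              45.04
#> 3      Escherichia_coli      0.02452   6.842              51.88
```

Reading the numbers: the AAGR comparison at this seed lands at p = 0.12 —
the planted log-AG shift (d = 0.631) gives the design 80% power, so about
one replicate in five misses at α = 0.05, and the age term adds noise on
top. The PERMANOVA R² of 0.064 says group membership explains ~6% of the
Bray-Curtis variation among the 18 microbiome samples; with 9 + 9 samples
and moderate planted fold-changes this is usually not significant. The
SIMPER table attributes the 0.358 mean between-group dissimilarity to
individual species; the `percent` column sums to 100 and `contribution`
sums to the overall dissimilarity exactly.

The whole analysis — clinical table, diversity, networks, screens,
classifier, structural model — runs end-to-end from one config:

```r
report <- run_pipeline(run_config(seed = 42, out_dir = "out"))
report$latent_model$comparison   # Wilcoxon on lv1/lv2 factor scores
```

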