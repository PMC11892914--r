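# Synthetic two-group cohort generator.
#
# Emulates the statistical structure every downstream stage assumes: a
# case/control clinical table with group-shifted lognormal acylated ghrelin,
# instrument-bounded cognitive scores, compositional OTU counts from a
# logistic-normal/multinomial model with planted basis correlations and
# differential taxa, and a two-latent-factor indicator block driving group
# membership. Planted parameters are returned as a `truth` record so
# recovery can be tested.

default_taxa <- function() {
  firm <- c("Faecalibacterium_prausnitzii", "Clostridium_perfringens",
            "Blautia_obeum", "Blautia_producta", "Eubacterium_biforme",
            "Eubacterium_rectale", "Lactobacillus_ruminis",
            "Ruminococcus_bromii", "Ruminococcus_gnavus",
            "Streptococcus_anginosus", "Streptococcus_salivarius",
            "Dorea_formicigenerans", "Dorea_longicatena", "Roseburia_faecis",
            "Roseburia_intestinalis", "Veillonella_dispar",
            "Coprococcus_comes", "Coprococcus_eutactus", "Clostridium_leptum",
            "Clostridium_celatum", "Oscillospira_guilliermondii",
            "Dialister_invisus", "Megasphaera_elsdenii",
            "Phascolarctobacterium_faecium", "Anaerostipes_hadrus",
            "Eubacterium_dolichum", "Lachnospira_pectinoschiza",
            "Faecalibacterium_sp", "Ruminococcus_torques",
            "Ruminococcus_callidus", "Streptococcus_thermophilus",
            "Lactobacillus_mucosae", "Catenibacterium_mitsuokai",
            "Holdemania_filiformis")
  bact <- c("Prevotella_copri", "Prevotella_stercorea",
            "Bacteroides_eggerthii", "Bacteroides_fragilis",
            "Bacteroides_uniformis", "Bacteroides_ovatus",
            "Bacteroides_caccae", "Parabacteroides_distasonis",
            "Alistipes_putredinis", "Prevotella_melaninogenica")
  actino <- c("Bifidobacterium_longum", "Bifidobacterium_adolescentis",
              "Collinsella_aerofaciens", "Collinsella_stercoris",
              "Eggerthella_lenta")
  proteo <- c("Escherichia_coli", "Sutterella_wadsworthensis",
              "Haemophilus_parainfluenzae")
  verruco <- "Akkermansia_muciniphila"
  data.frame(
    taxon = c(firm, bact, actino, proteo, verruco),
    phylum = c(rep("Firmicutes", length(firm)),
               rep("Bacteroidetes", length(bact)),
               rep("Actinobacteria", length(actino)),
               rep("Proteobacteria", length(proteo)),
               rep("Verrucomicrobia", length(verruco))),
    stringsAsFactors = FALSE)
}

default_basis_correlation <- function() {
  list(list("Prevotella_copri", "Prevotella_stercorea", 0.6),
       list("Bifidobacterium_longum", "Bifidobacterium_adolescentis", 0.5),
       list("Faecalibacterium_prausnitzii", "Ruminococcus_bromii", 0.5),
       list("Eggerthella_lenta", "Blautia_producta", 0.45),
       list("Prevotella_melaninogenica", "Bacteroides_fragilis", -0.4))
}

default_differential_taxa <- function() {
  # case-vs-control log-fold-changes on the log-basis scale, magnitudes in
  # line with the abundance contrasts typical of dysbiosis studies
  c(Prevotella_copri = -0.7, Bifidobacterium_longum = 2.2,
    Eubacterium_biforme = -1.9, Lactobacillus_ruminis = 0.3,
    Faecalibacterium_prausnitzii = -0.5)
}

default_factor_loadings <- function() {
  list(lv1 = c(ind_F_prausnitzii = 0.61, ind_C_perfringens = 0.95),
       lv2 = c(ind_E_lenta = 0.66, ind_B_eggerthii = 0.93,
               ind_B_producta = 0.74, ind_age = 0.34, ind_AG = 0.63))
}

#' Configuration of a synthetic cohort
#'
#' Bundles every knob of the generator with validation. Defaults describe a
#' two-group cohort of 40 + 40 subjects with 9 + 9 microbiome samples,
#' 53 retained species, a per-sample sequencing depth of 295,684 reads, a
#' 0.631 standardized shift in log acylated ghrelin, a handful of planted
#' basis correlations and differential taxa, and a two-latent-factor block
#' with opposite-signed effects (+1.55 / -1.31) on the binary outcome.
#'
#' @param n_control,n_case subjects per group (> 0).
#' @param n_microbiome_per_group microbiome subset size per group.
#' @param age_range low/high age in years.
#' @param ag_effect_size Cohen's d of the group shift on log-AG.
#' @param n_taxa number of taxa (default 53; at least 4).
#' @param sequencing_depth reads per sample (> 0).
#' @param basis_correlation list of planted pairs `list(taxon_a, taxon_b, r)`
#'   with |r| < 1.
#' @param differential_taxa named vector of case-vs-control log-fold-changes.
#' @param factor_loadings list with named loading vectors `lv1`, `lv2`.
#' @param structural_effects length-2 vector (lv1 and lv2 effects on the
#'   outcome's latent linear predictor).
#' @param noise_sd optional fixed residual sd per factor indicator (default:
#'   `sqrt(1 - loading^2)`, giving unit-variance indicators).
#' @param seed integer seed; a fixed seed makes the cohort byte-identical
#'   across runs.
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 40, n_case = 40,
                          n_microbiome_per_group = 9,
                          age_range = c(60, 85),
                          ag_effect_size = 0.631,
                          n_taxa = 53,
                          sequencing_depth = 295684,
                          basis_correlation = default_basis_correlation(),
                          differential_taxa = default_differential_taxa(),
                          factor_loadings = default_factor_loadings(),
                          structural_effects = c(lv1 = 1.55, lv2 = -1.31),
                          noise_sd = NULL,
                          seed = 1L) {
  if (n_control <= 0 || n_case <= 0) stop("group sizes must be positive")
  if (n_microbiome_per_group <= 0 ||
      n_microbiome_per_group > min(n_control, n_case))
    stop("invalid n_microbiome_per_group")
  if (n_taxa < 4) stop("need >= 4 taxa")
  if (sequencing_depth <= 0) stop("sequencing depth must be positive")
  for (p in basis_correlation)
    if (abs(p[[3]]) >= 1)
      stop("planted correlation for (", p[[1]], ", ", p[[2]],
           ") must satisfy |r| < 1")
  if (any(abs(unlist(factor_loadings)) > 1.5))
    stop("|factor loadings| must be <= 1.5")
  structure(list(n_control = n_control, n_case = n_case,
                 n_microbiome_per_group = n_microbiome_per_group,
                 age_range = age_range, ag_effect_size = ag_effect_size,
                 n_taxa = n_taxa, sequencing_depth = sequencing_depth,
                 basis_correlation = basis_correlation,
                 differential_taxa = differential_taxa,
                 factor_loadings = factor_loadings,
                 structural_effects = structural_effects,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

# planted-pair list -> full correlation matrix (unit diagonal)
basis_correlation_matrix <- function(taxa, pairs) {
  d <- length(taxa)
  r <- diag(d)
  dimnames(r) <- list(taxa, taxa)
  for (p in pairs) {
    a <- p[[1]]; b <- p[[2]]
    if (!(a %in% taxa) || !(b %in% taxa)) next
    r[a, b] <- r[b, a] <- p[[3]]
  }
  ok <- tryCatch({chol(r); TRUE}, error = function(e) FALSE)
  if (!ok)
    stop("basis correlation matrix not positive definite; offending pairs: ",
         paste(vapply(pairs, function(p) paste0("(", p[[1]], ",", p[[2]], ")"),
                      character(1)), collapse = " "))
  r
}

#' Generate compositional OTU counts (logistic-normal / multinomial)
#'
#' Log-basis abundances are drawn from a multivariate normal with unit
#' variances and correlation `basis_corr` around `mean_logs`, closed to
#' proportions by softmax, and sampled as multinomial counts at the given
#' depth. This is exactly the generative model under which SparCC's basis
#' correlations are the recoverable target.
#'
#' @param basis_corr symmetric positive-definite correlation matrix
#'   (>= 4 taxa).
#' @param mean_logs per-taxon mean of the log-basis abundance.
#' @param n_samples number of samples.
#' @param depth reads per sample (>= 1).
#' @param seed integer seed.
#' @param sample_prefix prefix for generated sample ids.
#' @param phylum optional phylum annotations.
#' @return an [otu_table()].
#' @export
generate_compositional_counts <- function(basis_corr, mean_logs, n_samples,
                                          depth, seed = 1L,
                                          sample_prefix = "S",
                                          phylum = NULL) {
  basis_corr <- as.matrix(basis_corr)
  d <- nrow(basis_corr)
  if (d < 4) stop("need >= 4 taxa")
  if (depth < 1) stop("depth must be >= 1")
  if (max(abs(basis_corr - t(basis_corr))) > 1e-10)
    stop("basis_corr must be symmetric")
  stopifnot(length(mean_logs) == d)
  set.seed(seed)
  logs <- MASS::mvrnorm(n_samples, mu = mean_logs, Sigma = basis_corr)
  if (n_samples == 1) logs <- matrix(logs, 1)
  # softmax closure per sample
  props <- exp(logs - apply(logs, 1, max))
  props <- props / rowSums(props)
  counts <- apply(props, 1, function(p) stats::rmultinom(1, depth, p))
  rownames(counts) <- if (!is.null(rownames(basis_corr)))
    rownames(basis_corr) else paste0("taxon_", seq_len(d))
  colnames(counts) <- paste0(sample_prefix, seq_len(n_samples))
  otu_table(counts, phylum = phylum)
}

# truncate to an instrument range
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a latent two-factor indicator block
#'
#' Two independent standard-normal factors; each indicator is
#' `loading * factor + residual`, residual sd `sqrt(1 - loading^2)` by
#' default (unit-variance indicators, so fitted standardized loadings are
#' directly comparable to the planted ones). The binary outcome is 1 when
#' `e1 * f1 + e2 * f2 + logistic noise > 0`.
#'
#' @param loadings list of named loading vectors `lv1`, `lv2`
#'   (|loading| <= 1.5).
#' @param structural_effects length-2 numeric (lv1, lv2 effects).
#' @param n subjects; must exceed the free-parameter count of the matching
#'   two-factor model.
#' @param seed integer seed.
#' @param noise_sd optional fixed residual sd for every indicator.
#' @return list: `data` (data.frame of indicators + `outcome`), `truth`
#'   (factors and planted parameters).
#' @export
generate_factor_cohort <- function(loadings, structural_effects, n,
                                   seed = 1L, noise_sd = NULL) {
  l1 <- loadings$lv1; l2 <- loadings$lv2
  if (any(abs(c(l1, l2)) > 1.5)) stop("|loadings| must be <= 1.5")
  p <- length(l1) + length(l2)
  nfree <- p + 2 + 1 + (p + 1)
  if (n <= nfree)
    stop("n (", n, ") too small: must exceed ", nfree, " free parameters")
  set.seed(seed)
  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  gen_ind <- function(lam, f) {
    sds <- if (is.null(noise_sd)) sqrt(pmax(1 - lam^2, 0.05)) else
      rep(noise_sd, length(lam))
    sapply(seq_along(lam), function(j)
      lam[j] * f + stats::rnorm(n, sd = sds[j]))
  }
  x1 <- gen_ind(l1, f1); x2 <- gen_ind(l2, f2)
  colnames(x1) <- names(l1); colnames(x2) <- names(l2)
  eta <- structural_effects[1] * f1 + structural_effects[2] * f2
  outcome <- as.integer(eta + stats::rlogis(n) > 0)
  data <- data.frame(x1, x2, outcome = outcome)
  list(data = data,
       truth = list(f1 = f1, f2 = f2, eta = eta, loadings = loadings,
                    structural_effects = structural_effects))
}

#' Generate a full synthetic cohort
#'
#' Produces the clinical table (demographics, hormones, cognitive scores,
#' latent-factor indicator block), the compositional OTU table for the
#' microbiome subset, and a `truth` record of every planted parameter.
#'
#' Group membership is tied to the latent structure: subjects are ranked by
#' the latent linear predictor plus logistic noise and the top `n_case`
#' become cases, keeping the group sizes exact while preserving the
#' factor-outcome association. Acylated ghrelin is lognormal with a group
#' shift of `ag_effect_size` standard deviations on the log scale;
#' cognitive scores are normal, truncated to their instrument ranges
#' (MMSE, MoCA 0-30). OTU counts come from
#' [generate_compositional_counts()] with group-specific mean
#' log-abundances for the differential taxa.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort`: `clinical` (data.frame),
#'   `otu` (an [otu_table()] over the microbiome subset), `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_control + config$n_case
  set.seed(config$seed)
  # latent-factor block drives group membership
  fac <- generate_factor_cohort(config$factor_loadings,
                                config$structural_effects, n,
                                seed = config$seed + 1L,
                                noise_sd = config$noise_sd)
  set.seed(config$seed + 2L)
  score <- fac$truth$eta + stats::rlogis(n)
  group <- rep("control", n)
  group[order(-score)[seq_len(config$n_case)]] <- "dementia"
  is_case <- group == "dementia"
  age <- round(stats::runif(n, config$age_range[1], config$age_range[2]))
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.66, 0.34))
  # hormones: lognormal, calibrated to control means AG 0.58 / UAG 0.02
  sdlog_ag <- 0.45
  mu_ag <- log(0.58) - sdlog_ag^2 / 2
  ag <- stats::rlnorm(n, mu_ag + is_case * config$ag_effect_size * sdlog_ag,
                      sdlog_ag)
  uag <- stats::rlnorm(n, log(0.02) - 0.4^2 / 2, 0.4)
  insulin <- stats::rlnorm(n, log(9.8) - 0.5^2 / 2, 0.5)
  score_gen <- function(mu_ctrl, mu_case, sd_ctrl, sd_case, lo, hi)
    clamp(stats::rnorm(n, ifelse(is_case, mu_case, mu_ctrl),
                       ifelse(is_case, sd_case, sd_ctrl)), lo, hi)
  clinical <- data.frame(
    subject_id = sprintf("subj_%02d", seq_len(n)),
    group = group, age = age, sex = sex,
    AG = ag, UAG = uag, insulin = insulin,
    MMSE = score_gen(28.5, 19.5, 1.2, 2.5, 0, 30),
    MoCA = score_gen(28, 20.5, 1.2, 3.0, 0, 30),
    GADL = score_gen(26, 13, 0.5, 2.8, 0, 27),
    HADS_A = score_gen(2, 9.5, 1.1, 1.3, 0, 21),
    HADS_D = score_gen(2, 9, 0.9, 1.0, 0, 21),
    SES = sample(1:5, n, replace = TRUE),
    stringsAsFactors = FALSE)
  clinical <- cbind(clinical, fac$data[setdiff(names(fac$data), "outcome")])
  # microbiome subset: first n_microbiome_per_group subjects of each group
  sub <- c(which(!is_case)[seq_len(config$n_microbiome_per_group)],
           which(is_case)[seq_len(config$n_microbiome_per_group)])
  tax <- default_taxa()
  if (config$n_taxa <= nrow(tax)) tax <- tax[seq_len(config$n_taxa), ]
  else tax <- rbind(tax, data.frame(
    taxon = paste0("taxon_", seq_len(config$n_taxa - nrow(tax))),
    phylum = "Firmicutes"))
  r <- basis_correlation_matrix(tax$taxon, config$basis_correlation)
  set.seed(config$seed + 3L)
  base_logs <- stats::rnorm(nrow(tax), 0, 1.5)
  names(base_logs) <- tax$taxon
  lfc <- config$differential_taxa[names(config$differential_taxa) %in%
                                    tax$taxon]
  case_logs <- base_logs
  case_logs[names(lfc)] <- case_logs[names(lfc)] + lfc
  otu_list <- lapply(seq_along(sub), function(k) {
    i <- sub[k]
    ml <- if (is_case[i]) case_logs else base_logs
    tab <- generate_compositional_counts(
      r, ml, 1, config$sequencing_depth, seed = config$seed + 10L + i,
      sample_prefix = clinical$subject_id[i], phylum = tax$phylum)
    cnt <- tab$counts
    colnames(cnt) <- clinical$subject_id[i]
    cnt
  })
  counts <- do.call(cbind, otu_list)
  otu <- otu_table(counts, phylum = tax$phylum,
                  sample_group = group[sub])
  truth <- list(basis_correlation = config$basis_correlation,
                differential_taxa = as.list(lfc),
                base_mean_logs = as.list(base_logs),
                factor_loadings = config$factor_loadings,
                structural_effects = as.list(config$structural_effects),
                factor_scores = list(lv1 = fac$truth$f1,
                                     lv2 = fac$truth$f2),
                seed = config$seed)
  structure(list(clinical = clinical, otu = otu, truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$clinical), "subjects (",
      sum(x$clinical$group == "control"), "control /",
      sum(x$clinical$group == "dementia"), "dementia ),",
      ncol(x$otu$counts), "microbiome samples,",
      nrow(x$otu$counts), "taxa\n")
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Clinical table as CSV, OTU table as TSV, truth record as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("clinical.csv", "otu.tsv", "truth.json"))
  utils::write.csv(cohort$clinical, paths[1], row.names = FALSE)
  write_otu_tsv(cohort$otu, paths[2])
  jsonlite::write_json(cohort$truth, paths[3], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
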