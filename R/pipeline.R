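# Config-driven orchestration of the full analysis.

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one list: OTU filter (`min_total`),
#' incidence threshold and top-N, SparCC passes, network node/edge
#' thresholds, regression-screen R-squared threshold, ROC decision cutoffs
#' (0.65 clinical / 0.70 microbial), permutation counts, and the seed.
#' Either `synthetic` (arguments to [cohort_config()]) or `input`
#' (`clinical_csv`, `otu_tsv`) selects the data source.
#'
#' @param ... overrides of any default element.
#' @return list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    synthetic = list(),          # cohort_config() arguments
    input = NULL,                # list(clinical_csv =, otu_tsv =)
    min_total = 10,
    abundance_threshold = 0.01,
    top_n = 15,
    sparcc_iterations = 20,
    node_min_total = 10,
    edge_threshold = 0.3,
    r2_threshold = 0.55,
    roc_cutoff_clinical = 0.65,
    roc_cutoff_microbe = 0.70,
    n_perm = 999,
    ag_cutpoint = 1.0,
    seed = 1L,
    out_dir = NULL,
    force = FALSE)
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (!is.null(cfg$input) && length(cfg$synthetic))
    stop("give either 'input' paths or a 'synthetic' config, not both")
  stopifnot(cfg$min_total >= 0, cfg$edge_threshold >= 0,
            cfg$edge_threshold <= 1, cfg$r2_threshold >= 0,
            cfg$r2_threshold <= 1, cfg$n_perm >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are [run_config()] fields.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg <- cfg[setdiff(names(cfg), c("out_dir", "force"))]  # analytic identity only
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: cohort loading or synthesis, the clinical
#' summary table, OTU filtering and the abundance/incidence core-microbiota
#' summary, the F/B ratio comparison, alpha and beta diversity with
#' PERMANOVA and SIMPER, per-group SparCC co-occurrence networks with
#' Louvain communities, representative species and the
#' centrality-difference keystone screen, Mantel and per-species regression
#' screens with ROC curves, the MLP classifier with permutation feature
#' contributions, the two-latent-variable structural model with
#' factor-score group comparison, and the AG subgroup analysis. A stage
#' that fails is recorded with its error and its dependents are skipped.
#'
#' Identical config + seed reproduces the identical report. When
#' `config$out_dir` is set, every section is written there as TSV/JSON
#' together with a manifest carrying the config hash; an existing directory
#' holding a different config hash is refused unless `force = TRUE`.
#'
#' @param config a [run_config()] (or a list of overrides).
#' @return list of class `report_bundle` with one element per stage and a
#'   `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  report <- list(manifest = list(config_hash = config_hash(config),
                                 seed = config$seed,
                                 started = "fixed-seed deterministic run"))
  failed <- character(0)
  stage <- function(name, deps, expr) {
    if (length(intersect(deps, failed))) {
      report[[name]] <<- list(skipped = TRUE,
                              reason = paste("dependency failed:",
                                             paste(intersect(deps, failed),
                                                   collapse = ", ")))
      failed <<- c(failed, name)
      return(invisible(NULL))
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      report[[name]] <<- list(failed = TRUE, error = conditionMessage(res))
      failed <<- c(failed, name)
    } else report[[name]] <<- res
    invisible(NULL)
  }

  stage("cohort", character(0), {
    if (!is.null(config$input)) {
      if (!file.exists(config$input$clinical_csv) ||
          !file.exists(config$input$otu_tsv))
        stop("input file missing: ",
             paste(c(config$input$clinical_csv, config$input$otu_tsv)[
               !file.exists(c(config$input$clinical_csv,
                              config$input$otu_tsv))], collapse = ", "))
      clinical <- utils::read.csv(config$input$clinical_csv)
      otu <- read_otu_tsv(config$input$otu_tsv,
                          sample_group = NULL)
      if (!is.null(clinical$group)) {
        grp <- stats::setNames(clinical$group, clinical$subject_id)
        otu$sample_group <- grp[colnames(otu$counts)]
      }
      list(clinical = clinical, otu = otu, truth = NULL)
    } else {
      cc <- do.call(cohort_config,
                    c(config$synthetic,
                      if (is.null(config$synthetic$seed))
                        list(seed = config$seed)))
      generate_cohort(cc)
    }
  })
  cohort <- report$cohort

  stage("table1", "cohort", {
    cl <- cohort$clinical
    gi <- ghrelin_indices(cl$AG, cl$UAG, cl$age)
    cl$ag_uag_ratio <- gi$ratio
    cl$aagr <- gi$aagr
    vars <- intersect(c("age", "AG", "UAG", "ag_uag_ratio", "aagr",
                        "insulin", "MMSE", "MoCA", "GADL", "HADS_A",
                        "HADS_D"), names(cl))
    table1_summary(cl, vars)
  })

  stage("otu_summary", "cohort", {
    filt <- filter_by_total(cohort$otu, config$min_total)
    props <- relative_abundance(filt)
    inc <- incidence_summary(props, filt$sample_group,
                             threshold = config$abundance_threshold,
                             top_n = config$top_n)
    fb <- fb_ratio(filt)
    grp <- filt$sample_group
    ok <- !is.na(fb)
    fb_test <- if (length(unique(grp[ok])) == 2)
      compare_groups(fb[ok & grp == "control"], fb[ok & grp != "control"])
    else NULL
    list(filtered = filt, proportions = props, incidence = inc,
         fb_ratio = fb, fb_test = fb_test)
  })

  stage("diversity", "otu_summary", {
    filt <- report$otu_summary$filtered
    alpha <- alpha_diversity_table(filt)
    bc <- bray_curtis_matrix(filt)
    ord <- pcoa(bc)
    perm <- permanova(bc, filt$sample_group, n_perm = config$n_perm,
                      seed = config$seed)
    smp <- simper(report$otu_summary$proportions, filt$sample_group)
    alpha_tests <- lapply(c("richness", "shannon", "simpson", "pielou"),
      function(v) {
        x <- alpha[[v]]
        ok <- !is.na(x)
        compare_groups(x[ok & alpha$group == "control"],
                       x[ok & alpha$group != "control"])
      })
    names(alpha_tests) <- c("richness", "shannon", "simpson", "pielou")
    list(alpha = alpha, alpha_tests = alpha_tests, bray_curtis = bc,
         pcoa = ord, permanova = perm, simper = smp)
  })

  stage("network", "otu_summary", {
    filt <- report$otu_summary$filtered
    groups <- unique(filt$sample_group)
    nets <- lapply(groups, function(g) {
      sub <- subset_otu(filt, samples = filt$sample_group == g)
      sub <- filter_by_total(sub, 0)   # drop taxa absent from this group
      rho <- sparcc_correlations(sub,
                                 outer_iterations = config$sparcc_iterations,
                                 seed = config$seed)
      net <- build_cooccurrence_network(rho, sub,
                                        node_min_total = config$node_min_total,
                                        edge_threshold = config$edge_threshold)
      net <- louvain_partition(net, seed = config$seed)
      list(network = net, representatives = representative_species(net))
    })
    names(nets) <- groups
    ctrl <- nets[["control"]]$network
    case <- nets[[setdiff(groups, "control")[1]]]$network
    delta <- centrality_difference(ctrl, case)
    list(networks = nets, centrality_delta = delta)
  })

  stage("association", c("otu_summary", "diversity"), {
    filt <- report$otu_summary$filtered
    props <- report$otu_summary$proportions
    cl <- cohort$clinical
    rownames(cl) <- cl$subject_id
    clin_vars <- intersect(c("age", "AG", "MMSE", "MoCA", "GADL",
                             "HADS_A", "HADS_D", "SES"), names(cl))
    samp <- colnames(filt$counts)
    clin_sub <- cl[samp, clin_vars, drop = FALSE]
    mantel <- mantel_test(report$diversity$bray_curtis,
                          clinical_distance(clin_sub),
                          n_perm = config$n_perm, seed = config$seed)
    screens <- lapply(unique(filt$sample_group), function(g) {
      idx <- filt$sample_group == g
      species_clinical_screen(props[, idx, drop = FALSE],
                              clin_sub[idx, , drop = FALSE],
                              r2_threshold = config$r2_threshold)
    })
    names(screens) <- unique(filt$sample_group)
    y <- as.integer(filt$sample_group != "control")
    roc_ag <- roc_auc(clin_sub$AG, y, cutoff = config$roc_cutoff_clinical)
    top_sp <- report$diversity$simper$species[1]
    roc_top_species <- roc_auc(props[top_sp, ], y,
                               cutoff = config$roc_cutoff_microbe)
    list(mantel = mantel, screens = screens, roc_ag = roc_ag,
         roc_top_species = roc_top_species,
         roc_species = top_sp)
  })

  stage("classifier", "cohort", {
    cl <- cohort$clinical
    feat_cols <- setdiff(names(cl)[vapply(cl, is.numeric, logical(1))],
                         "SES")
    x <- as.matrix(cl[, feat_cols])
    y <- as.integer(cl$group != "control")
    sp <- prepare_features(x, y, seed = config$seed)
    fit <- train_mlp(sp$train, sp$val, seed = config$seed)
    contrib <- feature_contributions(fit, sp$test, seed = config$seed)
    list(splits = sp, model = fit,
         test_accuracy = mlp_accuracy(fit, sp$test),
         contributions = contrib)
  })

  stage("latent_model", "cohort", {
    cl <- cohort$clinical
    fl <- if (!is.null(cohort$truth))
      cohort$truth$factor_loadings else NULL
    if (is.null(fl)) stop("no latent-model indicators configured for file input")
    spec <- latent_model_spec(names(fl$lv1), names(fl$lv2),
                              outcome = "outcome01")
    cl$outcome01 <- as.integer(cl$group != "control")
    pr <- prune_indicators(cl, spec, seed = config$seed)
    scores <- stats::predict(pr$fit, cl)
    rownames(scores) <- cl$subject_id
    comparison <- compare_factor_scores(scores, cl$group)
    list(fit = pr$fit, pruned = pr$removed, scores = scores,
         comparison = comparison)
  })

  stage("subgroup", "otu_summary", {
    subgroup_analysis(cohort, report$otu_summary$filtered,
                      cutpoint = config$ag_cutpoint,
                      n_perm = config$n_perm, seed = config$seed)
  })

  class(report) <- "report_bundle"
  if (!is.null(config$out_dir))
    write_report(report, config, config$out_dir, force = config$force)
  report
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("Analysis report (config", substr(x$manifest$config_hash, 1, 8),
      ", seed", x$manifest$seed, ")\n")
  for (nm in setdiff(names(x), "manifest")) {
    s <- x[[nm]]
    status <- if (is.list(s) && isTRUE(s$failed)) paste("FAILED:", s$error)
    else if (is.list(s) && isTRUE(s$skipped)) paste("skipped:", s$reason)
    else "ok"
    cat(sprintf("  %-12s %s\n", nm, status))
  }
  invisible(x)
}

#' AG subgroup analysis within the case group
#'
#' Splits the case group's microbiome samples at an acylated-ghrelin
#' cutpoint (strictly greater goes to the high stratum, `<=` to the low
#' stratum) and compares alpha indices (Welch t) and beta diversity
#' (PERMANOVA) between strata. An empty or singleton stratum skips the
#' comparison with a warning rather than failing.
#'
#' @param cohort cohort list with `clinical` and `otu`.
#' @param filtered optionally, the filtered [otu_table()] to use.
#' @param variable clinical variable to stratify on.
#' @param cutpoint stratum boundary (default 1.0 ng/mL).
#' @param n_perm,seed PERMANOVA settings.
#' @return list: `strata` sizes, `alpha_tests`, `permanova` (or skip note).
#' @export
subgroup_analysis <- function(cohort, filtered = NULL, variable = "AG",
                              cutpoint = 1.0, n_perm = 999, seed = 1L) {
  otu <- if (is.null(filtered)) cohort$otu else filtered
  cl <- cohort$clinical
  rownames(cl) <- cl$subject_id
  case_samples <- colnames(otu$counts)[otu$sample_group != "control"]
  vals <- cl[case_samples, variable]
  if (cutpoint < min(vals) || cutpoint > max(vals))
    warning("cutpoint ", cutpoint, " outside the observed range of ",
            variable)
  high <- case_samples[vals > cutpoint]
  low <- case_samples[vals <= cutpoint]
  out <- list(strata = c(high = length(high), low = length(low)),
              cutpoint = cutpoint, variable = variable)
  if (length(high) < 2 || length(low) < 2) {
    warning("stratum too small; subgroup comparisons skipped")
    out$skipped <- TRUE
    out$reason <- "stratum with < 2 samples"
    return(out)
  }
  sub <- subset_otu(otu, samples = c(high, low))
  strata <- ifelse(colnames(sub$counts) %in% high, "high", "low")
  alpha <- alpha_diversity_table(sub)
  out$alpha_tests <- lapply(c("richness", "shannon", "simpson", "pielou"),
    function(v) {
      x <- alpha[[v]]; ok <- !is.na(x)
      tryCatch(compare_groups(x[ok & strata == "high"],
                              x[ok & strata == "low"]),
               error = function(e) NULL)
    })
  names(out$alpha_tests) <- c("richness", "shannon", "simpson", "pielou")
  out$permanova <- permanova(bray_curtis_matrix(sub), strata,
                             n_perm = n_perm, seed = seed)
  out
}

write_report <- function(report, config, dir, force = FALSE) {
  manifest_path <- file.path(dir, "manifest.json")
  if (file.exists(manifest_path) && !force) {
    old <- jsonlite::read_json(manifest_path)
    if (!identical(old$config_hash, report$manifest$config_hash))
      stop("output directory holds a different config hash; use force = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  jsonlite::write_json(report$manifest, manifest_path, auto_unbox = TRUE)
  if (!is.null(report$table1$variable)) wt(report$table1, "table1.tsv")
  os <- report$otu_summary
  if (!isTRUE(os$failed) && !is.null(os$incidence))
    wt(os$incidence, "incidence_summary.tsv")
  dv <- report$diversity
  if (!isTRUE(dv$failed) && !is.null(dv$alpha)) {
    wt(dv$alpha, "alpha_diversity.tsv")
    write_dist_tsv(dv$bray_curtis, file.path(dir, "bray_curtis.tsv"))
    wt(as.data.frame(dv$simper), "simper.tsv")
    jsonlite::write_json(list(pseudo_F = dv$permanova$pseudo_F,
                              r_squared = dv$permanova$r_squared,
                              p_value = dv$permanova$p_value),
                         file.path(dir, "permanova.json"), auto_unbox = TRUE)
  }
  nw <- report$network
  if (!isTRUE(nw$failed) && !is.null(nw$centrality_delta)) {
    wt(as.data.frame(nw$centrality_delta), "centrality_delta.tsv")
    for (g in names(nw$networks))
      write_network(nw$networks[[g]]$network,
                    edge_tsv = file.path(dir, paste0("network_", g, ".tsv")),
                    graphml = file.path(dir, paste0("network_", g,
                                                    ".graphml")))
  }
  cf <- report$classifier
  if (!isTRUE(cf$failed) && !is.null(cf$contributions)) {
    wt(as.data.frame(cf$contributions), "feature_contributions.tsv")
    jsonlite::write_json(list(test_accuracy = cf$test_accuracy),
                         file.path(dir, "classifier_metrics.json"),
                         auto_unbox = TRUE)
  }
  lm_ <- report$latent_model
  if (!isTRUE(lm_$failed) && !is.null(lm_$fit)) {
    jsonlite::write_json(
      list(loadings = as.list(lm_$fit$loadings),
           structural = as.list(lm_$fit$structural),
           chi_square = lm_$fit$chi_square, df = lm_$fit$df,
           gfi = lm_$fit$gfi, cfi = lm_$fit$cfi),
      file.path(dir, "latent_model.json"), auto_unbox = TRUE, digits = NA)
    wt(data.frame(subject = rownames(lm_$scores), lm_$scores),
       "factor_scores.tsv")
  }
  invisible(dir)
}
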