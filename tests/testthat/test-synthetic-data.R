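test_that("cohort configuration validates its invariants", {
  expect_error(cohort_config(n_control = 0), "positive")
  expect_error(cohort_config(n_case = -1), "positive")
  expect_error(cohort_config(sequencing_depth = 0), "depth")
  expect_error(cohort_config(n_taxa = 3), ">= 4")
  expect_error(cohort_config(
    basis_correlation = list(list("Prevotella_copri", "Blautia_obeum", 1.2))),
    "\\|r\\| < 1")
  expect_error(cohort_config(
    factor_loadings = list(lv1 = c(x = 2, y = 0.5),
                           lv2 = c(u = 0.5, v = 0.5))), "1.5")
})

test_that("a fixed seed reproduces the cohort byte-identically", {
  cfg <- cohort_config(sequencing_depth = 5000, seed = 77)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$otu$counts, c2$otu$counts)
  expect_identical(c1$truth, c2$truth)
  c3 <- generate_cohort(cohort_config(sequencing_depth = 5000, seed = 78))
  expect_false(identical(c1$otu$counts, c3$otu$counts))
})

test_that("the cohort honours its stated shape and instrument ranges", {
  co <- generate_cohort(cohort_config(sequencing_depth = 5000, seed = 3))
  cl <- co$clinical
  expect_equal(nrow(cl), 80)
  expect_equal(sum(cl$group == "control"), 40)
  expect_equal(sum(cl$group == "dementia"), 40)
  expect_true(all(cl$MMSE >= 0 & cl$MMSE <= 30))
  expect_true(all(cl$MoCA >= 0 & cl$MoCA <= 30))
  expect_true(all(cl$age >= 60 & cl$age <= 85))
  expect_true(all(cl$AG > 0 & cl$UAG > 0))
  expect_equal(ncol(co$otu$counts), 18)
  expect_equal(nrow(co$otu$counts), 53)
  expect_true(all(colnames(co$otu$counts) %in% cl$subject_id))
  expect_equal(unname(colSums(co$otu$counts)), rep(5000, 18))
  expect_setequal(unique(co$otu$sample_group), c("control", "dementia"))
})

test_that("compositional counts respect depth, closure and preconditions", {
  r <- diag(6)
  rownames(r) <- colnames(r) <- paste0("t", 1:6)
  tab <- generate_compositional_counts(r, rep(0, 6), 10, 1000, seed = 4)
  expect_equal(unname(colSums(tab$counts)), rep(1000, 10))
  expect_true(all(tab$counts >= 0))
  tab2 <- generate_compositional_counts(r, rep(0, 6), 10, 1000, seed = 4)
  expect_identical(tab$counts, tab2$counts)
  expect_error(generate_compositional_counts(r, rep(0, 6), 5, 0), "depth")
  expect_error(generate_compositional_counts(diag(3), rep(0, 3), 5, 100),
               ">= 4 taxa")
  # non-positive-definite planted structure errors and names the pairs
  expect_error(generate_cohort(cohort_config(
    basis_correlation = list(
      list("Prevotella_copri", "Blautia_obeum", 0.9),
      list("Prevotella_copri", "Blautia_producta", 0.9),
      list("Blautia_obeum", "Blautia_producta", -0.9)))),
    "not positive definite")
})

test_that("differential taxa shift abundance between groups as planted", {
  co <- generate_cohort(cohort_config(sequencing_depth = 20000, seed = 12,
                                      n_microbiome_per_group = 9))
  props <- relative_abundance(co$otu)
  grp <- co$otu$sample_group
  # strongest planted fold-change: Bifidobacterium longum up in cases
  bl <- props["Bifidobacterium_longum", ]
  expect_gt(mean(bl[grp == "dementia"]), mean(bl[grp == "control"]))
  eb <- props["Eubacterium_biforme", ]
  expect_lt(mean(eb[grp == "dementia"]), mean(eb[grp == "control"]))
})

test_that("the AG group shift matches its planted effect size direction", {
  co <- generate_cohort(cohort_config(seed = 5, sequencing_depth = 1000))
  cl <- co$clinical
  lag <- log(cl$AG)
  expect_gt(mean(lag[cl$group == "dementia"]),
            mean(lag[cl$group == "control"]))
})

test_that("null factor loadings and effects generate null structure", {
  fc <- generate_factor_cohort(list(lv1 = c(a = 0.8, b = 0.8, c = 0.8),
                                    lv2 = c(d = 0.8, e = 0.8, f = 0.8)),
                               c(0, 0), n = 2000, seed = 14)
  # outcome independent of the factors
  expect_lt(abs(cor(fc$data$outcome, fc$truth$f1)), 0.06)
  expect_lt(abs(cor(fc$data$outcome, fc$truth$f2)), 0.06)
  expect_error(generate_factor_cohort(list(lv1 = c(a = 0.8, b = 0.8),
                                           lv2 = c(c = 0.8, d = 0.8)),
                                      c(1, -1), n = 10), "too small")
})

test_that("the cohort and its truth record round-trip through disk", {
  co <- generate_cohort(cohort_config(sequencing_depth = 2000, seed = 9))
  dir <- file.path(tempdir(), "cohort-rt")
  write_cohort(co, dir)
  clin <- read.csv(file.path(dir, "clinical.csv"))
  expect_equal(clin$subject_id, co$clinical$subject_id)
  otu <- read_otu_tsv(file.path(dir, "otu.tsv"))
  expect_equal(otu$counts, co$otu$counts)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$structural_effects$lv1,
               unname(co$truth$structural_effects$lv1))
  expect_equal(truth$factor_scores$lv1, co$truth$factor_scores$lv1,
               tolerance = 1e-12)
})
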