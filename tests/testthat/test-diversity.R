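test_that("alpha indices match closed forms and vegan", {
  a <- alpha_diversity(c(5, 5, 5, 5))
  expect_equal(a$richness, 4)
  expect_equal(a$shannon, log(4), tolerance = 1e-12)
  expect_equal(a$simpson, 0.75, tolerance = 1e-12)
  expect_equal(a$pielou, 1, tolerance = 1e-12)
  a <- alpha_diversity(c(0, 7, 0))
  expect_equal(a$richness, 1)
  expect_equal(a$shannon, 0)
  expect_equal(a$simpson, 0)
  expect_true(is.na(a$pielou))
  # hand computation from p = (1/4, 1/4, 1/2)
  a <- alpha_diversity(c(1, 1, 2))
  expect_equal(a$shannon, -sum(c(.25, .25, .5) * log(c(.25, .25, .5))),
               tolerance = 1e-12)
  expect_equal(a$shannon, 1.0397, tolerance = 1e-4)
  expect_equal(a$simpson, 0.625, tolerance = 1e-12)
  expect_equal(a$pielou, 0.9464, tolerance = 1e-4)
  expect_error(alpha_diversity(c(0, 0)), "all-zero")
})

test_that("alpha indices are invariant to reordering and proportional rescaling", {
  set.seed(3)
  for (i in 1:5) {
    x <- rpois(12, 20)
    x[x == 0] <- 1
    a <- alpha_diversity(x)
    b <- alpha_diversity(rev(x))
    expect_equal(a, b)
    cc <- alpha_diversity(x * 7)
    expect_equal(a$shannon, cc$shannon, tolerance = 1e-12)
    expect_equal(a$simpson, cc$simpson, tolerance = 1e-12)
  }
})

test_that("Bray-Curtis matches hand values and is a valid dissimilarity", {
  m <- rbind(a = c(1, 1), b = c(1, 3), c = c(1, 1))
  d <- bray_curtis_matrix(m, samples_in = "rows")
  expect_equal(d["a", "b"], 2 / 6, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)
  disjoint <- rbind(x = c(5, 0), y = c(0, 9))
  expect_equal(bray_curtis_matrix(disjoint, samples_in = "rows")["x", "y"], 1)
  tab <- toy_otu()
  d <- bray_curtis_matrix(tab)
  expect_equal(d, t(d), tolerance = 1e-12)
  expect_true(all(diag(d) == 0) && all(d >= 0) && all(d <= 1))
  bad <- rbind(s1 = c(1, 2), s2 = c(0, 0))
  expect_error(bray_curtis_matrix(bad, samples_in = "rows"), "s2")
})

test_that("PCoA embeds classic configurations correctly", {
  # three points with all pairwise distances 1: equilateral triangle
  d <- matrix(1, 3, 3) - diag(3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  p <- pcoa(d)
  ev <- p$eigenvalues[1:2]
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_true(all(ev > 0))
  emb <- as.matrix(dist(p$coordinates))
  expect_equal(unname(emb), unname(d), tolerance = 1e-9)
  # Euclidean input distances are reproduced exactly
  set.seed(11)
  x <- matrix(rnorm(8 * 3), 8)
  d <- as.matrix(dist(x))
  p <- pcoa(d)
  expect_equal(as.matrix(dist(p$coordinates)), unname(d), tolerance = 1e-9,
               ignore_attr = TRUE)
  # coincident samples share coordinates
  x2 <- rbind(x, x[1, ])
  p2 <- pcoa(as.matrix(dist(x2)))
  expect_lt(max(abs(p2$coordinates[1, ] - p2$coordinates[9, ])), 1e-6)
})

test_that("permanova pseudo-F and R2 agree with vegan::adonis2", {
  tab <- toy_otu()
  d <- bray_curtis_matrix(tab)
  res <- permanova(d, tab$sample_group)
  g <- factor(tab$sample_group)
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-9)
  expect_equal(res$r_squared, ad$R2[1], tolerance = 1e-9)
})

test_that("permanova enumerates exhaustively and calibrates", {
  d <- random_dist(6, seed = 21)
  labs <- rep(c("a", "b"), each = 3)
  res <- permanova(d, labs)
  expect_true(res$exhaustive)
  expect_equal(res$n_permutations, 20)
  expect_equal(res$p_value, bf_permanova_p(d, labs), tolerance = 1e-12)
  # perfectly separated clusters in sampled mode reach the attainable minimum
  set.seed(5)
  x <- rbind(matrix(rnorm(7 * 2, 0, 0.01), 7),
             matrix(rnorm(7 * 2, 50, 0.01), 7))
  rownames(x) <- paste0("s", 1:14)
  res <- permanova(as.matrix(dist(x)), rep(c("a", "b"), each = 7),
                   n_perm = 199, seed = 2, exhaustive_max = 10)
  expect_false(res$exhaustive)
  expect_equal(res$p_value, 1 / 200)
  expect_error(permanova(d, rep("a", 6)), "2 groups")
})

test_that("simper decomposes mean between-group dissimilarity exactly", {
  # 2-species toy: contributions split 50/50, total dissimilarity 1
  m <- matrix(c(10, 0, 10, 0, 0, 10, 0, 10), nrow = 2,
              dimnames = list(c("spA", "spB"), paste0("s", 1:4)))
  st <- simper(m, c("g1", "g1", "g2", "g2"))
  expect_equal(attr(st, "overall"), 1)
  expect_equal(st$percent, c(50, 50))
  # one differing species carries 100%
  m2 <- matrix(c(5, 9, 5, 9, 5, 1, 5, 1), nrow = 2,
               dimnames = list(c("same", "diff"), paste0("s", 1:4)))
  st2 <- simper(m2, c("g1", "g1", "g2", "g2"))
  expect_equal(st2$percent[st2$species == "diff"], 100)
  # decomposition identity on random tables
  set.seed(9)
  for (i in 1:10) {
    m3 <- matrix(rpois(6 * 10, 15), nrow = 10,
                 dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
    labs <- rep(c("a", "b"), each = 3)
    st3 <- simper(m3, labs)
    bc <- bray_curtis_matrix(m3, samples_in = "cols")
    expect_equal(sum(st3$contribution), mean(bc[1:3, 4:6]),
                 tolerance = 1e-9)
  }
  expect_error(simper(m, c("a", "b", "c", "c")), "2 groups")
})

test_that("simper agrees with vegan's average contributions", {
  tab <- toy_otu()
  props <- relative_abundance(tab)
  st <- simper(props, tab$sample_group)
  vs <- summary(vegan::simper(t(props), tab$sample_group),
                ordered = TRUE)[[1]]
  expect_equal(st$contribution,
               unname(vs[st$species, "average"]), tolerance = 1e-9)
})
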