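# correlation matrix + counts fixture for network construction
net_fixture <- function(rmat, totals) {
  taxa <- rownames(rmat)
  counts <- matrix(0L, length(taxa), 2,
                   dimnames = list(taxa, c("s1", "s2")))
  counts[, 1] <- as.integer(ceiling(totals / 2))
  counts[, 2] <- as.integer(totals - ceiling(totals / 2))
  list(corr = rmat, otu = otu_table(counts))
}

sym_corr <- function(taxa) {
  r <- diag(length(taxa))
  dimnames(r) <- list(taxa, taxa)
  r
}

test_that("network construction applies node and edge thresholds strictly", {
  taxa <- paste0("sp", 1:4)
  r <- sym_corr(taxa)
  r["sp1", "sp2"] <- r["sp2", "sp1"] <- -0.5
  r["sp1", "sp3"] <- r["sp3", "sp1"] <- 0.2
  fx <- net_fixture(r, totals = c(100, 100, 100, 10))
  net <- build_cooccurrence_network(fx$corr, fx$otu)
  # sp4 total exactly 10: excluded (strict >)
  expect_setequal(net$nodes$taxon, c("sp1", "sp2", "sp3"))
  # only the |r| = 0.5 pair survives the 0.3 edge threshold
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$sign, "negative")
  expect_equal(net$edges$strength, 0.5)
  # all sub-threshold: edgeless but nodes kept
  r0 <- sym_corr(taxa)
  net0 <- build_cooccurrence_network(r0, net_fixture(r0, rep(100, 4))$otu)
  expect_equal(nrow(net0$edges), 0)
  expect_equal(nrow(net0$nodes), 4)
  expect_true(all(net$nodes$degree_centrality >= 0 &
                    net$nodes$degree_centrality <= 1))
})

test_that("louvain finds the two-clique partition with Q = 1/2", {
  taxa <- paste0("n", 1:10)
  r <- sym_corr(taxa)
  for (i in 1:5) for (j in 1:5) if (i != j) r[i, j] <- 0.8
  for (i in 6:10) for (j in 6:10) if (i != j) r[i, j] <- 0.8
  fx <- net_fixture(r, rep(100, 10))
  net <- louvain_partition(build_cooccurrence_network(r, fx$otu), seed = 1)
  expect_equal(length(unique(net$nodes$community)), 2)
  expect_equal(net$modularity, 0.5, tolerance = 1e-12)
  comm <- split(net$nodes$taxon, net$nodes$community)
  expect_true(setequal(comm[[1]], taxa[1:5]) ||
                setequal(comm[[1]], taxa[6:10]))
  # single complete graph: one community, Q = 0
  r1 <- sym_corr(taxa[1:5])
  r1[,] <- 0.7; diag(r1) <- 1
  net1 <- louvain_partition(
    build_cooccurrence_network(r1, net_fixture(r1, rep(100, 5))$otu))
  expect_equal(length(unique(net1$nodes$community)), 1)
  expect_equal(net1$modularity, 0, tolerance = 1e-12)
  # edgeless: error
  r0 <- sym_corr(taxa[1:4])
  net0 <- build_cooccurrence_network(r0, net_fixture(r0, rep(100, 4))$otu)
  expect_error(louvain_partition(net0), "edgeless")
})

test_that("louvain partition beats the singleton partition", {
  set.seed(8)
  taxa <- paste0("n", 1:12)
  r <- sym_corr(taxa)
  idx <- which(upper.tri(r))
  picked <- sample(idx, 20)
  r[picked] <- runif(20, 0.4, 0.9)
  r[lower.tri(r)] <- t(r)[lower.tri(r)]
  net <- build_cooccurrence_network(r, net_fixture(r, rep(100, 12))$otu)
  net <- louvain_partition(net, seed = 2)
  g <- net$graph
  q_singleton <- igraph::modularity(g, seq_len(igraph::vcount(g)),
                                    weights = abs(igraph::E(g)$weight))
  expect_gte(net$modularity, q_singleton)
})

test_that("representative species follow the top-k / max-degree rule", {
  # community of hubs plus an isolated pair whose best node ranks low
  taxa <- c(paste0("hub", 1:6), "iso1", "iso2")
  r <- sym_corr(taxa)
  for (i in 1:6) for (j in 1:6) if (i != j) r[i, j] <- 0.8
  r["iso1", "iso2"] <- r["iso2", "iso1"] <- 0.9
  net <- louvain_partition(
    build_cooccurrence_network(r, net_fixture(r, rep(100, 8))$otu))
  reps <- representative_species(net, top_k = 20)
  expect_equal(nrow(reps), 2)
  expect_false(anyNA(reps$representative))
  # with top_k so small the pair community's best node is outside it
  reps2 <- representative_species(net, top_k = 3)
  iso_comm <- net$nodes$community[net$nodes$taxon == "iso1"]
  expect_true(is.na(reps2$representative[reps2$community == iso_comm]))
  # degree tie inside a community: lexicographically smaller name wins
  hub_comm <- net$nodes$community[net$nodes$taxon == "hub1"]
  expect_equal(reps$representative[reps$community == hub_comm], "hub1")
})

test_that("centrality differences, antisymmetry and Tukey outliers", {
  taxa <- paste0("sp", 1:5)
  r <- sym_corr(taxa)
  r["sp1", "sp2"] <- r["sp2", "sp1"] <- 0.8
  r["sp1", "sp3"] <- r["sp3", "sp1"] <- 0.8
  fx <- net_fixture(r, rep(100, 5))
  net_a <- build_cooccurrence_network(r, fx$otu)
  # case network lacks sp5 and has no edges
  r2 <- sym_corr(taxa[1:4])
  net_b <- build_cooccurrence_network(r2, net_fixture(r2, rep(100, 4))$otu)
  delta <- centrality_difference(net_a, net_b)
  expect_setequal(delta$taxon, taxa)
  # sp1 has degree 2 of 4 possible in control, absent edges in case
  expect_equal(delta$delta[delta$taxon == "sp1"], 0.5)
  expect_true(all(delta$delta >= -1 & delta$delta <= 1))
  # identical networks: all zero, nothing flagged
  d0 <- centrality_difference(net_a, net_a)
  expect_true(all(d0$delta == 0))
  expect_false(any(d0$outlier))
  # antisymmetry
  d1 <- centrality_difference(net_b, net_a)
  m <- merge(as.data.frame(delta), as.data.frame(d1), by = "taxon")
  expect_equal(m$delta.x, -m$delta.y)
  # Tukey fences on the documented fixture
  flags <- tukey_outliers(c(rep(0, 8), 0.6, -0.6))
  expect_equal(sum(flags), 2)
  expect_true(all(flags[9:10]))
})

test_that("network export writes edge list and GraphML", {
  taxa <- paste0("sp", 1:4)
  r <- sym_corr(taxa)
  r["sp1", "sp2"] <- r["sp2", "sp1"] <- 0.6
  net <- build_cooccurrence_network(r, net_fixture(r, rep(100, 4))$otu)
  tsv <- tempfile(fileext = ".tsv"); gml <- tempfile(fileext = ".graphml")
  write_network(net, edge_tsv = tsv, graphml = gml)
  edges <- read.delim(tsv)
  expect_equal(edges$from, "sp1")
  expect_equal(edges$weight, 0.6)
  expect_true(file.size(gml) > 0)
})
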