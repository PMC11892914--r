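# Shared fixtures and independent oracles, all built in code.

# small OTU table: 4 taxa x 6 samples, two groups
toy_otu <- function() {
  counts <- matrix(c(10, 5, 0, 2,
                     12, 6, 1, 3,
                     9,  4, 0, 1,
                     1, 20, 8, 0,
                     2, 18, 9, 1,
                     0, 22, 7, 2),
                   nrow = 4,
                   dimnames = list(paste0("sp", 1:4), paste0("s", 1:6)))
  otu_table(counts,
            phylum = c("Firmicutes", "Bacteroidetes", "Firmicutes",
                       "Actinobacteria"),
            sample_group = rep(c("control", "dementia"), each = 3))
}

# brute-force one-way pseudo-F straight from Anderson's definition,
# written independently of the package implementation
bf_pseudo_f <- function(d, groups) {
  d <- as.matrix(d)
  n <- nrow(d)
  gl <- unique(groups)
  sst <- sum(d[lower.tri(d)]^2) / n
  ssw <- 0
  for (g in gl) {
    i <- which(groups == g)
    ssw <- ssw + sum(as.dist(d[i, i])^2) / length(i)
  }
  ((sst - ssw) / (length(gl) - 1)) / (ssw / (n - length(gl)))
}

# exhaustive two-group PERMANOVA p-value by enumerating every split
bf_permanova_p <- function(d, groups) {
  n <- length(groups)
  gl <- unique(groups)
  n1 <- sum(groups == gl[1])
  fobs <- bf_pseudo_f(d, groups)
  splits <- combn(n, n1, simplify = FALSE)
  fs <- vapply(splits, function(s) {
    g <- rep(gl[2], n)
    g[s] <- gl[1]
    bf_pseudo_f(d, g)
  }, numeric(1))
  mean(fs >= fobs - 1e-12)
}

# exhaustive Mantel p by enumerating every relabeling of one matrix
bf_mantel_p <- function(dx, dy) {
  dx <- as.matrix(dx); dy <- as.matrix(dy)
  robs <- cor(as.dist(dx), as.dist(dy))
  rs <- vapply(perm_list(nrow(dx)), function(p)
    cor(as.dist(dx), as.dist(dy[p, p])), numeric(1))
  mean(rs >= robs - 1e-12)
}

# all permutations of 1..n as a list (tiny n only)
perm_list <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in perm_list(n - 1L)) for (pos in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# random Euclidean distance matrix over n points
random_dist <- function(n, p = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n * p), n)
  rownames(x) <- paste0("s", seq_len(n))
  as.matrix(dist(x))
}

# linearly separable two-feature classification fixture
separable_fixture <- function(n_per_class = 60, seed = 1) {
  set.seed(seed)
  x <- cbind(signal = c(rnorm(n_per_class, -2, 0.5),
                        rnorm(n_per_class, 2, 0.5)),
             noise = rnorm(2 * n_per_class))
  list(x = x, y = rep(0:1, each = n_per_class))
}
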