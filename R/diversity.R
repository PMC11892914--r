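#' Alpha diversity indices for one sample
#'
#' Species richness, Shannon entropy (nats), Gini-Simpson diversity
#' (1 - sum p^2) and Pielou's evenness (Shannon / ln richness). Pielou is
#' `NA` for single-taxon samples, where the maximum entropy is zero.
#'
#' @param counts nonnegative counts (or proportions) for one sample.
#' @return Named list: `richness`, `shannon`, `simpson`, `pielou`.
#' @export
alpha_diversity <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("negative counts")
  if (sum(counts) == 0) stop("all-zero sample")
  richness <- sum(counts > 0)
  shannon <- vegan::diversity(counts, index = "shannon")
  simpson <- vegan::diversity(counts, index = "simpson")
  list(richness = richness,
       shannon = unname(shannon),
       simpson = unname(simpson),
       pielou = if (richness > 1) unname(shannon) / log(richness) else NA_real_)
}

#' Alpha diversity for every sample of an OTU table
#'
#' @param table an [otu_table()] or a taxa-by-samples matrix.
#' @return data.frame, one row per sample, columns `sample`, `richness`,
#'   `shannon`, `simpson`, `pielou` (and `group` when the table carries one).
#' @export
alpha_diversity_table <- function(table) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  out <- do.call(rbind, lapply(seq_len(ncol(counts)), function(j) {
    a <- alpha_diversity(counts[, j])
    data.frame(sample = colnames(counts)[j], richness = a$richness,
               shannon = a$shannon, simpson = a$simpson, pielou = a$pielou)
  }))
  if (inherits(table, "otu_table") && !is.null(table$sample_group))
    out$group <- unname(table$sample_group[out$sample])
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between every
#' pair of samples, computed with [vegan::vegdist()].
#'
#' @param table an [otu_table()], or a matrix; `samples_in` says whether
#'   samples are in columns (`"cols"`, the OTU-table orientation) or rows.
#' @return Square symmetric matrix of class `dist_matrix` with sample labels.
#' @export
bray_curtis_matrix <- function(table, samples_in = c("cols", "rows")) {
  samples_in <- match.arg(samples_in)
  m <- if (inherits(table, "otu_table")) t(table$counts) else as.matrix(table)
  if (!inherits(table, "otu_table") && samples_in == "cols") m <- t(m)
  if (nrow(m) < 2) stop("need >= 2 samples")
  if (any(m < 0)) stop("negative abundances")
  tot <- rowSums(m)
  if (any(tot == 0))
    stop("zero-total sample(s): ",
         paste(rownames(m)[tot == 0], collapse = ", "))
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  class(d) <- c("dist_matrix", class(d))
  d
}

#' Serialize / read a distance matrix as square TSV
#' @param d square matrix with labels; `path` file path.
#' @return `read_dist_tsv` returns the labelled matrix.
#' @export
write_dist_tsv <- function(d, path) {
  utils::write.table(as.matrix(d), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  m <- as.matrix(utils::read.delim(path, row.names = 1, check.names = FALSE))
  colnames(m) <- rownames(m)
  m
}

#' Principal coordinates analysis (classical scaling)
#'
#' Eigendecomposition of the double-centered Gower matrix via
#' [stats::cmdscale()]. Axes are ordered by descending eigenvalue; negative
#' eigenvalues are reported as-is (no Lingoes/Cailliez correction). The
#' proportion of variation per axis is the eigenvalue over the sum of
#' positive eigenvalues.
#'
#' @param dist square distance matrix (e.g. from [bray_curtis_matrix()]).
#' @param k number of axes to return (default all `n - 1`).
#' @return list with `coordinates` (samples x axes), `eigenvalues`,
#'   `proportion` of variation per returned axis.
#' @export
pcoa <- function(dist, k = NULL) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (is.null(k)) k <- n - 1
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  eig <- fit$eig
  pos <- sum(eig[eig > 0])
  coords <- fit$points
  if (!is.null(coords) && ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       proportion = if (ncol(coords) > 0) eig[seq_len(ncol(coords))] / pos
       else numeric(0))
}

# one-way pseudo-F from a squared-distance decomposition (Anderson)
permanova_f <- function(d2, groups) {
  n <- nrow(d2)
  labs <- unique(groups)
  a <- length(labs)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in labs) {
    idx <- which(groups == g)
    if (length(idx) > 1) {
      sub <- d2[idx, idx]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  ss_between <- ss_total - ss_within
  f <- (ss_between / (a - 1)) / (ss_within / (n - a))
  c(f = f, r2 = ss_between / ss_total)
}

# enumerate all distinct assignments of n items into groups of the given
# sizes; returns a list of integer label vectors
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  rec <- function(free, sizes_left, lab, labels) {
    if (length(sizes_left) == 1) {
      labels[free] <- lab
      return(list(labels))
    }
    # fix the smallest free index into the current group to avoid
    # generating the same partition under permuted group order only when
    # group sizes tie; labels are distinguishable here (named groups), so
    # enumerate all subsets
    sets <- utils::combn(free, sizes_left[1], simplify = FALSE)
    out <- list()
    for (s in sets) {
      labels2 <- labels
      labels2[s] <- lab
      out <- c(out, rec(setdiff(free, s), sizes_left[-1], lab + 1L, labels2))
    }
    out
  }
  rec(seq_len(n), sizes, 1L, integer(n))
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Distance-based one-way PERMANOVA: the pseudo-F statistic is computed from
#' the squared-distance decomposition and its significance from random
#' relabelings of the samples. When the number of distinct group assignments
#' is at most `exhaustive_max`, all of them are enumerated and the p-value is
#' exact; otherwise `n_perm` random permutations are drawn and
#' p = (number of permuted F >= observed + 1) / (n_perm + 1).
#'
#' @param dist square distance matrix.
#' @param labels group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutation draw.
#' @param exhaustive_max enumerate exactly when the count of distinct
#'   assignments does not exceed this.
#' @return object of class `permanova`: `pseudo_F`, `r_squared`, `p_value`,
#'   `n_permutations`, `exhaustive`.
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = NULL,
                      exhaustive_max = 10000) {
  d <- as.matrix(dist)
  labels <- as.character(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  tab <- table(labels)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("each group needs >= 2 samples")
  d2 <- d^2
  obs <- permanova_f(d2, labels)
  sizes <- as.integer(tab)
  n_distinct <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (n_distinct <= exhaustive_max) {
    assigns <- enumerate_assignments(sizes)
    lab_levels <- names(tab)
    fs <- vapply(assigns, function(a)
      permanova_f(d2, lab_levels[a])[["f"]], numeric(1))
    p <- mean(fs >= obs[["f"]] - 1e-12)
    nper <- length(fs)
    exhaustive <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      fp <- permanova_f(d2, sample(labels))[["f"]]
      if (fp >= obs[["f"]] - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (n_perm + 1)
    nper <- n_perm
    exhaustive <- FALSE
  }
  structure(list(pseudo_F = unname(obs[["f"]]),
                 r_squared = unname(obs[["r2"]]),
                 p_value = p, n_permutations = nper,
                 exhaustive = exhaustive),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g, R2 = %.3f, p = %.4g (%s, %d %s)\n",
              x$pseudo_F, x$r_squared, x$p_value,
              if (x$exhaustive) "exhaustive" else "sampled",
              x$n_permutations,
              if (x$exhaustive) "assignments" else "permutations"))
  invisible(x)
}

#' SIMPER: similarity-percentage decomposition of Bray-Curtis
#'
#' Attributes the mean between-group Bray-Curtis dissimilarity to individual
#' species. For every between-group sample pair (x, y), species i
#' contributes \eqn{|x_i - y_i| / \sum_j (x_j + y_j)}; the per-species
#' contribution is the mean over all between-group pairs. Contributions sum
#' exactly to the mean between-group dissimilarity.
#'
#' @param table an [otu_table()] or taxa-by-samples matrix (counts or
#'   proportions).
#' @param labels group label per sample; exactly two groups.
#' @return data.frame of class `simper_table`, species sorted by descending
#'   contribution: `species`, `contribution` (dissimilarity units),
#'   `percent`, `cumulative_percent`, `mean_<group>` per-group mean
#'   abundances. Attribute `overall` holds the mean between-group
#'   dissimilarity.
#' @export
simper <- function(table, labels) {
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(counts))
  gl <- sort(unique(labels))
  if (length(gl) != 2) stop("SIMPER here compares exactly 2 groups")
  ia <- which(labels == gl[1]); ib <- which(labels == gl[2])
  ntax <- nrow(counts)
  contrib <- numeric(ntax)
  npair <- 0L
  for (i in ia) for (j in ib) {
    x <- counts[, i]; y <- counts[, j]
    tot <- sum(x + y)
    if (tot == 0) stop("pair of all-zero samples")
    contrib <- contrib + abs(x - y) / tot
    npair <- npair + 1L
  }
  contrib <- contrib / npair
  overall <- sum(contrib)
  ord <- order(-contrib, rownames(counts))
  out <- data.frame(species = rownames(counts)[ord],
                    contribution = contrib[ord],
                    percent = 100 * contrib[ord] / overall,
                    row.names = NULL)
  out$cumulative_percent <- cumsum(out$percent)
  out[[paste0("mean_", gl[1])]] <- rowMeans(counts[, ia, drop = FALSE])[ord]
  out[[paste0("mean_", gl[2])]] <- rowMeans(counts[, ib, drop = FALSE])[ord]
  attr(out, "overall") <- overall
  class(out) <- c("simper_table", "data.frame")
  out
}

#' @export
print.simper_table <- function(x, n = 10, ...) {
  cat(sprintf("SIMPER decomposition; mean between-group Bray-Curtis = %.4f\n",
              attr(x, "overall")))
  print.data.frame(utils::head(x, n), digits = 4)
  invisible(x)
}
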