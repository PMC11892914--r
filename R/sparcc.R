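# SparCC: basis-correlation inference for compositional count data.
#
# The observed proportions of a microbiome sample are closed (sum to 1), so
# naive Pearson correlations between taxa are distorted by the closure.
# SparCC instead works from log-ratio variances
#   t_ij = var(log(x_i / x_j)),
# which are invariant to closure, and solves for "basis" variances w_i^2
# under the sparsity assumption that the average basis correlation is ~0:
#   t_ij = w_i^2 + w_j^2 - 2 r_ij w_i w_j,   sum_j t_ij ~ (D-1) w_i^2 + T
# giving a linear system M w2 = t with M = I*(D-2) + J (D = number of taxa).
# Strongly correlated pairs violate the sparsity assumption, so the single
# strongest pair above `exclusion_threshold` is removed from the system and
# the basis variances re-solved, up to `max_exclusion_rounds` times.
# Sampling noise in the fractions is integrated out by repeating the whole
# estimation over Dirichlet resamples of the per-sample fractions
# (`outer_iterations` times, the "iterative SparCC" of the toolkits) and
# taking the elementwise median.

sparcc_once <- function(logf, exclusion_threshold, max_exclusion_rounds) {
  d <- ncol(logf)
  # variation matrix t_ij = var over samples of (log x_i - log x_j)
  v <- stats::var(logf)
  tmat <- outer(diag(v), diag(v), "+") - 2 * v
  m <- matrix(1, d, d)
  diag(m) <- d - 1
  excluded <- matrix(FALSE, d, d)
  solve_basis <- function() {
    tvec <- rowSums(tmat * !excluded) - diag(tmat)
    w2 <- solve(m, tvec)
    w2[w2 <= 0] <- 1e-8   # numerical guard; variances must stay positive
    w <- sqrt(w2)
    rho <- (outer(w2, w2, "+") - tmat) / (2 * outer(w, w))
    rho[rho > 1] <- 1; rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }
  rho <- solve_basis()
  for (round in seq_len(max_exclusion_rounds)) {
    cand <- abs(rho)
    cand[excluded] <- 0
    diag(cand) <- 0
    mx <- max(cand)
    if (mx < exclusion_threshold) break
    ij <- which(cand == mx, arr.ind = TRUE)[1, ]
    i <- ij[1]; j <- ij[2]
    excluded[i, j] <- excluded[j, i] <- TRUE
    m[i, i] <- m[i, i] - 1
    m[j, j] <- m[j, j] - 1
    m[i, j] <- m[j, i] <- 0
    if (any(diag(m) < 2)) break  # component nearly fully excluded
    rho <- solve_basis()
  }
  rho
}

#' SparCC correlation inference for compositional counts
#'
#' Estimates taxon-taxon basis correlations from an OTU count table using
#' the SparCC log-ratio-variance approach with iterative exclusion of
#' strongly correlated pairs, repeated over Dirichlet resamples of the
#' underlying fractions and aggregated by the elementwise median.
#'
#' Fractions for the first pass are the posterior-mean point estimate
#' `(count + 1) / (total + D)`; subsequent passes draw fractions from
#' `Dirichlet(count + 1)` per sample, so the median over passes reflects
#' counting uncertainty at low depth.
#'
#' @param counts an [otu_table()] or a taxa-by-samples count matrix with at
#'   least 4 taxa and 3 samples.
#' @param outer_iterations number of resampling passes (default 20).
#' @param exclusion_threshold |correlation| above which the strongest pair
#'   is excluded from the basis-variance system (default 0.1).
#' @param max_exclusion_rounds maximum pairs excluded per pass (default 10).
#' @param seed integer seed for the Dirichlet resampling.
#' @return Symmetric correlation matrix with unit diagonal, entries in
#'   \eqn{[-1, 1]}, dimnames = taxa.
#' @references Friedman & Alm (2012) Inferring correlation networks from
#'   genomic survey data. PLoS Comput Biol 8:e1002687.
#' @export
sparcc_correlations <- function(counts, outer_iterations = 20,
                                exclusion_threshold = 0.1,
                                max_exclusion_rounds = 10, seed = NULL) {
  x <- if (inherits(counts, "otu_table")) counts$counts else as.matrix(counts)
  d <- nrow(x); n <- ncol(x)
  if (d < 4) stop("SparCC needs >= 4 taxa (basis-variance system)")
  if (n < 3) stop("SparCC needs >= 3 samples")
  if (!is.null(seed)) set.seed(seed)
  est <- array(NA_real_, dim = c(d, d, outer_iterations))
  for (it in seq_len(outer_iterations)) {
    if (it == 1) {
      frac <- sweep(x + 1, 2, colSums(x) + d, "/")
    } else {
      # draw per sample in sorted-label order so the estimate does not
      # depend on the column order of the input
      ord <- if (!is.null(colnames(x))) order(colnames(x)) else seq_len(n)
      g <- matrix(NA_real_, d, n)
      for (j in ord) g[, j] <- stats::rgamma(d, shape = x[, j] + 1)
      frac <- sweep(g, 2, colSums(g), "/")
    }
    est[, , it] <- sparcc_once(t(log(frac)), exclusion_threshold,
                               max_exclusion_rounds)
  }
  rho <- apply(est, c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(rownames(x), rownames(x))
  rho
}
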