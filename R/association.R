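#' Mantel test between two distance matrices
#'
#' Pearson correlation between the lower-triangle vectors of two distance
#' matrices over the same samples, with significance from permuting the
#' row/column order of the second matrix. One-sided (greater), the common
#' convention for distance-matrix association. When `n <= exhaustive_n` all
#' n! relabelings are enumerated and the p-value is exact.
#'
#' @param dist_x,dist_y square distance matrices with matching labels
#'   (n >= 4 samples).
#' @param n_perm number of random permutations when not exhaustive.
#' @param seed integer seed.
#' @param exhaustive_n enumerate all permutations when n is at most this
#'   (default 7; 7! = 5040).
#' @return object of class `mantel_test`: `r`, `r_squared`, `p_value`,
#'   `n_permutations`, `exhaustive`.
#' @export
mantel_test <- function(dist_x, dist_y, n_perm = 999, seed = NULL,
                        exhaustive_n = 7) {
  x <- as.matrix(dist_x); y <- as.matrix(dist_y)
  n <- nrow(x)
  if (n < 4) stop("need n >= 4 samples")
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    if (!setequal(rownames(x), rownames(y)))
      stop("label sets differ between the two matrices")
    y <- y[rownames(x), rownames(x)]
  } else if (any(dim(x) != dim(y))) stop("dimension mismatch")
  lt <- lower.tri(x)
  vx <- x[lt]
  if (stats::sd(vx) == 0 || stats::sd(y[lt]) == 0)
    stop("constant distance matrix: Mantel r undefined")
  r_obs <- stats::cor(vx, y[lt])
  perm_r <- function(p) stats::cor(vx, y[p, p][lt])
  if (n <= exhaustive_n) {
    perms <- all_permutations(n)
    rs <- vapply(perms, perm_r, numeric(1))
    p <- mean(rs >= r_obs - 1e-12)
    nper <- length(rs); exhaustive <- TRUE
  } else {
    if (!is.null(seed)) set.seed(seed)
    cnt <- 0L
    for (i in seq_len(n_perm))
      if (perm_r(sample.int(n)) >= r_obs - 1e-12) cnt <- cnt + 1L
    p <- (cnt + 1) / (n_perm + 1)
    nper <- n_perm; exhaustive <- FALSE
  }
  structure(list(r = r_obs, r_squared = r_obs^2, p_value = p,
                 n_permutations = nper, exhaustive = exhaustive),
            class = "mantel_test")
}

#' @export
print.mantel_test <- function(x, ...) {
  cat(sprintf("Mantel: r = %.4f (r2 = %.4f), p = %.4g (%s)\n",
              x$r, x$r_squared, x$p_value,
              if (x$exhaustive) "exhaustive" else "permutation"))
  invisible(x)
}

# all permutations of 1..n as a list of integer vectors
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Euclidean distance matrix of standardized clinical variables
#'
#' Clinical variables are z-scored column-wise before computing Euclidean
#' distances, so variables on different scales contribute comparably.
#'
#' @param clinical data.frame or matrix, one row per subject, numeric
#'   columns only (a `variables` subset may be given).
#' @param variables optional column subset.
#' @return Square symmetric matrix with subject labels.
#' @export
clinical_distance <- function(clinical, variables = NULL) {
  m <- as.data.frame(clinical)
  if (!is.null(variables)) m <- m[, variables, drop = FALSE]
  m <- as.matrix(m[, vapply(m, is.numeric, logical(1)), drop = FALSE])
  m <- scale(m)
  m <- m[, !is.nan(colSums(m)), drop = FALSE]  # drop constant columns
  as.matrix(stats::dist(m))
}

#' Per-species linear-regression screen against clinical variables
#'
#' Fits one simple ordinary-least-squares regression of each clinical
#' variable on each species abundance and retains pairs with R-squared
#' strictly greater than `r2_threshold` and p < 0.05. A Benjamini-Hochberg
#' adjusted p column is emitted for reference but not used for filtering.
#'
#' @param abundances species-by-subjects matrix (or subjects-by-species with
#'   `samples_in = "rows"`).
#' @param clinical data.frame of numeric clinical variables, one row per
#'   subject in the same order.
#' @param r2_threshold retention threshold on R-squared (strict >).
#' @param samples_in orientation of `abundances`.
#' @return list with `hits` (retained rows) and `all` (every fitted pair):
#'   columns `species`, `clinical`, `r_squared`, `slope`, `p_value`,
#'   `p_adjusted`.
#' @export
species_clinical_screen <- function(abundances, clinical, r2_threshold = 0.55,
                                    samples_in = c("cols", "rows")) {
  samples_in <- match.arg(samples_in)
  ab <- as.matrix(abundances)
  if (samples_in == "cols") ab <- t(ab)      # now subjects x species
  clinical <- as.data.frame(clinical)
  clinical <- clinical[, vapply(clinical, is.numeric, logical(1)),
                       drop = FALSE]
  stopifnot(nrow(ab) == nrow(clinical))
  rows <- list(); k <- 0L
  for (sp in colnames(ab)) {
    x <- ab[, sp]
    if (stats::sd(x) == 0) {
      warning("constant predictor skipped: ", sp)
      next
    }
    for (cv in colnames(clinical)) {
      y <- clinical[[cv]]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < 3) next
      fit <- stats::lm(y[ok] ~ x[ok])
      sm <- summary(fit)
      pv <- if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_
      k <- k + 1L
      rows[[k]] <- data.frame(species = sp, clinical = cv,
                              r_squared = sm$r.squared,
                              slope = stats::coef(fit)[2],
                              p_value = pv, row.names = NULL)
    }
  }
  all <- if (k) do.call(rbind, rows) else
    data.frame(species = character(), clinical = character(),
               r_squared = numeric(), slope = numeric(), p_value = numeric())
  all$p_adjusted <- stats::p.adjust(all$p_value, method = "BH")
  hits <- all[!is.na(all$p_value) & all$r_squared > r2_threshold &
                all$p_value < 0.05, , drop = FALSE]
  rownames(hits) <- rownames(all) <- NULL
  list(hits = hits, all = all)
}

#' Empirical ROC curve and AUC
#'
#' Empirical ROC over all score thresholds, with AUC in the Mann-Whitney
#' formulation (ties contribute 1/2), which equals the trapezoidal area
#' under the empirical curve. Optionally applies a fixed decision cutoff
#' (score strictly greater than `cutoff` calls the positive class) and
#' reports sensitivity/specificity there.
#'
#' @param scores numeric classifier scores or biomarker values.
#' @param labels binary labels (0/1, or a two-level factor; the larger/last
#'   level is the positive class).
#' @param cutoff optional decision threshold (strict >), e.g. 0.65 for
#'   clinical features or 0.70 for microbial features.
#' @return object of class `roc_result`: `auc`, `curve` (data.frame
#'   `threshold`, `fpr`, `tpr`), and when `cutoff` is given,
#'   `cutoff`, `sensitivity`, `specificity`.
#' @export
roc_auc <- function(scores, labels, cutoff = NULL) {
  labels <- as.integer(factor(labels)) - 1L
  if (length(unique(labels)) != 2) stop("both classes must be present")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  # Mann-Whitney with half-credit for ties
  r <- rank(c(pos, neg))
  auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  curve <- data.frame(
    threshold = th,
    fpr = vapply(th, function(t) mean(neg >= t), numeric(1)),
    tpr = vapply(th, function(t) mean(pos >= t), numeric(1)))
  out <- list(auc = auc, curve = curve)
  if (!is.null(cutoff)) {
    out$cutoff <- cutoff
    out$sensitivity <- mean(pos > cutoff)
    out$specificity <- mean(neg <= cutoff)
  }
  structure(out, class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f", x$auc))
  if (!is.null(x$cutoff))
    cat(sprintf("; at cutoff > %.2f: sens = %.3f, spec = %.3f",
                x$cutoff, x$sensitivity, x$specificity))
  cat("\n")
  invisible(x)
}
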