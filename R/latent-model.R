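# Two-latent-variable structural model.
#
# Measurement part: each observed indicator loads on exactly one of two
# factors (lv1, lv2); structural part: a binary outcome (0/1, treated as
# numeric under ML) regresses on both factors with coefficients of opposite
# sign in the motivating application. With factor variances fixed to 1 and
# factor correlation phi free, the model-implied covariance of the observed
# vector z = (lv1 indicators, lv2 indicators, outcome) is
#   Sigma(theta) = Lambda Phi Lambda' + diag(theta_resid),
# where the outcome's "loading" row is (b1, b2). Parameters minimise the ML
# discrepancy F = log|Sigma| + tr(S Sigma^-1) - log|S| - m.

#' Specify a two-latent-variable model
#'
#' @param lv1_indicators,lv2_indicators character vectors of observed
#'   indicator column names (disjoint, >= 2 each).
#' @param outcome name of the binary outcome column.
#' @return list of class `latent_model_spec`.
#' @export
latent_model_spec <- function(lv1_indicators, lv2_indicators,
                              outcome = "dementia") {
  if (length(intersect(lv1_indicators, lv2_indicators)))
    stop("indicator sets must be disjoint")
  if (length(lv1_indicators) < 2 || length(lv2_indicators) < 2)
    stop("each latent variable needs >= 2 indicators")
  structure(list(lv1 = lv1_indicators, lv2 = lv2_indicators,
                 outcome = outcome),
            class = "latent_model_spec")
}

# build Lambda and residual-variance vector from the parameter vector
tf_unpack <- function(par, p1, p2) {
  m <- p1 + p2 + 1
  lam <- par[seq_len(p1 + p2)]
  b <- par[p1 + p2 + 1:2]
  phi <- tanh(par[p1 + p2 + 3])
  theta <- exp(par[p1 + p2 + 3 + seq_len(m)])
  L <- matrix(0, m, 2)
  L[seq_len(p1), 1] <- lam[seq_len(p1)]
  L[p1 + seq_len(p2), 2] <- lam[p1 + seq_len(p2)]
  L[m, ] <- b
  list(L = L, phi = phi, theta = theta,
       Phi = matrix(c(1, phi, phi, 1), 2, 2))
}

tf_sigma <- function(u) u$L %*% u$Phi %*% t(u$L) + diag(u$theta)

tf_fml <- function(par, S, p1, p2, logdetS) {
  u <- tf_unpack(par, p1, p2)
  sig <- tf_sigma(u)
  ch <- tryCatch(chol(sig), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% S))
  val <- logdet + tr - logdetS - nrow(S)
  if (!is.finite(val)) 1e10 else val
}

#' Fit the two-latent-variable structural model
#'
#' Maximum-likelihood fit of the model-implied covariance to the sample
#' covariance, with indicators standardized internally and the binary
#' outcome entered as numeric 0/1. Identification is by unit factor
#' variances, so the reported loadings are directly on the standardized
#' scale. Factor-sign indeterminacy is resolved by making the first
#' indicator loading of each latent positive. Fit indices: chi-square =
#' (n-1) F_ML, GFI from the standard covariance-residual formula, CFI
#' against the independence baseline (clamped to `[0, 1]`). Optimisation is
#' quasi-Newton (BFGS) with `n_starts` jittered restarts to guard against
#' local minima; non-convergence is flagged, not hidden.
#'
#' @param data data.frame containing every indicator and the outcome
#'   column; indicators are z-scored internally, the outcome is not.
#' @param spec a [latent_model_spec()].
#' @param n_starts number of jittered optimiser starts.
#' @param seed integer seed for the start jitter.
#' @return object of class `two_factor_fit`: `loadings` (standardized, per
#'   indicator), `structural` (lv1/lv2 coefficients on the outcome),
#'   `phi` (factor correlation), `residual_variances`, `chi_square`, `df`,
#'   `p_value`, `gfi`, `cfi`, `loading_se`, `loading_p` (Wald), `converged`,
#'   plus internals needed by [predict.two_factor_fit()].
#' @export
fit_two_factor_model <- function(data, spec, n_starts = 3, seed = 1L) {
  stopifnot(inherits(spec, "latent_model_spec"))
  vars <- c(spec$lv1, spec$lv2, spec$outcome)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  p1 <- length(spec$lv1); p2 <- length(spec$lv2)
  m <- p1 + p2 + 1
  z <- as.matrix(data[, vars])
  if (anyNA(z)) stop("missing values in model variables")
  # standardize indicators, keep outcome on its 0/1 scale
  z[, seq_len(m - 1)] <- scale(z[, seq_len(m - 1)])
  n <- nrow(z)
  nfree <- (p1 + p2) + 2 + 1 + m
  if (n <= nfree)
    stop("n (", n, ") must exceed the number of free parameters (", nfree, ")")
  S <- stats::cov(z)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("sample covariance not positive definite")
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  set.seed(seed)
  base_start <- c(rep(0.5, p1 + p2), 0.2, -0.2, 0,
                  log(pmax(diag(S) * 0.5, 1e-3)))
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- base_start + if (s == 1) 0 else stats::rnorm(nfree, sd = 0.2)
    opt <- tryCatch(
      stats::optim(start, tf_fml, S = S, p1 = p1, p2 = p2,
                   logdetS = logdetS, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value))
      best <- opt
  }
  if (is.null(best)) stop("optimisation failed for every start")
  converged <- best$convergence == 0
  par <- best$par
  u <- tf_unpack(par, p1, p2)
  # resolve sign indeterminacy: first indicator of each latent loads positive
  s1 <- if (u$L[1, 1] < 0) -1 else 1
  s2 <- if (u$L[p1 + 1, 2] < 0) -1 else 1
  flip <- diag(c(s1, s2))
  u$L <- u$L %*% flip
  u$phi <- u$phi * s1 * s2
  u$Phi <- matrix(c(1, u$phi, u$phi, 1), 2, 2)
  sig <- tf_sigma(u)
  fmin <- tf_fml_at(u, S, logdetS)
  chi2 <- (n - 1) * fmin
  df <- m * (m + 1) / 2 - nfree
  # baseline (independence) model for CFI:
  # F0 = log|diag(S)| + tr(S diag(S)^-1) - log|S| - m = sum log s_ii - log|S|
  f0 <- sum(log(diag(S))) - as.numeric(logdetS)
  chi2_0 <- (n - 1) * f0
  df0 <- m * (m - 1) / 2
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_0 - df0, chi2 - df, 0)
  cfi <- min(max(cfi, 0), 1)
  siginv_s <- solve(sig, S)
  gfi <- 1 - sum(diag((siginv_s - diag(m)) %*% (siginv_s - diag(m)))) /
    sum(diag(siginv_s %*% siginv_s))
  # standardized solution: scale rows by implied sds
  isd <- 1 / sqrt(diag(sig))
  Lstd <- u$L * isd
  loadings <- stats::setNames(
    c(Lstd[seq_len(p1), 1], Lstd[p1 + seq_len(p2), 2]), c(spec$lv1, spec$lv2))
  structural <- stats::setNames(u$L[m, ], c("lv1", "lv2"))
  # Wald SEs from the numerical Hessian of the discrepancy
  se <- pval <- rep(NA_real_, p1 + p2)
  H <- tryCatch(
    stats::optimHess(par, tf_fml, S = S, p1 = p1, p2 = p2, logdetS = logdetS),
    error = function(e) NULL)
  if (!is.null(H)) {
    acov <- tryCatch(2 / (n - 1) * solve(H), error = function(e) NULL)
    if (!is.null(acov)) {
      d <- diag(acov)[seq_len(p1 + p2)]
      d[d < 0] <- NA
      se <- sqrt(d)
      zval <- abs(par[seq_len(p1 + p2)]) / se
      pval <- 2 * stats::pnorm(-zval)
    }
  }
  names(se) <- names(pval) <- c(spec$lv1, spec$lv2)
  structure(list(spec = spec, loadings = loadings, structural = structural,
                 phi = u$phi, residual_variances =
                   stats::setNames(u$theta, vars),
                 raw_loadings = stats::setNames(
                   c(u$L[seq_len(p1), 1], u$L[p1 + seq_len(p2), 2]),
                   c(spec$lv1, spec$lv2)),
                 chi_square = chi2, df = df,
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
                 gfi = gfi, cfi = cfi,
                 loading_se = se, loading_p = pval,
                 converged = converged, fmin = fmin, n = n,
                 Lambda = u$L, Phi = u$Phi, Sigma = sig,
                 center = colMeans(as.matrix(data[, vars])),
                 indicator_scale = attr(scale(as.matrix(data[, vars[seq_len(m - 1)]])), "scaled:scale"),
                 vars = vars),
            class = "two_factor_fit")
}

tf_fml_at <- function(u, S, logdetS) {
  sig <- tf_sigma(u)
  as.numeric(determinant(sig, TRUE)$modulus + sum(diag(solve(sig, S))) -
               logdetS - nrow(S))
}

#' @export
print.two_factor_fit <- function(x, ...) {
  cat(sprintf(paste0("Two-factor structural model (n = %d)%s\n",
                     "chi-square = %.3f, df = %d, p = %.4g; ",
                     "chi2/df = %.3f; GFI = %.3f, CFI = %.3f\n"),
              x$n, if (x$converged) "" else "  [NOT CONVERGED]",
              x$chi_square, x$df, x$p_value,
              x$chi_square / max(x$df, 1), x$gfi, x$cfi))
  cat("Structural coefficients: lv1 ->", sprintf("%.3f", x$structural[1]),
      "; lv2 ->", sprintf("%.3f", x$structural[2]),
      sprintf("; factor correlation %.3f\n", x$phi))
  cat("Standardized loadings:\n")
  print(round(x$loadings, 3))
  invisible(x)
}

#' @export
summary.two_factor_fit <- function(object, ...) {
  tab <- data.frame(indicator = names(object$loadings),
                    latent = c(rep("lv1", length(object$spec$lv1)),
                               rep("lv2", length(object$spec$lv2))),
                    loading = unname(object$loadings),
                    se = unname(object$loading_se),
                    p_value = unname(object$loading_p))
  out <- list(loadings = tab, structural = object$structural,
              phi = object$phi,
              fit = c(chi_square = object$chi_square, df = object$df,
                      p = object$p_value, gfi = object$gfi,
                      cfi = object$cfi))
  class(out) <- "summary.two_factor_fit"
  out
}

#' @export
print.summary.two_factor_fit <- function(x, ...) {
  print(x$loadings, digits = 3)
  cat("\nStructural:", sprintf("lv1 %.3f, lv2 %.3f (phi %.3f)\n",
                               x$structural[1], x$structural[2], x$phi))
  print(round(x$fit, 4))
  invisible(x)
}

#' @export
coef.two_factor_fit <- function(object, ...) {
  c(object$loadings, structure(object$structural,
                               names = c("lv1->outcome", "lv2->outcome")),
    phi = object$phi)
}

#' Regression-method factor scores
#'
#' Empirical-Bayes linear prediction of each subject's factor values from
#' the fitted model: scores = (z - center) Sigma^-1 Lambda Phi, computed
#' over every observed model variable (indicators and outcome), on the same
#' standardization as the fit. Over the fitting sample the scores have mean
#' zero by construction.
#'
#' @param object a converged [fit_two_factor_model()] result.
#' @param newdata data.frame containing every model column; defaults would
#'   be the fitting data.
#' @param ... unused.
#' @return matrix with columns `lv1`, `lv2`, one row per subject.
#' @export
predict.two_factor_fit <- function(object, newdata, ...) {
  miss <- setdiff(object$vars, names(newdata))
  if (length(miss))
    stop("missing indicator column(s): ", paste(miss, collapse = ", "))
  z <- as.matrix(newdata[, object$vars])
  if (anyNA(z)) stop("missing values in model variables")
  m <- length(object$vars)
  z <- sweep(z, 2, object$center[object$vars])
  z[, seq_len(m - 1)] <- sweep(z[, seq_len(m - 1), drop = FALSE], 2,
                               object$indicator_scale, "/")
  sc <- z %*% solve(object$Sigma, object$Lambda %*% object$Phi)
  colnames(sc) <- c("lv1", "lv2")
  sc
}

#' Iterative indicator pruning
#'
#' Refits the model repeatedly, each time dropping the weakest indicator
#' whose loading is non-significant (Wald p >= `p_threshold`) or whose
#' absolute standardized loading is below `loading_threshold` (weakest
#' first, by Wald z). Stops when nothing qualifies or when a drop would
#' leave a latent with fewer than 2 indicators (warned, not an error).
#'
#' @param data fitting data.frame.
#' @param spec initial [latent_model_spec()].
#' @param p_threshold Wald significance threshold.
#' @param loading_threshold minimum |standardized loading|.
#' @param ... passed to [fit_two_factor_model()].
#' @return list: `spec` (pruned), `removed` (character), `fit` (final fit).
#' @export
prune_indicators <- function(data, spec, p_threshold = 0.05,
                             loading_threshold = 0.2, ...) {
  removed <- character(0)
  repeat {
    fit <- fit_two_factor_model(data, spec, ...)
    lp <- fit$loading_p
    ll <- fit$loadings
    weak <- names(ll)[is.na(lp) | lp >= p_threshold |
                        abs(ll) < loading_threshold]
    if (!length(weak)) break
    zval <- abs(ll[weak]) / fit$loading_se[weak]
    zval[is.na(zval)] <- -Inf
    drop <- weak[order(zval)][1]
    in_lv1 <- drop %in% spec$lv1
    if ((in_lv1 && length(spec$lv1) <= 2) ||
        (!in_lv1 && length(spec$lv2) <= 2)) {
      warning("pruning halted: dropping '", drop,
              "' would leave a latent with < 2 indicators")
      break
    }
    if (in_lv1) spec$lv1 <- setdiff(spec$lv1, drop)
    else spec$lv2 <- setdiff(spec$lv2, drop)
    removed <- c(removed, drop)
  }
  list(spec = spec, removed = removed, fit = fit)
}

#' Compare factor scores between groups
#'
#' Wilcoxon rank-sum comparison of each latent variable's scores between two
#' groups (delegating to [compare_groups()]).
#'
#' @param scores matrix from [predict.two_factor_fit()].
#' @param groups two-level group label per subject.
#' @return data.frame: `latent`, `statistic`, `p_value`.
#' @export
compare_factor_scores <- function(scores, groups) {
  groups <- as.character(groups)
  gl <- sort(unique(groups))
  if (length(gl) != 2) stop("exactly two groups required")
  if (any(table(groups) == 0)) stop("empty group")
  do.call(rbind, lapply(colnames(scores), function(lv) {
    ht <- compare_groups(scores[groups == gl[1], lv],
                         scores[groups == gl[2], lv],
                         method = "wilcoxon_rank_sum")
    data.frame(latent = lv, statistic = ht$statistic, p_value = ht$p_value)
  }))
}
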