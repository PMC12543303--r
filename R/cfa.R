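#' RMSEA from a chi-square fit statistic
#'
#' `sqrt(max(0, (chi2 - df) / (df * (n - 1))))` -- the root mean square
#' error of approximation implied by a model chi-square.
#'
#' @param chi2 Model chi-square.
#' @param df Model degrees of freedom.
#' @param n Sample size.
#' @return RMSEA point estimate.
#' @export
rmsea_from_chi2 <- function(chi2, df, n) {
  sqrt(max(0, (chi2 - df) / (df * (n - 1))))
}

# 90% RMSEA interval from the noncentral chi-square: the lower/upper ncp
# solve pchisq(chi2, df, ncp) = 0.95 / 0.05.
rmsea_interval <- function(chi2, df, n, level = 0.90) {
  a <- (1 - level) / 2
  solve_ncp <- function(target) {
    f <- function(ncp) pchisq(chi2, df, ncp) - target
    if (f(0) < target - 1 + 1e-12) return(NA_real_)
    hi <- max(chi2 * 2, 10)
    while (f(hi) > 0 && hi < 1e7) hi <- hi * 2
    uniroot(f, c(0, hi), tol = 1e-10)$root
  }
  lo <- if (pchisq(chi2, df) < 1 - a) 0 else solve_ncp(1 - a)
  hi <- if (pchisq(chi2, df) < a) 0 else solve_ncp(a)
  c(lower = sqrt(max(0, lo) / (df * (n - 1))),
    upper = sqrt(max(0, hi) / (df * (n - 1))))
}

#' One-factor confirmatory factor analysis by maximum likelihood
#'
#' Fits a single latent factor to four indicators (latent variance fixed to
#' 1, all loadings free, uncorrelated residuals) by minimizing the ML
#' discrepancy `F = log|Sigma| + tr(S Sigma^-1) - log|S| - p`. The model has
#' df = 2 (10 sample moments, 8 free parameters). Fit indices: chi2 =
#' (n-1) F at the optimum with its p value; CFI against the independence
#' baseline; RMSEA with a 90% noncentral interval; SRMR over standardized
#' residual moments. Factor scores use the regression method and are
#' min-max scaled to [0, 1] (ranges recorded for held-out scoring).
#'
#' Indicators are min-max scaled to [0, 1] before fitting (the memory
#' indicators' conventional scale); the ML discrepancy and all standardized
#' quantities are invariant to this diagonal rescaling. Residual variances
#' are optimized on the log scale, so a Heywood tendency shows up as a
#' boundary solution and is flagged (`heywood`) with a warning rather than
#' silently absorbed.
#'
#' @param indicators n x 4 numeric matrix/data.frame; rows with missing
#'   values are dropped (complete-case, count reported as `n`).
#' @return List of class `cfa_fit`: `loadings`, `std_loadings`,
#'   `residual_variances`, `chi2`, `df`, `p`, `cfi`, `rmsea`,
#'   `rmsea_ci` (90%), `srmr`, `factor_scores` (in [0, 1]),
#'   `factor_scores_raw`, `score_range`, `n`, `converged`, `heywood`.
#' @export
fit_one_factor_cfa <- function(indicators) {
  X <- as.matrix(indicators)
  if (ncol(X) != 4L) stop("exactly 4 indicators required")
  X <- X[complete.cases(X), , drop = FALSE]
  n <- nrow(X)
  if (n < 50L) stop("need at least 50 complete cases, got ", n)
  rng <- apply(X, 2, range)
  X <- sweep(sweep(X, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
  p <- 4L
  S <- cov(X)
  logdetS <- determinant(S, logarithm = TRUE)$modulus
  ev <- eigen(S, symmetric = TRUE)
  l0 <- sqrt(max(ev$values[1], 1e-8)) * ev$vectors[, 1]
  if (sum(l0) < 0) l0 <- -l0
  psi0 <- pmax(diag(S) - l0^2, 0.05 * diag(S))
  fml <- function(par) {
    lam <- par[1:4]; psi <- exp(pmax(par[5:8], -20))
    Sigma <- tcrossprod(lam) + diag(psi)
    ld <- determinant(Sigma, logarithm = TRUE)
    if (ld$sign <= 0) return(1e10)
    as.numeric(ld$modulus + sum(diag(solve(Sigma, S))) - logdetS - p)
  }
  gml <- function(par) {
    lam <- par[1:4]; psi <- exp(pmax(par[5:8], -20))
    Sigma <- tcrossprod(lam) + diag(psi)
    Si <- tryCatch(solve(Sigma), error = function(e) NULL)
    if (is.null(Si)) return(rep(0, 8))
    A <- Si - Si %*% S %*% Si          # dF = tr(A dSigma)
    c(2 * as.numeric(A %*% lam), diag(A) * psi)
  }
  opt <- optim(c(l0, log(psi0)), fml, gml, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0) warning("CFA optimizer did not converge")
  lam <- opt$par[1:4]; psi <- exp(pmax(opt$par[5:8], -20))
  if (sum(lam) < 0) lam <- -lam   # sign indeterminacy: orient positive
  heywood <- any(psi < 1e-3 * diag(S))
  if (heywood) warning("Heywood tendency: residual variance at boundary")
  Sigma <- tcrossprod(lam) + diag(psi)
  df <- p * (p + 1) / 2 - 2 * p   # 10 moments - 8 free parameters = 2
  chi2 <- (n - 1) * opt$value
  chi2_base <- (n - 1) * as.numeric(sum(log(diag(S))) - logdetS)
  df_base <- p * (p - 1) / 2
  cfi <- 1 - max(chi2 - df, 0) / max(chi2_base - df_base, chi2 - df, 0)
  d <- sqrt(diag(S))
  res <- (S - Sigma) / tcrossprod(d)
  srmr <- sqrt(mean(res[upper.tri(res, diag = TRUE)]^2))
  scores_raw <- as.numeric((X - matrix(colMeans(X), n, p, byrow = TRUE)) %*%
                             solve(Sigma, lam))
  sr <- range(scores_raw)
  scores <- (scores_raw - sr[1]) / diff(sr)
  out <- list(loadings = lam,
              std_loadings = lam / sqrt(lam^2 + psi),
              residual_variances = psi,
              chi2 = chi2, df = df,
              p = pchisq(chi2, df, lower.tail = FALSE),
              cfi = cfi,
              rmsea = rmsea_from_chi2(chi2, df, n),
              rmsea_ci = rmsea_interval(chi2, df, n),
              srmr = srmr,
              factor_scores = scores, factor_scores_raw = scores_raw,
              score_range = sr, indicator_range = rng,
              n = n, converged = opt$convergence == 0, heywood = heywood)
  class(out) <- "cfa_fit"
  out
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf(paste0("<cfa_fit> n=%d, chi2(%d)=%.3f p=%.3f, CFI=%.3f, ",
                     "RMSEA=%.3f [%.3f, %.3f], SRMR=%.3f\n"),
              x$n, x$df, x$chi2, x$p, x$cfi, x$rmsea,
              x$rmsea_ci[1], x$rmsea_ci[2], x$srmr))
  cat("  std loadings:", paste(sprintf("%.3f", x$std_loadings),
                               collapse = " "), "\n")
  invisible(x)
}
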