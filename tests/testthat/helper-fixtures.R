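# Shared fixtures (built once per session) and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())
fixture <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- maker()
  .fixture_cache[[name]]
}

# small mixed cohort for structural/coupling unit tests
small_cohort <- function() fixture("small", function() {
  cfg <- generator_config(n_per_group = c(CN = 14, MCI = 12, AD = 11),
                          n_nodes = 12, dmn_size = 4, n_planted_edges = 2)
  generate_cohort(cfg, seed = 5)
})

# paper-scale cohort at the default study conditions
full_cohort <- function() fixture("full", function()
  generate_cohort(generator_config(), seed = 11))

# null generator: no planted coupling at any level
null_config <- function(...) {
  generator_config(profile_rho = c(CN = 0, MCI = 0, AD = 0),
                   edge_slope = c(CN = 0, MCI = 0, AD = 0),
                   n_planted_edges = 0, cognition_effect = 0, ...)
}

# --- independent oracles -------------------------------------------------

# Pearson r from raw covariance sums (no stats::cor)
oracle_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]; n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

# nodal strength by exhaustive loop over incident present edges
oracle_strength <- function(m, node0) {
  w <- m$weights; p <- m$present
  i <- node0 + 1L
  acc <- 0; any_edge <- FALSE
  for (j in seq_len(ncol(w))) if (j != i && p[i, j]) {
    acc <- acc + w[i, j]; any_edge <- TRUE
  }
  if (any_edge) acc else NA_real_
}

# least-squares betas via normal equations
oracle_lm_beta <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))

# partial F for dropping columns `drop` from design X (normal equations)
oracle_partial_F <- function(X, y, drop) {
  sse <- function(M) {
    b <- solve(crossprod(M), crossprod(M, y))
    sum((y - M %*% b)^2)
  }
  f <- sse(X); r <- sse(X[, -drop, drop = FALSE])
  q <- length(drop); df2 <- nrow(X) - ncol(X)
  ((r - f) / q) / (f / df2)
}

# Tukey-Kramer adjusted p for one pair from group data (textbook formula)
oracle_tukey_p <- function(values, groups, a, b) {
  groups <- factor(groups)
  k <- nlevels(groups)
  ni <- tapply(values, groups, length)
  mi <- tapply(values, groups, mean)
  df <- length(values) - k
  mse <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2))) / df
  se <- sqrt(mse / 2 * (1 / ni[a] + 1 / ni[b]))
  stat <- abs(mi[a] - mi[b]) / se
  unname(ptukey(stat, k, df, lower.tail = FALSE))
}
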