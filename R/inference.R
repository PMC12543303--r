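#' Bonferroni-corrected significance threshold across SC metrics
#'
#' Edge- and node-wise permutation tests are thresholded at a base two-tailed
#' level corrected for the number of SC weightings tested (four metrics:
#' 0.01 / 4 = 0.0025).
#'
#' @param base_p Uncorrected threshold.
#' @param n_metrics Number of SC metrics tested.
#' @return `base_p / n_metrics`.
#' @export
bonferroni_threshold <- function(base_p = 0.01, n_metrics = 4L) {
  stopifnot(n_metrics >= 1)
  base_p / n_metrics
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment, intended to be applied to p values pooled across
#' all edges of all group comparisons. Thin wrapper over
#' `stats::p.adjust(method = "BH")`; `NA`s are preserved.
#'
#' @param p Vector of p values in (0, 1].
#' @return Adjusted q values, capped at 1, monotone.
#' @export
bh_fdr <- function(p) p.adjust(p, method = "BH")

#' Compare two independent correlations via Fisher's r-to-Z
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-tailed normal p. Used to compare group-average overall couplings,
#' with n the number of edge pairs entering each group-average correlation.
#'
#' @param r1,r2 Correlations, `|r| < 1`.
#' @param n1,n2 Effective sample sizes, `> 3`.
#' @return List with `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (any(abs(c(r1, r2)) >= 1)) stop("|r| must be < 1")
  if (any(c(n1, n2) <= 3)) stop("n must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Permutation test for group differences in edge- or node-wise coupling
#'
#' The observed statistic per key (edge or node) is the difference in
#' coupling r between two groups. The null is built by reassigning the
#' pooled participants to pseudo-groups of the original sizes -- each
#' subject's SC and FC stay paired, only group labels are exchanged -- and
#' recomputing the coupling difference per key. Two-tailed p uses the
#' add-one estimator `(1 + #{|null| >= |obs|}) / (1 + n_perm)`, so the
#' smallest attainable p is `1/(n_perm + 1)`. With `exhaustive = TRUE` all
#' label assignments are enumerated and p is the exact proportion
#' `#{|null| >= |obs|} / n_assignments` (the identity assignment included).
#'
#' @param cohort An `fc_cohort`.
#' @param groupA,groupB Distinct group labels; the statistic is
#'   `r_groupA - r_groupB`.
#' @param level `"edge"` or `"node"`.
#' @param modality SC modality.
#' @param n_perm Number of permutations (default 5000; below 100 warns).
#' @param seed Optional seed for the permutation stream.
#' @param exhaustive Enumerate all assignments (small cohorts only).
#' @param min_subjects Passed to the coupling estimators.
#' @param base_p,n_metrics Bonferroni flag parameters
#'   (see [bonferroni_threshold()]).
#' @return `data.frame` of class `permutation_test_result` with one row per
#'   key: `key`, `r_groupA`, `r_groupB`, `diff`, `p`, `passes_bonferroni`,
#'   `q_fdr` (BH within this comparison; pool across comparisons with
#'   [bh_fdr()] for the full correction family), plus attributes
#'   `n_permutations`, `groups`, `level`, `modality`, `threshold`.
#' @export
permutation_test <- function(cohort, groupA, groupB, level = c("edge", "node"),
                             modality, n_perm = 5000L, seed = NULL,
                             exhaustive = FALSE, min_subjects = 10L,
                             base_p = 0.01, n_metrics = 4L) {
  level <- match.arg(level)
  modality <- match.arg(modality, SC_MODALITIES)
  if (identical(groupA, groupB)) stop("groups must be distinct")
  if (!exhaustive && n_perm < 100L) warning("n_perm < 100 is unreliable")
  if (!is.null(seed)) set.seed(as.integer(seed))
  rowsA <- cohort_group_rows(cohort, groupA)
  rowsB <- cohort_group_rows(cohort, groupB)
  if (length(intersect(rowsA, rowsB))) stop("groups overlap")
  if (level == "edge") {
    e <- cohort$edges[[modality]]
    X <- e$values; Y <- cohort$edges$FC$values
    W <- e$present & cohort$edges$FC$present
    key <- seq_len(ncol(X))
  } else {
    X <- cohort_strengths(cohort, modality)
    Y <- cohort_strengths(cohort, "FC")
    W <- is.finite(X) & is.finite(Y)
    key <- cohort$atlas$label
  }
  X[!W] <- 0; Y[!W] <- 0  # masked cells never enter the sums
  diff_for <- function(ra, rb)
    masked_col_corr(X, Y, W, ra, min_subjects) -
      masked_col_corr(X, Y, W, rb, min_subjects)
  obs <- diff_for(rowsA, rowsB)
  pool <- c(rowsA, rowsB)
  nA <- length(rowsA)
  if (exhaustive) {
    picks <- combn(length(pool), nA)
    nulls <- apply(picks, 2, function(ix)
      diff_for(pool[ix], pool[-ix]))
    nulls <- matrix(nulls, ncol = ncol(picks))
    ge <- rowSums(abs(nulls) >= abs(obs) - 1e-12, na.rm = TRUE)
    nv <- rowSums(!is.na(nulls))
    p <- ifelse(is.na(obs) | nv == 0, NA_real_, ge / nv)
    n_used <- ncol(picks)
  } else {
    ge <- numeric(length(obs))
    nv <- integer(length(obs))
    for (b in seq_len(n_perm)) {
      ix <- sample.int(length(pool), nA)
      d <- diff_for(pool[ix], pool[-ix])
      ge <- ge + (!is.na(d) & abs(d) >= abs(obs) - 1e-12)
      nv <- nv + !is.na(d)
    }
    p <- ifelse(is.na(obs) | nv == 0, NA_real_, (1 + ge) / (1 + nv))
    n_used <- n_perm
  }
  thr <- bonferroni_threshold(base_p, n_metrics)
  rA <- masked_col_corr(X, Y, W, rowsA, min_subjects)
  rB <- masked_col_corr(X, Y, W, rowsB, min_subjects)
  out <- data.frame(key = key, r_groupA = rA, r_groupB = rB, diff = obs,
                    p = p, passes_bonferroni = !is.na(p) & p < thr,
                    q_fdr = bh_fdr(p), stringsAsFactors = FALSE)
  attr(out, "n_permutations") <- n_used
  attr(out, "groups") <- c(groupA, groupB)
  attr(out, "level") <- level
  attr(out, "modality") <- modality
  attr(out, "threshold") <- thr
  class(out) <- c("permutation_test_result", "data.frame")
  out
}

#' Group effect on subject-level coupling, controlling for age and sex
#'
#' Linear model `response ~ group + age + sex`; the group effect is the
#' partial (type II) F test, and post hoc pairwise comparisons use contrasts
#' of estimated marginal means (covariates held at their means, sex averaged
#' over) on the model's residual degrees of freedom.
#'
#' @param data `data.frame` with the response and `group`, `age`, `sex`
#'   columns (e.g. [cohort_subject_coupling()] merged with a manifest).
#' @param response Name of the response column.
#' @param covariates Covariate column names.
#' @return List with `F`, `df1`, `df2`, `p`, `contrasts` (`data.frame`:
#'   contrast, estimate, t, df, p), and the fitted `lm`.
#' @export
ancova_group_effect <- function(data, response = "r",
                                covariates = c("age", "sex")) {
  data <- data[complete.cases(data[, c(response, "group", covariates)]), ]
  if (length(unique(data$group)) < 3)
    stop("need at least 3 groups")
  data$group <- factor(data$group, levels = intersect(GROUPS,
                                                      unique(data$group)))
  fml <- as.formula(paste(response, "~ group +",
                          paste(covariates, collapse = " + ")))
  fit <- lm(fml, data = data)
  if (any(is.na(coef(fit)))) stop("rank-deficient model")
  a2 <- car::Anova(fit, type = 2)
  emm <- emmeans::emmeans(fit, "group")
  ctr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  list(F = a2["group", "F value"], df1 = a2["group", "Df"],
       df2 = fit$df.residual, p = a2["group", "Pr(>F)"],
       contrasts = data.frame(contrast = ctr$contrast,
                              estimate = ctr$estimate, t = ctr$t.ratio,
                              df = ctr$df, p = ctr$p.value),
       fit = fit)
}

#' Chi-square test of independence with adjusted standardized residuals
#'
#' Pearson chi-square (no continuity correction) on an R x C count table,
#' with cell-level adjusted standardized residuals
#' `(O - E) / sqrt(E (1 - row/N) (1 - col/N))` for post hoc inspection.
#'
#' @param table Numeric matrix of counts (e.g. sex x group).
#' @return List with `chi2`, `df`, `p`, `expected`, `adjusted_residuals`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin in contingency table")
  ct <- chisq.test(table, correct = FALSE)
  if (any(ct$expected <= 0)) stop("expected counts must be positive")
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected,
       adjusted_residuals = ct$stdres)
}

#' Group comparisons of a cognitive outcome
#'
#' One-way ANOVA with Tukey HSD post hoc pairs, plus pairwise Wilcoxon
#' rank-sum tests with BH FDR over the pairs.
#'
#' @param data `data.frame` with the outcome and a `group` column.
#' @param outcome Outcome column name (e.g. `"mmse"`).
#' @return List with `F`, `df`, `p`, `tukey` (`data.frame`: pair, diff,
#'   p_adj) and `wilcoxon` (`data.frame`: pair, W, p, q_fdr).
#' @export
outcome_group_tests <- function(data, outcome) {
  data <- data[complete.cases(data[, c(outcome, "group")]), ]
  data$group <- factor(data$group, levels = intersect(GROUPS,
                                                      unique(data$group)))
  if (any(table(data$group) < 2)) stop("each group needs >= 2 observations")
  fml <- as.formula(paste(outcome, "~ group"))
  fit <- aov(fml, data = data)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairs <- combn(levels(data$group), 2)
  wil <- apply(pairs, 2, function(pr) {
    x <- data[[outcome]][data$group == pr[1]]
    y <- data[[outcome]][data$group == pr[2]]
    wt <- suppressWarnings(wilcox.test(x, y))
    c(W = unname(wt$statistic), p = wt$p.value)
  })
  list(F = an["group", "F value"], df = unname(an[, "Df"]),
       p = an["group", "Pr(>F)"],
       tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL),
       wilcoxon = data.frame(pair = paste(pairs[2, ], pairs[1, ], sep = "-"),
                             W = wil["W", ], p = wil["p", ],
                             q_fdr = bh_fdr(wil["p", ]), row.names = NULL))
}
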