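#' Memory composite from the RAVLT indicators of a cohort
#'
#' Fits the one-factor CFA ([fit_one_factor_cfa()]) on the four RAVLT scores
#' of all completers and returns per-subject composite scores (in [0, 1];
#' `NA` for non-completers) with the fit attached.
#'
#' @param cohort An `fc_cohort`.
#' @return Numeric vector aligned with the manifest, attribute `"fit"`.
#' @export
memory_composite <- function(cohort) {
  man <- cohort$manifest
  ind <- as.matrix(man[, c("ravlt_learning", "ravlt_immediate",
                           "ravlt_delay30", "ravlt_recognition")])
  cc <- complete.cases(ind)
  fit <- fit_one_factor_cfa(ind[cc, , drop = FALSE])
  scores <- rep(NA_real_, nrow(man))
  scores[cc] <- fit$factor_scores
  attr(scores, "fit") <- fit
  scores
}

#' Regress cognition on DMN coupling for one SC modality
#'
#' Linear model `outcome ~ dmn_edge_coupling + dmn_node_coupling + age +
#' sex + icv`, one model per SC modality. The response and all continuous
#' predictors are z-scored so coefficients are standardized betas; sex
#' enters as a factor. Collinearity diagnostics (VIF, tolerance = 1/VIF,
#' max pairwise predictor correlation) are attached and a warning raised if
#' VIF > 10, tolerance < 0.02 or |corr| > 0.8.
#'
#' @param cohort An `fc_cohort`.
#' @param modality SC modality.
#' @param outcome `"mmse"` or `"memory"` (CFA composite).
#' @param memory_scores Optional precomputed [memory_composite()] vector
#'   (avoids refitting the CFA per modality).
#' @return `data.frame` of class `regression_report`, one row per term:
#'   `modality`, `outcome`, `term`, `beta`, `ci_lo`, `ci_hi`, `p`,
#'   `is_coupling_term`; attributes `diagnostics` (VIF/tolerance/max corr),
#'   `n`, `fit`.
#' @export
cognition_regression <- function(cohort, modality, outcome = c("mmse", "memory"),
                                 memory_scores = NULL) {
  modality <- match.arg(modality, SC_MODALITIES)
  outcome <- match.arg(outcome)
  man <- cohort$manifest
  dmn <- cohort_dmn_coupling(cohort, modality)
  y <- if (outcome == "mmse") man$mmse else {
    if (is.null(memory_scores)) memory_scores <- memory_composite(cohort)
    as.numeric(memory_scores)
  }
  d <- data.frame(y = y, dmn_edge_coupling = dmn$edge_r,
                  dmn_node_coupling = dmn$node_r,
                  age = man$age, sex = factor(man$sex), icv = man$icv)
  d <- d[complete.cases(d), ]
  zs <- function(v) (v - mean(v)) / sd(v)
  for (v in c("y", "dmn_edge_coupling", "dmn_node_coupling", "age", "icv"))
    d[[v]] <- zs(d[[v]])
  fit <- lm(y ~ dmn_edge_coupling + dmn_node_coupling + age + sex + icv,
            data = d)
  vif <- car::vif(fit)
  cont <- d[, c("dmn_edge_coupling", "dmn_node_coupling", "age", "icv")]
  cmat <- cor(cont)
  max_corr <- max(abs(cmat[upper.tri(cmat)]))
  if (any(vif > 10) || any(1 / vif < 0.02) || max_corr > 0.8)
    warning("collinearity thresholds breached (VIF > 10, tolerance < 0.02, ",
            "or predictor |corr| > 0.8)")
  sm <- summary(fit)$coefficients
  ci <- confint(fit)
  terms <- setdiff(rownames(sm), "(Intercept)")
  out <- data.frame(modality = modality, outcome = outcome, term = terms,
                    beta = sm[terms, "Estimate"],
                    ci_lo = ci[terms, 1], ci_hi = ci[terms, 2],
                    p = sm[terms, "Pr(>|t|)"],
                    is_coupling_term = terms %in% c("dmn_edge_coupling",
                                                    "dmn_node_coupling"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "diagnostics") <- list(vif = vif, tolerance = 1 / vif,
                                   max_predictor_corr = max_corr)
  attr(out, "n") <- nrow(d)
  attr(out, "fit") <- fit
  class(out) <- c("regression_report", "data.frame")
  out
}

#' Full coupling-on-cognition report
#'
#' Runs [cognition_regression()] for every SC modality and both outcomes and
#' applies BH FDR over the family of coupling-term coefficients (4
#' modalities x 2 outcomes x 2 terms = 16 tests; covariates are excluded
#' from the family and get `NA` q).
#'
#' @param cohort An `fc_cohort`.
#' @param modalities SC modalities to include.
#' @param outcomes Outcomes to include.
#' @return `data.frame` with the rows of all models plus `q_fdr`.
#' @export
cognition_report <- function(cohort, modalities = SC_MODALITIES,
                             outcomes = c("mmse", "memory")) {
  mem <- if ("memory" %in% outcomes) memory_composite(cohort) else NULL
  rows <- list()
  for (oc in outcomes)
    for (mod in modalities)
      rows[[paste(oc, mod)]] <-
        cognition_regression(cohort, mod, oc, memory_scores = mem)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q_fdr <- NA_real_
  fam <- out$is_coupling_term
  out$q_fdr[fam] <- bh_fdr(out$p[fam])
  if (!is.null(mem)) attr(out, "cfa_fit") <- attr(mem, "fit")
  out
}
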