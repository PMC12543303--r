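# Pearson r between paired vectors under a joint usability mask.
# Fewer than min_pairs usable pairs, or zero variance, gives NA.
couple_vectors <- function(sc, fc, min_pairs = 3L, warn = TRUE) {
  ok <- is.finite(sc) & is.finite(fc)
  if (sum(ok) < min_pairs) {
    if (warn) warning("fewer than ", min_pairs, " usable (SC, FC) pairs")
    return(NA_real_)
  }
  x <- sc[ok]; y <- fc[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

# Column-wise Pearson r between X and Y over rows `rows`, using only cells
# where W is TRUE. Columns with fewer than min_n contributing rows, or zero
# variance, get NA. Shared workhorse of edge-wise/node-wise coupling and the
# permutation engine.
masked_col_corr <- function(X, Y, W, rows, min_n = 10L) {
  Wr <- W[rows, , drop = FALSE]
  Xr <- X[rows, , drop = FALSE] * Wr
  Yr <- Y[rows, , drop = FALSE] * Wr
  Xr[!Wr] <- 0; Yr[!Wr] <- 0
  nk <- colSums(Wr)
  sx <- colSums(Xr); sy <- colSums(Yr)
  sxx <- colSums(Xr * Xr); syy <- colSums(Yr * Yr)
  sxy <- colSums(Xr * Yr)
  num <- nk * sxy - sx * sy
  den2 <- (nk * sxx - sx^2) * (nk * syy - sy^2)
  r <- ifelse(nk >= min_n & den2 > 0, num / sqrt(pmax(den2, 0)), NA_real_)
  r[is.nan(r)] <- NA_real_
  r
}

apply_sign_filter <- function(fc, fc_sign_filter) {
  switch(fc_sign_filter,
         all = rep(TRUE, length(fc)),
         positive = !is.na(fc) & fc > 0,
         negative = !is.na(fc) & fc < 0,
         stop("fc_sign_filter must be all/positive/negative"))
}

#' Subject-level overall SC-FC coupling
#'
#' Pearson correlation between one subject's SC edge weights and the matching
#' FC edge weights. Only direct connections enter: FC edges with no SC
#' counterpart are excluded. The edge set can be restricted to a scope
#' (whole connectome, within-DMN, or one network) and to positive-only or
#' negative-only FC edges (FC exactly 0 belongs to neither sign).
#'
#' @param subj A `subject_record` from [cohort_subject()].
#' @param modality SC modality: `"FD"`, `"logFbC"`, `"FDC"`, `"streamline"`.
#' @param scope `"whole"`, `"dmn"`, or `"network:<name>"` (see
#'   [scope_edges()]).
#' @param fc_sign_filter `"all"`, `"positive"` or `"negative"`.
#' @param min_pairs Minimum usable pairs; below this the value is `NA` with
#'   a warning.
#' @return A single Pearson r (or `NA`).
#' @export
subject_coupling <- function(subj, modality, scope = "whole",
                             fc_sign_filter = "all", min_pairs = 3L) {
  stopifnot(inherits(subj, "subject_record"))
  modality <- match.arg(modality, SC_MODALITIES)
  sc <- vectorize(subj$matrices[[modality]])
  fc <- vectorize(subj$matrices[["FC"]])
  keep <- sc$present & fc$present & scope_edges(subj$atlas, scope) &
    apply_sign_filter(fc$values, fc_sign_filter)
  couple_vectors(ifelse(keep, sc$values, NA_real_),
                 ifelse(keep, fc$values, NA_real_), min_pairs)
}

#' Subject-level coupling for every subject in a cohort
#'
#' @param cohort An `fc_cohort`.
#' @inheritParams subject_coupling
#' @return `data.frame` with `subject_id`, `group`, `r`, `n_pairs`.
#' @export
cohort_subject_coupling <- function(cohort, modality, scope = "whole",
                                    fc_sign_filter = "all", min_pairs = 3L) {
  modality <- match.arg(modality, SC_MODALITIES)
  sc <- cohort$edges[[modality]]
  fc <- cohort$edges$FC
  sel <- scope_edges(cohort$atlas, scope)
  n <- nrow(cohort$manifest)
  r <- numeric(n); np <- integer(n)
  for (i in seq_len(n)) {
    keep <- sc$present[i, ] & fc$present[i, ] & sel &
      apply_sign_filter(fc$values[i, ], fc_sign_filter)
    np[i] <- sum(keep)
    r[i] <- couple_vectors(ifelse(keep, sc$values[i, ], NA_real_),
                           ifelse(keep, fc$values[i, ], NA_real_),
                           min_pairs, warn = FALSE)
  }
  data.frame(subject_id = cohort$manifest$subject_id,
             group = cohort$manifest$group, r = r, n_pairs = np,
             stringsAsFactors = FALSE)
}

#' Group-average overall coupling
#'
#' Each SC and FC edge value is averaged across the participants of one
#' group (ignoring subjects missing that edge), then the two mean-edge
#' vectors are correlated, giving one Pearson r per group.
#'
#' @param cohort An `fc_cohort`.
#' @param group Group label.
#' @inheritParams subject_coupling
#' @return List with `r`, `n_edges` (pairs entering the correlation, the
#'   effective n for [fisher_z_compare()]), `n_subjects`, and the
#'   correlation-test `p`.
#' @export
group_average_coupling <- function(cohort, group, modality, scope = "whole") {
  modality <- match.arg(modality, SC_MODALITIES)
  rows <- cohort_group_rows(cohort, group)
  sc <- cohort$edges[[modality]]; fc <- cohort$edges$FC
  scv <- sc$values[rows, , drop = FALSE]
  scp <- sc$present[rows, , drop = FALSE]
  scv[!scp] <- 0
  nsc <- colSums(scp)
  sc_mean <- ifelse(nsc > 0, colSums(scv) / nsc, NA_real_)
  fcv <- fc$values[rows, , drop = FALSE]
  fcp <- fc$present[rows, , drop = FALSE]
  fcv[!fcp] <- 0
  nfc <- colSums(fcp)
  fc_mean <- ifelse(nfc > 0, colSums(fcv) / nfc, NA_real_)
  sel <- scope_edges(cohort$atlas, scope)
  sc_mean[!sel] <- NA_real_; fc_mean[!sel] <- NA_real_
  ok <- is.finite(sc_mean) & is.finite(fc_mean)
  r <- couple_vectors(sc_mean, fc_mean, warn = FALSE)
  ne <- sum(ok)
  p <- if (!is.na(r) && abs(r) < 1 && ne > 3) {
    tt <- r * sqrt((ne - 2) / (1 - r^2))
    2 * pt(-abs(tt), ne - 2)
  } else NA_real_
  list(r = r, n_edges = ne, n_subjects = length(rows), p = p)
}

#' Edge-wise coupling across participants
#'
#' For each edge, individual SC values are correlated with matching FC values
#' across the participants of one group, giving one coupling r per edge.
#' Edges present in fewer than `min_subjects` participants, or with zero
#' variance, are `NA`.
#'
#' @inheritParams group_average_coupling
#' @param min_subjects Minimum participants contributing to an edge.
#' @return Numeric vector of length `n_edges(N)` of Pearson r.
#' @export
edge_wise_coupling <- function(cohort, group, modality, min_subjects = 10L) {
  modality <- match.arg(modality, SC_MODALITIES)
  rows <- cohort_group_rows(cohort, group)
  sc <- cohort$edges[[modality]]; fc <- cohort$edges$FC
  masked_col_corr(sc$values, fc$values, sc$present & fc$present,
                  rows, min_subjects)
}

#' Cohort nodal strengths
#'
#' Per-subject nodal strength (signed sum of present incident edge weights)
#' for one modality. FC strength uses all FC edges, not only those with SC
#' support; SC strength uses the subject's present SC edges. Nodes with no
#' present incident edge are `NA`.
#'
#' @param cohort An `fc_cohort`.
#' @param modality Any modality including `"FC"`.
#' @return Subjects x nodes matrix of strengths.
#' @export
cohort_strengths <- function(cohort, modality) {
  modality <- match.arg(modality, ALL_MODALITIES)
  e <- cohort$edges[[modality]]
  n <- n_nodes(cohort$atlas)
  map <- edge_index_map(n)
  A <- matrix(0, nrow(map), n)
  A[cbind(seq_len(nrow(map)), map$i + 1L)] <- 1
  A[cbind(seq_len(nrow(map)), map$j + 1L)] <- 1
  v <- e$values; v[!e$present] <- 0
  s <- v %*% A
  deg <- e$present %*% A
  s[deg == 0] <- NA_real_
  rownames(s) <- cohort$manifest$subject_id
  colnames(s) <- cohort$atlas$label
  s
}

#' Node-wise strength coupling across participants
#'
#' For each node, individual SC nodal strengths are correlated with matching
#' FC nodal strengths across the participants of one group, giving one
#' coupling r per node.
#'
#' @inheritParams edge_wise_coupling
#' @return Numeric vector of length N of Pearson r (named by node label).
#' @export
node_wise_coupling <- function(cohort, group, modality, min_subjects = 10L) {
  modality <- match.arg(modality, SC_MODALITIES)
  rows <- cohort_group_rows(cohort, group)
  ssc <- cohort_strengths(cohort, modality)
  sfc <- cohort_strengths(cohort, "FC")
  r <- masked_col_corr(ssc, sfc, is.finite(ssc) & is.finite(sfc),
                       rows, min_subjects)
  names(r) <- cohort$atlas$label
  r
}

#' Subject-level DMN coupling (edges and nodes)
#'
#' Two coupling values per participant: the *edge* part correlates SC and FC
#' weights of within-DMN edges; the *node* part correlates SC and FC nodal
#' strengths over the DMN nodes, with strengths computed from all incident
#' edges (not restricted to the DMN).
#'
#' @inheritParams subject_coupling
#' @return List with `edge` and `node` Pearson r.
#' @export
subject_dmn_coupling <- function(subj, modality, min_pairs = 3L) {
  stopifnot(inherits(subj, "subject_record"))
  modality <- match.arg(modality, SC_MODALITIES)
  edge_r <- subject_coupling(subj, modality, scope = "dmn",
                             min_pairs = min_pairs)
  dmn <- which(subj$atlas$is_dmn) - 1L
  s_sc <- node_strength(subj$matrices[[modality]], dmn)
  s_fc <- node_strength(subj$matrices[["FC"]], dmn)
  list(edge = edge_r, node = couple_vectors(s_sc, s_fc, min_pairs))
}

#' @rdname subject_dmn_coupling
#' @param cohort An `fc_cohort`.
#' @return `cohort_dmn_coupling`: `data.frame` with `subject_id`, `group`,
#'   `edge_r`, `node_r`.
#' @export
cohort_dmn_coupling <- function(cohort, modality, min_pairs = 3L) {
  modality <- match.arg(modality, SC_MODALITIES)
  edge <- cohort_subject_coupling(cohort, modality, scope = "dmn",
                                  min_pairs = min_pairs)
  dmn_cols <- which(cohort$atlas$is_dmn)
  ssc <- cohort_strengths(cohort, modality)[, dmn_cols, drop = FALSE]
  sfc <- cohort_strengths(cohort, "FC")[, dmn_cols, drop = FALSE]
  node_r <- vapply(seq_len(nrow(ssc)), function(i)
    couple_vectors(ssc[i, ], sfc[i, ], min_pairs, warn = FALSE), numeric(1))
  data.frame(subject_id = cohort$manifest$subject_id,
             group = cohort$manifest$group,
             edge_r = edge$r, node_r = node_r, stringsAsFactors = FALSE)
}
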