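#' Configuration for the synthetic-cohort generator
#'
#' Defaults emulate the study conditions of the motivating cohort: 225
#' cognitively normal (CN), 142 mild cognitive impairment (MCI) and 25
#' Alzheimer's disease (AD) participants on a 119-node atlas (seven cortical
#' resting-state networks plus a subcortical block) with a 24-node
#' default-mode network; a shared fixel-SC mask of 5,922 of the 7,021
#' possible edges (edges derive from one template tractogram); denser,
#' per-subject streamline-SC masks (mean 5,838 undirected edges, jittered
#' across subjects); signed, fully connected Fisher-Z FC; a within-subject
#' SC-FC profile correlation of 0.24 in every group (the whole-connectome
#' coupling the estimators should recover); planted cross-subject edge
#' slopes on a set of within-DMN edges; and cognition driven by DMN nodal
#' coupling plus a group gradient CN > MCI > AD.
#'
#' @param n_per_group Named counts for CN/MCI/AD.
#' @param n_nodes,dmn_size Atlas size and DMN size.
#' @param sc_density_fixel Fraction of edges present in the shared fixel mask.
#' @param sc_density_streamline Mean per-subject streamline-mask density.
#' @param streamline_density_sd Across-subject SD of that density.
#' @param sc_sigma Log-normal subject noise SD on fixel metric values.
#' @param profile_rho Named per-group within-subject SC-FC profile
#'   correlation, planted against `reference_modality`.
#' @param fc_profile_share Variance share of the shared (cross-subject) edge
#'   profile inside the non-coupled FC component. The default (0.9) makes
#'   the group-average coupling equal the planted within-subject
#'   `profile_rho`: averaging over subjects shrinks the coupled component by
#'   the subject-noise attenuation factor, and a shared-profile share equal
#'   to the square of that factor cancels the shrinkage.
#' @param n_planted_edges Number of within-DMN edges carrying a cross-subject
#'   coupling slope.
#' @param edge_slope Named per-group slope on planted edges (standardized SC
#'   scale).
#' @param fc_center,fc_scale Affine map from the unit-variance latent FC to
#'   the stored Fisher-Z scale (keeps |FC| mostly below 1.5).
#' @param cognition_effect Standardized effect of DMN nodal coupling on the
#'   latent memory factor.
#' @param cognition_group_shift,mmse_group_shift Named group shifts of the
#'   latent memory factor and of MMSE beyond it.
#' @param loadings Four factor loadings for the RAVLT indicators.
#' @param mmse_base,mmse_latent_slope MMSE intercept and slope on the latent.
#' @param ravlt_missing_frac,mmse_missing_frac Named per-group fractions of
#'   subjects with missing scores (defaults reproduce 349 RAVLT completers
#'   and one missing MMSE at full size).
#' @param age_mean,age_sd,female_prob,icv_mean,icv_sd,icv_sex_shift
#'   Demographic distributions (per-group age means, shared SD, per-group
#'   female probability, intracranial volume mean/SD and male shift).
#' @param reference_modality SC modality the FC coupling is planted against.
#' @param seed Default seed for [generate_cohort()].
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_per_group = c(CN = 225, MCI = 142, AD = 25),
                             n_nodes = 119,
                             dmn_size = 24,
                             sc_density_fixel = 5922 / 7021,
                             sc_density_streamline = 5838 / 7021,
                             streamline_density_sd = 546 / 7021,
                             sc_sigma = 0.3,
                             profile_rho = c(CN = 0.24, MCI = 0.24, AD = 0.24),
                             fc_profile_share = 0.9,
                             n_planted_edges = 20,
                             edge_slope = c(CN = 0.5, MCI = 0, AD = 0),
                             fc_center = 0.1,
                             fc_scale = 0.3,
                             cognition_effect = 0.3,
                             cognition_group_shift = c(CN = 0, MCI = -1, AD = -2.2),
                             loadings = c(learning = 0.9, immediate = 0.9,
                                          delay30 = 0.8, recognition = 0.7),
                             mmse_base = 29,
                             mmse_latent_slope = 1,
                             mmse_group_shift = c(CN = 0, MCI = -0.5, AD = -3.5),
                             ravlt_missing_frac = c(CN = 22 / 225, MCI = 15 / 142,
                                                    AD = 6 / 25),
                             mmse_missing_frac = c(CN = 1 / 225, MCI = 0, AD = 0),
                             age_mean = c(CN = 72.3, MCI = 73.9, AD = 74.7),
                             age_sd = 8,
                             female_prob = c(CN = 137 / 225, MCI = 63 / 142,
                                             AD = 7 / 25),
                             icv_mean = 1.4e6,
                             icv_sd = 1.3e5,
                             icv_sex_shift = 1e5,
                             reference_modality = "FD",
                             seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(GROUPS %in% names(cfg$n_per_group)),
            cfg$dmn_size < cfg$n_nodes, cfg$dmn_size >= 2,
            cfg$sc_density_fixel > 0, cfg$sc_density_fixel <= 1,
            cfg$sc_density_streamline > 0, cfg$sc_density_streamline <= 1,
            cfg$reference_modality %in% SC_MODALITIES,
            length(cfg$loadings) == 4)
  class(cfg) <- "generator_config"
  cfg
}

#' Generate an atlas with networks and DMN flags
#'
#' Nodes are partitioned deterministically into a subcortical block (scaled
#' from 19/119 of nodes), a Default network holding exactly `dmn_size` nodes
#' (all flagged DMN), and six further cortical networks sharing the
#' remainder.
#'
#' @param cfg A [generator_config()].
#' @return An [atlas_definition()].
#' @export
generate_atlas <- function(cfg) {
  n <- cfg$n_nodes
  n_sub <- max(1L, round(n * 19 / 119))
  n_default <- cfg$dmn_size
  other <- c("Visual", "Somatomotor", "DorsAttn", "SalVentAttn", "Limbic",
             "Cont")
  n_rest <- n - n_sub - n_default
  if (n_rest < 0) stop("dmn_size too large for n_nodes")
  sizes <- diff(round(seq(0, n_rest, length.out = 7L)))
  network <- c(rep("Default", n_default),
               rep(other, times = sizes),
               rep("Subcortical", n_sub))
  label <- paste0(network, "_",
                  unlist(lapply(split(network, network)[unique(network)],
                                seq_along), use.names = FALSE))
  atlas_definition(0:(n - 1L), label, network,
                   is_dmn = network == "Default")
}

# Cohort-level template: shared fixel mask, per-edge baseline fixel means,
# template streamline counts, shared FC edge profile, planted edge set, and
# the closed-form mean/sd of the reference SC weight used to standardize the
# planted slope without seeing other subjects.
sc_template <- function(cfg, atlas) {
  n <- n_nodes(atlas)
  m <- n_edges(n)
  n_present <- max(3L, round(cfg$sc_density_fixel * m))
  present_idx <- sort(sample.int(m, n_present))
  present <- rep(FALSE, m); present[present_idx] <- TRUE
  mu_fd <- exp(rnorm(m, log(0.5), 0.25))
  mu_fbc <- exp(rnorm(m, 0, 0.25))
  n_stream <- rnbinom(m, size = 1.5, mu = 30) + 1L
  c_profile <- rnorm(m)
  dmn_edges <- which(scope_edges(atlas, "dmn") & present)
  k <- min(cfg$n_planted_edges, length(dmn_edges))
  planted <- if (k > 0L) sort(sample(dmn_edges, k)) else integer(0)
  sig2 <- cfg$sc_sigma^2
  ref_mean <- mu_fd * n_stream * exp(sig2 / 2)
  ref_sd <- mu_fd * n_stream * sqrt((exp(sig2) - 1) * exp(sig2))
  list(n = n, m = m, present = present, mu_fd = mu_fd, mu_fbc = mu_fbc,
       n_stream = n_stream, c_profile = c_profile, planted = planted,
       ref_mean = ref_mean, ref_sd = ref_sd)
}

# One subject's SC edge vectors (internal; values NA where absent).
gen_sc_vectors <- function(cfg, tpl) {
  m <- tpl$m; pr <- tpl$present
  fd_val <- tpl$mu_fd * exp(rnorm(m, 0, cfg$sc_sigma))
  fbc_val <- tpl$mu_fbc * exp(rnorm(m, 0, cfg$sc_sigma))
  fdc_val <- fd_val * fbc_val
  blank <- function(x) { x[!pr] <- NA_real_; x }
  fd_w <- blank(fd_val * tpl$n_stream)
  logfbc_w <- blank(log(fbc_val) * tpl$n_stream)
  fdc_w <- blank(fdc_val * tpl$n_stream)
  dens <- min(1, max(0.05, rnorm(1, cfg$sc_density_streamline,
                                 cfg$streamline_density_sd)))
  smask <- runif(m) < dens
  scount <- rep(NA_real_, m)
  scount[smask] <- rnbinom(sum(smask), size = 0.8, mu = 250) + 1
  list(FD = fd_w, logFbC = logfbc_w, FDC = fdc_w,
       streamline = scount, streamline_present = smask)
}

# One subject's signed FC edge vector. Planted against the reference
# modality: on SC-present edges FC = rho * z(SC) + sqrt(1-rho^2) * (shared
# edge profile + subject noise); z-scoring is linear, so the within-subject
# Pearson coupling equals rho in expectation. Planted edges additionally get
# a cross-subject slope on the analytically standardized SC weight.
gen_fc_vector <- function(cfg, tpl, sc, group) {
  m <- tpl$m; pr <- tpl$present
  rho <- unname(cfg$profile_rho[group])
  a <- cfg$fc_profile_share
  ref <- sc[[cfg$reference_modality]]
  raw <- sqrt(a) * tpl$c_profile + sqrt(1 - a) * rnorm(m)
  u <- ref[pr]
  u <- (u - mean(u)) / sd(u)
  raw[pr] <- rho * u + sqrt(1 - rho^2) * raw[pr]
  b <- unname(cfg$edge_slope[group])
  if (b != 0 && length(tpl$planted)) {
    e <- tpl$planted
    raw[e] <- raw[e] + b * (ref[e] - tpl$ref_mean[e]) / tpl$ref_sd[e]
  }
  cfg$fc_center + cfg$fc_scale * raw
}

#' Generate one subject's structural connectomes
#'
#' Fixel-weighted SC (FD, log(FbC), FDC) on the shared cohort mask plus a
#' per-subject streamline-count SC on a denser, jittered mask. FDC values
#' equal FD x FbC elementwise before log/streamline weighting, and every
#' fixel weight follows the [fixel_edge_weight()] construction (average
#' fixel value times template streamline count).
#'
#' @param cfg A [generator_config()].
#' @param atlas An [atlas_definition()].
#' @param subject_group `"CN"`, `"MCI"` or `"AD"` (reserved; fixel SC is
#'   group-independent at baseline).
#' @param template Optional template from a previous call (shared mask etc.);
#'   generated fresh if `NULL`.
#' @return Named list of [connectome_matrix()] objects (`FD`, `logFbC`,
#'   `FDC`, `streamline`) with the template as attribute `"template"` and
#'   the template streamline counts as attribute `"n_streamlines"`.
#' @export
generate_sc <- function(cfg, atlas, subject_group = "CN", template = NULL) {
  if (is.null(template)) template <- sc_template(cfg, atlas)
  v <- gen_sc_vectors(cfg, template)
  map <- edge_index_map(template$n)
  as_cm <- function(vals, mod, pres) {
    devectorize(structure(list(values = vals, present = pres,
                               index_map = map, modality = mod),
                          class = "edge_vector"))
  }
  out <- list(FD = as_cm(v$FD, "FD", template$present),
              logFbC = as_cm(v$logFbC, "logFbC", template$present),
              FDC = as_cm(v$FDC, "FDC", template$present),
              streamline = as_cm(v$streamline, "streamline",
                                 v$streamline_present))
  attr(out, "template") <- template
  attr(out, "n_streamlines") <- template$n_stream
  out
}

#' Generate one subject's functional connectome
#'
#' Signed, fully connected Fisher-Z FC with the configured within-subject
#' coupling to the subject's own reference-modality SC, a shared edge
#' profile, and planted cross-subject slopes on designated edges. Edges with
#' no SC support still receive FC values.
#'
#' @inheritParams generate_sc
#' @param sc Output of [generate_sc()] for the same subject.
#' @return A [connectome_matrix()] with modality `"FC"`.
#' @export
generate_fc <- function(cfg, atlas, sc, subject_group = "CN") {
  tpl <- attr(sc, "template")
  if (is.null(tpl)) stop("sc must come from generate_sc()")
  vecs <- lapply(sc[SC_MODALITIES], function(m) vectorize(m)$values)
  fc <- gen_fc_vector(cfg, tpl, vecs, subject_group)
  devectorize(structure(list(values = fc, present = rep(TRUE, tpl$m),
                             index_map = edge_index_map(tpl$n),
                             modality = "FC"),
                        class = "edge_vector"))
}

#' Simulate standardized memory-test indicators from a latent factor
#'
#' Four indicators `x_k = loading_k * M + sqrt(1 - loading_k^2) * e_k` with
#' unit-variance residuals, so when `latent` is standard normal the
#' standardized loadings equal `loadings`.
#'
#' @param n Number of subjects (ignored if `latent` given).
#' @param loadings Four loadings in (0, 1).
#' @param latent Optional latent scores; default `rnorm(n)`.
#' @return `n x 4` matrix with attribute `"latent"`.
#' @export
simulate_memory_indicators <- function(n, loadings = c(0.9, 0.9, 0.8, 0.7),
                                       latent = NULL) {
  if (is.null(latent)) latent <- rnorm(n)
  n <- length(latent)
  x <- vapply(loadings,
              function(l) l * latent + sqrt(1 - l^2) * rnorm(n),
              numeric(n))
  colnames(x) <- c("learning", "immediate", "delay30", "recognition")
  attr(x, "latent") <- latent
  x
}

# Fill mmse + ravlt columns of a cohort manifest from DMN nodal coupling.
generate_cognition <- function(cfg, cohort) {
  man <- cohort$manifest
  n <- nrow(man)
  dmn <- cohort_dmn_coupling(cohort, cfg$reference_modality)
  zc <- dmn$node_r
  zc <- (zc - mean(zc, na.rm = TRUE)) / sd(zc, na.rm = TRUE)
  zc[is.na(zc)] <- 0
  ce <- cfg$cognition_effect
  latent <- unname(cfg$cognition_group_shift[man$group]) + ce * zc +
    sqrt(max(0, 1 - ce^2)) * rnorm(n)
  x <- simulate_memory_indicators(n, cfg$loadings, latent = latent)
  clipr <- function(v, lo, hi) pmin(hi, pmax(lo, round(v)))
  man$ravlt_learning <- clipr(5 + 2 * x[, 1], 0, 10)
  man$ravlt_immediate <- clipr(40 + 10 * x[, 2], 0, 75)
  man$ravlt_delay30 <- clipr(8 + 3.5 * x[, 3], 0, 15)
  man$ravlt_recognition <- clipr(12 + 2.5 * x[, 4], 0, 15)
  man$mmse <- clipr(cfg$mmse_base + cfg$mmse_latent_slope * latent +
                      unname(cfg$mmse_group_shift[man$group]), 0, 30)
  for (g in GROUPS) {
    rows <- which(man$group == g)
    drop_r <- round(cfg$ravlt_missing_frac[g] * length(rows))
    if (drop_r > 0) {
      sel <- sample(rows, drop_r)
      man[sel, c("ravlt_learning", "ravlt_immediate", "ravlt_delay30",
                 "ravlt_recognition")] <- NA
    }
    drop_m <- round(cfg$mmse_missing_frac[g] * length(rows))
    if (drop_m > 0) man$mmse[sample(rows, drop_m)] <- NA
  }
  cohort$manifest <- man
  cohort$ground_truth$latent_memory <- latent
  cohort$ground_truth$dmn_node_coupling_z <- zc
  cohort
}

#' Generate a full synthetic cohort
#'
#' Atlas, demographics, per-subject SC (four modalities) and FC connectomes,
#' and cognition, with all planted parameters recorded in `$ground_truth`.
#' Bit-reproducible under a fixed seed.
#'
#' @param cfg A [generator_config()].
#' @param seed Integer seed (default `cfg$seed`).
#' @return An `fc_cohort`: list with `atlas`, `manifest` (one row per
#'   subject), `edges` (per modality: `values` and `present` matrices of
#'   subjects x edges), and `ground_truth`.
#' @examples
#' cfg <- generator_config(n_per_group = c(CN = 8, MCI = 6, AD = 4),
#'                         n_nodes = 15, dmn_size = 4, n_planted_edges = 3)
#' coh <- generate_cohort(cfg, seed = 7)
#' nrow(coh$manifest)
#' @export
generate_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(as.integer(seed))
  atlas <- generate_atlas(cfg)
  tpl <- sc_template(cfg, atlas)
  groups <- rep(GROUPS, times = unname(cfg$n_per_group[GROUPS]))
  n <- length(groups)
  sex <- ifelse(runif(n) < unname(cfg$female_prob[groups]), "F", "M")
  age <- rnorm(n, unname(cfg$age_mean[groups]), cfg$age_sd)
  icv <- rnorm(n, cfg$icv_mean + ifelse(sex == "M", cfg$icv_sex_shift, 0),
               cfg$icv_sd)
  man <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                    group = groups, age = round(age, 1), sex = sex,
                    icv = round(icv),
                    mmse = NA_real_, ravlt_learning = NA_real_,
                    ravlt_immediate = NA_real_, ravlt_delay30 = NA_real_,
                    ravlt_recognition = NA_real_,
                    stringsAsFactors = FALSE)
  m <- tpl$m
  vals <- lapply(setNames(ALL_MODALITIES, ALL_MODALITIES),
                 function(x) matrix(NA_real_, n, m))
  spres <- matrix(FALSE, n, m)
  for (i in seq_len(n)) {
    sv <- gen_sc_vectors(cfg, tpl)
    for (mod in c("FD", "logFbC", "FDC", "streamline"))
      vals[[mod]][i, ] <- sv[[mod]]
    spres[i, ] <- sv$streamline_present
    vals$FC[i, ] <- gen_fc_vector(cfg, tpl, sv, groups[i])
  }
  fixel_pres <- matrix(tpl$present, n, m, byrow = TRUE)
  edges <- list(
    FD = list(values = vals$FD, present = fixel_pres),
    logFbC = list(values = vals$logFbC, present = fixel_pres),
    FDC = list(values = vals$FDC, present = fixel_pres),
    streamline = list(values = vals$streamline, present = spres),
    FC = list(values = vals$FC, present = matrix(TRUE, n, m)))
  cohort <- structure(list(atlas = atlas, manifest = man, edges = edges,
                           ground_truth = list(config = cfg, seed = seed,
                                               template = tpl,
                                               planted_edges = tpl$planted)),
                      class = "fc_cohort")
  generate_cognition(cfg, cohort)
}

#' @export
print.fc_cohort <- function(x, ...) {
  cat(sprintf("<fc_cohort> %d subjects (%s), %d nodes, %d edges\n",
              nrow(x$manifest),
              paste(names(table(x$manifest$group)),
                    table(x$manifest$group), sep = "=", collapse = " "),
              n_nodes(x$atlas), n_edges(n_nodes(x$atlas))))
  invisible(x)
}
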