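#' Pipeline configuration
#'
#' Describes one end-to-end coupling analysis: the cohort source (a directory
#' written by [write_cohort()] or a [generator_config()] to simulate), the SC
#' modalities and edge scopes to analyze, the group pairs for permutation
#' comparisons, permutation count, FC sign filter, seed, and output
#' directory.
#'
#' @param cohort_dir Directory with a cohort on disk, or `NULL` to simulate.
#' @param generator A [generator_config()] (used when `cohort_dir` is NULL).
#' @param modalities SC modalities to analyze.
#' @param scopes Edge scopes for overall coupling tables.
#' @param group_pairs List of 2-vectors of group labels to compare.
#' @param n_perm Permutations per comparison.
#' @param fc_sign FC sign filter for subject-level coupling
#'   (`"all"`/`"positive"`/`"negative"`).
#' @param seed Integer seed covering every stochastic stage.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL, generator = generator_config(),
                            modalities = SC_MODALITIES,
                            scopes = c("whole", "dmn"),
                            group_pairs = list(c("AD", "CN"), c("MCI", "CN"),
                                               c("AD", "MCI")),
                            n_perm = 5000L, fc_sign = "all", seed = 1L,
                            out_dir = "fixelcouple_results") {
  stopifnot(all(modalities %in% SC_MODALITIES))
  cfg <- list(cohort_dir = cohort_dir, generator = generator,
              modalities = modalities, scopes = scopes,
              group_pairs = group_pairs, n_perm = as.integer(n_perm),
              fc_sign = fc_sign, seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `generator`
#' mapping overrides [generator_config()] defaults.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  gen_args <- y$generator
  if (!is.null(gen_args))
    for (nm in c("n_per_group", "profile_rho", "edge_slope"))
      if (!is.null(gen_args[[nm]])) gen_args[[nm]] <- unlist(gen_args[[nm]])
  gen <- do.call(generator_config, if (is.null(gen_args)) list() else gen_args)
  args <- y[setdiff(names(y), "generator")]
  args$generator <- gen
  if (!is.null(args$group_pairs))
    args$group_pairs <- lapply(args$group_pairs, unlist)
  do.call(pipeline_config, args)
}

# 64-bit FNV-1a over the deparsed config, as a 16-hex-digit tag recorded in
# every output file header (determinism check: identical config+code ->
# identical hash and identical outputs).
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 14695981039346656037
  for (b in bytes) h <- ((bitwXor(h, b)) * 1099511628211) %% 2^64
  sprintf("%016x", h)
}

write_result_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

#' Read a pipeline result table
#'
#' @param path TSV written by [run_pipeline()] (skips the `#` header).
#' @return `data.frame`.
#' @export
read_result_tsv <- function(path)
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)

#' Run the full coupling pipeline
#'
#' Generates (or loads) a cohort and emits, under `cfg$out_dir`:
#' `demographics.tsv` (sex chi-square with adjusted residuals, age ANOVA),
#' `group_average_coupling.tsv` and `group_average_comparisons.tsv`
#' (per-group overall coupling with Fisher r-to-Z pairwise comparisons),
#' `subject_coupling_anova.tsv` and `subject_coupling_contrasts.tsv`
#' (ANCOVA of subject-level coupling on group, controlling age and sex, with
#' marginal-means contrasts), `edge_permutation.tsv` and
#' `node_permutation.tsv` (group differences with permutation p, Bonferroni
#' flags and FDR pooled across all keys of all comparisons per level),
#' `regression_report.tsv` (DMN coupling on MMSE and the CFA memory
#' composite) and `run_manifest.json`. Every TSV carries the config hash;
#' the run is byte-reproducible under a fixed seed.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with the cohort and all result tables.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(...) message("[fixelcouple] ", ...)
  cohort <- tryCatch({
    if (!is.null(cfg$cohort_dir)) read_cohort(cfg$cohort_dir)
    else generate_cohort(cfg$generator, seed = cfg$seed)
  }, error = function(e) stop("stage cohort: ", conditionMessage(e)))
  man <- cohort$manifest
  stage(nrow(man), " subjects, ", n_nodes(cohort$atlas), " nodes, ",
        sum(cohort$edges[[cfg$modalities[1]]]$present[1, ]), " fixel-SC edges")

  # (f) demographics
  demo <- tryCatch({
    chi <- chi_square_independence(table(man$sex, man$group))
    agov <- outcome_group_tests(man, "age")
    data.frame(test = c("sex_chi2", "age_anova"),
               statistic = c(chi$chi2, agov$F),
               df = c(chi$df, paste(agov$df, collapse = ",")),
               p = c(chi$p, agov$p))
  }, error = function(e) stop("stage demographics: ", conditionMessage(e)))
  write_result_tsv(demo, file.path(cfg$out_dir, "demographics.tsv"), hash)

  groups <- intersect(GROUPS, unique(man$group))
  # (a) group-average coupling + Fisher comparisons
  ga <- list(); gac <- list()
  for (mod in cfg$modalities) for (sc in cfg$scopes) {
    res <- lapply(groups, function(g)
      group_average_coupling(cohort, g, mod, sc))
    names(res) <- groups
    ga[[paste(mod, sc)]] <- data.frame(modality = mod, scope = sc,
                                       group = groups,
                                       r = vapply(res, `[[`, 1, "r"),
                                       n_edges = vapply(res, `[[`, 1, "n_edges"),
                                       p = vapply(res, `[[`, 1, "p"))
    prs <- lapply(cfg$group_pairs, function(pr) {
      a <- res[[pr[1]]]; b <- res[[pr[2]]]
      fz <- fisher_z_compare(a$r, a$n_edges, b$r, b$n_edges)
      data.frame(modality = mod, scope = sc,
                 pair = paste(pr, collapse = "-"), z = fz$z, p = fz$p)
    })
    gac[[paste(mod, sc)]] <- do.call(rbind, prs)
  }
  ga <- do.call(rbind, c(ga, list(make.row.names = FALSE)))
  gac <- do.call(rbind, c(gac, list(make.row.names = FALSE)))
  write_result_tsv(ga, file.path(cfg$out_dir, "group_average_coupling.tsv"),
                   hash)
  write_result_tsv(gac, file.path(cfg$out_dir,
                                  "group_average_comparisons.tsv"), hash)
  stage("group-average coupling done (", nrow(ga), " rows)")

  # (b) subject-level coupling ANCOVA + contrasts
  an <- list(); ctr <- list()
  for (mod in cfg$modalities) for (sc in cfg$scopes) {
    sco <- cohort_subject_coupling(cohort, mod, sc, cfg$fc_sign)
    d <- cbind(sco, man[match(sco$subject_id, man$subject_id),
                        c("age", "sex")])
    res <- tryCatch(ancova_group_effect(d),
                    error = function(e) stop("stage ancova: ",
                                             conditionMessage(e)))
    an[[paste(mod, sc)]] <- data.frame(modality = mod, scope = sc,
                                       F = res$F, df1 = res$df1,
                                       df2 = res$df2, p = res$p)
    ctr[[paste(mod, sc)]] <- cbind(modality = mod, scope = sc,
                                   res$contrasts)
  }
  an <- do.call(rbind, c(an, list(make.row.names = FALSE)))
  ctr <- do.call(rbind, c(ctr, list(make.row.names = FALSE)))
  write_result_tsv(an, file.path(cfg$out_dir, "subject_coupling_anova.tsv"),
                   hash)
  write_result_tsv(ctr, file.path(cfg$out_dir,
                                  "subject_coupling_contrasts.tsv"), hash)
  stage("subject-level ANCOVA done")

  # (c)/(d) edge and node permutation tests, FDR pooled per level
  perm_tabs <- list()
  for (lev in c("edge", "node")) {
    tabs <- list()
    k <- 0L
    for (mod in cfg$modalities) for (pr in cfg$group_pairs) {
      k <- k + 1L
      pt <- permutation_test(cohort, pr[1], pr[2], lev, mod,
                             n_perm = cfg$n_perm,
                             seed = cfg$seed + 1000L * k)
      tabs[[k]] <- cbind(modality = mod, pair = paste(pr, collapse = "-"),
                         as.data.frame(pt))
    }
    tab <- do.call(rbind, c(tabs, list(make.row.names = FALSE)))
    tab$q_fdr <- bh_fdr(tab$p)  # across all keys of all comparisons
    tab <- tab[!is.na(tab$p), ]
    write_result_tsv(tab, file.path(cfg$out_dir,
                                    paste0(lev, "_permutation.tsv")), hash)
    perm_tabs[[lev]] <- tab
    stage(lev, "-wise permutation done (", nrow(tab), " keys, ",
          sum(tab$passes_bonferroni), " pass Bonferroni, ",
          sum(tab$q_fdr < 0.05), " pass FDR)")
  }

  # (e) cognition regressions
  reg <- tryCatch(cognition_report(cohort, cfg$modalities),
                  error = function(e) stop("stage cognition: ",
                                           conditionMessage(e)))
  write_result_tsv(reg, file.path(cfg$out_dir, "regression_report.tsv"),
                   hash)
  stage("cognition regressions done")

  manifest <- list(config_hash = hash, seed = cfg$seed,
                   package_version =
                     as.character(utils::packageVersion("fixelcouple")),
                   n_subjects = nrow(man),
                   n_nodes = n_nodes(cohort$atlas),
                   modalities = cfg$modalities, scopes = cfg$scopes,
                   n_perm = cfg$n_perm)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, demographics = demo,
                 group_average = ga, group_average_comparisons = gac,
                 anova = an, contrasts = ctr,
                 edge_permutation = perm_tabs$edge,
                 node_permutation = perm_tabs$node,
                 regressions = reg, config_hash = hash))
}
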