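test_that("generated atlas has the configured structure", {
  atl <- generate_atlas(generator_config())
  expect_equal(n_nodes(atl), 119)
  expect_equal(sum(atl$is_dmn), 24)
  expect_setequal(unique(atl$network),
                  c("Default", "Visual", "Somatomotor", "DorsAttn",
                    "SalVentAttn", "Limbic", "Cont", "Subcortical"))
  expect_equal(sum(atl$network == "Subcortical"), 19)
  atl10 <- generate_atlas(generator_config(n_nodes = 10, dmn_size = 3))
  expect_equal(sum(atl10$is_dmn), 3)
  # atlas construction is deterministic given the config
  expect_identical(generate_atlas(generator_config()), atl)
})

test_that("fixel SC mask matches the template-tractogram edge count", {
  coh <- full_cohort()
  pres <- coh$edges$FD$present
  expect_equal(sum(pres[1, ]), 5922)
  # one shared mask for fixel SC across all subjects
  expect_true(all(apply(pres, 2, function(col) all(col) || !any(col))))
  # streamline masks are denser and vary across subjects
  scount <- rowSums(coh$edges$streamline$present)
  expect_gt(mean(scount), 5922 - 800)
  expect_gt(sd(scount), 100)
  # full-density config leaves no missing SC edge
  cfg1 <- generator_config(n_per_group = c(CN = 2, MCI = 2, AD = 2),
                           n_nodes = 8, dmn_size = 3,
                           sc_density_fixel = 1)
  coh1 <- generate_cohort(cfg1, seed = 4)
  expect_true(all(coh1$edges$FDC$present))
})

test_that("FDC equals FD x FbC elementwise before streamline weighting", {
  coh <- small_cohort()
  tpl <- coh$ground_truth$template
  pr <- tpl$present; ns <- tpl$n_stream
  for (i in c(1, 9)) {
    fd <- coh$edges$FD$values[i, pr] / ns[pr]
    fbc <- exp(coh$edges$logFbC$values[i, pr] / ns[pr])
    fdc <- coh$edges$FDC$values[i, pr] / ns[pr]
    expect_equal(fdc, fd * fbc, tolerance = 1e-12)
  }
})

test_that("cohorts are reproducible under a seed and differ across seeds", {
  cfg <- generator_config(n_per_group = c(CN = 5, MCI = 4, AD = 3),
                          n_nodes = 10, dmn_size = 3, n_planted_edges = 1)
  a <- generate_cohort(cfg, seed = 21)
  b <- generate_cohort(cfg, seed = 21)
  c <- generate_cohort(cfg, seed = 22)
  expect_identical(a$edges, b$edges)
  expect_identical(a$manifest, b$manifest)
  expect_false(identical(a$edges$FC$values, c$edges$FC$values))
  expect_false(identical(a$manifest$age, c$manifest$age))
})

test_that("FC is signed, complete, and on a bounded Fisher-Z scale", {
  coh <- small_cohort()
  fc <- coh$edges$FC
  expect_true(all(fc$present))
  expect_true(all(is.finite(fc$values)))
  expect_gt(sum(fc$values < 0), 0)
  expect_gt(mean(abs(fc$values) < 1.5), 0.95)
})

test_that("null generator gives zero expected coupling at every level", {
  cfg <- null_config(n_per_group = c(CN = 60, MCI = 60, AD = 10),
                     n_nodes = 60, dmn_size = 10)
  coh <- generate_cohort(cfg, seed = 31)
  sc <- cohort_subject_coupling(coh, "FD")
  # mean subject coupling within 3 SE of zero; the SE combines the
  # per-subject spread with the shared template-profile term, whose
  # variance scales with the FC profile share over the edge count
  ne <- mean(sc$n_pairs)
  se <- sqrt(0.9 / ne + var(sc$r) / nrow(sc))
  expect_lt(abs(mean(sc$r)), 3 * se)
  nr <- node_wise_coupling(coh, "CN", "FD")
  expect_lt(abs(mean(nr, na.rm = TRUE)), 3 * sd(nr, na.rm = TRUE) /
              sqrt(sum(!is.na(nr))))
})

test_that("planted edge slopes put the planted edges on top", {
  cfg <- generator_config(n_per_group = c(CN = 100, MCI = 100, AD = 10),
                          n_nodes = 25, dmn_size = 12,
                          profile_rho = c(CN = 0, MCI = 0, AD = 0),
                          n_planted_edges = 10,
                          edge_slope = c(CN = 0.8, MCI = 0, AD = 0))
  coh <- generate_cohort(cfg, seed = 41)
  planted <- coh$ground_truth$planted_edges
  r_cn <- edge_wise_coupling(coh, "CN", "FD")
  r_mci <- edge_wise_coupling(coh, "MCI", "FD")
  d <- abs(r_cn - r_mci)
  top <- order(d, decreasing = TRUE)[seq_along(planted)]
  expect_setequal(top, planted)
  expect_true(all(r_cn[planted] > 0))
})

test_that("cognition wiring follows the planted effects", {
  # zero effect: DMN-coupling beta is null
  cfg0 <- null_config(n_per_group = c(CN = 80, MCI = 50, AD = 20),
                      n_nodes = 16, dmn_size = 5,
                      ravlt_missing_frac = c(CN = 0, MCI = 0, AD = 0),
                      mmse_missing_frac = c(CN = 0, MCI = 0, AD = 0),
                      cognition_group_shift = c(CN = 0, MCI = 0, AD = 0),
                      mmse_group_shift = c(CN = 0, MCI = 0, AD = 0))
  coh0 <- generate_cohort(cfg0, seed = 51)
  rep0 <- cognition_regression(coh0, "FD", "memory")
  betas <- rep0$beta[rep0$is_coupling_term]
  expect_true(all(abs(betas) < 0.25))
  # planted group ordering separates all groups at study sizes
  coh <- full_cohort()
  ot <- outcome_group_tests(coh$manifest, "mmse")
  expect_true(all(ot$tukey$p_adj < 0.05))
  expect_true(all(ot$wilcoxon$q_fdr < 0.05))
  mem <- memory_composite(coh)
  gm <- tapply(mem, coh$manifest$group, mean, na.rm = TRUE)
  expect_true(gm["CN"] > gm["MCI"] && gm["MCI"] > gm["AD"])
})

test_that("missingness matches the configured completer counts", {
  coh <- full_cohort()
  man <- coh$manifest
  cc <- complete.cases(man[, c("ravlt_learning", "ravlt_immediate",
                               "ravlt_delay30", "ravlt_recognition")])
  expect_equal(sum(cc), 349)
  expect_equal(unname(table(man$group[cc])[c("CN", "MCI", "AD")]),
               c(203, 127, 19), ignore_attr = TRUE)
  expect_equal(sum(is.na(man$mmse)), 1)
})

test_that("cohort round-trips through disk", {
  coh <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_equal(back$manifest$group, coh$manifest$group)
  for (mod in c("FD", "logFbC", "FDC", "streamline", "FC")) {
    expect_identical(back$edges[[mod]]$present, coh$edges[[mod]]$present)
    expect_equal(back$edges[[mod]]$values, coh$edges[[mod]]$values,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_equal(back$atlas$is_dmn, coh$atlas$is_dmn)
})
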