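make_subject <- function(sc_w, fc_w, atlas, modality = "FD") {
  mats <- list(connectome_matrix(sc_w, modality),
               connectome_matrix(fc_w, "FC"))
  names(mats) <- c(modality, "FC")
  structure(list(subject_id = "T1", matrices = mats, atlas = atlas),
            class = "subject_record")
}

sym <- function(v, n) {           # build symmetric matrix from row-major
  w <- matrix(NA_real_, n, n)     # upper-triangle values
  map <- edge_index_map(n)
  w[cbind(map$i + 1, map$j + 1)] <- v
  w[cbind(map$j + 1, map$i + 1)] <- v
  w
}

toy_atlas <- function(n, dmn = min(3, n - 1)) {
  atlas_definition(0:(n - 1), paste0("n", seq_len(n)),
                   c(rep("Default", dmn), rep("Visual", n - dmn)),
                   c(rep(TRUE, dmn), rep(FALSE, n - dmn)))
}

test_that("subject coupling hits the exact limits and the oracle", {
  atl <- toy_atlas(3)
  sc <- sym(c(1, 2, 3), 3); fc <- sym(c(1, 2, 3), 3)
  expect_equal(subject_coupling(make_subject(sc, fc, atl), "FD"), 1.0)
  fc_rev <- sym(c(3, 2, 1), 3)
  expect_equal(subject_coupling(make_subject(sc, fc_rev, atl), "FD"), -1.0)
  # seeded 500-edge vectors against the covariance-formula oracle
  set.seed(99)
  n <- 32                          # 496 edges
  atl2 <- toy_atlas(n, 5)
  scv <- rnorm(n_edges(n))^2
  scv[sample(n_edges(n), 60)] <- NA
  fcv <- rnorm(n_edges(n))
  subj <- make_subject(sym(scv, n), sym(fcv, n), atl2)
  expect_equal(subject_coupling(subj, "FD"),
               oracle_pearson(scv, fcv), tolerance = 1e-12)
  # FC edges with no SC counterpart are excluded
  expect_equal(sum(!is.na(scv)), n_edges(n) - 60)
})

test_that("too few usable pairs gives NA with a warning", {
  atl <- toy_atlas(3)
  sc <- sym(c(1, NA, NA), 3)
  fc <- sym(c(0.5, 0.2, -0.1), 3)
  expect_warning(r <- subject_coupling(make_subject(sc, fc, atl), "FD"),
                 "fewer than")
  expect_true(is.na(r))
})

test_that("FC sign filters partition the usable pairs", {
  set.seed(7)
  n <- 15
  atl <- toy_atlas(n, 4)
  scv <- rnorm(n_edges(n))^2; scv[sample(n_edges(n), 20)] <- NA
  fcv <- round(rnorm(n_edges(n), 0, 0.4), 1)   # some exact zeros
  coh_like <- make_subject(sym(scv, n), sym(fcv, n), atl)
  usable <- !is.na(scv)
  n_all <- sum(usable)
  n_pos <- sum(usable & fcv > 0)
  n_neg <- sum(usable & fcv < 0)
  n_zero <- sum(usable & fcv == 0)
  expect_equal(n_all, n_pos + n_neg + n_zero)
  expect_gt(n_zero, 0)  # zeros exist and belong to neither signed variant
  r_pos <- subject_coupling(coh_like, "FD", fc_sign_filter = "positive")
  expect_equal(r_pos, oracle_pearson(scv[usable & fcv > 0],
                                     fcv[usable & fcv > 0]),
               tolerance = 1e-12)
})

test_that("group-average coupling averages then correlates", {
  # two-subject toy on 4 nodes / 6 edges, hand-averaged oracle
  atl <- toy_atlas(4)
  sc1 <- c(1, 2, NA, 4, 5, 6); sc2 <- c(3, NA, NA, 2, 1, 8)
  fc1 <- c(0.1, 0.4, -0.2, 0.3, 0.2, 0.9)
  fc2 <- c(0.3, 0.2, -0.4, 0.1, 0.0, 0.7)
  cohort <- structure(list(
    atlas = atl,
    manifest = data.frame(subject_id = c("A", "B"), group = c("CN", "CN")),
    edges = list(FD = list(values = rbind(sc1, sc2),
                           present = rbind(!is.na(sc1), !is.na(sc2))),
                 FC = list(values = rbind(fc1, fc2),
                           present = matrix(TRUE, 2, 6)))),
    class = "fc_cohort")
  res <- group_average_coupling(cohort, "CN", "FD")
  sc_mean <- c(2, 2, NA, 3, 3, 7)        # hand per-edge means, NA ignored
  fc_mean <- (fc1 + fc2) / 2
  expect_equal(res$r, oracle_pearson(sc_mean, fc_mean), tolerance = 1e-12)
  expect_equal(res$n_edges, 5)
  # averaging is idempotent: identical subjects reproduce a single subject
  cohort$edges$FD$values[2, ] <- sc1
  cohort$edges$FD$present[2, ] <- !is.na(sc1)
  cohort$edges$FC$values[2, ] <- fc1
  expect_equal(group_average_coupling(cohort, "CN", "FD")$r,
               oracle_pearson(sc1, fc1), tolerance = 1e-12)
  expect_error(group_average_coupling(cohort, "AD", "FD"), "empty group")
})

test_that("edge-wise coupling matches a hand oracle and drops degenerate edges", {
  atl <- toy_atlas(3)
  # 5 subjects, 3 edges; edge 2 has constant SC, edge 3 partly missing
  scm <- rbind(c(1, 5, 2), c(2, 5, NA), c(3, 5, 4), c(4, 5, NA), c(5, 5, 7))
  fcm <- rbind(c(0.1, 0.2, 0.5), c(0.3, 0.1, 0.2), c(0.2, 0.4, 0.6),
               c(0.5, 0.3, 0.1), c(0.6, 0.2, 0.8))
  cohort <- structure(list(
    atlas = atl,
    manifest = data.frame(subject_id = paste0("S", 1:5),
                          group = rep("CN", 5)),
    edges = list(FD = list(values = scm, present = !is.na(scm)),
                 FC = list(values = fcm, present = matrix(TRUE, 5, 3)))),
    class = "fc_cohort")
  r <- edge_wise_coupling(cohort, "CN", "FD", min_subjects = 3)
  expect_equal(r[1], oracle_pearson(scm[, 1], fcm[, 1]), tolerance = 1e-12)
  expect_true(is.na(r[2]))                       # zero SC variance
  expect_equal(r[3], oracle_pearson(scm[, 3], fcm[, 3]), tolerance = 1e-12)
  expect_true(is.na(edge_wise_coupling(cohort, "CN", "FD",
                                       min_subjects = 4)[3]))
})

test_that("node strength is the signed sum over present incident edges", {
  w <- matrix(NA_real_, 3, 3)
  w[1, 2] <- w[2, 1] <- 1; w[1, 3] <- w[3, 1] <- 2; w[2, 3] <- w[3, 2] <- 3
  expect_equal(node_strength(connectome_matrix(w, "FD"), 0), 3)
  wf <- matrix(0, 3, 3)
  wf[1, 2] <- wf[2, 1] <- 0.5; wf[1, 3] <- wf[3, 1] <- -0.7
  wf[2, 3] <- wf[3, 2] <- 0.1
  expect_equal(node_strength(connectome_matrix(wf, "FC"), 0), -0.2)
  # exhaustive-sum oracle on random 6-node matrices, igraph as second route
  set.seed(17)
  w6 <- matrix(rnorm(36), 6, 6); w6[upper.tri(w6)] <- t(w6)[upper.tri(w6)]
  drop <- matrix(runif(36) < 0.3, 6, 6)
  drop[lower.tri(drop)] <- t(drop)[lower.tri(drop)]
  w6[drop] <- NA
  m <- connectome_matrix(w6, "logFbC")
  s <- node_strength(m)
  for (v in 0:5) expect_equal(s[v + 1], oracle_strength(m, v))
  adj <- m$weights; adj[!m$present] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  si <- igraph::strength(g)
  has_edge <- rowSums(m$present) > 0
  expect_equal(unname(s[has_edge]), unname(si[has_edge]), tolerance = 1e-12)
})

test_that("node-wise coupling reproduces per-node hand correlations", {
  coh <- small_cohort()
  ssc <- cohort_strengths(coh, "FD")
  sfc <- cohort_strengths(coh, "FC")
  rows <- which(coh$manifest$group == "CN")
  r <- node_wise_coupling(coh, "CN", "FD", min_subjects = 5)
  for (k in c(1, 6, 12))
    expect_equal(unname(r[k]), oracle_pearson(ssc[rows, k], sfc[rows, k]),
                 tolerance = 1e-12)
  # proportional strengths give r = 1
  coh2 <- coh
  coh2$edges$FC$values <- coh$edges$FD$values * 2
  coh2$edges$FC$values[is.na(coh2$edges$FC$values)] <- 0
  r1 <- node_wise_coupling(coh2, "CN", "FD", min_subjects = 5)
  expect_true(all(abs(r1[!is.na(r1)] - 1) < 1e-8))
})

test_that("subject DMN coupling separates edge and node parts", {
  atl <- toy_atlas(10, 3)
  set.seed(23)
  scv <- rnorm(45)^2
  dmn_pos <- which(scope_edges(atl, "dmn"))   # keep the 3 within-DMN edges
  scv[sample(setdiff(1:45, dmn_pos), 8)] <- NA
  fcv <- rnorm(45, 0, 0.4)
  subj <- make_subject(sym(scv, 10), sym(fcv, 10), atl)
  got <- subject_dmn_coupling(subj, "FD")
  dmn_sel <- scope_edges(atl, "dmn")
  expect_equal(got$edge,
               oracle_pearson(scv[dmn_sel], fcv[dmn_sel]), tolerance = 1e-12)
  s_sc <- vapply(0:2, function(v) oracle_strength(subj$matrices$FD, v),
                 numeric(1))
  s_fc <- vapply(0:2, function(v) oracle_strength(subj$matrices$FC, v),
                 numeric(1))
  expect_equal(got$node, oracle_pearson(s_sc, s_fc), tolerance = 1e-12)
  # identical SC and FC couple perfectly at both levels
  subj2 <- make_subject(sym(fcv, 10), sym(fcv, 10), atl, modality = "logFbC")
  got2 <- subject_dmn_coupling(subj2, "logFbC")
  expect_equal(got2$edge, 1.0)
  expect_equal(got2$node, 1.0)
  # node part uses exactly |DMN| strength pairs
  coh <- full_cohort()
  expect_equal(sum(coh$atlas$is_dmn), 24)
})

test_that("coupling is invariant to node relabeling and subject order", {
  atl <- toy_atlas(8, 3)
  set.seed(31)
  scv <- rnorm(28)^2; scv[sample(28, 5)] <- NA
  fcv <- rnorm(28)
  scm <- sym(scv, 8); fcm <- sym(fcv, 8)
  perm <- sample(8)
  atl_p <- atlas_definition(0:7, atl$label[perm], atl$network[perm],
                            atl$is_dmn[perm])
  r0 <- subject_coupling(make_subject(scm, fcm, atl), "FD", scope = "dmn")
  r1 <- subject_coupling(make_subject(scm[perm, perm], fcm[perm, perm],
                                      atl_p), "FD", scope = "dmn")
  expect_equal(r1, r0, tolerance = 1e-12)
  coh <- small_cohort()
  ord <- rev(seq_len(nrow(coh$manifest)))
  coh_r <- coh
  coh_r$manifest <- coh$manifest[ord, ]
  for (mod in names(coh$edges)) {
    coh_r$edges[[mod]]$values <- coh$edges[[mod]]$values[ord, ]
    coh_r$edges[[mod]]$present <- coh$edges[[mod]]$present[ord, ]
  }
  expect_equal(edge_wise_coupling(coh_r, "MCI", "FDC", min_subjects = 5),
               edge_wise_coupling(coh, "MCI", "FDC", min_subjects = 5))
})
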